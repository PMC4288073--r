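<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <xs:simpleType name="uuidType">
    <xs:restriction base="xs:string">
      <xs:pattern value="[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="categoryType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="radiology_report"/>
      <xs:enumeration value="operative_note"/>
      <xs:enumeration value="laboratory_result"/>
      <xs:enumeration value="pathology_report"/>
      <xs:enumeration value="endoscopy_report"/>
      <xs:enumeration value="microbiology_result"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="sexType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="M"/>
      <xs:enumeration value="F"/>
    </xs:restriction>
  </xs:simpleType>

  <!-- ages of 90 or more are reported as 89 before serialization -->
  <xs:simpleType name="ageType">
    <xs:restriction base="xs:integer">
      <xs:minInclusive value="0"/>
      <xs:maxInclusive value="89"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="scenario-document">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="family" minOccurs="0">
          <xs:complexType>
            <xs:attribute name="uuid" type="uuidType" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="scenario">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="context" type="xs:string"/>
              <xs:element name="demographics">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="sex" type="sexType"/>
                    <xs:element name="age" type="ageType"/>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="items">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="item" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:simpleContent>
                          <xs:extension base="xs:string">
                            <xs:attribute name="uuid" type="uuidType" use="required"/>
                            <xs:attribute name="category" type="categoryType" use="required"/>
                          </xs:extension>
                        </xs:simpleContent>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="uuid" type="uuidType" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="schema-version" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
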