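<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">

  <xs:simpleType name="uuidType">
    <xs:restriction base="xs:string">
      <xs:pattern value="[0-9a-f]{8}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{4}-[0-9a-f]{12}"/>
    </xs:restriction>
  </xs:simpleType>

  <!-- the 4-step relevance scale: 0-3 -->
  <xs:simpleType name="scoreType">
    <xs:restriction base="xs:integer">
      <xs:minInclusive value="0"/>
      <xs:maxInclusive value="3"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="labelType">
    <xs:restriction base="xs:string">
      <xs:enumeration value="irrelevant"/>
      <xs:enumeration value="unlikely relevant"/>
      <xs:enumeration value="probably relevant"/>
      <xs:enumeration value="certainly relevant"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:simpleType name="timestampType">
    <xs:restriction base="xs:string">
      <xs:pattern value="[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9]{2}:[0-9]{2}:[0-9]{2}Z"/>
    </xs:restriction>
  </xs:simpleType>

  <xs:element name="ratings-document">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="family">
          <xs:complexType>
            <xs:attribute name="uuid" type="uuidType" use="required"/>
            <xs:attribute name="name" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
        <xs:element name="ratings">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="rating" minOccurs="0" maxOccurs="unbounded">
                <xs:complexType>
                  <xs:attribute name="rater-uuid" type="uuidType" use="required"/>
                  <xs:attribute name="scenario-uuid" type="uuidType" use="required"/>
                  <xs:attribute name="item-uuid" type="uuidType" use="required"/>
                  <xs:attribute name="score" type="scoreType" use="required"/>
                  <xs:attribute name="label" type="labelType" use="required"/>
                  <xs:attribute name="recorded-at" type="timestampType" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
      <xs:attribute name="schema-version" type="xs:string" use="required"/>
    </xs:complexType>
  </xs:element>

</xs:schema>
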