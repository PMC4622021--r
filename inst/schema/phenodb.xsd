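<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema" elementFormDefault="qualified">
  <xs:element name="phenotypeDatabase">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="phenotype" minOccurs="0" maxOccurs="unbounded">
          <xs:complexType>
            <xs:sequence>
              <xs:element name="term" type="xs:string"/>
              <xs:element name="surface" type="xs:string"/>
              <xs:element name="annotated" type="xs:string"/>
              <xs:element name="concepts">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="concept" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="role" use="required">
                          <xs:simpleType>
                            <xs:restriction base="xs:string">
                              <xs:enumeration value="quality"/>
                              <xs:enumeration value="entity"/>
                            </xs:restriction>
                          </xs:simpleType>
                        </xs:attribute>
                        <xs:attribute name="id" type="xs:string" use="required"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="disorders">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="disorder" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="name" type="xs:string" use="required"/>
                        <xs:attribute name="supportCount" type="xs:nonNegativeInteger" use="required"/>
                        <xs:attribute name="confidence" type="xs:decimal" use="required"/>
                        <xs:attribute name="pValue" type="xs:double" use="required"/>
                      </xs:complexType>
                    </xs:element>
                  </xs:sequence>
                </xs:complexType>
              </xs:element>
              <xs:element name="occurrences">
                <xs:complexType>
                  <xs:sequence>
                    <xs:element name="doc" minOccurs="0" maxOccurs="unbounded">
                      <xs:complexType>
                        <xs:attribute name="pmid" type="xs:string" use="required"/>
                        <xs:attribute name="sentence" type="xs:nonNegativeInteger" use="required"/>
                        <xs:attribute name="pattern" type="xs:string" use="required"/>
                      </xs:complexType>
                    </xs:element>
                    <xs:element name="pmid" type="xs:string" minOccurs="0" maxOccurs="unbounded"/>
                  </xs:sequence>
                  <xs:attribute name="df" type="xs:nonNegativeInteger" use="required"/>
                </xs:complexType>
              </xs:element>
            </xs:sequence>
            <xs:attribute name="id" type="xs:string" use="required"/>
          </xs:complexType>
        </xs:element>
      </xs:sequence>
    </xs:complexType>
  </xs:element>
</xs:schema>
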