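<?xml version="1.0" encoding="UTF-8"?>
<xs:schema xmlns:xs="http://www.w3.org/2001/XMLSchema"
           targetNamespace="urn:apterms:observation:1"
           xmlns:o="urn:apterms:observation:1"
           elementFormDefault="qualified">

  <xs:complexType name="Code">
    <xs:attribute name="code" type="xs:string" use="required"/>
    <xs:attribute name="codeSystem" type="xs:string" use="required"/>
    <xs:attribute name="displayName" type="xs:string" use="required"/>
    <xs:attribute name="approximate" type="xs:boolean"/>
  </xs:complexType>

  <xs:complexType name="CodedElement">
    <xs:sequence>
      <xs:element name="code" type="o:Code"/>
    </xs:sequence>
    <xs:attribute name="relationship" type="xs:string"/>
  </xs:complexType>

  <xs:complexType name="ContextType">
    <xs:sequence>
      <xs:element name="locator" type="o:CodedElement" minOccurs="0"/>
      <xs:element name="problemOrganizer" type="o:CodedElement" minOccurs="0"/>
      <xs:element name="method" type="o:CodedElement" minOccurs="0"/>
    </xs:sequence>
  </xs:complexType>

  <xs:complexType name="QuantityType">
    <xs:attribute name="value" type="xs:decimal" use="required"/>
    <xs:attribute name="unit" type="xs:string" use="required"/>
  </xs:complexType>

  <xs:complexType name="ValueType">
    <xs:choice>
      <xs:element name="code" type="o:Code"/>
      <xs:element name="quantity" type="o:QuantityType"/>
    </xs:choice>
  </xs:complexType>

  <xs:element name="observation">
    <xs:complexType>
      <xs:sequence>
        <xs:element name="context" type="o:ContextType"/>
        <xs:element name="target" type="o:CodedElement"/>
        <xs:element name="property" type="o:CodedElement"/>
        <xs:element name="qualifier" type="o:CodedElement"
                    minOccurs="0" maxOccurs="unbounded"/>
        <xs:element name="value" type="o:ValueType" minOccurs="0"/>
      </xs:sequence>
    </xs:complexType>
  </xs:element>

</xs:schema>
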