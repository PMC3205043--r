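# Structural vocabulary for the relaxed (third-generation) CML schema subset.
#
# Communities can extend the element set without code changes: point
# cml_vocabulary() at a file of this shape. Attribute entries are either a
# bare datatype (string, integer, real, qname-ref) or a map with `datatype`
# plus `values` (enumeration) or `n` (token-list).
namespace: http://www.xml-cml.org/schema
# Mixed-content legacy elements removed from the schema entirely.
obsoleted: [annotation, appinfo, documentation, relatedEntry]
# Generic attributes admitted on every CML element.
global_attributes:
  id: string
  title: string
  dictRef: qname-ref
  convention: qname-ref
  ref: string
elements:
  molecule:
    attributes:
      formalCharge: integer
      spinMultiplicity: integer
      count: real
      chirality: string
  atomArray: {}
  atom:
    attributes:
      elementType: string
      x3: real
      y3: real
      z3: real
      formalCharge: integer
      isotopeNumber: integer
      occupancy: real
      count: real
  bondArray: {}
  bond:
    attributes:
      atomRefs2: {datatype: token-list, n: 2}
      # numeric aliases are tolerated structurally but deprecated
      order: {datatype: enumeration, values: ["S", "D", "T", "A", "1", "2", "3"]}
  unitList: {}
  unit:
    attributes:
      unitType: qname-ref
      symbol: string
      multiplierToSI: real
      constantToSI: real
  unitType:
    attributes:
      symbol: string
  dictionary:
    attributes:
      namespace: string
  entry:
    attributes:
      term: string
      dataType: string
  definition: {content: text-only}
  description: {content: text-only}
  module:
    attributes:
      role: string
  property: {}
  parameter:
    attributes:
      name: string
  scalar:
    content: text-only
    attributes:
      dataType: string
      units: qname-ref
  list:
    attributes:
      type: string
  name: {content: text-only}
  label:
    content: text-only
    attributes:
      value: string
  formula:
    attributes:
      concise: string
      formalCharge: integer
  spectrum:
    attributes:
      type: {datatype: enumeration, values: ["infrared", "massSpectrum", "NMR", "UV/VIS", "other"]}
  peakStructure:
    attributes:
      type: {datatype: enumeration, values: ["coupling", "splitting", "other"]}
  cellParameter:
    attributes:
      type: {datatype: enumeration, values: ["length", "angle"]}
  crystal:
    attributes:
      z: integer
  reaction:
    attributes:
      type: {datatype: enumeration, values: ["chainReaction", "initiation", "termination", "reversible", "other"]}
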