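# cmlcheck

Layered validation for Chemical Markup Language (CML) documents, plus the
implicit chemistry semantics of CML molecules.

CML (namespace `http://www.xml-cml.org/schema`) deliberately keeps its
schema permissive — most elements accept any CML, foreign-namespace or
no-namespace children in any order — and pushes chemistry-specific
constraints into *conventions*: URI-identified MUST/SHOULD/MAY rule sets
that a document opts into with a `convention` attribute, scoped to that
element and all its descendants. Tools consuming CML (editors, repository
importers, computational-chemistry pipelines) need a validator that checks
a document *before* it reaches them, and a report precise enough to act on.

`cmlcheck` is that validator, for R. It runs four checks in order, stopping
at the first failure:

1. **well-formed-test** — XML well-formedness;
2. **schema-validation-test** — CML vocabulary membership, the relaxed
   ("any CML + foreign, no mixed content") content model, attribute
   datatypes/enumerations, and deprecated constructs (numeric bond orders
   `'1'/'2'/'3'` warn);
3. **convention-validation-test** — scoped convention handlers, with
   built-in rules for the **simpleUnit**, **molecular**, **compchem** and
   **unit-dictionary** conventions;
4. **uris-reachable-test** — every QName-valued attribute (`dictRef`,
   `convention`, `unitType`) must use a bound prefix and expand to a
   resolvable URI.

Findings (`error` > `warning` > `info`) aggregate to a single verdict:
**INVALID**, **VALID_WITH_WARNINGS** or **VALID**; reports serialize into
the report namespace `http://www.xml-cml.org/report/` with machine-usable
location paths of the form
`/*[local-name() = 'unitList' and namespace-uri() = '...'][1]`.

The package also implements the implicit chemistry semantics of molecule
documents:

* **effective formal charge** — an explicit `formalCharge` wins, otherwise
  the recursive aggregate
  `sum(child_charge · child_count) + sum(atom_charge · occupancy · count)`,
  with absent atom charges contributing 0 and non-integral totals rejected;
* **bond perception** — atoms *i*, *j* are bonded when
  `d(i, j) ≤ r(elem_i) + r(elem_j) + tol` with standard single-bond
  covalent radii (H 0.37, C 0.77, N 0.75, O 0.73, …) and `tol = 0.40`;
* **average bond length** — the arithmetic mean of Euclidean bond lengths.

## Worked example

Validate a unit list that declares the simpleUnit convention and also
contains a stray `molecule` element:

```r
library(cmlcheck)

doc <- '
<cml:unitList xmlns:cml="http://www.xml-cml.org/schema"
              xmlns:conventions="http://www.xml-cml.org/convention/"
              convention="conventions:simpleUnit">
  <cml:unit/>
  <cml:molecule/>
</cml:unitList>'

report <- cml_validate(doc)
report
#> <cml_report> VALID
#>   well-formed-test
#>     [valid] xml is well formed
#>   schema-validation-test
#>     [valid] document conforms to the schema
#>   convention-validation-test
#>     [info] molecule is not a part of the http://www.xml-cml.org/convention/simpleUnit convention and may be ignored by some processors.
#>     [valid] document conforms to all the conventions specified
#>   uris-reachable-test
#>     [valid] All appropriate URIs were reachable
#>     [valid] all dictRefs are resolvable

glance(report)
#> # A tibble: 1 × 5
#>   result n_sections n_error n_warning n_info
#>   <chr>       <int>   <int>     <int>  <int>
#> 1 VALID           4       0         0      1
```

The document is VALID — the stray `molecule` is allowed by the relaxed
schema and merely *not part of* the declared convention, so it earns an
informational finding (which never demotes the verdict). `tidy(report)`
returns one row per finding; `serialize_report(report)` emits the report
XML; `autoplot(report)` draws the findings per section.

Chemistry semantics on the packaged five-atom reference molecule
(C, N, O and two H with Cartesian coordinates):

```r
mol <- molecule_view(mol5_document())
bonds <- perceive_bonds(mol)
bonds
#> # A tibble: 4 × 3
#>   atom1 atom2 length
#>   <chr> <chr>  <dbl>
#> 1 a1    a2      1.3
#> 2 a1    a4      1.12
#> 3 a1    a5      1.12
#> 4 a2    a3      1.35
average_bond_length(mol, bonds)
#> [1] 1.223502
```

Four bonds are perceived (C–N, N–O and two C–H; every other pair exceeds
its radius-sum threshold) and their mean length is 1.2235 coordinate units.

A command-line wrapper is installed at `inst/cli/cml-validate`
(`cml-validate <file> [--format xml|text]`; exit code 0 = VALID,
1 = VALID_WITH_WARNINGS, 2 = INVALID, 3 = usage error).

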