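---
title: "Layered validation of CML documents: model, conventions and chemistry semantics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered validation of CML documents}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cmlcheck)
```

## The validation model

Chemical Markup Language (CML, namespace `http://www.xml-cml.org/schema`)
documents mix chemistry content with foreign-namespace and no-namespace
markup. The third-generation CML schema is deliberately relaxed: most CML
elements accept any CML, foreign or no-namespace children, in any order and
cardinality, with no mixed content. Nearly all chemistry-specific
constraints therefore live in *conventions*: URI-identified rule sets that
a document opts into by putting a QName in a `convention` attribute, whose
scope is that element and all of its descendants.

`cml_validate()` runs four checks in a fixed order, and stops at the first
check that produces an error ("fail fast"; sections never reached are
omitted from the report):

1. **well-formed-test** — XML well-formedness. An already-parsed tree is
   necessarily well-formed and passes directly, so a byte stream and its
   parsed tree always yield identical reports.
2. **schema-validation-test** — vocabulary membership (a CML-namespace
   element must be a known CML element), the relaxed content model (no
   mixed content in CML elements; whitespace-only text does not count),
   attribute admissibility and datatypes (integers, reals, QName tokens,
   token lists, closed enumerations such as `cellParameter/@type` in
   `{length, angle}`), and deprecated constructs. Deprecated forms —
   currently the numeric bond-order aliases `'1'/'2'/'3'` — are warnings in
   this section, because they are schema-level legacy spellings; a section
   holding warnings is not marked valid but does not stop the workflow.
3. **convention-validation-test** — convention discovery and the per-scope
   handlers (below). Declaring no convention at all is a warning.
4. **uris-reachable-test** — every QName-valued attribute (`convention`,
   `dictRef`, `unitType`, as classified by the vocabulary) must use a bound
   prefix (error otherwise) and its expanded URI is queried through a
   resolver (unreachable is a warning, not an error: a bound but
   temporarily unreachable dictionary should not invalidate a document).

Findings aggregate to a single result: any error means `INVALID`, otherwise
any warning means `VALID_WITH_WARNINGS`, otherwise `VALID`. Informational
findings never affect the result. Reports serialize into the report
namespace `http://www.xml-cml.org/report/`, with one element per section
and one element per finding, named by severity, carrying the message as
text and the cited node's location path in a `location` attribute.

Location paths use a namespace-neutral dialect so they remain stable under
prefix renaming: each element step is
`/*[local-name() = 'N' and namespace-uri() = 'U'][k]`, where `k` indexes
same-named preceding siblings, and an attribute terminates the path with
`@*[local-name() = 'N' and namespace-uri() = 'U']` appended directly to the
element step. The index counts siblings with the same *expanded* name
rather than all siblings, which makes the step unambiguous on its own. The
attribute step is attached without a `/` separator; tooling that wants to
evaluate a path as XPath should insert `/` before `@*`.

## Convention scoping

Traversal starts outside any scope and descends silently through elements
that declare nothing. A CML element bearing a `convention` attribute hands
its whole subtree to the matching handler; inside a scope, traversal passes
through foreign and no-namespace elements without comment, and every CML
element anywhere below — even below foreign elements — is subject to the
handler's rules. A descendant that declares its own convention supersedes
the outer handler for its subtree, which is how the compchem convention
delegates its molecules to the molecular convention. Because scopes are
subtrees, two scopes either nest or are disjoint; a "crossing" overlap
cannot be expressed by an attribute-scoped declaration, so no rejection
path is needed for it. Unknown convention URIs produce an informational
finding and the subtree is traversed out of mode: informing the user is
the most useful default for rules the validator does not know.

Handlers report three kinds of findings. Violations of MUST rules are
errors; violations of SHOULD rules are warnings; CML elements that are
merely not part of the convention (MAY territory) are informational, phrased
as "`<name>` is not a part of the `<uri>` convention and may be ignored by
some processors." Dispatch is restricted to elements in the CML namespace:
a `convention` attribute on a foreign element is inert, matching the
convention machinery's own definition of its domain.

Built-in handlers:

* **simpleUnit** (`.../convention/simpleUnit`) — may only be declared on
  `cml:unitList` (declaring it elsewhere is an error cited at the
  `convention` attribute, after which the subtree is processed out of mode
  so no secondary findings pile up); every in-scope unit list must have at
  least one *direct* `cml:unit` child; `unit` elements are silent; other
  CML elements are informational.
* **molecular** (`.../convention/molecular`) — molecules must contain at
  least one of molecule/atomArray/name/label/formula, must not mix child
  molecules with an atomArray, and may hold at most one bondArray;
  atomArrays and bondArrays must be non-empty; atoms need an `id`, unique
  within the *eldest containing molecule* (the outermost molecule
  ancestor-or-self — also the scope in which bond references are resolved);
  Cartesian coordinates are all-or-none (`x3` implies `y3` and `z3`); bonds
  must reference two distinct existing atoms in the same eldest molecule.
* **compchem** (`.../convention/compchem`) — there must be an
  initialization module (a `cml:module` whose `dictRef` expands to
  `http://xml-cml.org/dictionary/compchem/initialization`; any prefix bound
  to that dictionary URI is accepted, since QName comparison is by expanded
  value); it must contain exactly one molecule, which must declare the
  molecular convention, have an atomArray child, and whose atoms must all
  carry x3/y3/z3.
* **unit-dictionary** (`.../convention/unit-dictionary`) — entries must
  have a definition and at most one description; units must have an `id`;
  a dictionary without a `title` earns a warning.

## Chemistry semantics

Three operations implement the implicit semantics of molecule documents.

**Effective formal charge.** An explicit `formalCharge` on a molecule wins.
Otherwise the charge is aggregated recursively as
`sum(child_charge * child_count) + sum(atom_charge * occupancy * count)`,
with atoms lacking a `formalCharge` contributing zero — the minimal reading
of an attribute that is simply absent. Fractional occupancies can make the
aggregate non-integral; that is reported as an error
(`cml_nonintegral_charge_error`) rather than silently rounded, because a
fractional total always indicates an inconsistent model.

**Bond perception.** Two atoms are bonded when their Euclidean separation
is at most the sum of their single-bond covalent radii plus a tolerance.
The packaged table (H 0.37, C 0.77, N 0.75, O 0.73, ... ; tolerance 0.40,
all in coordinate units) uses standard single-bond radii; both table and
tolerance are loadable from YAML for other unit systems. The rule is
symmetric, produces no self-bonds, and returns bonds in a canonical order
(sorted id pairs) so results are reproducible under atom reordering.

**Average bond length** is the arithmetic mean of the Euclidean bond
lengths, and requires every referenced atom to have all three coordinates
(`cml_missing_coordinates_error` otherwise; `cml_no_bonds_error` on zero
bonds). On the packaged five-atom reference molecule the perceived bond set
is `{a1–a2, a2–a3, a1–a4, a1–a5}` and the average is 1.2235 (to four
decimals):

```{r mol5}
mol <- molecule_view(mol5_document())
bonds <- perceive_bonds(mol)
bonds
average_bond_length(mol, bonds)
```

## The fixture corpus

`fixture_corpus()` generates every test document in code — 11 unit-list
documents expected `VALID` with no informational findings, 5 expected
`VALID` with exactly one informational finding, 7 expected `INVALID` with
exactly one error, 4 namespace-membership documents for the structural
layer, the reference molecule, synthetic all-rules-pass documents for the
molecular, compchem and unit-dictionary conventions, and one
mutation-derived failing document per implemented rule
(`mutate_fixture()`). Generating fixtures programmatically keeps prefix and
namespace variants systematic (the same document is produced with default,
explicit and foreign-prefixed bindings) and keeps every expected finding
next to the document that provokes it. `cml_write_corpus()` materializes
the corpus as `.cml` files with a YAML manifest for use outside R.

What the corpus does *not* emulate: real-world documents are far larger,
mix many more CML elements (the full schema has on the order of a hundred),
and carry encoding oddities; the packaged vocabulary covers the element
subset the built-in conventions touch, and is an explicit extension point
(`cml_vocabulary()` accepts a user file) rather than a complete schema.
Passing the corpus therefore demonstrates the scoping, reporting and rule
semantics, not coverage of every CML element in the wild.

## Numerical and design choices

* The bond-perception criterion (radius sum + 0.40 tolerance) is a
  documented choice validated against the reference molecule; distance
  comparisons use `<=` so borderline pairs bond.
* Formal-charge integrality is checked to 1e-9 before rounding.
* Rigid-motion invariance of the average bond length holds to 1e-9 in the
  test suite (double precision; no tolerance tuning).
* The report's `valid` marks are appended at section close, after all
  findings, so informational findings print before the valid mark, and a
  section with warnings or errors is never marked valid.
* Offline resolution treats any absolute URI (scheme + non-empty remainder)
  as reachable. This keeps the distributed suite deterministic; an
  HTTP-backed resolver can be passed in where real reachability matters.
* The property suites run at fixed seeds with 200 random molecule trees of
  depth ≤ 4 (charges −3..3, counts 1..3) and a handful of random wrappings
  per valid document — sizes chosen so the whole suite exercises every rule
  while staying quick on a laptop.

## Known limitations

* The vocabulary is a subset; unknown CML elements outside it are reported
  as schema errors, which is the desired strictness for the covered
  conventions but means extending to new CML element sets requires a
  vocabulary file.
* Spectroscopy and solid-state conventions are not implemented.
* DTDs, XInclude and schema-driven parsing are out of scope; text nodes are
  preserved but never cited in findings (only elements and attributes carry
  locations).
* The unit/unitType/dictionary "standard" conventions are implemented only
  to the depth of the published rules (definitions, descriptions, unit ids,
  dictionary titles).
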