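# Programmatic fixture corpus: every document with a known expected outcome
# that the validator is developed and regression-tested against, generated
# in code so namespace/prefix variants can be produced systematically.

XMLNS_CML <- c("xmlns:cml" = "http://www.xml-cml.org/schema")
XMLNS_CONVENTIONS <- c("xmlns:conventions" = "http://www.xml-cml.org/convention/")
XMLNS_X <- c("xmlns:x" = "http://www.w3.org/1999/xhtml")
XMLNS_COMPCHEM <- c("xmlns:compchem" = "http://xml-cml.org/dictionary/compchem/")

# Minimal XML writer used only to *generate* fixture documents.
xel <- function(name, attrs = character(), ...) {
  children <- unlist(list(...), use.names = FALSE)
  a <- if (length(attrs)) {
    paste0(" ", names(attrs), "=\"", escape_attr(attrs), "\"", collapse = "")
  } else ""
  if (is.null(children) || !length(children)) {
    paste0("<", name, a, "/>")
  } else {
    paste0("<", name, a, ">", paste0(children, collapse = ""),
           "</", name, ">")
  }
}

su_info_message <- function(local) {
  paste0(local, " is not a part of the ", CONV_SIMPLEUNIT,
         " convention and may be ignored by some processors.")
}

MSG_SU_CHILD <- "A unit list MUST contain child cml:unit elements"
MSG_SU_DECLARING <-
  "the only valid cml element that can specify the simpleUnit convention is \"unitList\""

expected_finding <- function(severity, message, location = NA_character_,
                             match = "exact") {
  tibble(severity = severity, message = message, location = location,
         match = match)
}

no_expected <- function() {
  tibble(severity = character(), message = character(),
         location = character(), match = character())
}

fixture_row <- function(id, provenance, document, expected_result,
                        expected_findings = no_expected(), strict = TRUE) {
  tibble(id = id, provenance = provenance, document = document,
         expected_result = expected_result,
         expected_findings = list(expected_findings), strict = strict)
}

step <- function(local, ns = CML_NS, k = 1) element_step(local, ns, k)

simpleunit_fixtures <- function() {
  d <- c(XMLNS_CML, XMLNS_CONVENTIONS)
  su <- c(convention = "conventions:simpleUnit")
  ul <- function(attrs, ...) xel("cml:unitList", attrs, ...)
  unit <- xel("cml:unit")
  xp <- function(...) xel("x:p", XMLNS_X, ...)

  valid <- list(
    ul(c(d, su), unit),
    xp(ul(c(XMLNS_CML, XMLNS_CONVENTIONS, su), unit)),
    xel("cml:module", d, ul(su, unit)),
    xel("element-in-default-namespace", d, ul(su, unit)),
    xp("the unitList need not be the root element",
       ul(c(XMLNS_CML, XMLNS_CONVENTIONS, su), unit)),
    xp("there are multiple instances of the simpleUnit convention in this document",
       ul(c(XMLNS_CML, XMLNS_CONVENTIONS, su), unit),
       ul(c(XMLNS_CML, XMLNS_CONVENTIONS, su), unit)),
    ul(c(d, su), unit, xp("non cml child-this is fine")),
    ul(c(d, su), xel("element-in-default-namespace"), unit),
    ul(c(d, su), xel("cml:unit", character(),
                     xp("non cml child-this is fine"))),
    ul(c(d, su), xel("cml:unit", character(),
                     xel("element-in-default-namespace"))),
    ul(c(d, su), unit,
       xel("cml:unit", character(), xp("multiple cml:unit elements are allowed")))
  )

  info_loc1 <- paste0(step("unitList"), step("molecule"))
  info <- list(
    list(ul(c(d, su), unit, xel("cml:molecule")),
         expected_finding("info", su_info_message("molecule"), info_loc1)),
    list(ul(c(d, su), xel("cml:unit", character(), xel("cml:atom"))),
         expected_finding("info", su_info_message("atom"))),
    list(ul(c(d, su), unit, xel("cml:unit", character(), xel("cml:bond"))),
         expected_finding("info", su_info_message("bond"))),
    list(ul(c(d, su),
            xel("cml:unit", character(),
                xp("this is still going to be processed in unitList mode.",
                   xel("cml:bond")))),
         expected_finding("info", su_info_message("bond"))),
    list(xp("the unitList need not be the root element",
            ul(c(XMLNS_CML, XMLNS_CONVENTIONS, su), xel("cml:molecule"), unit)),
         expected_finding("info", su_info_message("molecule")))
  )

  invalid_loc1 <- paste0(step("molecule"),
                         attribute_step("convention", ""))
  invalid <- list(
    list(xel("cml:molecule", c(d, su), ul(character(), unit)),
         expected_finding("error", MSG_SU_DECLARING, invalid_loc1)),
    list(xp(xel("cml:molecule", c(XMLNS_CML, XMLNS_CONVENTIONS, su),
                ul(character(), unit))),
         expected_finding("error", MSG_SU_DECLARING)),
    list(ul(c(d, su)),
         expected_finding("error", MSG_SU_CHILD)),
    list(paste0("<cml:unitList xmlns:cml=\"", CML_NS,
                "\" xmlns:conventions=\"", CONVENTION_BASE,
                "\" convention=\"conventions:simpleUnit\">",
                "<!-- not valid, a unitList must have at least one unit child -->",
                "</cml:unitList>"),
         expected_finding("error", MSG_SU_CHILD)),
    list(ul(c(d, su), xp("no unit child of unitList")),
         expected_finding("error", MSG_SU_CHILD)),
    list(ul(c(d, su), xp(unit,
                         "This unit is not a direct child of unitList and therefore should cause an error.")),
         expected_finding("error", MSG_SU_CHILD)),
    list(ul(c(d, su),
            ul(character(),
               xel("cml:unit", character(),
                   xp("the outer unitList does not have at least one unit child")))),
         expected_finding("error", MSG_SU_CHILD))
  )

  bind_rows(
    map_dfr(seq_along(valid), function(i) {
      fixture_row(sprintf("simpleunit-valid-%02d", i), "appendixB-valid",
                  valid[[i]], "VALID")
    }),
    map_dfr(seq_along(info), function(i) {
      fixture_row(sprintf("simpleunit-info-%02d", i), "appendixB-info",
                  info[[i]][[1]], "VALID", info[[i]][[2]])
    }),
    map_dfr(seq_along(invalid), function(i) {
      fixture_row(sprintf("simpleunit-invalid-%02d", i), "appendixB-invalid",
                  invalid[[i]][[1]], "INVALID", invalid[[i]][[2]])
    })
  )
}

schema_test_fixtures <- function() {
  no_conv <- expected_finding("warning",
                              "no conventions are declared in the document")
  vocab_err <- function(k = 1) expected_finding(
    "error", "the element 'non-cml-element' does not appear in the schema"
  )
  docs <- list(
    xel("cml:molecule", XMLNS_CML,
        xel("element-in-default-namespace", character(),
            paste("This is fine. The null prefix is not bound to anything",
                  "and therefore is associated with the default namespace"))),
    xel("molecule", c(xmlns = CML_NS, "xmlns:other" = "http://www.example.net"),
        xel("other:foreign-element", character(),
            paste("This is fine. The null prefix is bound to the CML",
                  "namespace and the \"other\" prefix is bound to a",
                  "non-CML namespace"))),
    xel("molecule", c(xmlns = CML_NS),
        xel("non-cml-element", character(),
            paste("This is invalid. The null prefix is bound to the CML",
                  "namespace and the element \"non-cml-element\" is not",
                  "part of this"))),
    xel("cml:molecule", XMLNS_CML,
        xel("cml:non-cml-element", character(),
            paste("This is invalid. The cml prefix is bound to the CML",
                  "namespace and the element \"non-cml-element\" does not",
                  "form part of this")))
  )
  bind_rows(
    fixture_row("schema-test-01", "schema-test", docs[[1]],
                "VALID_WITH_WARNINGS", no_conv),
    fixture_row("schema-test-02", "schema-test", docs[[2]],
                "VALID_WITH_WARNINGS", no_conv),
    fixture_row("schema-test-03", "schema-test", docs[[3]], "INVALID",
                vocab_err()),
    fixture_row("schema-test-04", "schema-test", docs[[4]], "INVALID",
                vocab_err())
  )
}

#' The five-atom reference molecule used for the chemistry operations
#'
#' @return An XML string: a CML molecule with explicit Cartesian
#'   coordinates (one C, one N, one O, two H).
#' @export
mol5_document <- function() {
  atom <- function(id, el, x, y, z) {
    xel("cml:atom", c(id = id, elementType = el, x3 = x, y3 = y, z3 = z))
  }
  xel("cml:molecule", c(XMLNS_CML, id = "mol5"),
      xel("cml:atomArray", character(),
          atom("a1", "C", "0.0", "0.0", "0.0"),
          atom("a2", "N", "0.0", "1.3", "0.0"),
          atom("a3", "O", "1.0", "2.2", "0.0"),
          atom("a4", "H", "0.85", "-0.54", "0.5"),
          atom("a5", "H", "-0.85", "-0.54", "0.5")))
}

# Formaldehyde-like coordinates reused by the molecular/compchem fixtures.
molecular_atoms <- function() {
  list(
    xel("cml:atom", c(id = "a1", elementType = "C",
                      x3 = "0.0", y3 = "0.0", z3 = "0.0")),
    xel("cml:atom", c(id = "a2", elementType = "O",
                      x3 = "1.21", y3 = "0.0", z3 = "0.0")),
    xel("cml:atom", c(id = "a3", elementType = "H",
                      x3 = "-0.54", y3 = "0.94", z3 = "0.0")),
    xel("cml:atom", c(id = "a4", elementType = "H",
                      x3 = "-0.54", y3 = "-0.94", z3 = "0.0"))
  )
}

synthetic_fixtures <- function() {
  d <- c(XMLNS_CML, XMLNS_CONVENTIONS)
  molc <- c(convention = "conventions:molecular")
  atoms <- molecular_atoms()
  atom_array <- xel("cml:atomArray", character(),
                    atoms[[1]], atoms[[2]], atoms[[3]], atoms[[4]])
  bond_array <- xel(
    "cml:bondArray", character(),
    xel("cml:bond", c(atomRefs2 = "a1 a2", order = "D")),
    xel("cml:bond", c(atomRefs2 = "a1 a3", order = "S")),
    xel("cml:bond", c(atomRefs2 = "a1 a4", order = "S"))
  )

  molecular_minimal <- xel("cml:molecule", c(d, molc),
                           xel("cml:name", character(), "formaldehyde"))
  molecular_atoms_doc <- xel("cml:molecule", c(d, molc, id = "m1"),
                             atom_array)
  molecular_full <- xel("cml:molecule", c(d, molc, id = "m1"),
                        atom_array, bond_array,
                        xel("cml:name", character(), "formaldehyde"))
  molecular_nested <- xel(
    "cml:molecule", c(d, molc, id = "complex"),
    xel("cml:molecule", c(id = "frag1"),
        xel("cml:atomArray", character(),
            xel("cml:atom", c(id = "f1a1", elementType = "C")))),
    xel("cml:molecule", c(id = "frag2"),
        xel("cml:atomArray", character(),
            xel("cml:atom", c(id = "f2a1", elementType = "O"))))
  )

  compchem_full <- xel(
    "cml:module", c(d, XMLNS_COMPCHEM, convention = "conventions:compchem"),
    xel("cml:module", c(dictRef = "compchem:initialization"),
        xel("cml:molecule", molc,
            atom_array,
            xel("cml:name", character(), "formaldehyde")),
        xel("cml:parameter", c(name = "basis"),
            xel("cml:scalar", character(), "6-31G*")))
  )

  unitdict_full <- xel(
    "cml:dictionary", c(d, convention = "conventions:unit-dictionary",
                        title = "SI units", namespace = "http://example.org/units/"),
    xel("cml:entry", c(id = "e-metre", term = "metre"),
        xel("cml:definition", character(), "the SI base unit of length"),
        xel("cml:description", character(),
            "defined via the speed of light")),
    xel("cml:unitList", character(),
        xel("cml:unit", c(id = "u-metre", symbol = "m")))
  )

  bind_rows(
    fixture_row("mol5", "synthetic", mol5_document(), "VALID_WITH_WARNINGS",
                expected_finding("warning",
                                 "no conventions are declared in the document")),
    fixture_row("molecular-minimal", "synthetic", molecular_minimal, "VALID"),
    fixture_row("molecular-atoms", "synthetic", molecular_atoms_doc, "VALID"),
    fixture_row("molecular-full", "synthetic", molecular_full, "VALID"),
    fixture_row("molecular-nested", "synthetic", molecular_nested, "VALID"),
    fixture_row("compchem-full", "synthetic", compchem_full, "VALID"),
    fixture_row("unitdict-full", "synthetic", unitdict_full, "VALID")
  )
}

#' Generate the complete fixture corpus
#'
#' Builds every document with a known expected validation outcome: the
#' simpleUnit corpus (11 valid, 5 valid-with-info, 7 invalid), the four
#' structural namespace tests, the five-atom reference molecule, synthetic
#' all-rules-pass documents for the molecular, compchem and unit-dictionary
#' conventions, and one mutation-derived failing document per implemented
#' convention rule.
#'
#' @return A tibble with columns `id`, `provenance`, `document` (XML
#'   string), `expected_result`, `expected_findings` (list of tibbles with
#'   `severity`, `message`, `location`, `match`), and `strict` (whether the
#'   expected findings are the complete set of notable findings).
#' @export
fixture_corpus <- function() {
  base <- bind_rows(simpleunit_fixtures(), schema_test_fixtures(),
                    synthetic_fixtures())
  mutants <- map_dfr(names(mutation_rules()), function(rule) {
    if (rule == "none") return(NULL)
    mutate_fixture(base[base$id == mutation_rules()[[rule]]$base, ], rule)
  })
  bind_rows(base, mutants)
}

#' Write the fixture corpus to a directory
#'
#' Materializes each fixture as a `.cml` file plus a YAML manifest of ids,
#' expected results and expected findings.
#'
#' @param dir Output directory (created if needed).
#' @param corpus A corpus tibble; defaults to [fixture_corpus()].
#' @return `dir`, invisibly.
#' @export
cml_write_corpus <- function(dir, corpus = fixture_corpus()) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- lapply(seq_len(nrow(corpus)), function(i) {
    row <- corpus[i, ]
    writeLines(row$document, file.path(dir, paste0(row$id, ".cml")))
    list(id = row$id, provenance = row$provenance,
         expected_result = row$expected_result,
         expected_findings = lapply(
           seq_len(nrow(row$expected_findings[[1]])), function(j) {
             as.list(row$expected_findings[[1]][j, ])
           }))
  })
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

# rule id -> base fixture, mutation over an xml2 document, expectation
mutation_rules <- function() {
  ns <- c(c = CML_NS)
  first <- function(doc, xpath) xml2::xml_find_first(doc, xpath, ns)
  all <- function(doc, xpath) xml2::xml_find_all(doc, xpath, ns)
  list(
    none = list(base = NA_character_),
    simpleunit.child = list(
      base = "simpleunit-valid-01",
      mutate = function(doc) xml2::xml_remove(all(doc, "//c:unitList/c:unit")),
      result = "INVALID",
      expect = expected_finding("error", MSG_SU_CHILD)
    ),
    simpleunit.declaring_element = list(
      base = "simpleunit-valid-01",
      mutate = function(doc) xml2::xml_set_name(xml2::xml_root(doc), "molecule"),
      result = "INVALID",
      expect = expected_finding("error", MSG_SU_DECLARING)
    ),
    molecular.required_children = list(
      base = "molecular-minimal",
      mutate = function(doc) xml2::xml_remove(all(doc, "//c:name")),
      result = "INVALID",
      expect = expected_finding(
        "error", "MUST contain at least one of the following elements",
        match = "pattern")
    ),
    molecular.molecule_atomarray_exclusion = list(
      base = "molecular-atoms",
      mutate = function(doc) {
        m <- xml2::xml_add_child(xml2::xml_root(doc), "cml:molecule")
        nm <- xml2::xml_add_child(m, "cml:name")
        xml2::xml_text(nm) <- "fragment"
      },
      result = "INVALID",
      expect = expected_finding(
        "error",
        "MUST NOT contain both a child molecule and a child atomArray",
        match = "pattern")
    ),
    molecular.atomarray_nonempty = list(
      base = "molecular-atoms",
      mutate = function(doc) xml2::xml_remove(all(doc, "//c:atom")),
      result = "INVALID",
      expect = expected_finding(
        "error", "An atomArray MUST contain at least one atom")
    ),
    molecular.bondarray_nonempty = list(
      base = "molecular-full",
      mutate = function(doc) xml2::xml_remove(all(doc, "//c:bond")),
      result = "INVALID",
      expect = expected_finding(
        "error", "A bondArray MUST contain at least one bond")
    ),
    molecular.bondarray_at_most_one = list(
      base = "molecular-full",
      mutate = function(doc) {
        ba <- first(doc, "//c:bondArray")
        xml2::xml_add_sibling(ba, ba)
      },
      result = "INVALID",
      expect = expected_finding(
        "error", "MAY contain zero or one bondArray", match = "pattern")
    ),
    molecular.atom_id = list(
      base = "molecular-atoms",
      mutate = function(doc) {
        xml2::xml_set_attr(first(doc, "//c:atom[@id = 'a4']"), "id", NULL)
      },
      result = "INVALID",
      expect = expected_finding("error", "An atom MUST have an id attribute")
    ),
    molecular.atom_id_unique = list(
      base = "molecular-atoms",
      mutate = function(doc) {
        xml2::xml_set_attr(first(doc, "//c:atom[@id = 'a2']"), "id", "a1")
      },
      result = "INVALID",
      expect = expected_finding(
        "error", "MUST be unique within the eldest containing molecule",
        match = "pattern")
    ),
    molecular.coordinate_triple = list(
      base = "molecular-atoms",
      mutate = function(doc) {
        xml2::xml_set_attr(first(doc, "//c:atom[@id = 'a1']"), "y3", NULL)
      },
      result = "INVALID",
      expect = expected_finding(
        "error", "MUST also have y3 and z3", match = "pattern")
    ),
    molecular.bond_references = list(
      base = "molecular-full",
      mutate = function(doc) {
        xml2::xml_set_attr(first(doc, "//c:bond"), "atomRefs2", "a1 a1")
      },
      result = "INVALID",
      expect = expected_finding(
        "error", "references to two distinct atoms", match = "pattern")
    ),
    compchem.initialization_module = list(
      base = "compchem-full",
      mutate = function(doc) {
        xml2::xml_set_attr(first(doc, "//c:module[@dictRef]"),
                           "dictRef", "compchem:calculation")
      },
      result = "INVALID",
      expect = expected_finding(
        "error", "There MUST be an initialization module")
    ),
    compchem.single_molecule = list(
      base = "compchem-full",
      mutate = function(doc) {
        m <- xml2::xml_add_child(first(doc, "//c:module[@dictRef]"),
                                 "cml:molecule",
                                 convention = "conventions:molecular")
        nm <- xml2::xml_add_child(m, "cml:name")
        xml2::xml_text(nm) <- "extra"
      },
      result = "INVALID",
      expect = expected_finding(
        "error", "The initialization module MUST contain exactly one molecule")
    ),
    compchem.molecular_declared = list(
      base = "compchem-full",
      mutate = function(doc) {
        xml2::xml_set_attr(first(doc, "//c:molecule"), "convention", NULL)
      },
      result = "INVALID",
      expect = expected_finding(
        "error",
        "molecules MUST declare that they conform to the molecular convention")
    ),
    compchem.atomarray_required = list(
      base = "compchem-full",
      mutate = function(doc) xml2::xml_remove(all(doc, "//c:atomArray")),
      result = "INVALID",
      expect = expected_finding(
        "error", "REQUIRED to have an atomArray child", match = "pattern")
    ),
    compchem.coordinates_3d = list(
      base = "compchem-full",
      mutate = function(doc) {
        a <- first(doc, "//c:atom[@id = 'a3']")
        xml2::xml_set_attr(a, "x3", NULL)
        xml2::xml_set_attr(a, "y3", NULL)
        xml2::xml_set_attr(a, "z3", NULL)
      },
      result = "INVALID",
      expect = expected_finding(
        "error", "MUST have three dimensional coordinates", match = "pattern")
    ),
    unitdict.entry_definition = list(
      base = "unitdict-full",
      mutate = function(doc) xml2::xml_remove(all(doc, "//c:definition")),
      result = "INVALID",
      expect = expected_finding("error", "An entry MUST have a definition")
    ),
    unitdict.entry_single_description = list(
      base = "unitdict-full",
      mutate = function(doc) {
        de <- first(doc, "//c:description")
        xml2::xml_add_sibling(de, de)
      },
      result = "INVALID",
      expect = expected_finding(
        "error", "An entry MAY have at most one description")
    ),
    unitdict.unit_id = list(
      base = "unitdict-full",
      mutate = function(doc) {
        xml2::xml_set_attr(first(doc, "//c:unit"), "id", NULL)
      },
      result = "INVALID",
      expect = expected_finding("error", "A unit MUST have an id attribute")
    ),
    unitdict.dictionary_title = list(
      base = "unitdict-full",
      mutate = function(doc) {
        xml2::xml_set_attr(first(doc, "//c:dictionary"), "title", NULL)
      },
      result = "VALID_WITH_WARNINGS",
      expect = expected_finding(
        "warning", "SHOULD have a title", match = "pattern")
    )
  )
}

#' Derive a minimally broken document targeting one rule
#'
#' Applies a named minimal edit to a fixture expected to be VALID so that it
#' violates exactly the targeted structural or convention rule, and attaches
#' the expected error-message pattern. The identity mutation `"none"`
#' returns the fixture unchanged.
#'
#' @param base A one-row corpus tibble (see [fixture_corpus()]) expected
#'   VALID.
#' @param rule_id One of `names(mutation_rules)`; see the corpus ids
#'   `fail-<rule_id>`.
#' @return A one-row fixture tibble expected to fail with the rule's
#'   message.
#' @export
mutate_fixture <- function(base, rule_id) {
  stopifnot(is.data.frame(base), nrow(base) == 1)
  rules <- mutation_rules()
  if (!rule_id %in% names(rules)) {
    abort(glue::glue("unknown mutation rule '{rule_id}'"),
          class = "cml_unknown_rule_error")
  }
  if (rule_id == "none") return(base)
  rule <- rules[[rule_id]]
  doc <- xml2::read_xml(base$document)
  rule$mutate(doc)
  fixture_row(
    id = paste0("fail-", rule_id),
    provenance = "synthetic",
    document = as.character(doc),
    expected_result = rule$result,
    expected_findings = rule$expect,
    strict = FALSE
  )
}
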