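corpus <- fixture_corpus()
doc_of <- function(id) corpus$document[corpus$id == id][[1]]
conv_findings <- function(document) run_conventions(cml_parse(document))

test_that("convention discovery finds bindings in document order", {
  d6 <- discover_conventions(cml_parse(doc_of("simpleunit-valid-06")))
  expect_identical(nrow(d6$bindings), 2L)
  expect_identical(unique(d6$bindings$uri),
                   "http://www.xml-cml.org/convention/simpleUnit")
  expect_identical(nrow(d6$findings), 0L)

  dnone <- discover_conventions(cml_parse(doc_of("mol5")))
  expect_identical(nrow(dnone$bindings), 0L)
  expect_identical(dnone$findings$severity, "warning")

  unbound <- cml_parse(paste0('<cml:unitList xmlns:cml="', CML,
                              '" convention="nosuch:thing"/>'))
  dbad <- discover_conventions(unbound)
  expect_identical(dbad$findings$severity, "error")
  expect_match(dbad$findings$message, "not bound", fixed = TRUE)
})

test_that("unknown convention URIs inform and traverse out of mode", {
  document <- paste0(
    '<cml:unitList xmlns:cml="', CML, '" xmlns:conventions="',
    "http://www.xml-cml.org/convention/",
    '" convention="conventions:noSuchConvention"><cml:molecule/>',
    "</cml:unitList>")
  f <- conv_findings(document)
  expect_identical(f$severity, "info")
  expect_match(f$message, "noSuchConvention", fixed = TRUE)
  # no simpleUnit-style findings for the molecule: subtree is out of mode
  expect_identical(nrow(f), 1L)
})

test_that("simpleUnit scoping follows the published corpus exactly", {
  # silent out-of-mode traversal around the scope
  expect_identical(nrow(conv_findings(doc_of("simpleunit-valid-03"))), 0L)
  # unit list missing its unit child
  f <- conv_findings(doc_of("simpleunit-invalid-03"))
  expect_identical(f$message, "A unit list MUST contain child cml:unit elements")
  # declaration on a non-unitList element cited at the convention attribute
  f2 <- conv_findings(doc_of("simpleunit-invalid-01"))
  expect_identical(nrow(f2), 1L)
  expect_match(f2$location, "@\\*\\[local-name\\(\\) = 'convention'")
  # in-mode traversal crosses foreign elements (bond inside x:p inside unit)
  f3 <- conv_findings(doc_of("simpleunit-info-04"))
  expect_identical(f3$severity, "info")
  expect_match(f3$message, "^bond is not a part of")
})

test_that("molecular rules accept conformant molecules and reject violations", {
  d <- paste0('xmlns:cml="', CML, '" xmlns:conventions="',
              "http://www.xml-cml.org/convention/",
              '" convention="conventions:molecular"')
  mol <- function(inner, attrs = "") {
    paste0("<cml:molecule ", d, attrs, ">", inner, "</cml:molecule>")
  }
  expect_identical(nrow(conv_findings(mol("<cml:name>ethanol</cml:name>"))),
                   0L)

  f <- conv_findings(mol(paste0(
    "<cml:molecule><cml:name>frag</cml:name></cml:molecule>",
    '<cml:atomArray><cml:atom id="a1"/></cml:atomArray>')))
  expect_match(f$message[f$severity == "error"],
               "MUST NOT contain both", fixed = TRUE)

  # duplicate atom ids across nested molecules within one eldest molecule
  f2 <- conv_findings(mol(paste0(
    "<cml:molecule><cml:atomArray>",
    '<cml:atom id="a1"/></cml:atomArray></cml:molecule>',
    "<cml:molecule><cml:atomArray>",
    '<cml:atom id="a1"/></cml:atomArray></cml:molecule>')))
  errs <- f2[f2$severity == "error", ]
  expect_true(all(grepl("unique within the eldest", errs$message)))
  expect_gte(nrow(errs), 1)

  f3 <- conv_findings(mol(paste0(
    '<cml:atomArray><cml:atom id="a1" x3="0.0"/></cml:atomArray>')))
  expect_match(f3$message[f3$severity == "error"],
               "MUST also have y3 and z3", fixed = TRUE)

  f4 <- conv_findings(mol(paste0(
    '<cml:atomArray><cml:atom id="a1"/><cml:atom id="a2"/></cml:atomArray>',
    '<cml:bondArray><cml:bond atomRefs2="a1 a1"/></cml:bondArray>')))
  expect_match(f4$message[f4$severity == "error"],
               "two distinct atoms", fixed = TRUE)

  # a bond may not reference an atom outside its eldest molecule
  f5 <- conv_findings(mol(paste0(
    '<cml:atomArray><cml:atom id="a1"/><cml:atom id="a2"/></cml:atomArray>',
    '<cml:bondArray><cml:bond atomRefs2="a1 zz"/></cml:bondArray>')))
  expect_match(f5$message[f5$severity == "error"],
               "two distinct atoms", fixed = TRUE)
})

test_that("compchem requires a conformant initialization module", {
  f <- conv_findings(doc_of("compchem-full"))
  expect_identical(nrow(f), 0L)

  for (rule in c("compchem.initialization_module", "compchem.single_molecule",
                 "compchem.molecular_declared")) {
    mut <- mutate_fixture(corpus[corpus$id == "compchem-full", ], rule)
    ff <- conv_findings(mut$document[[1]])
    errs <- ff[ff$severity == "error", ]
    expect_gte(nrow(errs), 1)
    expect_true(all(grepl(mut$expected_findings[[1]]$message[[1]],
                          errs$message, fixed = TRUE)),
                label = rule)
  }
})

test_that("unit-dictionary rules cover entries, units and titles", {
  expect_identical(nrow(conv_findings(doc_of("unitdict-full"))), 0L)

  mut <- mutate_fixture(corpus[corpus$id == "unitdict-full", ],
                        "unitdict.unit_id")
  f <- conv_findings(mut$document[[1]])
  expect_identical(f$message[f$severity == "error"],
                   "A unit MUST have an id attribute")

  mut2 <- mutate_fixture(corpus[corpus$id == "unitdict-full", ],
                         "unitdict.dictionary_title")
  f2 <- conv_findings(mut2$document[[1]])
  expect_identical(f2$severity, "warning")

  mut3 <- mutate_fixture(corpus[corpus$id == "unitdict-full", ],
                         "unitdict.entry_single_description")
  f3 <- conv_findings(mut3$document[[1]])
  expect_match(f3$message[f3$severity == "error"],
               "at most one description", fixed = TRUE)
})

test_that("wrapping a valid document in foreign ancestors never changes findings", {
  set.seed(7)
  valid_ids <- corpus$id[corpus$provenance == "appendixB-valid"]
  wrappers <- c(
    '<w:wrap xmlns:w="http://wrap.example/">%s</w:wrap>',
    "<outer-default>%s</outer-default>",
    paste0('<w:a xmlns:w="http://wrap.example/"><w:b>some text %s more',
           "</w:b></w:a>")
  )
  for (id in sample(valid_ids, 5)) {
    base_doc <- corpus$document[corpus$id == id][[1]]
    base_notable <- notable_findings(cml_validate(base_doc))
    for (w in sample(wrappers, 2)) {
      wrapped <- sprintf(w, base_doc)
      rep <- cml_validate(wrapped)
      expect_identical(rep$result, "VALID", label = paste(id, w))
      expect_identical(nrow(notable_findings(rep)), nrow(base_notable))
    }
  }
})

test_that("disjoint sibling scopes validate independently", {
  info_list <- paste0(
    '<cml:unitList xmlns:cml="', CML, '" xmlns:conventions="',
    "http://www.xml-cml.org/convention/",
    '" convention="conventions:simpleUnit"><cml:unit/><cml:molecule/>',
    "</cml:unitList>")
  single <- conv_findings(info_list)
  double <- conv_findings(paste0('<x:p xmlns:x="http://www.w3.org/1999/xhtml">',
                                 info_list, info_list, "</x:p>"))
  expect_identical(nrow(single), 1L)
  expect_identical(nrow(double), 2L)
  expect_identical(unique(double$message), unique(single$message))
})

test_that("a nested convention supersedes the outer handler for its subtree", {
  # a unitList (simpleUnit) containing a molecular-scoped molecule: the
  # molecule is judged by molecular rules, not reported as foreign to
  # simpleUnit
  document <- paste0(
    '<cml:unitList xmlns:cml="', CML, '" xmlns:conventions="',
    "http://www.xml-cml.org/convention/",
    '" convention="conventions:simpleUnit"><cml:unit/>',
    '<cml:molecule convention="conventions:molecular">',
    "<cml:name>nested</cml:name></cml:molecule></cml:unitList>")
  f <- conv_findings(document)
  expect_identical(nrow(f), 0L)
})

test_that("handler info findings never demote a VALID result", {
  for (id in corpus$id[corpus$provenance == "appendixB-info"]) {
    rep <- cml_validate(corpus$document[corpus$id == id][[1]])
    expect_identical(rep$result, "VALID", label = id)
    expect_identical(sum(tidy(rep)$severity == "info"), 1L, label = id)
  }
})
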