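corpus <- fixture_corpus()
doc_of <- function(id) corpus$document[corpus$id == id][[1]]

test_that("parsing yields namespace-expanded elements with parented children", {
  root <- cml_parse(doc_of("simpleunit-valid-01"))
  expect_identical(root$ns, CML)
  expect_identical(root$local, "unitList")
  kids <- Filter(function(x) x$kind == "element", root$children)
  expect_length(kids, 1)
  expect_identical(kids[[1]]$local, "unit")
  expect_identical(kids[[1]]$ns, CML)
  expect_identical(kids[[1]]$same_name_index, 1L)
})

test_that("malformed input returns a well-formedness failure, never an error", {
  for (bad in list("", raw(0), "<a><b></a>", "not xml at all", "<a>")) {
    res <- cml_parse(bad)
    expect_s3_class(res, "cml_wellformedness_failure")
    expect_true(nzchar(res$message))
  }
})

test_that("in-scope namespace contexts inherit, include defaults, and shadow", {
  t1 <- cml_parse(doc_of("schema-test-01"))
  child <- Filter(function(x) x$kind == "element", t1$children)[[1]]
  ctx <- in_scope_namespaces(child)
  expect_identical(ctx[["cml"]], CML)
  expect_false("" %in% names(ctx))

  t2 <- cml_parse(doc_of("schema-test-02"))
  ctx2 <- in_scope_namespaces(t2)
  expect_identical(unname(ctx2[names(ctx2) == ""]), CML)
  expect_identical(ctx2[["other"]], "http://www.example.net")

  t3 <- cml_parse("<root/>")
  expect_length(in_scope_namespaces(t3), 0)

  # inner redeclaration shadows the outer binding
  t4 <- cml_parse(paste0('<a xmlns:p="http://one.example/">',
                         '<b xmlns:p="http://two.example/"/></a>'))
  inner <- Filter(function(x) x$kind == "element", t4$children)[[1]]
  expect_identical(in_scope_namespaces(t4)[["p"]], "http://one.example/")
  expect_identical(in_scope_namespaces(inner)[["p"]], "http://two.example/")
})

test_that("QName expansion resolves prefixes and flags unbound ones", {
  root <- cml_parse(doc_of("simpleunit-valid-01"))
  xn <- expand_qname("conventions:simpleUnit", root)
  expect_identical(xn$uri, "http://www.xml-cml.org/convention/simpleUnit")

  cc <- cml_parse(doc_of("compchem-full"))
  xn2 <- expand_qname("compchem:hfenergy", cc)
  expect_identical(xn2$uri, "http://xml-cml.org/dictionary/compchem/hfenergy")

  expect_error(expand_qname("foo:bar", root),
               class = "cml_unbound_prefix_error")

  # a bare token takes the default namespace when one is bound
  t <- cml_parse(paste0('<d xmlns="http://d.example/"/>'))
  expect_identical(expand_qname("thing", t)$uri, "http://d.example/thing")
})

test_that("location paths match the report dialect", {
  info1 <- cml_parse(doc_of("simpleunit-info-01"))
  mol <- Filter(function(x) x$kind == "element" && x$local == "molecule",
                info1$children)[[1]]
  expect_identical(
    location_path(mol),
    paste0("/*[local-name() = 'unitList' and namespace-uri() = ",
           "'http://www.xml-cml.org/schema'][1]",
           "/*[local-name() = 'molecule' and namespace-uri() = ",
           "'http://www.xml-cml.org/schema'][1]")
  )

  inv1 <- cml_parse(doc_of("simpleunit-invalid-01"))
  conv_attr <- Filter(function(a) a$local == "convention", inv1$attrs)[[1]]
  expect_identical(
    conv_attr$path,
    paste0("/*[local-name() = 'molecule' and namespace-uri() = ",
           "'http://www.xml-cml.org/schema'][1]",
           "@*[local-name() = 'convention' and namespace-uri() = '']")
  )

  # the second same-named sibling is indexed [2]
  v11 <- cml_parse(doc_of("simpleunit-valid-11"))
  units <- Filter(function(x) x$kind == "element" && x$local == "unit",
                  v11$children)
  expect_length(units, 2)
  expect_match(location_path(units[[2]]), "\\[2\\]$")
})

test_that("every location path uniquely selects its node in every fixture", {
  for (i in seq_len(nrow(corpus))) {
    document <- corpus$document[[i]]
    root <- cml_parse(document)
    for (el in cmlcheck:::all_elements(root)) {
      hits <- nodes_at_location(document, location_path(el))
      expect_length(hits, 1)
      expect_identical(xml2::xml_name(hits[[1]]), el$local)
      for (a in el$attrs) {
        ahits <- nodes_at_location(document, a$path)
        expect_length(ahits, 1)
        expect_identical(xml2::xml_text(ahits[[1]]), a$value)
      }
    }
  }
})

test_that("QName expansion is total on corpus convention/dictRef attributes", {
  for (i in seq_len(nrow(corpus))) {
    root <- cml_parse(corpus$document[[i]])
    for (el in cmlcheck:::all_elements(root)) {
      for (a in el$attrs) {
        if (a$local %in% c("convention", "dictRef") && a$ns == "") {
          expect_no_error(expand_qname(a$value, el))
        }
      }
    }
  }
})

test_that("serialize/parse round-trips preserve the tree", {
  for (i in seq_len(nrow(corpus))) {
    t1 <- cml_parse(corpus$document[[i]])
    s1 <- cml_serialize(t1)
    t2 <- cml_parse(s1)
    expect_false(inherits(t2, "cml_wellformedness_failure"))
    expect_identical(cml_serialize(t2), s1, label = corpus$id[[i]])
    expect_true(xml_structurally_equal(corpus$document[[i]], s1))
  }
})
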