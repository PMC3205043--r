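# Shared oracles and comparators, independent of the implementation paths
# they check.

CML <- "http://www.xml-cml.org/schema"

# Published report XML for the first valid and first invalid unit-list
# documents (modulo insignificant whitespace).
REPORT_VALID_I <- paste0(
  '<report xmlns="http://www.xml-cml.org/report/">',
  "<well-formed-test><valid>xml is well formed</valid></well-formed-test>",
  "<schema-validation-test><valid>document conforms to the schema</valid>",
  "</schema-validation-test>",
  "<convention-validation-test>",
  "<valid>document conforms to all the conventions specified</valid>",
  "</convention-validation-test>",
  "<uris-reachable-test><valid>All appropriate URIs were reachable</valid>",
  "<valid>all dictRefs are resolvable</valid></uris-reachable-test>",
  "</report>"
)

REPORT_INVALID_I <- paste0(
  '<report xmlns="http://www.xml-cml.org/report/">',
  "<well-formed-test><valid>xml is well formed</valid></well-formed-test>",
  "<schema-validation-test><valid>document conforms to the schema</valid>",
  "</schema-validation-test>",
  "<convention-validation-test>",
  "<error location=\"/*[local-name() = 'molecule' and namespace-uri() = ",
  "'http://www.xml-cml.org/schema'][1]@*[local-name() = 'convention' and ",
  "namespace-uri() = '']\">",
  "the only valid cml element that can specify the simpleUnit convention ",
  "is &quot;unitList&quot;</error>",
  "</convention-validation-test>",
  "</report>"
)

# Structural XML equality through xml2: expanded names, attribute sets and
# non-whitespace text must agree; whitespace and prefix choices are ignored.
xml_structurally_equal <- function(a, b) {
  norm <- function(x) {
    doc <- xml2::read_xml(x)
    as_shape <- function(node) {
      ns <- xml2::xml_ns(doc)
      kids <- xml2::xml_contents(node)
      child_shapes <- list()
      text <- character()
      for (k in seq_along(kids)) {
        type <- as.character(xml2::xml_type(kids[[k]]))
        if (type == "element") {
          child_shapes[[length(child_shapes) + 1L]] <- as_shape(kids[[k]])
        } else if (type %in% c("text", "cdata")) {
          t <- trimws(xml2::xml_text(kids[[k]]))
          if (nzchar(t)) text <- c(text, t)
        }
      }
      attrs <- xml2::xml_attrs(node, ns)
      attrs <- attrs[!grepl("^xmlns", names(attrs))]
      list(
        name = xml2::xml_name(node, ns),
        ns = xml2::xml_ns(node),
        attrs = attrs[order(names(attrs))],
        text = paste(text, collapse = " "),
        children = child_shapes
      )
    }
    shape <- as_shape(xml2::xml_root(doc))
    resolve <- function(s) {
      # resolve doc-unique prefixes to URIs so the two documents compare
      nm <- s$name
      uri <- ""
      if (grepl(":", nm, fixed = TRUE)) {
        parts <- strsplit(nm, ":", fixed = TRUE)[[1]]
        uri <- tryCatch(xml2::xml_ns(doc)[[parts[[1]]]],
                        error = function(e) "")
        nm <- parts[[2]]
      }
      s$name <- paste0("{", uri, "}", nm)
      s$ns <- NULL
      s$attrs <- stats::setNames(
        unname(s$attrs),
        vapply(names(s$attrs), function(an) {
          if (grepl(":", an, fixed = TRUE)) {
            p <- strsplit(an, ":", fixed = TRUE)[[1]]
            paste0("{", tryCatch(xml2::xml_ns(doc)[[p[[1]]]],
                                 error = function(e) ""), "}", p[[2]])
          } else an
        }, character(1))
      )
      s$children <- lapply(s$children, resolve)
      s
    }
    resolve(shape)
  }
  identical(norm(a), norm(b))
}

# Evaluate a report location path against the source document; the printed
# attribute-step dialect is translated to legal XPath first.
nodes_at_location <- function(document, location) {
  xpath <- gsub("]@*", "]/@*", location, fixed = TRUE)
  xml2::xml_find_all(xml2::read_xml(document), xpath)
}

# Severity-ranked result order for monotonicity checks.
result_rank <- function(result) {
  match(result, c("VALID", "VALID_WITH_WARNINGS", "INVALID"))
}

notable_findings <- function(report) {
  f <- tidy(report)
  f[f$severity != "valid", , drop = FALSE]
}

# Assert that one corpus fixture validates exactly as its expectations say.
expect_fixture_outcome <- function(row, report = NULL) {
  if (is.null(report)) report <- cml_validate(row$document[[1]])
  expect_identical(report$result, row$expected_result,
                   label = paste0(row$id, " result"))
  notable <- notable_findings(report)
  expected <- row$expected_findings[[1]]
  if (isTRUE(row$strict)) {
    expect_identical(nrow(notable), nrow(expected),
                     label = paste0(row$id, " notable finding count"))
    for (j in seq_len(nrow(expected))) {
      e <- expected[j, ]
      hit <- notable$severity == e$severity &
        (if (identical(e$match, "pattern")) {
          grepl(e$message, notable$message, fixed = TRUE)
        } else notable$message == e$message) &
        (if (is.na(e$location)) TRUE else notable$location == e$location)
      expect_true(any(hit),
                  label = paste0(row$id, ": expected ", e$severity, " '",
                                 e$message, "'"))
    }
  } else {
    # mutation-derived: every error/warning matches the targeted rule
    e <- expected[1, ]
    targeted <- notable[notable$severity == e$severity, , drop = FALSE]
    expect_gte(nrow(targeted), 1)
    expect_true(all(grepl(e$message, targeted$message, fixed = TRUE)),
                label = paste0(row$id, " targeted findings"))
    others <- notable[notable$severity %in% c("error", "warning"), ,
                      drop = FALSE]
    expect_true(all(grepl(e$message, others$message, fixed = TRUE)),
                label = paste0(row$id, " no findings from other rules"))
  }
  invisible(report)
}

# ---- random molecule trees for the formal-charge property -----------------

# A molecule specification as plain R lists, independent of any CML parsing.
random_molecule_spec <- function(depth = 3) {
  spec <- list(
    charge = if (runif(1) < 0.3) sample(-3:3, 1) else NULL,
    count = sample(1:3, 1),
    atoms = lapply(seq_len(sample(0:4, 1)), function(i) {
      has_occ <- runif(1) < 0.2
      list(
        charge = if (runif(1) < 0.7) sample(-3:3, 1) else NULL,
        # fractional occupancy only on neutral atoms keeps totals integral
        occupancy = if (has_occ) 0.25 else 1,
        count = if (has_occ) 1 else sample(1:3, 1)
      )
    }),
    children = if (depth > 0 && runif(1) < 0.6) {
      lapply(seq_len(sample(1:2, 1)), function(i) {
        random_molecule_spec(depth - 1)
      })
    } else list()
  )
  for (k in seq_along(spec$atoms)) {
    if (spec$atoms[[k]]$occupancy != 1) spec$atoms[[k]]$charge <- NULL
  }
  spec
}

# Render a specification as a CML document string.
spec_to_cml <- function(spec, root = TRUE) {
  attrs <- character()
  if (root) attrs <- c(attrs, 'xmlns:cml="http://www.xml-cml.org/schema"')
  if (!is.null(spec$charge)) {
    attrs <- c(attrs, sprintf('formalCharge="%d"', spec$charge))
  }
  attrs <- c(attrs, sprintf('count="%s"', format(spec$count)))
  atoms <- vapply(seq_along(spec$atoms), function(i) {
    a <- spec$atoms[[i]]
    paste0('<cml:atom id="a', i, '"',
           if (!is.null(a$charge)) sprintf(' formalCharge="%d"', a$charge)
           else "",
           sprintf(' occupancy="%s"', format(a$occupancy)),
           sprintf(' count="%s"', format(a$count)), "/>")
  }, character(1))
  children <- vapply(spec$children, spec_to_cml, character(1), root = FALSE)
  paste0("<cml:molecule ", paste(attrs, collapse = " "), ">",
         if (length(atoms)) {
           paste0("<cml:atomArray>", paste(atoms, collapse = ""),
                  "</cml:atomArray>")
         } else "",
         paste(children, collapse = ""),
         "</cml:molecule>")
}

# Brute-force oracle: flatten the tree into explicit (contribution,
# multiplier) rows with an iterative stack, then sum. Expansion stops at any
# molecule with an explicit charge, whose charge enters once (times the
# accumulated multiplier of its parent chain).
oracle_formal_charge <- function(spec) {
  total <- 0
  stack <- list(list(spec = spec, mult = 1, top = TRUE))
  while (length(stack)) {
    item <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    s <- item$spec
    mult <- item$mult
    if (!is.null(s$charge)) {
      total <- total + s$charge * (if (item$top) 1 else mult)
      next
    }
    eff_mult <- if (item$top) 1 else mult
    for (a in s$atoms) {
      charge <- if (is.null(a$charge)) 0 else a$charge
      total <- total + charge * a$occupancy * a$count * eff_mult
    }
    for (ch in s$children) {
      stack[[length(stack) + 1L]] <- list(spec = ch,
                                          mult = eff_mult * ch$count,
                                          top = FALSE)
    }
  }
  total
}
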