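#' Load the structural vocabulary table
#'
#' The vocabulary maps CML element names to their allowed attributes (with
#' datatypes and enumerations) and content model. The packaged default covers
#' the element subset needed for unit lists, small molecules, computational
#' chemistry modules and dictionaries; communities can extend it by supplying
#' their own YAML file of the same shape.
#'
#' @param path Path to a vocabulary YAML file; `NULL` for the packaged
#'   default.
#' @return A `cml_vocabulary` object.
#' @export
cml_vocabulary <- function(path = NULL) {
  path <- path %||% system.file("extdata", "cml-vocabulary.yaml",
                                package = "cmlcheck", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  elements <- lapply(raw$elements %||% list(), function(spec) {
    spec <- spec %||% list()
    list(
      content = spec$content %||% "any-cml-plus-foreign",
      attributes = lapply(spec$attributes %||% list(), normalize_attr_spec)
    )
  })
  structure(
    list(
      namespace = raw$namespace %||% CML_NS,
      obsoleted = as.character(raw$obsoleted %||% character()),
      global_attributes = lapply(raw$global_attributes %||% list(),
                                 normalize_attr_spec),
      elements = elements
    ),
    class = "cml_vocabulary"
  )
}

normalize_attr_spec <- function(spec) {
  if (is.character(spec)) spec <- list(datatype = spec)
  stopifnot(spec$datatype %in% c("string", "integer", "real", "qname-ref",
                                 "token-list", "enumeration"))
  spec$values <- as.character(spec$values %||% character())
  spec
}

#' @export
print.cml_vocabulary <- function(x, ...) {
  cat("<cml_vocabulary>", length(x$elements), "elements in", x$namespace,
      "\n")
  invisible(x)
}

#' Check CML vocabulary membership
#'
#' Emits one error finding for every element whose namespace is the CML
#' namespace but whose local name is absent from the vocabulary (including
#' the obsoleted mixed-content legacy elements). Elements in foreign or no
#' namespace are unconstrained.
#'
#' @param root Root element from [cml_parse()].
#' @param vocab A [cml_vocabulary()] table.
#' @return A findings tibble.
#' @export
check_vocabulary <- function(root, vocab = cml_vocabulary()) {
  findings <- map(all_elements(root), function(el) {
    if (identical(el$ns, vocab$namespace) &&
        !el$local %in% names(vocab$elements)) {
      finding("error",
              glue::glue("the element '{el$local}' does not appear in the ",
                         "schema"),
              el$path)
    }
  })
  bind_rows(no_findings(), compact(findings))
}

#' Check the relaxed content model
#'
#' CML elements accept any mix of CML, foreign-namespace and no-namespace
#' child elements in any order and cardinality, but have no mixed content:
#' an element in the CML namespace holding both non-whitespace text and
#' element children yields an error. Foreign elements are unconstrained
#' (mixed content there is fine). Whitespace-only text between children does
#' not count as mixed content.
#'
#' @inheritParams check_vocabulary
#' @return A findings tibble.
#' @export
check_content_model <- function(root, vocab = cml_vocabulary()) {
  findings <- map(all_elements(root), function(el) {
    if (identical(el$ns, vocab$namespace) &&
        length(element_children(el)) > 0 && has_nonws_text(el)) {
      finding("error",
              glue::glue("the element '{el$local}' has mixed content (text ",
                         "and element children), which CML does not allow"),
              el$path)
    }
  })
  bind_rows(no_findings(), compact(findings))
}

#' Check attribute admissibility and datatypes
#'
#' Every no-namespace attribute on a CML element is checked against the
#' vocabulary: unknown attributes yield an error, and values violating the
#' attribute's datatype or enumeration yield an error naming the attribute
#' and the offending value. Attributes on foreign elements, and
#' foreign-namespace attributes, are unconstrained.
#'
#' @inheritParams check_vocabulary
#' @return A findings tibble.
#' @export
check_attribute_types <- function(root, vocab = cml_vocabulary()) {
  findings <- map(all_elements(root), function(el) {
    if (!identical(el$ns, vocab$namespace)) return(NULL)
    espec <- vocab$elements[[el$local]]
    if (is.null(espec)) return(NULL)  # vocabulary error reported elsewhere
    checks <- map(el$attrs, function(a) {
      if (!identical(a$ns, "")) return(NULL)
      spec <- espec$attributes[[a$local]] %||%
        vocab$global_attributes[[a$local]]
      if (is.null(spec)) {
        return(finding("error",
                       glue::glue("the attribute '{a$local}' is not allowed ",
                                  "on the element '{el$local}'"),
                       a$path))
      }
      problem <- attr_value_problem(a$value, spec)
      if (!is.null(problem)) {
        finding("error",
                glue::glue("the attribute '{a$local}' has the invalid value ",
                           "'{a$value}': {problem}"),
                a$path)
      }
    })
    bind_rows(compact(checks))
  })
  bind_rows(no_findings(), compact(findings))
}

attr_value_problem <- function(value, spec) {
  switch(
    spec$datatype,
    string = NULL,
    integer = if (!grepl("^[+-]?[0-9]+$", value)) "an integer is required",
    real = if (is.na(suppressWarnings(as.numeric(value))))
      "a real number is required",
    `qname-ref` = if (!grepl("^[^[:space:]:]+(:[^[:space:]:]+)?$", value))
      "a QName (prefix:localName) token is required",
    `token-list` = {
      n <- spec$n %||% 2L
      tokens <- strsplit(trimws(value), "[[:space:]]+")[[1]]
      if (length(tokens) != n)
        glue::glue("exactly {n} whitespace-separated tokens are required")
    },
    enumeration = if (!value %in% spec$values)
      glue::glue("allowed values are ",
                 "{paste(sprintf('\"%s\"', spec$values), collapse = ' ')}")
  )
}

#' Check for deprecated constructs
#'
#' Deprecated legacy forms are tolerated by the schema but trigger warnings.
#' Currently: numeric bond order aliases `'1'`, `'2'`, `'3'` (the letter
#' forms `'S'`, `'D'`, `'T'` are canonical).
#'
#' @inheritParams check_vocabulary
#' @return A findings tibble of warnings.
#' @export
check_deprecated <- function(root) {
  findings <- map(all_elements(root), function(el) {
    if (!is_cml_element(el, "bond")) return(NULL)
    order <- node_attr(el, "order")
    if (!is.null(order) && order %in% c("1", "2", "3")) {
      finding("warning",
              glue::glue("numeric bond orders are deprecated ",
                         "(order = '{order}'); use 'S', 'D' or 'T'"),
              node_attr_path(el, "order"))
    }
  })
  bind_rows(no_findings(), compact(findings))
}
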