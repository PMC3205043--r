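#' URI resolvers
#'
#' `check_uri_resolvability()` and [cml_validate()] abstract URI resolution
#' behind a resolver function `function(uri) TRUE/FALSE`. The offline
#' resolver performs no network access and treats every syntactically valid
#' absolute URI as reachable, so validation runs are deterministic without a
#' network. The stub resolver marks a fixed set of URIs unreachable (useful
#' in tests); the recording resolver wraps another resolver and counts
#' invocations.
#'
#' @param unreachable Character vector of URIs the stub reports unreachable.
#' @param resolver A resolver function to wrap.
#' @return A resolver function; the recording resolver additionally carries
#'   an environment `calls` with the vector of URIs queried.
#' @export
offline_resolver <- function() {
  function(uri) grepl("^[A-Za-z][A-Za-z0-9+.-]*:[^[:space:]]", uri)
}

#' @rdname offline_resolver
#' @export
stub_resolver <- function(unreachable = character()) {
  force(unreachable)
  function(uri) !(uri %in% unreachable)
}

#' @rdname offline_resolver
#' @export
recording_resolver <- function(resolver = offline_resolver()) {
  log <- new.env(parent = emptyenv())
  log$calls <- character()
  out <- function(uri) {
    log$calls <- c(log$calls, uri)
    resolver(uri)
  }
  attr(out, "log") <- log
  out
}

#' Check that QName-valued attributes are bound and their URIs reachable
#'
#' Every QName-valued attribute on a CML element (`dictRef`, `convention`,
#' `unitType` and peers, as declared in the vocabulary) must use a bound
#' prefix (an unbound prefix is an error) and its expanded URI is queried
#' through the resolver (an unreachable URI is a warning). When every URI
#' checks out the section receives its two canonical valid findings.
#'
#' @param root Root element from [cml_parse()].
#' @param resolver A resolver function, e.g. [offline_resolver()].
#' @param vocab A [cml_vocabulary()]; determines which attributes are
#'   QName-valued.
#' @return A findings tibble (empty on full success).
#' @export
check_uri_resolvability <- function(root, resolver = offline_resolver(),
                                    vocab = cml_vocabulary()) {
  findings <- list()
  for (el in all_elements(root)) {
    if (!identical(el$ns, vocab$namespace)) next
    espec <- vocab$elements[[el$local]]
    for (a in el$attrs) {
      if (!identical(a$ns, "")) next
      spec <- (espec$attributes[[a$local]] %||%
                 vocab$global_attributes[[a$local]])
      if (is.null(spec) || !identical(spec$datatype, "qname-ref")) next
      expanded <- tryCatch(expand_qname(a$value, el),
                           cml_unbound_prefix_error = function(e) e)
      if (inherits(expanded, "error")) {
        findings[[length(findings) + 1L]] <- finding(
          "error",
          glue::glue("the prefix in '{a$value}' ({a$local}) has not been ",
                     "bound to a namespace"),
          a$path)
      } else if (!nzchar(expanded$ns)) {
        findings[[length(findings) + 1L]] <- finding(
          "error",
          glue::glue("'{a$value}' ({a$local}) does not expand to a URI: no ",
                     "namespace is bound"),
          a$path)
      } else if (!isTRUE(resolver(expanded$uri))) {
        findings[[length(findings) + 1L]] <- finding(
          "warning",
          glue::glue("the URI {expanded$uri} ({a$local} = '{a$value}') was ",
                     "not reachable"),
          a$path)
      }
    }
  }
  bind_rows(no_findings(), findings)
}

#' Validate a CML document through the full ordered workflow
#'
#' Runs, in order: well-formedness; structural checks (vocabulary, content
#' model, attribute datatypes) plus deprecated-construct warnings as the
#' schema-validation test; convention discovery and the convention handlers;
#' and QName/URI resolvability. Processing stops after the first section
#' containing an error ("no further processing is performed"), and sections
#' never reached are omitted from the report. All problems are reported as
#' findings; the function never throws for bad documents.
#'
#' @param x Document bytes, an XML string, a file path, or an
#'   already-parsed `cml_node` tree (necessarily well-formed).
#' @param vocab A [cml_vocabulary()].
#' @param registry A [convention_registry()].
#' @param resolver A resolver function, e.g. [offline_resolver()].
#' @return A [cml_report()] whose `result` is `"VALID"`,
#'   `"VALID_WITH_WARNINGS"` or `"INVALID"`.
#' @export
cml_validate <- function(x, vocab = cml_vocabulary(),
                         registry = convention_registry(),
                         resolver = offline_resolver()) {
  sections <- list()

  root <- if (is_element(x)) x else cml_parse(x)
  wf <- new_section("well-formed-test")
  if (is_failure(root)) {
    wf <- record_finding(wf, finding("error", root$message))
    return(cml_report(list(wf)))
  }
  sections <- c(sections, list(close_section(wf, "xml is well formed")))

  schema <- new_section("schema-validation-test",
                        bind_rows(check_vocabulary(root, vocab),
                                  check_content_model(root, vocab),
                                  check_attribute_types(root, vocab),
                                  check_deprecated(root)))
  schema <- close_section(schema, "document conforms to the schema")
  sections <- c(sections, list(schema))
  if (any(schema$findings$severity == "error")) {
    return(cml_report(sections))
  }

  discovery <- discover_conventions(root)
  conv <- new_section("convention-validation-test",
                      bind_rows(discovery$findings,
                                run_conventions(root, registry)))
  conv <- close_section(conv,
                        "document conforms to all the conventions specified")
  sections <- c(sections, list(conv))
  if (any(conv$findings$severity == "error")) {
    return(cml_report(sections))
  }

  uris <- new_section("uris-reachable-test",
                      check_uri_resolvability(root, resolver, vocab))
  uris <- close_section(uris, c("All appropriate URIs were reachable",
                                "all dictRefs are resolvable"))
  sections <- c(sections, list(uris))
  cml_report(sections)
}

#' Plain-text digest of a validation report
#'
#' @param report A [cml_report()].
#' @return A character vector of lines.
#' @export
report_to_text <- function(report) {
  lines <- paste("result:", report$result)
  for (section in report$sections) {
    lines <- c(lines, section$name)
    for (i in seq_len(nrow(section$findings))) {
      f <- section$findings[i, ]
      loc <- if (is.na(f$location)) "" else paste0(" [", f$location, "]")
      lines <- c(lines, paste0("  ", f$severity, ": ", f$message, loc))
    }
  }
  lines
}

#' Command-line entry point
#'
#' Validates a file and prints the report to standard output. Exit codes:
#' 0 = VALID, 1 = VALID_WITH_WARNINGS, 2 = INVALID, 3 = usage or I/O error.
#'
#' Usage: `cml-validate <file> [--offline] [--format xml|text]
#' [--vocab FILE] [--radii FILE]` (the validator is offline by default;
#' `--offline` is accepted for explicitness).
#'
#' @param args Character vector of command-line arguments.
#' @return The exit code, invisibly.
#' @export
cml_validate_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste("usage: cml-validate <file> [--offline]",
                 "[--format xml|text] [--vocab FILE] [--radii FILE]")
  format <- "xml"
  vocab_path <- NULL
  file <- NULL
  i <- 1L
  while (i <= length(args)) {
    a <- args[[i]]
    if (a == "--offline") {
      # offline resolution is the default; accepted for explicitness
    } else if (a == "--format") {
      if (i == length(args) || !args[[i + 1L]] %in% c("xml", "text")) {
        message(usage); return(invisible(3L))
      }
      format <- args[[i + 1L]]; i <- i + 1L
    } else if (a == "--vocab") {
      if (i == length(args)) { message(usage); return(invisible(3L)) }
      vocab_path <- args[[i + 1L]]; i <- i + 1L
    } else if (a == "--radii") {
      if (i == length(args)) { message(usage); return(invisible(3L)) }
      i <- i + 1L  # reserved for chemistry subcommands
    } else if (startsWith(a, "--")) {
      message(usage); return(invisible(3L))
    } else if (is.null(file)) {
      file <- a
    } else {
      message(usage); return(invisible(3L))
    }
    i <- i + 1L
  }
  if (is.null(file)) { message(usage); return(invisible(3L)) }
  if (!file.exists(file)) {
    message("cml-validate: cannot read '", file, "'")
    return(invisible(3L))
  }
  vocab <- tryCatch(cml_vocabulary(vocab_path), error = function(e) e)
  if (inherits(vocab, "error")) {
    message("cml-validate: ", conditionMessage(vocab))
    return(invisible(3L))
  }
  report <- cml_validate(file, vocab = vocab)
  if (format == "xml") {
    cat(serialize_report(report), "\n")
  } else {
    cat(report_to_text(report), sep = "\n")
  }
  code <- switch(report$result, VALID = 0L, VALID_WITH_WARNINGS = 1L,
                 INVALID = 2L)
  invisible(code)
}
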