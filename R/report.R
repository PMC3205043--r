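#' Construct a validation finding
#'
#' A finding is one entry of a validation report: a severity, a
#' human-readable message, and (for findings that cite a document node) the
#' location path of that node. Findings are plain tibbles so they compose
#' with the usual dplyr verbs.
#'
#' @param severity One of `"valid"`, `"info"`, `"warning"`, `"error"`.
#' @param message Non-empty message text.
#' @param location Optional location path string (see [location_path()]).
#' @return A one-row tibble with columns `severity`, `message`, `location`.
#' @export
finding <- function(severity, message, location = NA_character_) {
  severity <- match.arg(severity, c("valid", "info", "warning", "error"))
  stopifnot(is.character(message), length(message) == 1, nzchar(message))
  tibble(severity = severity, message = message,
         location = location %||% NA_character_)
}

no_findings <- function() {
  tibble(severity = character(), message = character(),
         location = character())
}

SECTION_NAMES <- c("well-formed-test", "schema-validation-test",
                   "convention-validation-test", "uris-reachable-test")

new_section <- function(name, findings = no_findings()) {
  stopifnot(name %in% SECTION_NAMES)
  list(name = name, findings = findings)
}

#' Append a finding to a report test section
#'
#' Enforces the report-language contract that a section holding a `valid`
#' finding must not also hold `warning` or `error` findings: appending a
#' warning or error to a section already marked valid (or marking valid a
#' section holding a warning/error) is a contract violation and raises an
#' error of class `cml_report_contract_error`.
#'
#' @param section A section created by the workflow (a list with `name` and
#'   `findings`).
#' @param finding A one-row findings tibble from [finding()].
#' @return The section with the finding appended.
#' @export
record_finding <- function(section, finding) {
  combined <- bind_rows(section$findings, finding)
  if (any(combined$severity == "valid") &&
      any(combined$severity %in% c("warning", "error"))) {
    abort(
      paste0("section '", section$name, "' cannot hold a valid finding ",
             "together with warning or error findings"),
      class = "cml_report_contract_error"
    )
  }
  section$findings <- combined
  section
}

# Close a section: add its canonical valid finding(s) only when it holds no
# warning and no error.
close_section <- function(section, valid_messages) {
  if (!any(section$findings$severity %in% c("warning", "error"))) {
    for (msg in valid_messages) {
      section <- record_finding(section, finding("valid", msg))
    }
  }
  section
}

#' Assemble a validation report from test sections
#'
#' @param sections A list of sections in workflow order.
#' @return An object of class `cml_report`; its `result` field is the
#'   aggregate [aggregate_result()] of all findings.
#' @export
cml_report <- function(sections = list()) {
  report <- structure(list(sections = sections, result = NA_character_),
                      class = "cml_report")
  report$result <- aggregate_result(report)
  report
}

#' Aggregate a report's findings into an overall validation result
#'
#' Any error makes the document INVALID; otherwise any warning makes it
#' VALID_WITH_WARNINGS; otherwise it is VALID. Informational findings never
#' affect the result.
#'
#' @param report A `cml_report`.
#' @return `"VALID"`, `"VALID_WITH_WARNINGS"` or `"INVALID"`.
#' @export
aggregate_result <- function(report) {
  severities <- tidy(report)$severity
  if (any(severities == "error")) "INVALID"
  else if (any(severities == "warning")) "VALID_WITH_WARNINGS"
  else "VALID"
}

#' @export
print.cml_report <- function(x, ...) {
  cat("<cml_report>", x$result, "\n")
  for (section in x$sections) {
    cat("  ", section$name, "\n", sep = "")
    for (i in seq_len(nrow(section$findings))) {
      f <- section$findings[i, ]
      cat("    [", f$severity, "] ", f$message, "\n", sep = "")
    }
  }
  invisible(x)
}

#' Tidy a validation report into one row per finding
#'
#' @param x A `cml_report`.
#' @param ... Unused.
#' @return A tibble with columns `section`, `severity`, `message`,
#'   `location`.
#' @method tidy cml_report
#' @export
tidy.cml_report <- function(x, ...) {
  if (!length(x$sections)) {
    return(tibble(section = character(), severity = character(),
                  message = character(), location = character()))
  }
  map_dfr(x$sections, function(s) {
    if (!nrow(s$findings)) return(NULL)
    mutate(s$findings, section = s$name, .before = 1)
  })
}

#' One-row summary of a validation report
#'
#' @param x A `cml_report`.
#' @param ... Unused.
#' @return A tibble with the aggregate result and finding counts.
#' @method glance cml_report
#' @export
glance.cml_report <- function(x, ...) {
  findings <- tidy(x)
  tibble(
    result = x$result,
    n_sections = length(x$sections),
    n_error = sum(findings$severity == "error"),
    n_warning = sum(findings$severity == "warning"),
    n_info = sum(findings$severity == "info")
  )
}

#' Plot the findings of a validation report
#'
#' Bar chart of finding counts per test section, filled by severity.
#'
#' @param object A `cml_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cml_report
#' @export
autoplot.cml_report <- function(object, ...) {
  findings <- tidy(object)
  findings$section <- factor(findings$section, levels = SECTION_NAMES)
  findings$severity <- factor(findings$severity,
                              levels = c("valid", "info", "warning", "error"))
  ggplot2::ggplot(findings,
                  ggplot2::aes(x = .data$section, fill = .data$severity)) +
    ggplot2::geom_bar() +
    ggplot2::scale_fill_manual(
      values = c(valid = "#2e7d32", info = "#1565c0",
                 warning = "#ef6c00", error = "#c62828"),
      drop = FALSE
    ) +
    ggplot2::labs(x = NULL, y = "findings",
                  title = paste("Validation result:", object$result)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot .data
#' @export
ggplot2::autoplot

#' Serialize a validation report to its XML form
#'
#' Writes the report in the CML report namespace
#' `http://www.xml-cml.org/report/`: a `report` root holding one element per
#' test section, whose children are named by finding severity, carry the
#' message as text, and a `location` attribute when the finding cites a
#' document node.
#'
#' @param report A `cml_report`.
#' @return An XML string.
#' @export
serialize_report <- function(report) {
  doc <- xml2::xml_new_root("report", xmlns = REPORT_NS)
  for (section in report$sections) {
    sec <- xml2::xml_add_child(doc, section$name)
    for (i in seq_len(nrow(section$findings))) {
      f <- section$findings[i, ]
      el <- xml2::xml_add_child(sec, f$severity)
      xml2::xml_text(el) <- f$message
      if (!is.na(f$location)) xml2::xml_set_attr(el, "location", f$location)
    }
  }
  as.character(doc)
}

#' Read a serialized report back into a `cml_report`
#'
#' Inverse of [serialize_report()] (round-tripping is byte-identical).
#'
#' @param x An XML string or raw vector in the report namespace.
#' @return A `cml_report`.
#' @export
parse_report <- function(x) {
  root <- cml_parse(x)
  if (is_failure(root)) abort(root$message, class = "cml_report_parse_error")
  stopifnot(identical(root$ns, REPORT_NS), identical(root$local, "report"))
  sections <- map(element_children(root), function(sec) {
    findings <- map_dfr(element_children(sec), function(f) {
      text <- paste0(
        purrr::map_chr(purrr::keep(f$children,
                                   ~ identical(.x$kind, "text")), "value"),
        collapse = ""
      )
      finding(f$local, text, node_attr(f, "location"))
    })
    if (is.null(findings) || !nrow(findings)) findings <- no_findings()
    new_section(sec$name %||% sec$local, findings)
  })
  cml_report(sections)
}
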