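#' Parse an XML document into a navigable, namespace-aware tree
#'
#' Parses CML (or any XML) input into a tree of `cml_node` records. Each
#' element node carries its expanded name (namespace URI + local name), its
#' attributes with expanded names, the namespace prefix bindings in scope at
#' that element, its 1-based index among same-named preceding siblings, and
#' the error-location path used in validation reports. Parsing never throws
#' for malformed input: a `cml_wellformedness_failure` object holding a
#' human-readable message is returned instead.
#'
#' @param x A file path, an XML string, or a raw vector of document bytes.
#' @return The root `cml_node` on success, otherwise a
#'   `cml_wellformedness_failure` object with a `message` field.
#' @examples
#' root <- cml_parse('<u xmlns="http://www.xml-cml.org/schema"/>')
#' root$local
#' cml_parse("<a><b></a>")$message
#' @export
cml_parse <- function(x) {
  doc <- tryCatch(
    {
      if (is.raw(x) && length(x) == 0) stop("empty input: no root element")
      if (is.character(x) && length(x) == 1 && !nzchar(trimws(x))) {
        stop("empty input: no root element")
      }
      suppressWarnings(xml2::read_xml(x))
    },
    error = function(e) e
  )
  if (inherits(doc, "error")) {
    return(structure(
      list(message = paste("document is not well-formed XML:",
                           conditionMessage(doc))),
      class = "cml_wellformedness_failure"
    ))
  }
  nsmap <- xml2::xml_ns(doc)
  build_node(xml2::xml_root(doc), nsmap,
             nsctx = character(), parent_path = "")
}

#' @export
print.cml_wellformedness_failure <- function(x, ...) {
  cat("<not well-formed>", x$message, "\n")
  invisible(x)
}

is_failure <- function(x) inherits(x, "cml_wellformedness_failure")

# Resolve a doc-map-prefixed name ("d1:child" / "child") to c(ns, local).
resolve_docmap_name <- function(name, nsmap) {
  if (grepl(":", name, fixed = TRUE)) {
    parts <- strsplit(name, ":", fixed = TRUE)[[1]]
    uri <- nsmap[[parts[[1]]]] %||% ""
    c(uri, paste(parts[-1], collapse = ":"))
  } else {
    c("", name)
  }
}

build_node <- function(x, nsmap, nsctx, parent_path) {
  nm <- resolve_docmap_name(xml2::xml_name(x, nsmap), nsmap)
  ns <- nm[[1]]
  local <- nm[[2]]

  raw_attrs <- xml2::xml_attrs(x, nsmap)
  attr_names <- names(raw_attrs) %||% character()

  # xmlns declarations made at this element update the in-scope context;
  # an empty URI undeclares the binding.
  is_decl <- attr_names == "xmlns" | startsWith(attr_names, "xmlns:")
  ns_decl <- raw_attrs[is_decl]
  if (length(ns_decl)) {
    names(ns_decl) <- sub("^xmlns:?", "", names(ns_decl))
    for (k in seq_along(ns_decl)) {
      p <- names(ns_decl)[[k]]
      v <- unname(ns_decl[[k]])
      if (nzchar(v)) {
        nsctx <- nsctx[names(nsctx) != p]
        nsctx <- c(nsctx, stats::setNames(v, p))
      } else {
        nsctx <- nsctx[names(nsctx) != p]
      }
    }
  }

  node <- list(
    kind = "element", ns = ns, local = local, value = NULL,
    nsctx = nsctx, ns_decl = ns_decl,
    attrs = list(), children = list(),
    same_name_index = 1L, path = ""
  )

  # placeholder path; fixed up below once the index is known by the caller
  attrs <- list()
  for (i in which(!is_decl)) {
    anm <- resolve_docmap_name(attr_names[[i]], nsmap)
    attrs[[length(attrs) + 1L]] <- list(
      ns = anm[[1]], local = anm[[2]], value = unname(raw_attrs[[i]])
    )
  }
  node$attrs <- attrs

  kids <- list()
  counts <- list()
  for (child in xml2::xml_contents(x)) {
    type <- as.character(xml2::xml_type(child))
    if (type %in% c("text", "cdata")) {
      kids[[length(kids) + 1L]] <- list(kind = "text",
                                        value = xml2::xml_text(child))
    } else if (type == "element") {
      built <- build_node(child, nsmap, nsctx, parent_path = "")
      key <- paste0("{", built$ns, "}", built$local)
      counts[[key]] <- (counts[[key]] %||% 0L) + 1L
      built$same_name_index <- counts[[key]]
      kids[[length(kids) + 1L]] <- built
    }
    # comments, processing instructions and DTD nodes are dropped
  }
  node$children <- kids
  finalize_paths(node, parent_path)
}

# Assign location paths once same-name indices are known.
finalize_paths <- function(node, parent_path) {
  node$path <- paste0(
    parent_path,
    element_step(node$local, node$ns, node$same_name_index)
  )
  node$attrs <- lapply(node$attrs, function(a) {
    a$path <- paste0(node$path, attribute_step(a$local, a$ns))
    a
  })
  node$children <- lapply(node$children, function(ch) {
    if (ch$kind == "element") finalize_paths(ch, node$path) else ch
  })
  node
}

element_step <- function(local, ns, index) {
  sprintf("/*[local-name() = '%s' and namespace-uri() = '%s'][%d]",
          local, ns, index)
}

attribute_step <- function(local, ns) {
  sprintf("@*[local-name() = '%s' and namespace-uri() = '%s']", local, ns)
}

# Named-vector lookup that tolerates the empty ("" = default) prefix.
ctx_lookup <- function(nsctx, prefix) {
  hit <- which(names(nsctx) == prefix)
  if (length(hit)) unname(nsctx[[hit[[1]]]]) else NULL
}

is_element <- function(node) {
  is.list(node) && identical(node$kind, "element")
}

is_cml_element <- function(node, local = NULL) {
  is_element(node) && identical(node$ns, CML_NS) &&
    (is.null(local) || node$local %in% local)
}

element_children <- function(node) {
  purrr::keep(node$children, is_element)
}

# Value of a no-namespace (or `ns`-namespace) attribute, or NULL.
node_attr <- function(node, local, ns = "") {
  for (a in node$attrs) {
    if (identical(a$local, local) && identical(a$ns, ns)) return(a$value)
  }
  NULL
}

# Location path of an attribute, or NULL when absent.
node_attr_path <- function(node, local, ns = "") {
  for (a in node$attrs) {
    if (identical(a$local, local) && identical(a$ns, ns)) return(a$path)
  }
  NULL
}

has_nonws_text <- function(node) {
  any(purrr::map_lgl(node$children, function(ch) {
    identical(ch$kind, "text") && nzchar(trimws(ch$value))
  }))
}

#' Namespace prefix bindings in scope at a node
#'
#' Returns every prefix-to-URI binding visible at an element, including
#' bindings inherited from ancestors; inner declarations shadow outer ones.
#' The default (null) prefix is reported under the name `""`.
#'
#' @param node An element `cml_node` from [cml_parse()].
#' @return A named character vector mapping prefix to namespace URI.
#' @export
in_scope_namespaces <- function(node) {
  stopifnot(is_element(node))
  node$nsctx
}

#' Expand a QName token against a node's namespace context
#'
#' Resolves a `prefix:local` (or bare `local`) token using the namespace
#' bindings in scope at `node`. A bare token takes the default namespace when
#' one is bound. The expanded URI used to identify conventions and dictionary
#' entries is the namespace URI concatenated with the local name.
#'
#' @param token A QName token such as `"conventions:simpleUnit"`.
#' @param node The element whose namespace context governs resolution.
#' @return A list with fields `ns`, `local` and `uri` (= `ns` + `local`).
#'   Signals a condition of class `cml_unbound_prefix_error` when the prefix
#'   has no in-scope binding.
#' @export
expand_qname <- function(token, node) {
  stopifnot(is.character(token), length(token) == 1)
  nsctx <- in_scope_namespaces(node)
  if (grepl(":", token, fixed = TRUE)) {
    parts <- strsplit(token, ":", fixed = TRUE)[[1]]
    prefix <- parts[[1]]
    local <- paste(parts[-1], collapse = ":")
    uri <- ctx_lookup(nsctx, prefix) %||% NA_character_
    if (is.na(uri)) {
      abort(
        glue::glue("prefix '{prefix}' in QName '{token}' is not bound ",
                   "to a namespace"),
        class = "cml_unbound_prefix_error"
      )
    }
  } else {
    local <- token
    uri <- ctx_lookup(nsctx, "") %||% ""
  }
  list(ns = uri, local = local, uri = paste0(uri, local))
}

#' Error-location path of a node
#'
#' Returns the absolute location path used to cite a node in validation
#' reports. Each element step has the form
#' `/*[local-name() = 'N' and namespace-uri() = 'U'][k]` where `k` counts
#' preceding siblings with the same expanded name; an attribute terminates
#' the path with `@*[local-name() = 'N' and namespace-uri() = 'U']`.
#'
#' @param node An element `cml_node`.
#' @return A single string.
#' @export
location_path <- function(node) {
  stopifnot(is_element(node))
  node$path
}

#' Serialize a parsed tree back to XML
#'
#' Writes a `cml_node` tree as an XML string. Namespace declarations are
#' re-emitted where they were declared; element and attribute prefixes are
#' chosen from the bindings in scope. `cml_parse(cml_serialize(tree))`
#' reproduces a tree with identical expanded names, values and ordering.
#'
#' @param node The root element of a parsed tree.
#' @return An XML string.
#' @export
cml_serialize <- function(node) {
  stopifnot(is_element(node))
  serialize_node(node)
}

serialize_node <- function(node) {
  if (identical(node$kind, "text")) return(escape_text(node$value))
  tag <- prefixed_name(node$local, node$ns, node$nsctx)
  decls <- ""
  if (length(node$ns_decl)) {
    nm <- ifelse(nzchar(names(node$ns_decl)),
                 paste0("xmlns:", names(node$ns_decl)), "xmlns")
    decls <- paste0(" ", nm, '="', escape_attr(unname(node$ns_decl)), '"',
                    collapse = "")
  }
  attrs <- ""
  if (length(node$attrs)) {
    attrs <- paste0(
      vapply(node$attrs, function(a) {
        paste0(" ", prefixed_name(a$local, a$ns, node$nsctx, attribute = TRUE),
               '="', escape_attr(a$value), '"')
      }, character(1)),
      collapse = ""
    )
  }
  open <- paste0("<", tag, decls, attrs)
  if (!length(node$children)) return(paste0(open, "/>"))
  inner <- paste0(vapply(node$children, serialize_node, character(1)),
                  collapse = "")
  paste0(open, ">", inner, "</", tag, ">")
}

prefixed_name <- function(local, ns, nsctx, attribute = FALSE) {
  if (!nzchar(ns)) return(local)
  prefixes <- names(nsctx)[nsctx == ns]
  if (!attribute && "" %in% prefixes) return(local)
  prefixes <- prefixes[nzchar(prefixes)]
  if (!length(prefixes)) {
    abort(glue::glue("no in-scope prefix for namespace '{ns}'"))
  }
  paste0(prefixes[[1]], ":", local)
}

escape_text <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

escape_attr <- function(x) {
  gsub('"', "&quot;", escape_text(x), fixed = TRUE)
}

# Depth-first list of all element nodes in a subtree (including `node`).
all_elements <- function(node) {
  out <- list(node)
  for (ch in element_children(node)) {
    out <- c(out, all_elements(ch))
  }
  out
}
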