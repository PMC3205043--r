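#' Convention handlers and registry
#'
#' A convention is a URI-identified set of MUST/SHOULD/MAY constraints
#' layered over the relaxed CML schema, declared on a CML element through
#' its `convention` attribute and scoped to that element and all its
#' descendants. A handler bundles the convention URI, the set of element
#' names that belong to the convention (anything else in the CML namespace
#' inside the scope is reported as an informational finding), and a
#' validation function over the scope.
#'
#' @param uri The expanded convention URI.
#' @param members CML element local names that are part of the convention.
#' @param validate `function(binding, registry)` returning a findings
#'   tibble for the subtree rooted at the declaring element.
#' @return A `cml_convention_handler`.
#' @export
convention_handler <- function(uri, members, validate) {
  structure(list(uri = uri, members = members, validate = validate),
            class = "cml_convention_handler")
}

#' Registry of convention handlers, keyed by URI
#'
#' The built-in handlers cover the simpleUnit, molecular, compchem and
#' unit-dictionary conventions. Additional handlers (or overrides) can be
#' supplied as named arguments `uri = handler`.
#'
#' @param ... Named `cml_convention_handler`s to add, keyed by URI.
#' @return A named list of handlers.
#' @export
convention_registry <- function(...) {
  registry <- list()
  registry[[CONV_SIMPLEUNIT]] <- simpleunit_handler()
  registry[[CONV_MOLECULAR]] <- molecular_handler()
  registry[[CONV_COMPCHEM]] <- compchem_handler()
  registry[[CONV_UNITDICT]] <- unitdict_handler()
  extra <- list(...)
  for (nm in names(extra)) registry[[nm]] <- extra[[nm]]
  registry
}

conv_info <- function(local, uri, location) {
  finding(
    "info",
    glue::glue("{local} is not a part of the {uri} convention and may be ",
               "ignored by some processors."),
    location
  )
}

#' Discover convention declarations in document order
#'
#' One binding is produced per CML element bearing a `convention` attribute.
#' A document declaring no conventions yields a warning finding; a
#' convention value whose prefix is unbound yields an error finding.
#'
#' @param root Root element from [cml_parse()].
#' @return A list with `bindings` (tibble of `uri`, `location`, and the
#'   declaring node in list-column `element`) and `findings`.
#' @export
discover_conventions <- function(root) {
  bindings <- tibble(uri = character(), location = character(),
                     element = list())
  findings <- no_findings()
  for (el in all_elements(root)) {
    if (!is_cml_element(el)) next
    token <- node_attr(el, "convention")
    if (is.null(token)) next
    expanded <- tryCatch(expand_qname(token, el),
                         cml_unbound_prefix_error = function(e) e)
    if (inherits(expanded, "error")) {
      findings <- bind_rows(findings, finding(
        "error",
        glue::glue("the convention attribute value '{token}' uses a ",
                   "namespace prefix that is not bound"),
        node_attr_path(el, "convention")
      ))
    } else {
      bindings <- bind_rows(bindings,
                            tibble(uri = expanded$uri,
                                   location = el$path,
                                   element = list(el)))
    }
  }
  if (!nrow(bindings) && !nrow(findings)) {
    findings <- finding(
      "warning",
      "no conventions are declared in the document",
      root$path
    )
  }
  list(bindings = bindings, findings = findings)
}

#' Run the convention handlers over a document
#'
#' Traversal starts outside any convention scope and descends silently. At a
#' CML element declaring a convention, the matching handler takes over the
#' subtree; within a scope the traversal continues through foreign and
#' no-namespace elements without findings, and CML elements anywhere in the
#' subtree are subject to the handler's rules. A convention declared on a
#' descendant of another scope supersedes the outer handler for the inner
#' subtree. Unknown convention URIs yield an informational finding and the
#' subtree is traversed out of mode.
#'
#' @inheritParams discover_conventions
#' @param registry A [convention_registry()].
#' @return A findings tibble.
#' @export
run_conventions <- function(root, registry = convention_registry()) {
  walk_out_of_mode(root, registry)
}

# Template-2 behaviour: descend silently until a convention declaration.
walk_out_of_mode <- function(node, registry) {
  if (is_cml_element(node) && !is.null(node_attr(node, "convention"))) {
    return(dispatch_convention(node, registry))
  }
  bind_rows(no_findings(),
            map(element_children(node), walk_out_of_mode, registry))
}

dispatch_convention <- function(node, registry) {
  token <- node_attr(node, "convention")
  expanded <- tryCatch(expand_qname(token, node),
                       cml_unbound_prefix_error = function(e) e)
  if (inherits(expanded, "error")) {
    return(bind_rows(
      finding("error",
              glue::glue("the convention attribute value '{token}' uses a ",
                         "namespace prefix that is not bound"),
              node_attr_path(node, "convention")),
      map(element_children(node), walk_out_of_mode, registry)
    ))
  }
  handler <- registry[[expanded$uri]]
  if (is.null(handler)) {
    return(bind_rows(
      finding("info",
              glue::glue("the convention {expanded$uri} is not known to ",
                         "this validator and has not been checked"),
              node_attr_path(node, "convention")),
      map(element_children(node), walk_out_of_mode, registry)
    ))
  }
  handler$validate(node, registry)
}

# In-mode traversal of a scope: `on_element` is called for every element of
# the subtree (including the binding element); a CML descendant declaring
# its own convention switches handlers for its subtree.
walk_scope <- function(binding, registry, on_element) {
  walk <- function(node) {
    if (!identical(node$path, binding$path) &&
        is_cml_element(node) && !is.null(node_attr(node, "convention"))) {
      return(dispatch_convention(node, registry))
    }
    bind_rows(on_element(node) %||% no_findings(),
              map(element_children(node), walk))
  }
  walk(binding)
}

# Elements of a scope, stopping at nested convention declarations (which
# belong to the inner handler).
scope_elements <- function(binding) {
  collect <- function(node) {
    if (!identical(node$path, binding$path) &&
        is_cml_element(node) && !is.null(node_attr(node, "convention"))) {
      return(list())
    }
    c(list(node), unlist(lapply(element_children(node), collect),
                         recursive = FALSE))
  }
  collect(binding)
}

direct_cml_children <- function(node, local = NULL) {
  purrr::keep(element_children(node), is_cml_element, local = local)
}

# ---------------------------------------------------------------- simpleUnit

simpleunit_handler <- function() {
  convention_handler(
    uri = CONV_SIMPLEUNIT,
    members = c("unitList", "unit"),
    validate = function(binding, registry) {
      if (!is_cml_element(binding, "unitList")) {
        # out-of-mode traversal resumes below the faulty declaration
        return(bind_rows(
          finding("error",
                  paste0("the only valid cml element that can specify the ",
                         "simpleUnit convention is \"unitList\""),
                  node_attr_path(binding, "convention")),
          map(element_children(binding), walk_out_of_mode, registry)
        ))
      }
      walk_scope(binding, registry, function(e) {
        if (!is_cml_element(e)) return(NULL)
        if (identical(e$local, "unitList")) {
          if (!length(direct_cml_children(e, "unit"))) {
            finding("error",
                    "A unit list MUST contain child cml:unit elements",
                    e$path)
          }
        } else if (!identical(e$local, "unit")) {
          conv_info(e$local, CONV_SIMPLEUNIT, e$path)
        }
      })
    }
  )
}

#' Validate a simpleUnit convention scope
#'
#' Rules: the convention must be declared on a `cml:unitList`; every
#' in-scope unit list must have at least one direct `cml:unit` child; other
#' CML elements in scope are reported as informational; foreign and
#' no-namespace elements are unconstrained.
#'
#' @param binding The CML element declaring the convention.
#' @param registry A [convention_registry()] used for nested scopes.
#' @return A findings tibble.
#' @export
validate_simpleunit <- function(binding, registry = convention_registry()) {
  simpleunit_handler()$validate(binding, registry)
}

# ----------------------------------------------------------------- molecular

MOLECULAR_MEMBERS <- c("molecule", "atomArray", "atom", "bondArray", "bond",
                       "name", "label", "formula")

molecular_handler <- function() {
  convention_handler(
    uri = CONV_MOLECULAR,
    members = MOLECULAR_MEMBERS,
    validate = function(binding, registry) {
      bind_rows(
        walk_scope(binding, registry, molecular_element_check),
        molecular_reference_checks(binding)
      )
    }
  )
}

molecular_element_check <- function(e) {
  if (!is_cml_element(e)) return(NULL)
  switch(
    e$local,
    molecule = {
      kid_names <- map_chr(direct_cml_children(e), "local")
      out <- list()
      if (!any(kid_names %in% c("molecule", "atomArray", "name", "label",
                                "formula"))) {
        out <- c(out, list(finding(
          "error",
          paste("A molecule MUST contain at least one of the following",
                "elements: molecule, atomArray, name, label, formula"),
          e$path)))
      }
      if ("molecule" %in% kid_names && "atomArray" %in% kid_names) {
        out <- c(out, list(finding(
          "error",
          "A molecule MUST NOT contain both a child molecule and a child atomArray",
          e$path)))
      }
      if (sum(kid_names == "bondArray") > 1) {
        out <- c(out, list(finding(
          "error",
          "A molecule MAY contain zero or one bondArray children",
          e$path)))
      }
      bind_rows(out)
    },
    atomArray = if (!length(direct_cml_children(e, "atom"))) {
      finding("error", "An atomArray MUST contain at least one atom", e$path)
    },
    bondArray = if (!length(direct_cml_children(e, "bond"))) {
      finding("error", "A bondArray MUST contain at least one bond", e$path)
    },
    atom = {
      out <- list()
      if (is.null(node_attr(e, "id"))) {
        out <- c(out, list(finding(
          "error", "An atom MUST have an id attribute", e$path)))
      }
      coords <- !vapply(c("x3", "y3", "z3"),
                        function(a) is.null(node_attr(e, a)), logical(1))
      if (any(coords) && !all(coords)) {
        out <- c(out, list(finding(
          "error",
          paste("If an atom has an x3 coordinate it MUST also have y3 and",
                "z3 (and similarly if y3 or z3 are present)"),
          e$path)))
      }
      bind_rows(out)
    },
    bond = NULL,  # reference resolution is checked per eldest molecule
    if (!e$local %in% MOLECULAR_MEMBERS) {
      conv_info(e$local, CONV_MOLECULAR, e$path)
    }
  )
}

# Atom-id uniqueness and bond-reference resolution, scoped to the eldest
# containing molecule (the outermost molecule element within the scope).
molecular_reference_checks <- function(binding) {
  findings <- list()
  visit <- function(node) {
    if (is_cml_element(node, "molecule")) {
      atoms <- list()
      bonds <- list()
      gather <- function(n) {
        if (is_cml_element(n, "atom")) atoms[[length(atoms) + 1L]] <<- n
        if (is_cml_element(n, "bond")) bonds[[length(bonds) + 1L]] <<- n
        lapply(element_children(n), gather)
      }
      gather(node)
      ids <- map_chr(atoms, ~ node_attr(.x, "id") %||% NA_character_)
      dup <- ids[!is.na(ids)][duplicated(ids[!is.na(ids)])]
      for (a in atoms) {
        id <- node_attr(a, "id")
        if (!is.null(id) && id %in% dup) {
          findings[[length(findings) + 1L]] <<- finding(
            "error",
            glue::glue("the id of an atom MUST be unique within the eldest ",
                       "containing molecule (duplicate id '{id}')"),
            a$path)
        }
      }
      for (b in bonds) {
        refs <- node_attr(b, "atomRefs2")
        tokens <- if (is.null(refs)) character()
                  else strsplit(trimws(refs), "[[:space:]]+")[[1]]
        ok <- length(tokens) == 2 && tokens[[1]] != tokens[[2]] &&
          all(tokens %in% ids)
        if (!ok) {
          findings[[length(findings) + 1L]] <<- finding(
            "error",
            paste("a bond MUST contain references to two distinct atoms,",
                  "the atoms MUST exist, and be in the same ancestor",
                  "molecule"),
            b$path)
        }
      }
      return(invisible(NULL))  # contents handled within the eldest molecule
    }
    for (ch in element_children(node)) {
      if (is_cml_element(ch) &&
          !is.null(node_attr(ch, "convention"))) next  # nested scope
      visit(ch)
    }
  }
  visit(binding)
  bind_rows(no_findings(), findings)
}

#' Validate a molecular convention scope
#'
#' Rules for small-molecule documents: required molecule children, the
#' molecule/atomArray exclusion, non-empty atomArray and bondArray, at most
#' one bondArray, atom ids present and unique within the eldest containing
#' molecule, all-or-none Cartesian coordinates, and bond references naming
#' two distinct existing atoms in the same ancestor molecule.
#'
#' @inheritParams validate_simpleunit
#' @return A findings tibble.
#' @export
validate_molecular <- function(binding, registry = convention_registry()) {
  molecular_handler()$validate(binding, registry)
}

# ------------------------------------------------------------------ compchem

compchem_handler <- function() {
  members <- c("module", "molecule", "atomArray", "atom", "property",
               "parameter", "scalar", "list")
  convention_handler(
    uri = CONV_COMPCHEM,
    members = members,
    validate = function(binding, registry) {
      general <- walk_scope(binding, registry, function(e) {
        if (is_cml_element(e) && !e$local %in% members) {
          conv_info(e$local, CONV_COMPCHEM, e$path)
        }
      })
      bind_rows(general, compchem_module_checks(binding))
    }
  )
}

compchem_module_checks <- function(binding) {
  init_uri <- paste0(COMPCHEM_DICT_NS, "initialization")
  modules <- purrr::keep(scope_elements(binding), function(e) {
    if (!is_cml_element(e, "module")) return(FALSE)
    token <- node_attr(e, "dictRef")
    if (is.null(token)) return(FALSE)
    expanded <- tryCatch(expand_qname(token, e), error = function(e) NULL)
    !is.null(expanded) && identical(expanded$uri, init_uri)
  })
  if (!length(modules)) {
    return(finding("error", "There MUST be an initialization module",
                   binding$path))
  }
  findings <- list()
  for (m in modules) {
    mols <- direct_cml_children(m, "molecule")
    if (length(mols) != 1) {
      findings <- c(findings, list(finding(
        "error", "The initialization module MUST contain exactly one molecule",
        m$path)))
      next
    }
    mol <- mols[[1]]
    token <- node_attr(mol, "convention")
    declared <- !is.null(token) && identical(
      tryCatch(expand_qname(token, mol), error = function(e) NULL)$uri,
      CONV_MOLECULAR
    )
    if (!declared) {
      findings <- c(findings, list(finding(
        "error",
        "molecules MUST declare that they conform to the molecular convention",
        mol$path)))
    }
    if (!length(direct_cml_children(mol, "atomArray"))) {
      findings <- c(findings, list(finding(
        "error",
        "The molecule in the initialization module is REQUIRED to have an atomArray child",
        mol$path)))
    }
    for (a in purrr::keep(all_elements(mol), is_cml_element, local = "atom")) {
      coords <- !vapply(c("x3", "y3", "z3"),
                        function(at) is.null(node_attr(a, at)), logical(1))
      if (!all(coords)) {
        findings <- c(findings, list(finding(
          "error",
          paste("All the atoms in the molecule in the initialization module",
                "MUST have three dimensional coordinates"),
          a$path)))
      }
    }
  }
  bind_rows(no_findings(), findings)
}

#' Validate a compchem convention scope
#'
#' Rules for computational-chemistry jobs: an initialization module (a
#' `cml:module` whose `dictRef` expands to the compchem dictionary's
#' `initialization` entry) must exist and contain exactly one molecule; that
#' molecule must declare the molecular convention (which then engages the
#' molecular handler on its subtree), have an atomArray child, and all its
#' atoms must carry three-dimensional coordinates.
#'
#' @inheritParams validate_simpleunit
#' @return A findings tibble.
#' @export
validate_compchem <- function(binding, registry = convention_registry()) {
  compchem_handler()$validate(binding, registry)
}

# ------------------------------------------------------------ unit-dictionary

unitdict_handler <- function() {
  members <- c("dictionary", "entry", "definition", "description",
               "unitList", "unit", "unitType", "name", "label")
  convention_handler(
    uri = CONV_UNITDICT,
    members = members,
    validate = function(binding, registry) {
      walk_scope(binding, registry, function(e) {
        if (!is_cml_element(e)) return(NULL)
        switch(
          e$local,
          entry = {
            out <- list()
            if (!length(direct_cml_children(e, "definition"))) {
              out <- c(out, list(finding(
                "error", "An entry MUST have a definition", e$path)))
            }
            if (length(direct_cml_children(e, "description")) > 1) {
              out <- c(out, list(finding(
                "error", "An entry MAY have at most one description",
                e$path)))
            }
            bind_rows(out)
          },
          unit = if (is.null(node_attr(e, "id"))) {
            finding("error", "A unit MUST have an id attribute", e$path)
          },
          dictionary = if (is.null(node_attr(e, "title"))) {
            finding("warning",
                    "the dictionary element SHOULD have a title but none was found",
                    e$path)
          },
          if (!e$local %in% members) {
            conv_info(e$local, CONV_UNITDICT, e$path)
          }
        )
      })
    }
  )
}

#' Validate a unit-dictionary convention scope
#'
#' Rules for unit dictionaries: every entry must have a definition and may
#' have at most one description; every unit must have an id; a dictionary
#' should have a title (warning when absent).
#'
#' @inheritParams validate_simpleunit
#' @return A findings tibble.
#' @export
validate_unit_dictionary <- function(binding,
                                     registry = convention_registry()) {
  unitdict_handler()$validate(binding, registry)
}
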