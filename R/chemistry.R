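#' Covalent radius table for bond perception
#'
#' Single-bond covalent radii in the same length unit as the atom
#' coordinates, plus the tolerance added to the radius sum when deciding
#' whether two atoms are bonded. The packaged defaults (H 0.37, C 0.77,
#' N 0.75, O 0.73, tolerance 0.40) are standard single-bond radii; a custom
#' table can be loaded from a YAML file with `radii:` and `tolerance:` keys.
#'
#' @param path Path to a radii YAML file; `NULL` for the packaged default.
#' @return A `cml_radius_table` with fields `radii` (named numeric) and
#'   `tolerance`.
#' @export
covalent_radii <- function(path = NULL) {
  path <- path %||% system.file("extdata", "covalent-radii.yaml",
                                package = "cmlcheck", mustWork = TRUE)
  raw <- yaml::read_yaml(path)
  radii <- unlist(raw$radii)
  stopifnot(is.numeric(radii), all(radii > 0))
  structure(list(radii = radii, tolerance = as.numeric(raw$tolerance)),
            class = "cml_radius_table")
}

#' Typed view of a CML molecule subtree
#'
#' Projects a `cml:molecule` element (or an XML string containing one) into
#' the typed structure the chemistry operations work on: an atoms tibble
#' (`id`, `element_type`, `x3`, `y3`, `z3`, `formal_charge`, `occupancy`,
#' `count`), a bonds tibble (`atom1`, `atom2`, `order`), nested child
#' molecule views, and the molecule-level `formal_charge` and `count`.
#' Atoms and bonds belonging to nested child molecules are attributed to the
#' child view, not the parent.
#'
#' @param x A `cml_node` molecule element, a parsed document containing one,
#'   or an XML string.
#' @return A `cml_molecule_view`.
#' @export
molecule_view <- function(x) {
  if (is.character(x) || is.raw(x)) {
    x <- cml_parse(x)
    if (is_failure(x)) abort(x$message)
  }
  stopifnot(is_element(x))
  if (!is_cml_element(x, "molecule")) {
    mols <- purrr::keep(all_elements(x), is_cml_element, local = "molecule")
    if (!length(mols)) abort("no cml:molecule element found")
    x <- mols[[1]]
  }
  build_molecule_view(x)
}

build_molecule_view <- function(mol) {
  atoms <- list()
  bonds <- list()
  children <- list()
  gather <- function(node) {
    for (ch in element_children(node)) {
      if (is_cml_element(ch, "molecule")) {
        children[[length(children) + 1L]] <<- build_molecule_view(ch)
      } else if (is_cml_element(ch, "atom")) {
        atoms[[length(atoms) + 1L]] <<- ch
        gather(ch)
      } else if (is_cml_element(ch, "bond")) {
        bonds[[length(bonds) + 1L]] <<- ch
        gather(ch)
      } else {
        gather(ch)
      }
    }
  }
  gather(mol)

  num_or <- function(node, name, default = NA_real_) {
    v <- node_attr(node, name)
    if (is.null(v)) default else as.numeric(v)
  }
  atoms_tbl <- map_dfr(atoms, function(a) {
    tibble(
      id = node_attr(a, "id") %||% NA_character_,
      element_type = node_attr(a, "elementType") %||% NA_character_,
      x3 = num_or(a, "x3"), y3 = num_or(a, "y3"), z3 = num_or(a, "z3"),
      formal_charge = {
        v <- node_attr(a, "formalCharge")
        if (is.null(v)) NA_integer_ else as.integer(v)
      },
      occupancy = num_or(a, "occupancy", 1),
      count = num_or(a, "count", 1)
    )
  })
  if (!nrow(atoms_tbl)) {
    atoms_tbl <- tibble(id = character(), element_type = character(),
                        x3 = double(), y3 = double(), z3 = double(),
                        formal_charge = integer(), occupancy = double(),
                        count = double())
  }
  bonds_tbl <- map_dfr(bonds, function(b) {
    refs <- strsplit(trimws(node_attr(b, "atomRefs2") %||% ""),
                     "[[:space:]]+")[[1]]
    tibble(atom1 = refs[1] %||% NA_character_,
           atom2 = if (length(refs) >= 2) refs[2] else NA_character_,
           order = node_attr(b, "order") %||% NA_character_)
  })
  if (!nrow(bonds_tbl)) {
    bonds_tbl <- tibble(atom1 = character(), atom2 = character(),
                        order = character())
  }
  fc <- node_attr(mol, "formalCharge")
  structure(
    list(
      formal_charge = if (is.null(fc)) NULL else as.integer(fc),
      count = num_or(mol, "count", 1),
      atoms = atoms_tbl,
      bonds = bonds_tbl,
      children = children
    ),
    class = "cml_molecule_view"
  )
}

#' @export
print.cml_molecule_view <- function(x, ...) {
  cat("<cml_molecule_view>", nrow(x$atoms), "atoms,", nrow(x$bonds),
      "bonds,", length(x$children), "child molecules\n")
  invisible(x)
}

#' @method tidy cml_molecule_view
#' @export
tidy.cml_molecule_view <- function(x, ...) x$atoms

#' @method glance cml_molecule_view
#' @export
glance.cml_molecule_view <- function(x, ...) {
  tibble(n_atoms = nrow(x$atoms), n_bonds = nrow(x$bonds),
         n_children = length(x$children),
         formal_charge = x$formal_charge %||% NA_integer_)
}

#' Effective formal charge of a molecule
#'
#' If the molecule carries an explicit `formalCharge`, that value is
#' returned. Otherwise the charge is aggregated recursively: the sum over
#' child molecules of their effective charge times their `count`, plus the
#' sum over atoms of `formalCharge * occupancy * count` (atoms without a
#' formal charge contribute 0). The aggregate must be integral.
#'
#' @param mol A [molecule_view()].
#' @param tol Numerical tolerance for the integrality check.
#' @return An integer charge. Signals `cml_nonintegral_charge_error` when
#'   occupancy/count products yield a non-integer total.
#' @export
effective_formal_charge <- function(mol, tol = 1e-9) {
  stopifnot(inherits(mol, "cml_molecule_view"))
  if (!is.null(mol$formal_charge)) return(as.integer(mol$formal_charge))
  from_children <- sum(vapply(mol$children, function(ch) {
    effective_formal_charge(ch, tol) * ch$count
  }, numeric(1)))
  charges <- ifelse(is.na(mol$atoms$formal_charge), 0,
                    mol$atoms$formal_charge)
  from_atoms <- sum(charges * mol$atoms$occupancy * mol$atoms$count)
  total <- from_children + from_atoms
  if (abs(total - round(total)) > tol) {
    abort(
      glue::glue("aggregated formal charge {total} is not an integer"),
      class = "cml_nonintegral_charge_error"
    )
  }
  as.integer(round(total))
}

atom_coords <- function(mol, require_complete = TRUE) {
  coords <- as.matrix(mol$atoms[, c("x3", "y3", "z3")])
  if (require_complete && (nrow(coords) == 0L || anyNA(coords))) {
    if (anyNA(coords)) {
      abort("all atoms must have x3, y3 and z3 coordinates",
            class = "cml_missing_coordinates_error")
    }
  }
  rownames(coords) <- mol$atoms$id
  coords
}

#' Perceive bonds from interatomic distances
#'
#' Emits one (unordered) bond for each atom pair whose Euclidean separation
#' is at most the sum of the two covalent radii plus the table's tolerance.
#' No self-bonds are produced and the result is in canonical order (sorted
#' id pairs, then lexicographic).
#'
#' @param mol A [molecule_view()] whose atoms all carry x3/y3/z3.
#' @param radii A [covalent_radii()] table.
#' @return A bonds tibble with columns `atom1`, `atom2`, `length`.
#'   Signals `cml_missing_coordinates_error` when an atom lacks a
#'   coordinate.
#' @export
perceive_bonds <- function(mol, radii = covalent_radii()) {
  stopifnot(inherits(mol, "cml_molecule_view"))
  coords <- atom_coords(mol)
  n <- nrow(coords)
  empty <- tibble(atom1 = character(), atom2 = character(),
                  length = double())
  if (n < 2) return(empty)
  unknown <- setdiff(unique(mol$atoms$element_type), names(radii$radii))
  if (length(unknown)) {
    abort(glue::glue("no covalent radius for element(s): ",
                     "{paste(unknown, collapse = ', ')}"))
  }
  r <- radii$radii[mol$atoms$element_type]
  d <- as.matrix(dist(coords))
  out <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      if (d[i, j] <= r[[i]] + r[[j]] + radii$tolerance) {
        pair <- sort(c(mol$atoms$id[[i]], mol$atoms$id[[j]]))
        out[[length(out) + 1L]] <- tibble(atom1 = pair[[1]],
                                          atom2 = pair[[2]],
                                          length = d[i, j])
      }
    }
  }
  if (!length(out)) return(empty)
  arrange(bind_rows(out), .data$atom1, .data$atom2)
}

#' Average bond length of a molecule
#'
#' Arithmetic mean of the Euclidean lengths of the molecule's bonds
#' (perceived or given). All referenced atoms must have three-dimensional
#' coordinates.
#'
#' @param mol A [molecule_view()].
#' @param bonds Optional bonds tibble with `atom1`, `atom2` columns;
#'   defaults to the molecule's own bonds.
#' @return The mean bond length. Signals `cml_no_bonds_error` on zero bonds
#'   and `cml_missing_coordinates_error` when a referenced atom lacks a
#'   coordinate.
#' @export
average_bond_length <- function(mol, bonds = NULL) {
  stopifnot(inherits(mol, "cml_molecule_view"))
  bonds <- bonds %||% mol$bonds
  if (!nrow(bonds)) {
    abort("the molecule has no bonds", class = "cml_no_bonds_error")
  }
  coords <- atom_coords(mol)
  missing <- setdiff(c(bonds$atom1, bonds$atom2), rownames(coords))
  if (length(missing)) {
    abort(glue::glue("bond references unknown atom(s): ",
                     "{paste(missing, collapse = ', ')}"))
  }
  lengths <- vapply(seq_len(nrow(bonds)), function(i) {
    sqrt(sum((coords[bonds$atom1[[i]], ] - coords[bonds$atom2[[i]], ])^2))
  }, numeric(1))
  mean(lengths)
}

#' Plot a molecule's atoms and perceived bonds
#'
#' A simple 2-D projection (x3 against y3) with bonds drawn as segments.
#'
#' @param object A [molecule_view()] with coordinates.
#' @param bonds Optional bonds tibble; defaults to [perceive_bonds()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cml_molecule_view
#' @export
autoplot.cml_molecule_view <- function(object, bonds = NULL, ...) {
  bonds <- bonds %||% perceive_bonds(object)
  atoms <- object$atoms
  seg <- dplyr::left_join(
    dplyr::left_join(bonds, atoms[, c("id", "x3", "y3")],
                     by = c(atom1 = "id")),
    atoms[, c("id", "x3", "y3")],
    by = c(atom2 = "id"), suffix = c("", "_end")
  )
  ggplot2::ggplot(atoms, ggplot2::aes(x = .data$x3, y = .data$y3)) +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x3, y = .data$y3,
                   xend = .data$x3_end, yend = .data$y3_end),
      colour = "grey50"
    ) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$element_type),
                        size = 4) +
    ggplot2::geom_text(ggplot2::aes(label = .data$id), vjust = -1.2,
                       size = 3) +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal() +
    ggplot2::labs(colour = "element")
  }
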