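mol5 <- molecule_view(mol5_document())
cml_mol <- function(inner, attrs = "") {
  paste0('<cml:molecule xmlns:cml="', CML, '"', attrs, ">", inner,
         "</cml:molecule>")
}

test_that("molecule views project atoms, bonds and nesting", {
  expect_identical(nrow(mol5$atoms), 5L)
  expect_identical(mol5$atoms$element_type, c("C", "N", "O", "H", "H"))
  expect_identical(mol5$atoms$x3[4], 0.85)
  expect_identical(nrow(mol5$bonds), 0L)

  nested <- molecule_view(cml_mol(paste0(
    '<cml:molecule formalCharge="-1"><cml:name>inner</cml:name>',
    "</cml:molecule>",
    '<cml:atomArray><cml:atom id="a1" formalCharge="1"/></cml:atomArray>')))
  expect_length(nested$children, 1)
  expect_identical(nested$children[[1]]$formal_charge, -1L)
  expect_identical(nrow(nested$atoms), 1L)  # inner atoms stay with the child

  expect_identical(glance(mol5)$n_atoms, 5L)
  expect_identical(nrow(tidy(mol5)), 5L)
})

test_that("an explicit formal charge wins over aggregation", {
  m <- molecule_view(cml_mol('<cml:atomArray><cml:atom id="a1" formalCharge="2"/></cml:atomArray>',
                             ' formalCharge="-1"'))
  expect_identical(effective_formal_charge(m), -1L)
})

test_that("missing charges default to zero and child counts multiply", {
  m <- molecule_view(cml_mol(paste0(
    "<cml:atomArray>",
    '<cml:atom id="a1" formalCharge="1"/>',
    '<cml:atom id="a2" formalCharge="-1"/>',
    '<cml:atom id="a3"/>',
    "</cml:atomArray>")))
  expect_identical(effective_formal_charge(m), 0L)

  m2 <- molecule_view(cml_mol(paste0(
    '<cml:molecule formalCharge="-1" count="2">',
    "<cml:name>anion</cml:name></cml:molecule>")))
  expect_identical(effective_formal_charge(m2), -2L)
})

test_that("non-integral aggregate charges are errors, not silently rounded", {
  m <- molecule_view(cml_mol(paste0(
    '<cml:atomArray><cml:atom id="a1" formalCharge="1" occupancy="0.5"/>',
    "</cml:atomArray>")))
  expect_error(effective_formal_charge(m),
               class = "cml_nonintegral_charge_error")
})

test_that("formal charge matches the brute-force oracle on random trees", {
  set.seed(20260920)
  for (i in 1:200) {
    spec <- random_molecule_spec(depth = 3)
    m <- molecule_view(spec_to_cml(spec))
    expect_identical(effective_formal_charge(m),
                     as.integer(round(oracle_formal_charge(spec))))
  }
})

test_that("bond perception reproduces the reference molecule's bond set", {
  bonds <- perceive_bonds(mol5)
  expect_identical(bonds$atom1, c("a1", "a1", "a1", "a2"))
  expect_identical(bonds$atom2, c("a2", "a4", "a5", "a3"))
})

test_that("bond perception handles degenerate geometries", {
  far <- molecule_view(cml_mol(paste0(
    '<cml:atomArray>',
    '<cml:atom id="h1" elementType="H" x3="0" y3="0" z3="0"/>',
    '<cml:atom id="h2" elementType="H" x3="10.0" y3="0" z3="0"/>',
    "</cml:atomArray>")))
  expect_identical(nrow(perceive_bonds(far)), 0L)

  single <- molecule_view(cml_mol(
    '<cml:atomArray><cml:atom id="a1" elementType="C" x3="0" y3="0" z3="0"/></cml:atomArray>'))
  expect_identical(nrow(perceive_bonds(single)), 0L)

  incomplete <- molecule_view(cml_mol(
    '<cml:atomArray><cml:atom id="a1" elementType="C" x3="0" y3="0"/><cml:atom id="a2" elementType="C" x3="1" y3="0" z3="0"/></cml:atomArray>'))
  expect_error(perceive_bonds(incomplete),
               class = "cml_missing_coordinates_error")
})

test_that("bond perception is invariant under reordering and translation", {
  set.seed(11)
  shift <- c(3.2, -1.7, 0.4)
  shifted <- mol5
  shifted$atoms$x3 <- shifted$atoms$x3 + shift[1]
  shifted$atoms$y3 <- shifted$atoms$y3 + shift[2]
  shifted$atoms$z3 <- shifted$atoms$z3 + shift[3]
  expect_identical(perceive_bonds(shifted)[, c("atom1", "atom2")],
                   perceive_bonds(mol5)[, c("atom1", "atom2")])

  perm <- mol5
  ord <- sample(nrow(perm$atoms))
  perm$atoms <- perm$atoms[ord, ]
  expect_identical(perceive_bonds(perm)[, c("atom1", "atom2")],
                   perceive_bonds(mol5)[, c("atom1", "atom2")])
})

test_that("average bond length matches the reference value and simple cases", {
  bonds <- perceive_bonds(mol5)
  expect_equal(average_bond_length(mol5, bonds), 1.2235, tolerance = 1e-4)

  one <- molecule_view(cml_mol(paste0(
    "<cml:atomArray>",
    '<cml:atom id="a1" elementType="C" x3="0" y3="0" z3="0"/>',
    '<cml:atom id="a2" elementType="C" x3="1" y3="0" z3="0"/>',
    "</cml:atomArray>",
    '<cml:bondArray><cml:bond atomRefs2="a1 a2"/></cml:bondArray>')))
  expect_identical(average_bond_length(one), 1)
})

test_that("average bond length is invariant under rigid motion", {
  bonds <- perceive_bonds(mol5)
  base <- average_bond_length(mol5, bonds)
  theta <- 0.83
  rot <- matrix(c(cos(theta), -sin(theta), 0,
                  sin(theta), cos(theta), 0,
                  0, 0, 1), 3, 3, byrow = TRUE)
  xyz <- as.matrix(mol5$atoms[, c("x3", "y3", "z3")]) %*% rot
  moved <- mol5
  moved$atoms$x3 <- xyz[, 1] + 5
  moved$atoms$y3 <- xyz[, 2] - 2
  moved$atoms$z3 <- xyz[, 3] + 0.1
  expect_equal(average_bond_length(moved, bonds), base, tolerance = 1e-9)
})

test_that("chemistry errors are typed and informative", {
  expect_error(average_bond_length(mol5), class = "cml_no_bonds_error")

  missing_z <- molecule_view(cml_mol(paste0(
    "<cml:atomArray>",
    '<cml:atom id="a1" elementType="C" x3="0" y3="0"/>',
    '<cml:atom id="a2" elementType="C" x3="1" y3="0" z3="0"/>',
    "</cml:atomArray>",
    '<cml:bondArray><cml:bond atomRefs2="a1 a2"/></cml:bondArray>')))
  expect_error(average_bond_length(missing_z),
               class = "cml_missing_coordinates_error")
})
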