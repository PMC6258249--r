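test_that("build_molecule constructs valid graphs and rejects bad input", {
  benzene <- make_benzene()
  expect_s3_class(benzene, "molgraph")
  expect_equal(n_atoms(benzene), 6L)
  expect_equal(n_bonds(benzene), 6L)

  # duplicate bond
  expect_error(
    build_molecule(data.frame(element = c("C", "C"), implicit_h = c(3, 3)),
                   data.frame(a = c(1, 2), b = c(2, 1))),
    "duplicate bond")
  # valence violation: C with 5 incident bonds
  expect_error(
    build_molecule(data.frame(element = rep("C", 6)),
                   data.frame(a = rep(1, 5), b = 2:6)),
    "valence")
  # self-bond
  expect_error(
    build_molecule(data.frame(element = c("C", "C")),
                   data.frame(a = 1, b = 1)),
    "identical endpoints")
})

test_that("pi-deficiency follows valence minus hydrogens minus bond load", {
  expect_equal(unname(pi_deficiency(make_benzene())), rep(1L, 6))

  # sp carbon: no H, two unresolved neighbours -> deficiency 2
  sp_chain <- make_chain(c(1L, 2L, 2L, 1L))
  expect_equal(unname(pi_deficiency(sp_chain)), c(1L, 2L, 2L, 1L))

  # trivalent N with three single bonds has deficiency 0
  pyrrole_like <- build_molecule(
    data.frame(element = c("N", "C", "C", "C"),
               implicit_h = c(0L, 3L, 3L, 3L)),
    data.frame(a = c(1, 1, 1), b = 2:4, order = c(1L, 1L, 1L)))
  expect_equal(unname(pi_deficiency(pyrrole_like)), c(0L, 0L, 0L, 0L))

  # deficiency above 2 (a bare terminal alkyne carbon) is rejected
  expect_error(
    pi_deficiency(build_molecule(
      data.frame(element = c("C", "C"), implicit_h = c(0L, 0L)),
      data.frame(a = 1, b = 2))),
    "hybridization")
})

test_that("pi-system extraction collects demanding atoms and their edges", {
  ps <- extract_pi_system(make_benzene())
  expect_length(ps$members, 6L)
  expect_equal(unname(ps$d), rep(1L, 6))
  expect_length(ps$edges, 6L)

  # fully saturated molecule -> empty pi-system
  ethane <- build_molecule(
    data.frame(element = c("C", "C"), implicit_h = c(3L, 3L)),
    data.frame(a = 1, b = 2, order = 1L))
  ps0 <- extract_pi_system(ethane)
  expect_length(ps0$members, 0L)
  expect_length(ps0$edges, 0L)

  # an unresolved bond touching a deficiency-0 atom is inconsistent
  expect_error(
    extract_pi_system(build_molecule(
      data.frame(element = c("C", "C"), implicit_h = c(3L, 1L)),
      data.frame(a = 1, b = 2))),
    "inconsistency")
})

test_that("GY1 monomer pi-system holds both aromatic and acetylenic carbons", {
  # 12 rings x 6 = 72 ring carbons (d = 1), 21 linkers x 2 = 42 sp
  # carbons (d = 2); the 22 methyl cap carbons are saturated (d = 0)
  g <- generate_gy1(1)
  ps <- extract_pi_system(g)
  expect_equal(sum(ps$d == 1L), 72L)
  expect_equal(sum(ps$d == 2L), 42L)
  expect_length(ps$members, 114L)
})

test_that("assignment validation enforces exact demand satisfaction", {
  benzene <- make_benzene()
  expect_true(validate_assignment(benzene, c(1, 0, 1, 0, 1, 0)))
  expect_false(validate_assignment(benzene, rep(0, 6)))
  expect_false(validate_assignment(benzene, rep(1, 6)))
  expect_error(validate_assignment(benzene, c(1, 0)), "cover")

  # cumulene chain: d = (1,2,2,1) satisfied by pi-orders (1,1,1)
  chain <- make_chain(c(1L, 2L, 2L, 1L))
  expect_true(validate_assignment(chain, c(1, 1, 1)))
  expect_false(validate_assignment(chain, c(0, 2, 0)))

  # applying a valid assignment resolves all bonds and keeps the formula
  res <- apply_assignment(benzene, c(1, 0, 1, 0, 1, 0))
  expect_equal(sort(res$order), c(1L, 1L, 1L, 2L, 2L, 2L))
  expect_identical(molecular_formula(res), molecular_formula(benzene))
  expect_error(apply_assignment(benzene, rep(0, 6)), "satisfy")
})

test_that("molecular formulas count implicit hydrogens in Hill order", {
  expect_equal(molecular_formula(make_benzene(), as_string = TRUE), "C6H6")
  expect_equal(molecular_formula(porphine(), as_string = TRUE), "C20H14N4")
  counts <- molecular_formula(porphine())
  expect_equal(names(counts), c("C", "H", "N"))
  expect_equal(unname(counts), c(20L, 14L, 4L))
})

test_that("explicit-hydrogen expansion preserves the formula", {
  g <- expand_hydrogens(make_benzene())
  expect_equal(n_atoms(g), 12L)
  expect_equal(sum(g$implicit_h), 0L)
  expect_equal(molecular_formula(g, as_string = TRUE), "C6H6")
  # hydrogens attached by single bonds, one per former implicit H
  expect_equal(sum(g$element == "H"), 6L)
})

test_that("odd total deficiency makes kekulization fail (parity law)", {
  for (n in c(3L, 5L, 7L, 9L)) {
    ring <- make_ring(n)
    res <- kekulize(ring, kekulize_config(seed = n))
    expect_false(res$success)
    expect_equal(res$unmatched_first_pass %% 2L, 1L)
  }
})

test_that("successful kekulization always yields a valid assignment", {
  for (s in 1:40) {
    g <- random_pi_graph(max_atoms = 12L, seed = 1000L + s)
    res <- kekulize(g, kekulize_config(seed = s))
    if (res$success) {
      expect_true(validate_assignment(g, res$assignment))
      expect_identical(molecular_formula(apply_assignment(g, res$assignment)),
                       molecular_formula(g))
    }
  }
})
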