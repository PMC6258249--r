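test_that("composition laws match the published formulas", {
  fstr <- function(g) molecular_formula(g, as_string = TRUE)
  for (n in c(1L, 2L, 3L, 10L, 100L)) {
    expect_equal(fstr(generate_nanotube(n)),
                 sprintf("C%dH48", 144L * n))
    expect_equal(fstr(generate_graphene(n)),
                 sprintf("C%dH%d", 144L * n, 12L * n + 26L))
    expect_equal(fstr(generate_gy1(n)),
                 sprintf("C%dH%d", 136L * n, 8L * n + 66L))
    expect_equal(fstr(generate_gy7(n)),
                 sprintf("C%dH%d", 188L * n, 4L * n + 82L))
    expect_equal(fstr(generate_graphyne_tube(n)),
                 sprintf("C%dH72", 192L * n))
    expect_equal(fstr(generate_polycyclopentadiene(n, "linear")),
                 sprintf("C%dH%d", 150L * n, 50L * n + 4L))
    expect_equal(fstr(generate_polycyclopentadiene(n, "cyclic")),
                 sprintf("C%dH%d", 150L * n, 50L * n))
    expect_equal(fstr(generate_polycyclopentadiene(n, "moebius")),
                 sprintf("C%dH%d", 150L * n, 50L * n))
  }
  expect_error(generate_nanotube(0), ">= 1")
  expect_error(generate_polycyclopentadiene(1, "figure8"))
})

test_that("fullerene graphs are the cubic polyhedra", {
  c20 <- generate_fullerene("C20")
  expect_equal(n_atoms(c20), 20L)
  expect_equal(n_bonds(c20), 30L)
  deg20 <- tabulate(c(c20$bond_a, c20$bond_b), nbins = 20L)
  expect_true(all(deg20 == 3L))
  expect_equal(unname(pi_deficiency(c20)), rep(1L, 20))

  c60 <- generate_fullerene("C60")
  expect_equal(n_atoms(c60), 60L)
  expect_equal(n_bonds(c60), 90L)
  deg60 <- tabulate(c(c60$bond_a, c60$bond_b), nbins = 60L)
  expect_true(all(deg60 == 3L))
  expect_equal(molecular_formula(c60, as_string = TRUE), "C60")

  expect_error(generate_fullerene("C70"))
})

test_that("porphine fixture has the canonical composition and nitrogens", {
  g <- porphine()
  expect_equal(n_atoms(g), 24L)                 # 20 C + 4 N heavy atoms
  expect_equal(molecular_formula(g, as_string = TRUE), "C20H14N4")
  d <- pi_deficiency(g)
  n_idx <- which(g$element == "N")
  expect_length(n_idx, 4L)
  # two pyrrole-type (N-H, deficiency 0), two pyridine-type (deficiency 1)
  expect_equal(sort(d[n_idx]), c(0L, 0L, 1L, 1L))
  expect_equal(sum(g$implicit_h[n_idx]), 2L)
  expect_true(kekulize(g, kekulize_config(seed = 1))$success)
})

test_that("aza substitution swaps hydrogen-free carbons for nitrogen", {
  c20 <- generate_fullerene("C20")
  expect_equal(molecular_formula(substitute_aza(c20, 2L, seed = 1),
                                 as_string = TRUE), "C18N2")
  c60 <- generate_fullerene("C60")
  expect_equal(molecular_formula(substitute_aza(c60, 8L, seed = 1),
                                 as_string = TRUE), "C52N8")
  # identity at k = 0
  expect_identical(substitute_aza(c20, 0L, seed = 1), c20)

  # hydrogen count is untouched (only H-free carbons are eligible)
  pc <- generate_polycyclopentadiene(10L, "linear")
  expect_equal(molecular_formula(substitute_aza(pc, 2L, seed = 3),
                                 as_string = TRUE), "C1498H504N2")

  expect_warning(substitute_aza(c20, 3L, seed = 1), "odd")
  expect_error(substitute_aza(c20, 100L, seed = 1), "exceeds")

  # substituted nitrogens keep three single converging bonds
  ga <- substitute_aza(c60, 2L, seed = 9)
  n_idx <- which(ga$element == "N")
  expect_equal(unname(pi_deficiency(ga)[n_idx]), c(0L, 0L))
  touched <- ga$bond_a %in% n_idx | ga$bond_b %in% n_idx
  expect_true(all(ga$order[touched] == 1L))
})

test_that("cyclic and Moebius closures differ only in the closing bonds", {
  cyc <- generate_polycyclopentadiene(2L, "cyclic")
  moe <- generate_polycyclopentadiene(2L, "moebius")
  expect_identical(molecular_formula(cyc), molecular_formula(moe))
  degc <- tabulate(c(cyc$bond_a, cyc$bond_b), nbins = n_atoms(cyc))
  degm <- tabulate(c(moe$bond_a, moe$bond_b), nbins = n_atoms(moe))
  expect_identical(sort(degc), sort(degm))
  key <- function(g) sort(paste(pmin(g$bond_a, g$bond_b),
                                pmax(g$bond_a, g$bond_b)))
  expect_false(identical(key(cyc), key(moe)))
  expect_length(setdiff(key(cyc), key(moe)), 2L)   # the crisscrossed pair
})

test_that("generator output is deterministic", {
  expect_identical(generate_gy7(3L), generate_gy7(3L))
  expect_identical(generate_graphyne_tube(2L), generate_graphyne_tube(2L))
  expect_identical(generate_structure("fullerene", fullerene_name = "C20",
                                      aza_count = 2L, seed = 4L),
                   generate_structure("fullerene", fullerene_name = "C20",
                                      aza_count = 2L, seed = 4L))
})

test_that("every generated family is kekulizable (exact check, small n)", {
  fams <- list(
    function(n) generate_nanotube(n),
    function(n) generate_graphene(n),
    function(n) generate_gy1(n),
    function(n) generate_gy7(n),
    function(n) generate_graphyne_tube(n),
    function(n) generate_polycyclopentadiene(n, "linear"),
    function(n) generate_polycyclopentadiene(n, "cyclic"),
    function(n) generate_polycyclopentadiene(n, "moebius"))
  for (gen in fams) {
    for (n in 1:3) {
      g <- gen(n)
      bt <- backtrack_exact(g)
      expect_true(bt$exists)
      expect_true(validate_assignment(g, bt$assignment))
    }
  }
})
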