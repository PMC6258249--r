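test_that("V2000 aromatic benzene reads into a six-atom pi-system", {
  lines <- write_molfile(make_benzene())
  expect_true(any(grepl("V2000", lines)))
  g <- read_molfile(lines)
  expect_equal(molecular_formula(g, as_string = TRUE), "C6H6")
  expect_equal(unname(pi_deficiency(g)), rep(1L, 6))
  expect_equal(sum(g$order == BOND_UNRESOLVED), 6L)
})

test_that("kekulized benzene writes three double and three single bonds", {
  res <- kekulize(make_benzene(), kekulize_config(seed = 1))
  gk <- apply_assignment(make_benzene(), res$assignment)
  lines <- write_molfile(gk, kekulized = TRUE)
  bond_lines <- lines[grep("V2000", lines) + 6 + (1:6)]
  types <- as.integer(substr(bond_lines, 7, 9))
  expect_equal(sort(types), c(1L, 1L, 1L, 2L, 2L, 2L))
  # an unresolved structure refuses the kekulized dialect
  expect_error(write_molfile(make_benzene(), kekulized = TRUE),
               "unresolved")
})

test_that("structures beyond 999 atoms switch to V3000 automatically", {
  g <- generate_nanotube(10)                      # 1440 carbons
  lines <- write_molfile(g)
  expect_true(any(grepl("V30 COUNTS 1440", lines)))
  expect_error(write_molfile(g, dialect = "molfile_v2000"), "V3000")
})

test_that("molfiles round-trip topology and bond orders in both dialects", {
  g <- generate_fullerene("C60")
  res <- kekulize(g, kekulize_config(seed = 2))
  gk <- apply_assignment(g, res$assignment)
  for (dial in c("molfile_v2000", "molfile_v3000")) {
    back <- read_molfile(write_molfile(gk, dialect = dial))
    expect_equal(back$element, gk$element)
    expect_equal(back$bond_a, gk$bond_a)
    expect_equal(back$bond_b, gk$bond_b)
    expect_equal(back$order, gk$order)
    expect_equal(molecular_formula(back), molecular_formula(gk))
  }
  # aromatic (unresolved) round trip
  back <- read_molfile(write_molfile(g))
  expect_equal(back$order, g$order)
  expect_equal(molecular_formula(back), molecular_formula(g))
})

test_that("hydrogen-bearing aromatic structures round-trip explicitly", {
  g <- porphine()
  back <- read_molfile(write_molfile(g, explicit_h = TRUE))
  expect_equal(molecular_formula(back, as_string = TRUE), "C20H14N4")
  expect_equal(sum(back$element == "H"), 14L)
  # heavy-atom bond orders preserved
  heavy <- back$element[back$bond_a] != "H" & back$element[back$bond_b] != "H"
  expect_equal(sum(back$order[heavy] == BOND_UNRESOLVED),
               sum(g$order == BOND_UNRESOLVED))
})

test_that("XYZ export and import preserve elements and coordinates", {
  g <- generate_fullerene("C20")
  lines <- write_xyz(g)
  expect_equal(as.integer(lines[1]), 20L)
  rec <- read_xyz(lines)
  expect_equal(rec$element, g$element)
  expect_equal(rec$coords, unname(g$coords), tolerance = 1e-4)
  # no coordinates -> export refused
  expect_error(write_xyz(porphine()), "coordinates")
})

test_that("unsupported formats give informative errors", {
  expect_error(read_structure("foo.cc1"), "not supported")
  expect_error(read_structure("foo.smi"), "unsupported")
  expect_error(read_molfile(c("a", "b")), "fewer than 4")
  expect_error(read_molfile(c("", "", "", "abc V2000")), "counts line")
})

test_that("an independent reader agrees with the written file", {
  # cross-check the V2000 writer against ChemmineR
  res <- kekulize(make_benzene(), kekulize_config(seed = 1))
  gk <- apply_assignment(make_benzene(), res$assignment)
  path <- tempfile(fileext = ".sdf")
  writeLines(c(write_molfile(gk, kekulized = TRUE), "$$$$"), path)
  sdf <- ChemmineR::read.SDFset(path)
  ab <- ChemmineR::atomblock(sdf[[1]])
  bb <- ChemmineR::bondblock(sdf[[1]])
  expect_equal(nrow(ab), 6L)
  expect_equal(nrow(bb), 6L)
  expect_equal(sort(as.integer(bb[, 3])), c(1L, 1L, 1L, 2L, 2L, 2L))
})
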