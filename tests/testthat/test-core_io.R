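test_that("unit converters are mutually consistent and invertible", {
  expect_equal(convert_energy(1, "hartree", "ev"), 27.2114)
  expect_equal(convert_energy(1, "hartree", "kcal"), 627.509)
  expect_equal(convert_energy(1, "hartree", "kj"), 2625.50)
  x <- c(0.001, 1, 53.7)
  for (u in c("ev", "kcal", "kj"))
    expect_equal(convert_energy(convert_energy(x, "hartree", u),
                                u, "hartree"),
                 x, tolerance = 1e-12)
  expect_equal(convert_length(1, "angstrom", "bohr"), 1 / 0.529177)
  expect_equal(convert_length(convert_length(x, "bohr", "angstrom"),
                              "angstrom", "bohr"),
               x, tolerance = 1e-12)
})

test_that("XYZ read handles the minimal file and rejects malformed input", {
  p <- withr::local_tempfile(fileext = ".xyz")
  writeLines(c("1", "", "O 0.0 0.0 0.0"), p)
  g <- read_xyz(p)
  expect_equal(g$elements, "O")
  expect_equal(unname(g$coords[1, ]), c(0, 0, 0))

  writeLines(c("3", "", "O 0 0 0", "H 1 0 0"), p)
  expect_error(read_xyz(p), "declared 3 atoms")
  writeLines(c("2", "", "O 0 0 0", "H 1 zero 0"), p)
  expect_error(read_xyz(p), "atom line 2")
})

test_that("XYZ write/read round-trips generated geometries", {
  p <- withr::local_tempfile(fileext = ".xyz")
  for (seed in c(1L, 7L)) {
    g <- toy_geometry("hbonded_dimer", seed = seed)
    write_xyz(g, p)
    g2 <- read_xyz(p)
    expect_equal(g2$elements, g$elements)
    expect_lt(max(abs(g2$coords - g$coords)), 1e-6)
  }
})

test_that("cube files round-trip fields and tolerate empty geometries", {
  p <- withr::local_tempfile(fileext = ".cube")
  f <- grid_field(c(0, 0, 0), c(0.2, 0.2, 0.2), c(2, 2, 2), rep(1, 8))
  g <- toy_pair()
  write_cube(f, g, p)
  rt <- read_cube(p)
  expect_equal(rt$field$values, rep(1, 8))
  expect_equal(rt$field$dims, c(2L, 2L, 2L))
  expect_equal(rt$geometry$elements, g$elements)

  # empty geometry: header atom count 0, values intact
  empty <- molecule_geometry(character(0), matrix(numeric(0), 0, 3))
  write_cube(f, empty, p)
  expect_equal(as.integer(strsplit(trimws(readLines(p)[3]),
                                   "\\s+")[[1]][1]), 0L)
  expect_equal(read_cube(p)$field$values, rep(1, 8))

  # a computed RDG field round-trips within 1e-5 relative
  grid <- make_grid(toy_pair(), spacing = 0.5, padding = 2)
  pf <- promolecular_field(toy_pair(), grid$points, toy_h_model(),
                           hessian = FALSE)
  s <- rdg_field(pf$rho, pf$grad)
  fld <- grid_field(grid$origin, grid$spacing, grid$dims, s, "rdg")
  write_cube(fld, toy_pair(), p)
  back <- read_cube(p)$field$values
  ok <- is.finite(s) & s > 0
  expect_lt(max(abs(back[ok] - s[ok]) / s[ok]), 1e-5)

  expect_error(grid_field(c(0, 0, 0), c(0.2, 0.2, 0.2), c(2, 2, 2), 1:7),
               "contract")
})

test_that("grid_points orders voxels z-fastest from the origin", {
  f <- list(origin = c(1, 2, 3), spacing = c(1, 1, 1), dims = c(2L, 2L, 2L))
  p <- grid_points(f)
  expect_equal(p[1, ], c(x = 1, y = 2, z = 3))
  expect_equal(p[2, ], c(x = 1, y = 2, z = 4))  # z varies first
  expect_equal(p[3, ], c(x = 1, y = 3, z = 3))
  expect_equal(p[5, ], c(x = 2, y = 2, z = 3))
})

test_that("summary tables are typed, unit-checked and medium-validated", {
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("#! table: orbitals", "#! unit: eV",
               "molecule\tmedium\thomo\tlumo",
               "Neu5Gc\tGas\t-8.900\t0.753",
               "Neu5Gc\t WATER \t-8.731\t0.988"), p)
  df <- read_summary_tables(p)
  expect_equal(nrow(df), 2L)
  expect_equal(attr(df, "table_kind"), "orbitals")

  # header-only file gives an empty record set
  writeLines(c("#! table: orbitals", "#! unit: eV",
               "molecule\tmedium\thomo\tlumo"), p)
  expect_equal(nrow(read_summary_tables(p)), 0L)

  # missing unit directive / wrong unit / missing column
  writeLines(c("#! table: orbitals",
               "molecule\tmedium\thomo\tlumo"), p)
  expect_error(read_summary_tables(p), "unit")
  writeLines(c("#! table: orbitals", "#! unit: kcal/mol",
               "molecule\tmedium\thomo\tlumo"), p)
  expect_error(read_summary_tables(p), "unit")
  writeLines(c("#! table: orbitals", "#! unit: eV",
               "molecule\tmedium\thomo"), p)
  expect_error(read_summary_tables(p), "lumo")

  # enthalpy table for a medium with no reference enthalpies configured
  writeLines(c("#! table: enthalpies", "#! unit: kcal/mol",
               paste("molecule", "medium", "site", "h_parent", "h_cation",
                     "h_radical", "h_anion", sep = "\t"),
               "X\twater\tO2-H\t-1000\t-850\t-590\t-680"), p)
  expect_error(read_summary_tables(p), "reference enthalpies")
})

test_that("media resolve case-insensitively and carry gas defaults", {
  m <- resolve_medium("  Gas ")
  expect_equal(m$H_hydrogen, -312.30)
  expect_equal(m$H_electron, 0.75)
  expect_equal(m$H_proton, 1.48)
  expect_equal(resolve_medium("WATER")$dielectric, 78.35)
  expect_error(resolve_medium("glycerol"), "unknown medium")
  expect_error(resolve_medium("benzene", require_refs = TRUE),
               "reference enthalpies")
  expect_error(medium("x", -1), "dielectric")
})

test_that("fragment annotations must not overlap", {
  expect_error(molecule_geometry(c("O", "H"), rbind(c(0, 0, 0), c(1, 0, 0)),
                                 fragments = list(a = 1:2, b = 2L)),
               "overlap")
})
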