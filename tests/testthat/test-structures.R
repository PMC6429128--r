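test_that("PDB read/write roundtrip preserves labels and coordinates to field width", {
  st <- pseudo_complex("1:1", n_models = 2, jitter_rms = 1, seed = 11)
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st, f)
  st2 <- read_pdb(f)
  expect_equal(length(st2$models), 2L)
  expect_equal(nrow(st2$atoms), nrow(st$atoms))
  expect_equal(st2$atoms$chain_id, st$atoms$chain_id)
  expect_equal(st2$atoms$residue_id, st$atoms$residue_id)
  expect_equal(st2$atoms$name, st$atoms$name)
  for (k in 1:2)
    expect_lt(max(abs(st2$models[[k]] - st$models[[k]])), 1e-3)
})

test_that("single-model files and MODEL-block counting behave as specified", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
    "ATOM      3  CA  GLY A   3       7.600   0.000   0.000  1.00  0.00           C",
    "END"), f)
  st <- read_pdb(f)
  expect_equal(length(st$models), 1L)
  expect_equal(nrow(st$atoms), 3L)

  # 5 equal MODEL blocks -> 5 models
  st5 <- hc_structure(st$atoms, rep(st$models, 5))
  f5 <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(st5, f5)
  expect_equal(length(read_pdb(f5)$models), 5L)

  # unequal MODEL blocks -> error
  lines <- readLines(f5)
  drop <- which(grepl("^ATOM", lines))[4]  # remove one atom from model 2
  writeLines(lines[-drop], f5)
  expect_error(read_pdb(f5), "differ in atom count")
})

test_that("unparseable coordinates are reported with their line number", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
    "ATOM      2  CA  GLY A   2       xxx..   0.000   0.000  1.00  0.00           C"),
    f)
  expect_error(read_pdb(f), "line 2")
  writeLines("REMARK nothing here", f)
  expect_error(read_pdb(f), "no ATOM")
})

test_that("overlong atom names are rejected by the writer", {
  st <- pseudo_complex("1:1", n_models = 1, seed = 1)
  st$atoms$name[1] <- "ABCDE"
  expect_error(write_pdb(st, withr::local_tempfile(fileext = ".pdb")),
               "4-character")
})

test_that("residue centre of mass is the mass-weighted mean and is translation-equivariant", {
  atoms <- tibble::tibble(
    element = c("C", "C", "O", "N"), name = c("C1", "C2", "O1", "N1"),
    residue_id = 1L, residue_name = "XXX", chain_id = "A",
    radius = 1.7, mass = c(12.011, 12.011, 15.999, 14.007))
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(1, 3, -1), c(-2, 1, 4))
  st <- hc_structure(atoms, list(coords))
  com <- residue_center_of_mass(st, 1, "A", 1)
  expect_equal(com, com_brute(coords, atoms$mass), tolerance = 1e-12)

  # two identical-mass atoms at (0,0,0), (2,0,0) -> midpoint
  st2 <- hc_structure(atoms[1:2, ], list(coords[1:2, ]))
  expect_equal(residue_center_of_mass(st2, 1, "A", 1), c(1, 0, 0))

  # single-atom residue -> its own position
  st1 <- hc_structure(atoms[3, ], list(coords[3, , drop = FALSE]))
  expect_equal(residue_center_of_mass(st1, 1, "A", 1), coords[3, ])

  # translation equivariance
  v <- c(11.2, -5.4, 0.7)
  stT <- hc_structure(atoms, list(sweep(coords, 2, -v)))
  expect_equal(residue_center_of_mass(stT, 1, "A", 1), com + v,
               tolerance = 1e-9)

  expect_error(residue_center_of_mass(st, 1, "B", 1), "no residue")
})

test_that("element radius and mass assignment uses the published table with defaults", {
  er <- hydrocomplex:::element_radius
  em <- hydrocomplex:::element_mass
  expect_equal(er(c("C", "N", "O", "S")), c(1.70, 1.55, 1.52, 1.80))
  expect_equal(er("Xx"), 1.70)   # documented default
  expect_gt(em("S"), em("O"))
})
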