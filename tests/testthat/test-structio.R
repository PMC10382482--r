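# Structure and profile I/O, assembly expansion.

make_mini_atoms <- function() {
  data.frame(type = c("ATOM", "ATOM", "HETATM"),
             elety = c("CA", "CA", "CO"),
             resid = c("ALA", "GLY", "CO"),
             chain = c("A", "A", "B"),
             resno = c(1L, 2L, 100L), insert = "",
             x = c(11.104, 12.000, 1.000),
             y = c(6.134, 7.000, 2.000),
             z = c(-6.504, -5.000, 3.000),
             o = c(1, 0.6, 1), b = c(10, 11, 20),
             elesy = c("C", "C", "CO"), stringsAsFactors = FALSE)
}

test_that("hand-written PDB fixture reads with all records retained", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00 10.00           C",
    "ATOM      2  CA  GLY A   2      12.000   7.000  -5.000  0.60 11.00           C",
    "HETATM    3 CO    CO B 100       1.000   2.000   3.000  1.00 20.00          CO",
    "END"), path)
  m <- read_structure(path)
  expect_s3_class(m, "structure_model")
  expect_equal(nrow(m$atoms), 3L)
  expect_setequal(model_chains(m), c("A", "B"))
  expect_equal(m$atoms$resno, c(1L, 2L, 100L))
  expect_equal(m$atoms$elesy[3], "CO")
  expect_equal(m$atoms$type[3], "HETATM")
})

test_that("corrupt coordinate records are reported with their line", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA  ALA A   1      11.104   6.134  -6.504  1.00 10.00           C",
    "ATOM      2  CA  GLY A   2      twelve   7.000  -5.000  1.00 11.00           C"),
    path)
  expect_error(read_structure(path), "line 2")
})

test_that("PDB and mmCIF renderings agree and round-trip exactly", {
  m <- structure_model(make_mini_atoms())
  p_pdb <- withr::local_tempfile(fileext = ".pdb")
  p_cif <- withr::local_tempfile(fileext = ".cif")
  write_structure(m, p_pdb)
  write_structure(m, p_cif)
  m_pdb <- read_structure(p_pdb)
  m_cif <- read_structure(p_cif)
  expect_lt(max(abs(model_coords(m_pdb) - model_coords(m_cif))), 1e-3)
  expect_lt(max(abs(model_coords(m_pdb) - model_coords(m))), 1e-3)
  for (col in c("chain", "resno", "resid", "elety")) {
    expect_identical(m_cif$atoms[[col]], m$atoms[[col]])
  }
})

test_that("mmCIF write preserves assembly chain suffixes", {
  m <- structure_model(make_mini_atoms())
  asm <- build_assembly(m, list(rigid_transform(),
                                rigid_transform(rotation_z(pi))))
  p <- withr::local_tempfile(fileext = ".cif")
  write_structure(asm, p)
  back <- read_structure(p)
  expect_setequal(model_chains(back), c("A", "B", "A-2", "B-2"))
  expect_lt(max(abs(model_coords(back) - model_coords(asm))), 1e-3)
})

test_that("altloc reduction keeps the highest-occupancy conformer", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  CA AALA A   1      10.000   0.000   0.000  0.40 10.00           C",
    "ATOM      2  CA BALA A   1      20.000   0.000   0.000  0.60 10.00           C",
    "END"), path)
  m <- read_structure(path)
  expect_equal(nrow(m$atoms), 1L)
  expect_equal(m$atoms$x, 20)
})

test_that("assembly expansion duplicates chains and respects rigidity", {
  m <- structure_model(make_mini_atoms())
  # identity: atom-for-atom equal copy
  same <- build_assembly(m, list(rigid_transform()))
  expect_equal(model_coords(same), model_coords(m))
  expect_identical(same$atoms$chain, m$atoms$chain)
  # 2-chain unit + twofold -> 4 chains, atom count doubles
  asm <- build_assembly(m, list(rigid_transform(),
                                rigid_transform(rotation_z(pi))))
  expect_equal(nrow(asm$atoms), 2L * nrow(m$atoms))
  expect_equal(length(model_chains(asm)), 4L)
  # per-chain interatomic distances conserved to 1e-9
  d0 <- dist(model_coords(m))
  d1 <- dist(model_coords(asm)[4:6, ])
  expect_lt(max(abs(d0 - d1)), 1e-9)
  # involution: 180 degrees about z applied twice returns to start
  r180 <- rigid_transform(rotation_z(pi))
  twice <- build_assembly(build_assembly(m, list(r180)), list(r180))
  expect_lt(max(abs(model_coords(twice) - model_coords(m))), 1e-9)
})

test_that("improper rotations are rejected", {
  m <- structure_model(make_mini_atoms())
  refl <- diag(4); refl[3, 3] <- -1
  expect_error(build_assembly(m, list(refl)), "improper")
})

test_that("SAXS profile read handles headers, sigma and invalid rows", {
  path <- withr::local_tempfile(fileext = ".dat")
  q <- seq(0.01, 1, length.out = 100)
  I <- exp(-q^2 * 50); s <- 0.01 * I
  lines <- c("# a header", "q I sigma", sprintf("%g %g %g", q, I, s))
  lines[51] <- "0.5 NaN 0.001"  # one bad row
  writeLines(lines, path)
  expect_message(p <- read_saxs_profile(path), "dropped 1")
  expect_equal(length(p$q), 99L)
  expect_false(p$unit_weights)
  # two columns -> unit weights flagged
  path2 <- withr::local_tempfile(fileext = ".dat")
  writeLines(sprintf("%g %g", q, I), path2)
  p2 <- read_saxs_profile(path2)
  expect_true(p2$unit_weights)
  expect_equal(p2$sigma, rep(1, 100))
  # fewer than 5 valid rows is unusable
  path3 <- withr::local_tempfile(fileext = ".dat")
  writeLines(c("0.1 1", "0.2 2", "0.3 3"), path3)
  expect_error(read_saxs_profile(path3), "unusable")
})

test_that("profile write-read round trip preserves values", {
  q <- seq(0.01, 0.5, length.out = 50)
  p <- saxs_profile(q, exp(-q^2 * 400), rep(0.01, 50))
  path <- withr::local_tempfile(fileext = ".dat")
  write_saxs_profile(p, path)
  back <- read_saxs_profile(path)
  expect_equal(back$q, p$q, tolerance = 1e-6)
  expect_equal(back$intensity, p$intensity, tolerance = 1e-6)
  expect_equal(back$sigma, p$sigma, tolerance = 1e-6)
})

test_that("profile constructor enforces its invariants", {
  expect_error(saxs_profile(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(saxs_profile(c(0.1, 0.2), c(1, NA)), "finite")
  expect_error(saxs_profile(c(0.1, 0.2), c(1, 1), c(1, -1)), "positive")
})
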