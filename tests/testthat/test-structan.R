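# Metal sites, coordination geometry, interfaces, hydrogen bonds and
# His-motif scanning.

octahedron_fixture <- function(d = 2.1, centre = c(3, -2, 5)) {
  dirs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  atoms <- data.frame(
    type = c("HETATM", rep("ATOM", 6)),
    elety = c("ZN", rep("NE2", 6)),
    resid = c("ZN", rep("HIS", 6)),
    chain = "A", resno = c(500L, 1:6), insert = "",
    x = centre[1] + c(0, d * dirs[, 1]),
    y = centre[2] + c(0, d * dirs[, 2]),
    z = centre[3] + c(0, d * dirs[, 3]),
    o = 1, b = 0, elesy = c("ZN", rep("N", 6)),
    stringsAsFactors = FALSE)
  structure_model(atoms)
}

test_that("a synthetic octahedron is found and classified exactly", {
  m <- octahedron_fixture()
  sites <- find_metal_sites(m, cutoff = 2.8)
  expect_length(sites, 1L)
  s <- sites[[1]]
  expect_equal(nrow(s$donors), 6L)
  expect_equal(s$n_protein_residues, 6L)
  expect_equal(s$geometry$label, "octahedral")
  expect_lt(s$geometry$angle_rmsd, 1e-6)
  # cutoff 0 leaves every site empty
  empty <- find_metal_sites(m, cutoff = 0)
  expect_equal(nrow(empty[[1]]$donors), 0L)
  # no metals present is an empty list, not an error
  no_metal <- m
  no_metal$atoms <- m$atoms[-1, ]
  expect_length(find_metal_sites(structure_model(no_metal$atoms)), 0L)
})

test_that("ideal trigonal bipyramid classifies with zero angle RMSD", {
  tbp <- saxsens:::ideal_geometries(5)$trigonal_bipyramidal
  site <- list(metal_pos = c(0, 0, 0), donor_pos = 2.2 * tbp)
  g <- classify_geometry(site)
  expect_equal(g$label, "trigonal_bipyramidal")
  expect_lt(g$angle_rmsd, 1e-6)
  few <- classify_geometry(list(metal_pos = c(0, 0, 0),
                                donor_pos = tbp[1:2, ]))
  expect_equal(few$label, "other")
})

test_that("geometry labels agree with the permutation oracle", {
  set.seed(404)
  labels_impl <- character(100); labels_oracle <- character(100)
  for (k in 1:100) {
    cn <- sample(c(3L, 5L, 6L), 1)
    base <- switch(as.character(cn),
      "3" = saxsens:::ideal_geometries(3)[[sample(2, 1)]],
      "5" = saxsens:::ideal_geometries(5)[[sample(2, 1)]],
      "6" = saxsens:::ideal_geometries(6)$octahedral)
    R <- test_rotation()
    dirs <- base %*% t(R)
    # random angular distortion, sometimes beyond the acceptance limit
    jitter <- matrix(rnorm(3 * cn, sd = sample(c(0.05, 0.2, 0.45), 1)),
                     ncol = 3)
    dirs <- dirs + jitter
    dirs <- dirs / sqrt(rowSums(dirs^2))
    donor_pos <- 2.1 * dirs[sample(cn), , drop = FALSE]
    site <- list(metal_pos = c(0, 0, 0), donor_pos = donor_pos)
    labels_impl[k] <- classify_geometry(site)$label
    labels_oracle[k] <- oracle_classify(c(0, 0, 0), donor_pos)
  }
  expect_identical(labels_impl, labels_oracle)
})

test_that("distant chains bury no area; touching spheres match caps", {
  far <- structure_model(data.frame(
    type = "ATOM", elety = "CA", resid = "ALA",
    chain = c("A", "B"), resno = 1L, insert = "",
    x = c(0, 100), y = 0, z = 0, o = 1, b = 0, elesy = "C",
    stringsAsFactors = FALSE))
  expect_lt(abs(interface_area(far, "A", "B")), 1)
  # two identical touching solvent spheres: buried cap area 2 pi R h
  d <- 4.0
  near <- far
  near$atoms$x <- c(0, d)
  R <- 1.70 + 1.4
  h <- R - d / 2
  expect_equal(interface_area(near, "A", "B", n_points = 2000),
               2 * pi * R * h, tolerance = 0.02)
  expect_error(interface_area(near, "A", "C"), "empty")
})

test_that("SASA converges against a high-density reference", {
  m <- build_monomer(seed = 3, tail = FALSE)
  m$atoms <- m$atoms[1:80, ]
  m <- structure_model(m$atoms)
  s960 <- sum(shrake_rupley_sasa(m, n_points = 960))
  s10k <- sum(shrake_rupley_sasa(m, n_points = 10000))
  expect_lt(abs(s960 - s10k) / s10k, 0.01)
})

test_that("SASA and metal detection are rigid-motion invariant", {
  m <- octahedron_fixture()
  R <- test_rotation()
  m2 <- m
  m2$atoms[, c("x", "y", "z")] <-
    sweep(model_coords(m) %*% t(R), 2, c(12, 3, -9), `+`)
  s1 <- find_metal_sites(m); s2 <- find_metal_sites(m2)
  expect_identical(s1[[1]]$signature, s2[[1]]$signature)
  expect_equal(s1[[1]]$donors$distance, s2[[1]]$donors$distance,
               tolerance = 1e-9)
  # the Fibonacci point lattice is orientation-dependent, so areas agree
  # to the sampling resolution, not machine precision
  a1 <- shrake_rupley_sasa(m); a2 <- shrake_rupley_sasa(m2)
  expect_equal(sum(a1), sum(a2), tolerance = 0.01)
})

test_that("designed inter-strand hydrogen bonds are all recovered", {
  fx <- two_strand_hbond_fixture(n_bonds = 4)
  bonds <- hydrogen_bonds(fx$model, "A", "B")
  expect_equal(nrow(bonds), fx$designed)
  expect_true(all(bonds$distance <= 3.5))
  expect_true(all(is.na(bonds$angle) | bonds$angle >= 120))
  # tightening the distance criterion to 2.0 A removes every bond
  none <- hydrogen_bonds(fx$model, "A", "B",
                         hbond_criteria(da_max = 2.0))
  expect_equal(nrow(none), 0L)
  # criteria are echoed in the output
  expect_equal(attr(bonds, "criteria")$da_max, 3.5)
})

test_that("unknown residues are skipped with a warning", {
  fx <- two_strand_hbond_fixture(n_bonds = 2)
  fx$model$atoms$resid[1:4] <- "XYZ"
  expect_warning(hydrogen_bonds(fx$model, "A", "B"), "XYZ")
})

test_that("His-motif scan finds runs, contacts and 3D motifs", {
  # no histidines at all
  m <- build_monomer(seed = 1)
  expect_equal(nrow(his_motif_scan(m)), 0L)
  # a 6xHis run contacting a metal whose other ligand lies 50 residues
  # away in sequence: a three-dimensional motif
  rows <- list()
  add <- function(chain, resno, resid, elety, elesy, p, type = "ATOM") {
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, elety = elety, resid = resid, chain = chain,
      resno = resno, insert = "", x = p[1], y = p[2], z = p[3],
      o = 1, b = 0, elesy = elesy, stringsAsFactors = FALSE)
  }
  for (i in 1:6) add("A", 100L + i, "HIS", "CA", "C", c(4 * i, 10, 0))
  add("A", 101L, "HIS", "NE2", "N", c(2.1, 0, 0))
  add("A", 153L, "GLU", "OE1", "O", c(-2.1, 0, 0))
  add("A", 153L, "GLU", "CA", "C", c(-5, 0, 0))
  add("M", 1L, "NI", "NI", "NI", c(0, 0, 0), type = "HETATM")
  m3d <- structure_model(do.call(rbind, rows))
  scan <- his_motif_scan(m3d)
  expect_equal(nrow(scan), 1L)
  expect_equal(scan$run_start, 101L)
  expect_equal(scan$run_length, 6L)
  expect_equal(scan$metal_contacts, 1L)
  expect_equal(scan$motif_class, "three_dimensional")
  # the same coordination within a short window is linear
  m_lin <- m3d
  m_lin$atoms$resno[m_lin$atoms$resno == 153L] <- 105L
  m_lin$atoms$resid[m_lin$atoms$resid == "GLU"] <- "HIS"
  scan_lin <- his_motif_scan(structure_model(m_lin$atoms))
  expect_equal(scan_lin$motif_class[1], "linear")
  # a gap in the modelled sequence breaks the run
  gap <- m3d$atoms[!(m3d$atoms$resno == 104L & m3d$atoms$chain == "A"), ]
  expect_equal(nrow(his_motif_scan(structure_model(gap))), 0L)
})

test_that("the synthetic TetrHis assembly reproduces its design topology", {
  m <- synthetic_tetrhis_assembly(seed = 2)
  sites <- find_metal_sites(m)
  expect_length(sites, 8L)
  expect_length(attr(sites, "classes"), 4L)
  counts <- vapply(sites, `[[`, integer(1), "n_protein_residues")
  expect_true(all(counts %in% 3:5))
  geoms <- vapply(sites, function(s) s$geometry$label, character(1))
  expect_setequal(unique(geoms),
                  c("trigonal_bipyramidal", "octahedral",
                    "trigonal_pyramidal"))
})
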