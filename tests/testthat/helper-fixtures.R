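# Shared fixtures and independent oracles for the test suite.  Expensive
# objects are built once per run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A mid-size mixed pool shared by EOM/state tests.
shared_pool <- function() {
  cached("pool", function() {
    generate_pool(c(closed_monomer = 30, open_monomer = 15, tetramer = 15),
                  seed = 101)
  })
}

# Analytic solid-sphere form factor and distance distribution.
sphere_intensity <- function(q, R, i0 = 1) {
  x <- q * R
  i0 * (3 * (sin(x) - x * cos(x)) / x^3)^2
}

sphere_pr <- function(r, R) {
  p <- r^2 * (1 - 1.5 * (r / (2 * R)) + 0.5 * (r / (2 * R))^3)
  p[r < 0 | r > 2 * R] <- 0
  p
}

# Independent brute-force Debye oracle: full n x n double sum evaluated
# per q from the complete distance matrix (a different formulation from
# the package's pair-vector / binned paths).
debye_oracle <- function(positions, f, q) {
  n <- nrow(positions)
  D <- as.matrix(stats::dist(positions))
  F2 <- outer(f, f)
  vapply(q, function(qk) {
    S <- qk * D
    sterm <- matrix(1, n, n)
    nz <- S != 0
    sterm[nz] <- sin(S[nz]) / S[nz]
    sum(F2 * sterm)
  }, numeric(1))
}

# Independent geometry-classification oracle: enumerates permutations with
# its own angle computation and ideal tables.
oracle_classify <- function(metal_pos, donor_pos, max_rmsd = 25) {
  dirs <- sweep(donor_pos, 2, metal_pos)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  n <- nrow(dirs)
  ideals <- list()
  if (n == 3) {
    ideals$trigonal_pyramidal <- rbind(
      c(2 * sqrt(2) / 3, 0, -1 / 3),
      c(-sqrt(2) / 3, sqrt(2 / 3), -1 / 3),
      c(-sqrt(2) / 3, -sqrt(2 / 3), -1 / 3))
    ideals$trigonal_planar <- rbind(c(1, 0, 0), c(-0.5, sqrt(3) / 2, 0),
                                    c(-0.5, -sqrt(3) / 2, 0))
  } else if (n == 5) {
    ideals$trigonal_bipyramidal <- rbind(
      c(0, 0, 1), c(0, 0, -1), c(1, 0, 0),
      c(-0.5, sqrt(3) / 2, 0), c(-0.5, -sqrt(3) / 2, 0))
    ideals$square_pyramidal <- rbind(c(0, 0, 1), c(1, 0, 0), c(0, 1, 0),
                                     c(-1, 0, 0), c(0, -1, 0))
  } else if (n == 6) {
    ideals$octahedral <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                               c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  } else {
    return("other")
  }
  ang <- function(u, v) acos(max(-1, min(1, sum(u * v)))) * 180 / pi
  pairs <- utils::combn(n, 2)
  obs <- apply(pairs, 2, function(ij) ang(dirs[ij[1], ], dirs[ij[2], ]))
  perm_list <- function(v) {
    if (length(v) <= 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perm_list(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best_label <- "other"; best_rmsd <- Inf
  for (nm in names(ideals)) {
    idl <- ideals[[nm]]
    for (perm in perm_list(seq_len(n))) {
      ideal_ang <- apply(pairs, 2, function(ij) {
        ang(idl[perm[ij[1]], ], idl[perm[ij[2]], ])
      })
      rmsd <- sqrt(mean((obs - ideal_ang)^2))
      if (rmsd < best_rmsd) { best_rmsd <- rmsd; best_label <- nm }
    }
  }
  if (best_rmsd > max_rmsd ||
      !best_label %in% c("trigonal_pyramidal", "trigonal_bipyramidal",
                         "octahedral")) {
    return("other")
  }
  best_label
}

# Random rotation for invariance tests.
test_rotation <- function() {
  q_ <- qr(matrix(stats::rnorm(9), 3))
  R <- qr.Q(q_)
  if (det(R) < 0) R[, 1] <- -R[, 1]
  R
}

# Two-strand fixture with an exactly designed number of inter-chain
# backbone hydrogen bonds (ideal amide geometry: the placed H points
# straight at the acceptor, N...O = 2.9 A).  Residues are spaced widely so
# no accidental contacts arise; only chain A donates.
two_strand_hbond_fixture <- function(n_bonds = 3) {
  rows <- list()
  add <- function(chain, resno, elety, elesy, p) {
    rows[[length(rows) + 1]] <<- data.frame(
      type = "ATOM", eleno = 0L, elety = elety, resid = "ALA",
      chain = chain, resno = resno, insert = "",
      x = p[1], y = p[2], z = p[3], o = 1, b = 0, elesy = elesy,
      stringsAsFactors = FALSE)
  }
  n_res <- n_bonds + 1  # residue 1 only provides the preceding carbonyl C
  for (i in seq_len(n_res)) {
    N <- c(8 * i, 0, 0)
    add("A", i, "N", "N", N)
    add("A", i, "CA", "C", N + c(1.05, -1.05, 0))
    add("A", i, "C", "C", c(8 * (i + 1) - 1.05, -1.05, 0))
    add("A", i, "O", "O", c(8 * i + 2, -6, 0))
    if (i >= 2) {
      # acceptor O of chain B straight along the ideal N-H direction
      add("B", i, "O", "O", N + c(0, 2.9, 0))
    }
    add("B", i, "N", "N", c(8 * i + 4, 8, 0))
    add("B", i, "CA", "C", c(8 * i + 5, 9, 0))
    add("B", i, "C", "C", c(8 * (i + 1) + 3, 7, 0))
  }
  list(model = structure_model(do.call(rbind, rows)), designed = n_bonds)
}
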