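# Synthetic conformer generation and mixture simulation.

test_that("monomer states sit on the right side of the thresholds", {
  spec <- conformer_spec()
  for (seed in 1:3) {
    mc <- build_monomer(spec, "closed", seed, tail = FALSE)
    xyz <- model_coords(mc)
    n <- spec$n_res_domain
    sep <- sqrt(sum((colMeans(xyz[1:n, ]) -
                       colMeans(xyz[(n + 1):(2 * n), ]))^2))
    expect_lt(sep, spec$open_threshold)
    mo <- build_monomer(spec, "open", seed, tail = FALSE)
    xyz <- model_coords(mo)
    sep <- sqrt(sum((colMeans(xyz[1:n, ]) -
                       colMeans(xyz[(n + 1):(2 * n), ]))^2))
    expect_gte(sep, spec$open_threshold)
  }
})

test_that("generation is bitwise deterministic in (spec, seed)", {
  expect_identical(model_coords(build_monomer(seed = 42)),
                   model_coords(build_monomer(seed = 42)))
  expect_identical(model_coords(build_tetramer(seed = 42)),
                   model_coords(build_tetramer(seed = 42)))
  expect_false(identical(model_coords(build_monomer(seed = 42)),
                         model_coords(build_monomer(seed = 43))))
})

test_that("appended tails keep the virtual bond and avoid clashes", {
  m0 <- build_monomer(seed = 3, tail = FALSE)
  expect_identical(append_tail(m0, 0), m0)
  m <- append_tail(m0, 39, seed = 9)
  xyz <- model_coords(m)
  n0 <- nrow(m0$atoms)
  tail_xyz <- xyz[n0:(n0 + 39), ]  # anchor + walk
  steps <- sqrt(rowSums(diff(tail_xyz)^2))
  expect_lt(max(abs(steps - 3.8)), 1e-9)
  # clash distance against the parent
  parent <- xyz[seq_len(n0 - 1), ]
  for (k in 2:nrow(tail_xyz)) {
    expect_gte(min(sqrt(colSums((t(parent) - tail_xyz[k, ])^2))),
               2 * 1.9 - 1e-6)
  }
})

test_that("tail end-to-end distance matches a self-avoiding walk oracle", {
  # oracle: independently coded self-avoiding walks with the same step
  # length, clash rule and retry/restart sampling scheme
  oracle_walk <- function(n, seed) {
    set.seed(seed)
    repeat {
      pos <- matrix(0, 1, 3)
      ok <- TRUE
      for (k in seq_len(n)) {
        placed <- FALSE
        for (try_ in 1:300) {
          u <- rnorm(3); u <- u / sqrt(sum(u^2))
          cand <- pos[nrow(pos), ] + 3.8 * u
          d <- sqrt(colSums((t(pos) - cand)^2))
          if (all(d[-length(d)] >= 3.8 - 1e-9) || nrow(pos) == 1) {
            pos <- rbind(pos, cand); placed <- TRUE; break
          }
        }
        if (!placed) { ok <- FALSE; break }
      }
      if (ok) return(sqrt(sum((pos[nrow(pos), ] - pos[1, ])^2)))
    }
  }
  n_rep <- 400
  oracle_e2e <- mean(vapply(seq_len(n_rep), function(s) {
    oracle_walk(39, s)
  }, numeric(1)))
  anchor_model <- structure_model(data.frame(
    type = "ATOM", elety = "CA", resid = "ALA", chain = "A", resno = 1L,
    x = 0, y = 0, z = 0, o = 1, b = 0, elesy = "C"))
  ours <- mean(vapply(seq_len(n_rep), function(s) {
    m <- append_tail(anchor_model, 39, seed = 1000 + s)
    xyz <- model_coords(m)
    sqrt(sum((xyz[nrow(xyz), ] - xyz[1, ])^2))
  }, numeric(1)))
  expect_lt(abs(ours - oracle_e2e) / oracle_e2e, 0.10)
  # self-avoidance expands the chain beyond the freely-jointed baseline
  expect_gt(ours, 3.8 * sqrt(39))
})

test_that("tetramers are C2 symmetric with the configured channel", {
  tet <- build_tetramer(seed = 4)
  expect_equal(length(model_chains(tet)), 4L)
  # chain centroids map onto each other under the twofold about z
  cents <- t(vapply(model_chains(tet), function(ch) {
    colMeans(model_coords(tet)[tet$atoms$chain == ch, ])
  }, numeric(3)))
  flip <- cents %*% diag(c(-1, -1, 1))
  for (i in seq_len(4)) {
    expect_lt(min(sqrt(rowSums(sweep(cents, 2, flip[i, ])^2))), 1e-6)
  }
  # channel width: minimum bead-to-axis distance within 1 A of the target
  tet15 <- build_tetramer(conformer_spec(channel_width = 15), seed = 4)
  xyz <- model_coords(tet15)
  rmin <- min(sqrt(xyz[, 1]^2 + xyz[, 2]^2))
  expect_gte(rmin, 14)
  expect_lte(rmin, 16)
})

test_that("tetramer Rg exceeds monomer Rg for every seed", {
  for (seed in 1:5) {
    expect_gt(coordinate_rg(build_tetramer(seed = seed)),
              coordinate_rg(build_monomer(seed = seed)))
  }
})

test_that("pools honour requested label counts and Rg ordering", {
  pool <- shared_pool()
  expect_equal(unname(table(pool$labels)[c("closed_monomer",
                                           "open_monomer", "tetramer")]),
               c(30L, 15L, 15L), ignore_attr = TRUE)
  rg_by <- tapply(pool$rg, pool$labels, mean)
  expect_lt(rg_by["closed_monomer"], rg_by["open_monomer"])
  expect_lt(rg_by["open_monomer"], rg_by["tetramer"])
  expect_error(generate_pool(c(closed_monomer = 0)), "empty")
})

test_that("monomer/tetramer pools give a bimodal Rg distribution", {
  pool <- shared_pool()
  rg <- pool$rg[pool$labels != "open_monomer"]
  dens <- density(rg, bw = "SJ")
  peaks <- which(diff(sign(diff(dens$y))) == -2) + 1L
  peaks <- peaks[dens$y[peaks] > 0.05 * max(dens$y)]
  expect_gte(length(peaks), 2L)
  valley <- min(dens$y[seq(min(peaks), max(peaks))])
  expect_lt(valley, 0.5 * min(dens$y[range(peaks)]))
})

test_that("pool serialisation round-trips labels, Rg and profiles", {
  dir <- withr::local_tempdir()
  pool <- generate_pool(c(closed_monomer = 2, tetramer = 1), seed = 5,
                        q_grid = seq(0.01, 0.3, length.out = 40))
  suppressWarnings(write_pool(pool, dir))
  back <- read_pool(dir)
  expect_identical(back$labels, pool$labels)
  expect_equal(back$rg, pool$rg, tolerance = 1e-6)
  expect_equal(back$profiles, pool$profiles, tolerance = 1e-6)
  # reduced-scale emulation of the study pool serialises completely
  expect_equal(length(back$conformers), 3L)
})

test_that("simulated mixtures are exact weight-averages before noise", {
  pool <- shared_pool()
  single <- mixture_truth(c(tetramer = 1))
  idx <- which(pool$labels == "tetramer")
  exact <- simulate_experiment(pool, single, noise = FALSE)
  expect_equal(exact$intensity, rowMeans(pool$profiles[, idx]),
               tolerance = 1e-12)
  mixed <- simulate_experiment(
    pool, mixture_truth(c(closed_monomer = 0.5, tetramer = 0.5)),
    noise = FALSE)
  half <- 0.5 * rowMeans(pool$profiles[, pool$labels == "closed_monomer"]) +
    0.5 * rowMeans(pool$profiles[, idx])
  expect_equal(mixed$intensity, half, tolerance = 1e-12)
  expect_error(mixture_truth(c(closed_monomer = 0.5, tetramer = 0.6)),
               "sum to 1")
})

test_that("noise residuals are standard normal against the true sigma", {
  pool <- shared_pool()
  truth <- mixture_truth(c(closed_monomer = 0.7, tetramer = 0.3),
                         seed = 31)
  noiseless <- simulate_experiment(pool, truth, noise = FALSE)
  # pool the standardised residuals over several noise seeds
  z <- unlist(lapply(1:4, function(s) {
    tr <- truth; tr$seed <- s
    noisy <- simulate_experiment(pool, tr)
    (noisy$intensity - noiseless$intensity) / noisy$sigma
  }))
  expect_lt(abs(mean(z)), 3 / sqrt(length(z)))
  expect_lt(abs(var(z) - 1), 0.15)
})
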