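# Genetic-algorithm selection of a small sub-ensemble whose weighted
# average theoretical curve best fits a target profile.  Chromosomes are
# multisets of conformer ids (repetition = weight quantisation in units of
# 1/ensemble_size); fitness is the reduced chi of the multiset-mean curve
# after a closed-form scale/offset fit.

#' Genetic-algorithm parameters
#'
#' @param ensemble_size Slots per chromosome (models repeatable).
#' @param population Chromosomes per generation.
#' @param generations Maximum generations.
#' @param patience Early stop after this many stagnant generations.
#' @param mutation_rate Per-slot mutation probability.
#' @param crossover_rate Per-pair uniform crossover probability.
#' @param elitism Chromosomes copied unchanged each generation.
#' @param repeats Independent GA runs (per-repeat seeds are
#'   `seed + repeat - 1`).
#' @param seed Integer master seed.
#' @param fit_offset Allow a constant offset in the curve fit.
#' @return An object of class `ga_params`.
#' @export
ga_params <- function(ensemble_size = 20L, population = 50L,
                      generations = 1000L, patience = 100L,
                      mutation_rate = 0.1, crossover_rate = 0.5,
                      elitism = 2L, repeats = 10L, seed = 1L,
                      fit_offset = TRUE) {
  stopifnot(ensemble_size >= 1, population >= 4, generations >= 1,
            patience >= 1, mutation_rate >= 0, mutation_rate <= 1,
            crossover_rate >= 0, crossover_rate <= 1,
            elitism >= 0, repeats >= 1)
  structure(list(ensemble_size = as.integer(ensemble_size),
                 population = as.integer(population),
                 generations = as.integer(generations),
                 patience = as.integer(patience),
                 mutation_rate = mutation_rate,
                 crossover_rate = crossover_rate,
                 elitism = as.integer(elitism),
                 repeats = as.integer(repeats), seed = as.integer(seed),
                 fit_offset = fit_offset),
            class = "ga_params")
}

#' Closed-form scale/offset fit of a model curve to a target
#'
#' Minimises `sum(((target - scale * model - offset) / sigma)^2)` in closed
#' form (2x2 normal equations) and reports the reduced chi
#' `sqrt(min / (n - k))` with `k` the number of fitted constants.
#'
#' @param model_curve,target [saxs_profile()] objects on a common q grid;
#'   the target must carry uncertainties.
#' @param fit_offset Fit the additive constant (default) or fix it at 0.
#' @param fit_scale Fit the multiplicative scale (default) or fix it at 1.
#' @return list with `scale`, `offset`, `chi`.
#' @export
fit_scale_offset <- function(model_curve, target, fit_offset = TRUE,
                             fit_scale = TRUE) {
  if (length(model_curve$q) != length(target$q) ||
      any(model_curve$q != target$q)) {
    stop("model and target q grids differ", call. = FALSE)
  }
  m <- model_curve$intensity; y <- target$intensity
  w <- 1 / target$sigma^2
  n <- length(y)
  if (fit_scale && stats::sd(m) == 0) {
    stop("degenerate system: constant model curve", call. = FALSE)
  }
  if (fit_scale && fit_offset) {
    a11 <- sum(w * m * m); a12 <- sum(w * m); a22 <- sum(w)
    b1 <- sum(w * m * y); b2 <- sum(w * y)
    det_ <- a11 * a22 - a12^2
    if (abs(det_) < 1e-300) stop("degenerate system", call. = FALSE)
    scale <- (b1 * a22 - b2 * a12) / det_
    offset <- (a11 * b2 - a12 * b1) / det_
    k <- 2L
  } else if (fit_scale) {
    scale <- sum(w * m * y) / sum(w * m * m); offset <- 0; k <- 1L
  } else if (fit_offset) {
    scale <- 1; offset <- sum(w * (y - m)) / sum(w); k <- 1L
  } else {
    scale <- 1; offset <- 0; k <- 0L
  }
  ss <- sum(w * (y - scale * m - offset)^2)
  list(scale = scale, offset = offset,
       chi = sqrt(max(ss, 0) / max(n - k, 1L)))
}

# Vectorised fitness of count-matrix chromosomes.
# P: nq x npool profile matrix; C: npool x pop multiplicity matrix.
chi_of_counts <- function(P, C, y, w, K, fit_offset) {
  M <- (P %*% C) / K                     # nq x pop mean curves
  n <- length(y)
  b1 <- as.numeric(crossprod(M, w * y))
  a11 <- colSums(M * M * w)
  if (fit_offset) {
    a12 <- as.numeric(crossprod(M, w))
    a22 <- sum(w)
    b2 <- sum(w * y)
    det_ <- a11 * a22 - a12^2
    scale <- (b1 * a22 - b2 * a12) / det_
    offset <- (a11 * b2 - a12 * b1) / det_
    k <- 2L
  } else {
    scale <- b1 / a11
    offset <- rep(0, ncol(M))
    k <- 1L
  }
  resid <- y - sweep(M, 2, scale, `*`) - matrix(offset, n, ncol(M),
                                                byrow = TRUE)
  ss <- colSums(w * resid^2)
  list(chi = sqrt(pmax(ss, 0) / max(n - k, 1L)), scale = scale,
       offset = offset)
}

counts_from_chrom <- function(chrom, npool) {
  tabulate(chrom, nbins = npool)
}

# One GA run; returns best multiset and its fit.
ga_run <- function(P, y, w, params, seed) {
  npool <- ncol(P); K <- params$ensemble_size; pop <- params$population
  with_seed(seed, {
    chroms <- matrix(sample.int(npool, K * pop, replace = TRUE), K, pop)
    best_chi <- Inf; best_chrom <- chroms[, 1]; stagnant <- 0L
    for (gen in seq_len(params$generations)) {
      C <- matrix(0L, npool, pop)
      for (j in seq_len(pop)) C[, j] <- counts_from_chrom(chroms[, j], npool)
      fit <- chi_of_counts(P, C, y, w, K, params$fit_offset)
      ord <- order(fit$chi)
      if (fit$chi[ord[1]] < best_chi - 1e-12) {
        best_chi <- fit$chi[ord[1]]; best_chrom <- chroms[, ord[1]]
        stagnant <- 0L
      } else {
        stagnant <- stagnant + 1L
        if (stagnant >= params$patience) break
      }
      # tournament selection (k = 3)
      parents <- matrix(0L, K, pop)
      for (j in seq_len(pop)) {
        cand <- sample.int(pop, 3L)
        parents[, j] <- chroms[, cand[which.min(fit$chi[cand])]]
      }
      # uniform crossover on consecutive pairs
      for (j in seq(1L, pop - 1L, by = 2L)) {
        if (stats::runif(1) < params$crossover_rate) {
          swap <- stats::runif(K) < 0.5
          tmp <- parents[swap, j]
          parents[swap, j] <- parents[swap, j + 1L]
          parents[swap, j + 1L] <- tmp
        }
      }
      # per-slot mutation to a uniform random pool member
      mut <- matrix(stats::runif(K * pop) < params$mutation_rate, K, pop)
      if (any(mut)) {
        parents[mut] <- sample.int(npool, sum(mut), replace = TRUE)
      }
      # elitism
      if (params$elitism > 0L) {
        keep <- ord[seq_len(min(params$elitism, pop))]
        parents[, seq_along(keep)] <- chroms[, keep]
      }
      chroms <- parents
    }
    Cb <- matrix(counts_from_chrom(best_chrom, npool), ncol = 1)
    fb <- chi_of_counts(P, Cb, y, w, K, params$fit_offset)
    list(chi = fb$chi[1], scale = fb$scale[1], offset = fb$offset[1],
         counts = Cb[, 1], generations = gen)
  })
}

# Interpolate pool profiles onto the target grid (cubic), if needed.
pool_profile_matrix <- function(pool, target) {
  if (is.null(pool$profiles)) {
    stop("pool has no precomputed profiles", call. = FALSE)
  }
  if (length(pool$q) == length(target$q) && all(pool$q == target$q)) {
    return(pool$profiles)
  }
  if (min(target$q) < min(pool$q) || max(target$q) > max(pool$q)) {
    stop("target q range extends beyond pool profiles", call. = FALSE)
  }
  message("interpolating pool profiles onto target grid (cubic spline)")
  apply(pool$profiles, 2, function(I) {
    stats::spline(pool$q, I, xout = target$q, method = "natural")$y
  })
}

#' Ensemble optimisation by genetic algorithm
#'
#' Selects a multiset of `ensemble_size` pool conformers whose mean
#' theoretical curve, after a closed-form scale/offset fit, minimises the
#' reduced chi against the target.  `repeats` independent runs are
#' performed; the best is reported and all per-repeat solutions retained
#' (population uncertainties bootstrap over them).
#'
#' @param pool An `ensemble_pool` with profiles.
#' @param target A [saxs_profile()] with uncertainties.
#' @param params A [ga_params()].
#' @return An `eom_result`: `multiplicities` (named by conformer index,
#'   summing to `ensemble_size`), `chi_eom = min(per_repeat_chis)`, `scale`,
#'   `offset`, `per_repeat_chis`, `per_repeat_counts`,
#'   `rg_distribution_selected` / `_pool`, `ensemble_size`.
#' @export
run_eom <- function(pool, target, params = ga_params()) {
  npool <- length(pool$labels)
  if (npool < 2L) stop("pool must contain at least 2 conformers",
                       call. = FALSE)
  P <- pool_profile_matrix(pool, target)
  y <- target$intensity; w <- 1 / target$sigma^2
  runs <- lapply(seq_len(params$repeats), function(r) {
    ga_run(P, y, w, params, seed = params$seed + r - 1L)
  })
  chis <- vapply(runs, `[[`, numeric(1), "chi")
  best <- runs[[which.min(chis)]]
  counts <- best$counts
  names(counts) <- seq_len(npool)
  sel_idx <- rep(seq_len(npool), counts)
  structure(list(multiplicities = counts[counts > 0],
                 chi_eom = min(chis), scale = best$scale,
                 offset = best$offset, per_repeat_chis = chis,
                 per_repeat_counts = lapply(runs, `[[`, "counts"),
                 rg_distribution_selected = pool$rg[sel_idx],
                 rg_distribution_pool = pool$rg,
                 ensemble_size = params$ensemble_size,
                 pool_labels = pool$labels),
            class = "eom_result")
}

#' @export
print.eom_result <- function(x, ...) {
  cat(sprintf(
    "<eom_result> chi_EOM = %.4f (best of %d repeats), %d distinct model(s)\n",
    x$chi_eom, length(x$per_repeat_chis), length(x$multiplicities)))
  invisible(x)
}

#' Exhaustive multiset search (small instances)
#'
#' Enumerates every multiset of size `ensemble_size` from the pool and
#' returns the chi-optimal one.  Feasible when
#' `choose(npool + K - 1, K)` is small; used as an independent optimum
#' reference for the genetic algorithm.
#'
#' @param pool An `ensemble_pool` with profiles.
#' @param target A [saxs_profile()] with uncertainties.
#' @param ensemble_size Multiset size K.
#' @param fit_offset As in [fit_scale_offset()].
#' @param max_multisets Safety cap on the enumeration size.
#' @return list with `chi`, `counts`, `n_multisets`.
#' @export
eom_exhaustive <- function(pool, target, ensemble_size,
                           fit_offset = TRUE, max_multisets = 2e5) {
  npool <- length(pool$labels)
  K <- as.integer(ensemble_size)
  n_ms <- choose(npool + K - 1, K)
  if (n_ms > max_multisets) {
    stop("instance too large for exhaustive search (", n_ms, " multisets)",
         call. = FALSE)
  }
  P <- pool_profile_matrix(pool, target)
  y <- target$intensity; w <- 1 / target$sigma^2
  combos <- utils::combn(npool + K - 1L, K)   # multisets via stars and bars
  idx <- combos - (seq_len(K) - 1L)           # column-wise decreasing map
  C <- matrix(0L, npool, ncol(idx))
  for (j in seq_len(ncol(idx))) C[, j] <- tabulate(idx[, j], nbins = npool)
  # evaluate in blocks to bound memory
  best_chi <- Inf; best_counts <- NULL
  block <- 5000L
  for (s in seq(1L, ncol(C), by = block)) {
    e <- min(s + block - 1L, ncol(C))
    fit <- chi_of_counts(P, C[, s:e, drop = FALSE], y, w, K, fit_offset)
    j <- which.min(fit$chi)
    if (fit$chi[j] < best_chi) {
      best_chi <- fit$chi[j]; best_counts <- C[, s + j - 1L]
    }
  }
  list(chi = best_chi, counts = best_counts, n_multisets = ncol(C))
}

#' Goodness of fit versus ensemble size
#'
#' Runs the optimiser for each requested ensemble size, reports the
#' monotone envelope of the best chi values and flags the elbow: the first
#' size at which the relative improvement over the previous size falls
#' below `elbow_tol`.
#'
#' @param pool An `ensemble_pool` with profiles.
#' @param target A [saxs_profile()].
#' @param sizes Increasing integer ensemble sizes.
#' @param params Base [ga_params()] (its `ensemble_size` is overridden).
#' @param elbow_tol Relative-improvement threshold (default 0.02).
#' @return data.frame (size, chi, chi_envelope) with attribute `elbow`.
#' @export
size_sweep <- function(pool, target, sizes, params = ga_params(),
                       elbow_tol = 0.02) {
  sizes <- sort(as.integer(sizes))
  chis <- vapply(sizes, function(K) {
    p <- params; p$ensemble_size <- K
    run_eom(pool, target, p)$chi_eom
  }, numeric(1))
  env <- cummin(chis)
  elbow <- sizes[1]
  if (length(sizes) > 1L) {
    # elbow: the first size beyond which the envelope improves by < elbow_tol
    rel_impr <- -diff(env) / env[-length(env)]
    first_flat <- which(rel_impr < elbow_tol)
    elbow <- if (length(first_flat)) sizes[first_flat[1]] else
      sizes[length(sizes)]
  }
  out <- data.frame(size = sizes, chi = chis, chi_envelope = env)
  attr(out, "elbow") <- elbow
  out
}

#' Serialise an EOM result as JSON + TSV histograms
#'
#' @param result An `eom_result`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_eom_result <- function(result, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(multiplicities = as.list(result$multiplicities),
         chi_eom = result$chi_eom, scale = result$scale,
         offset = result$offset,
         per_repeat_chis = result$per_repeat_chis,
         ensemble_size = result$ensemble_size),
    file.path(dir, "eom_result.json"), auto_unbox = TRUE, digits = NA)
  h_sel <- graphics::hist(result$rg_distribution_selected, breaks = 20,
                          plot = FALSE)
  h_pool <- graphics::hist(result$rg_distribution_pool, breaks = 20,
                           plot = FALSE)
  utils::write.table(
    data.frame(rg_mid = h_sel$mids, density = h_sel$density),
    file.path(dir, "rg_selected.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  utils::write.table(
    data.frame(rg_mid = h_pool$mids, density = h_pool$density),
    file.path(dir, "rg_pool.tsv"), sep = "\t", row.names = FALSE,
    quote = FALSE)
  invisible(dir)
}
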