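# Primary reduction of measured (or simulated) SAXS curves: Guinier
# analysis with automatic range selection, Kratky transform, regularised
# indirect transform to p(r), molecular-weight estimation and SEC-SAXS
# frame analysis.

# Two-sided Wald-Wolfowitz runs test (normal approximation) on residual
# signs; small p indicates a systematic trend.
runs_test_p <- function(x) {
  s <- x > 0
  n1 <- sum(s); n2 <- sum(!s); n <- n1 + n2
  if (n1 == 0L || n2 == 0L) return(0)
  R <- 1L + sum(diff(as.integer(s)) != 0L)
  mu <- 1 + 2 * n1 * n2 / n
  v <- 2 * n1 * n2 * (2 * n1 * n2 - n) / (n^2 * (n - 1))
  if (v <= 0) return(1)
  2 * stats::pnorm(-abs((R - mu) / sqrt(v)))
}

#' Guinier fit with automatic low-q window
#'
#' Fits `ln I = ln I(0) - q^2 Rg^2 / 3` by weighted least squares on an
#' automatically selected low-q window: the fit grows from the lowest
#' usable q while `qmax * Rg <= qrg_limit`, then the lowest-q points are
#' trimmed (up to `max_trim`) until the residuals show no systematic trend
#' (runs test at `alpha = 0.05`).  If no stable window is found the result
#' is returned with `flagged = TRUE`.
#'
#' @param profile A [saxs_profile()].
#' @param qrg_limit Upper bound on `qmax * Rg` (conventional 1.3 for
#'   globular scatterers; use 1.0 for strict windows).
#' @param min_points Minimum points in the window.
#' @param max_trim Maximum low-q points dropped during stabilisation.
#' @return A `guinier_result`: `rg` and `rg_sigma` (Angstrom), `i0`,
#'   `q_range_used`, `n_points`, `flagged`, `residual_runs_p`.
#' @export
guinier_fit <- function(profile, qrg_limit = 1.3, min_points = 10L,
                        max_trim = 10L) {
  q <- profile$q; I <- profile$intensity; sg <- profile$sigma
  pos <- which(I > 0)
  if (!length(pos)) stop("non-positive intensities throughout", call. = FALSE)
  # longest contiguous positive stretch starting at the lowest usable q
  start <- pos[1]
  end <- start
  while (end < length(q) && I[end + 1L] > 0) end <- end + 1L
  idx_all <- start:end
  if (length(idx_all) < min_points) {
    stop("fewer than ", min_points, " positive low-q points", call. = FALSE)
  }
  fit_window <- function(idx) {
    x <- q[idx]^2
    y <- log(I[idx])
    w <- (I[idx] / sg[idx])^2
    fit <- stats::lm.wfit(cbind(1, x), y, w)
    b <- fit$coefficients[2]
    if (!is.finite(b) || b >= 0) return(NULL)
    rg <- sqrt(-3 * b)
    dof <- length(idx) - 2L
    s2 <- sum(w * fit$residuals^2) / max(dof, 1L)
    XtWX <- crossprod(cbind(1, x) * sqrt(w))
    var_b <- s2 * solve(XtWX)[2, 2]
    list(rg = rg, i0 = exp(fit$coefficients[1]),
         rg_sigma = 3 / (2 * rg) * sqrt(var_b),
         residuals = fit$residuals, idx = idx)
  }
  grow <- function(from) {
    idx <- idx_all[idx_all >= from]
    if (length(idx) < min_points) return(NULL)
    idx <- idx[seq_len(min_points)]
    f <- fit_window(idx)
    if (is.null(f)) return(NULL)
    repeat {
      nxt <- idx[length(idx)] + 1L
      if (!(nxt %in% idx_all) || q[nxt] * f$rg > qrg_limit) break
      idx2 <- c(idx, nxt)
      f2 <- fit_window(idx2)
      if (is.null(f2)) break
      idx <- idx2; f <- f2
    }
    f
  }
  flagged <- TRUE
  best <- NULL
  for (trim in 0:max_trim) {
    f <- grow(start + trim)
    if (is.null(f)) break
    if (is.null(best)) best <- f
    p_runs <- runs_test_p(f$residuals)
    if (p_runs >= 0.05) {
      best <- f; best$residual_runs_p <- p_runs; flagged <- FALSE
      break
    }
    best <- f; best$residual_runs_p <- p_runs
  }
  if (is.null(best)) stop("no usable Guinier window", call. = FALSE)
  structure(list(rg = unname(best$rg), i0 = unname(best$i0),
                 rg_sigma = unname(best$rg_sigma),
                 q_range_used = c(q[best$idx[1]],
                                  q[best$idx[length(best$idx)]]),
                 n_points = length(best$idx), flagged = flagged,
                 residual_runs_p = best$residual_runs_p %||% NA_real_),
            class = "guinier_result")
}

#' @export
print.guinier_result <- function(x, ...) {
  cat(sprintf(
    "<guinier_result> Rg = %.2f +/- %.2f A, I(0) = %.4g, %d pts, q [%.4f, %.4f]%s\n",
    x$rg, x$rg_sigma, x$i0, x$n_points, x$q_range_used[1], x$q_range_used[2],
    if (x$flagged) " [flagged]" else ""))
  invisible(x)
}

#' Kratky transform
#'
#' @param profile A [saxs_profile()].
#' @return data.frame with `q` and `kratky = q^2 I(q)` (no smoothing).
#' @export
kratky_transform <- function(profile) {
  data.frame(q = profile$q, kratky = profile$q^2 * profile$intensity)
}

#' Indirect transform: regularised p(r) inversion
#'
#' Solves `I(q) = sum_k p(r_k) sinc(q r_k) dr` for `p` on a fixed r grid,
#' minimising `chi^2 + alpha * ||p''||^2` with `p(0) = p(dmax) = 0` and
#' (by default) `p >= 0` via non-negative least squares.
#'
#' @param profile A [saxs_profile()] with uncertainties.
#' @param dmax Support limit, Angstrom.
#' @param alpha Regularisation weight; `NULL` uses an automatic scale-aware
#'   default (`alpha_scale` times the ratio of the data-term to the
#'   smoothness-term norms).
#' @param n_r Number of r-grid points (including both zero endpoints).
#' @param nonneg Enforce `p >= 0`.
#' @param alpha_scale Dimensionless strength of the automatic default.
#' @return A `pr_curve` with `r`, `p`, `dmax`, `alpha`, implied `i0`,
#'   real-space `rg`, and the reduced `chi` of the back-computed fit.
#' @export
ift_pr <- function(profile, dmax, alpha = NULL, n_r = 101L, nonneg = TRUE,
                   alpha_scale = 0.01) {
  stopifnot(dmax > 0, n_r >= 10L)
  q <- profile$q; I <- profile$intensity; sg <- profile$sigma
  r <- seq(0, dmax, length.out = n_r)
  dr <- r[2] - r[1]
  interior <- 2:(n_r - 1L)
  A <- sinc(outer(q, r[interior])) * dr
  Aw <- A / sg
  # second difference over the full grid with fixed zero endpoints
  D <- matrix(0, n_r, n_r)
  for (k in 2:(n_r - 1L)) D[k, (k - 1L):(k + 1L)] <- c(1, -2, 1)
  D <- D[, interior, drop = FALSE]
  norm_ratio <- sum(Aw^2) / sum(D^2)
  if (is.null(alpha)) alpha <- alpha_scale * norm_ratio
  M <- rbind(Aw, sqrt(alpha) * D)
  kappa <- kappa(crossprod(M), exact = FALSE)
  if (!is.finite(kappa) || kappa > 1e14) {
    stop(sprintf("ill-conditioned p(r) system (condition number %.3g)",
                 kappa), call. = FALSE)
  }
  rhs <- c(I / sg, numeric(nrow(D)))
  p_int <- if (nonneg) {
    pracma::lsqnonneg(M, rhs)$x
  } else {
    stats::lm.fit(M, rhs)$coefficients
  }
  p <- numeric(n_r)
  p[interior] <- p_int
  I_fit <- as.numeric(A %*% p_int)
  chi <- sqrt(sum(((I - I_fit) / sg)^2) / max(length(q) - length(interior), 1))
  rg <- sqrt(sum(r^2 * p) / (2 * sum(p)))
  structure(list(r = r, p = p, dmax = dmax, alpha = alpha,
                 i0_implied = sum(p) * dr, rg = rg, chi = chi,
                 bin_width = dr),
            class = "pr_curve")
}

#' Choose Dmax by scanning candidate supports
#'
#' For each candidate the inversion is run unconstrained; the selected
#' Dmax is the smallest candidate whose p(r) has no forced negative lobe
#' (most negative value within `-neg_tol` of the maximum) *and* whose fit
#' quality is within `chi_tol` of the best chi over the scan — a support
#' chosen too small cannot reproduce the low-q data even when its p(r)
#' happens to stay positive.  A user-supplied `dmax` to [ift_pr()] always
#' overrides this.
#'
#' @param profile A [saxs_profile()].
#' @param dmax_grid Candidate supports, Angstrom.
#' @param neg_tol Tolerated negative-lobe fraction.
#' @param chi_tol Multiple of the best scan chi still accepted.
#' @param ... Passed to [ift_pr()].
#' @return list with `dmax` (selected) and `scan` (data.frame of candidate,
#'   negative-lobe fraction, chi).
#' @export
select_dmax <- function(profile, dmax_grid, neg_tol = 0.05, chi_tol = 2,
                        ...) {
  scan <- lapply(dmax_grid, function(dm) {
    pr <- tryCatch(ift_pr(profile, dm, nonneg = FALSE, ...),
                   error = function(e) NULL)
    if (is.null(pr)) return(c(NA_real_, NA_real_))
    c(-min(pr$p) / max(abs(pr$p)), pr$chi)
  })
  scan <- do.call(rbind, scan)
  out <- data.frame(dmax = dmax_grid, neg_fraction = scan[, 1],
                    chi = scan[, 2])
  ok <- which(is.finite(out$neg_fraction) & out$neg_fraction <= neg_tol &
                out$chi <= chi_tol * min(out$chi, na.rm = TRUE))
  list(dmax = if (length(ok)) dmax_grid[ok[1]] else NA_real_, scan = out)
}

#' Molecular weight from the volume of correlation
#'
#' Computes `Vc = I(0) / int q I(q) dq` over `q <= qmax` and converts the
#' size-normalised invariant `Qr = Vc^2 / Rg` to mass as `Qr / mw_constant`.
#' The default constant (0.1231, mass in Da for atomistic protein contrast)
#' follows the published volume-of-correlation estimator; bead-level
#' synthetic profiles need a calibration constant from
#' [calibrate_mw_constant()].  An alternative Porod-volume route
#' (`method = "porod"`, `MW ~ Vp / 1630`) is available.
#'
#' @param profile A [saxs_profile()].
#' @param guinier A [guinier_fit()] result for the same curve.
#' @param mw_constant Protein-class constant relating `Qr` to mass in Da.
#' @param qmax Integration limit, Angstrom^-1.
#' @param method `"vc"` (default) or `"porod"`.
#' @return Mass in kDa, with attributes `vc` (or `vp`) and `flagged`
#'   (TRUE when the integral has not converged on the measured range).
#' @export
estimate_mw <- function(profile, guinier, mw_constant = 0.1231, qmax = 0.3,
                        method = c("vc", "porod")) {
  method <- match.arg(method)
  keep <- profile$q <= qmax
  if (sum(keep) < 10L) stop("too few points below qmax", call. = FALSE)
  q <- profile$q[keep]; I <- profile$intensity[keep]
  if (method == "vc") {
    integrand <- q * I
    total <- pracma::trapz(q, integrand)
    tail_frac <- pracma::trapz(q[q >= 0.8 * max(q)],
                               integrand[q >= 0.8 * max(q)]) / total
    vc <- guinier$i0 / total
    mw <- (vc^2 / guinier$rg) / mw_constant / 1000
    structure(mw, vc = vc, flagged = !is.finite(tail_frac) || tail_frac > 0.2)
  } else {
    integrand <- q^2 * I
    total <- pracma::trapz(q, integrand)
    tail_frac <- pracma::trapz(q[q >= 0.8 * max(q)],
                               integrand[q >= 0.8 * max(q)]) / total
    vp <- 2 * pi^2 * guinier$i0 / total
    structure(vp / 1630, vp = vp,
              flagged = !is.finite(tail_frac) || tail_frac > 0.2)
  }
}

#' Calibrate the bead-level molecular-weight constant
#'
#' Generates solid bead spheres of the requested sizes (one bead per
#' residue at protein packing density), computes their volume-of-correlation
#' invariant on the default grid, and returns the mean `Qr / mass` ratio in
#' the units used by [estimate_mw()].
#'
#' @param n_residues Integer vector of calibration sphere sizes.
#' @param residue_mass kDa per bead.
#' @param residue_volume Angstrom^3 per bead.
#' @param qmax Passed to the invariant integral.
#' @param seed Integer seed for sphere generation.
#' @return Calibration constant for `mw_constant` (Da units).
#' @export
calibrate_mw_constant <- function(n_residues = c(150L, 300L, 600L),
                                  residue_mass = 0.110,
                                  residue_volume = 134, qmax = 0.3,
                                  seed = 1L) {
  ratios <- vapply(seq_along(n_residues), function(i) {
    n <- n_residues[i]
    R <- (3 * n * residue_volume / (4 * pi))^(1 / 3)
    xyz <- with_seed(seed + i, grow_globule(n, R))
    prof <- debye_profile(scatterer_set(xyz), default_q_grid())
    prof <- saxs_profile(prof$q, prof$intensity,
                         sigma = 0.01 * prof$intensity)
    g <- guinier_fit(prof, qrg_limit = 1.3)
    keep <- prof$q <= qmax
    vc <- g$i0 / pracma::trapz(prof$q[keep],
                               prof$q[keep] * prof$intensity[keep])
    (vc^2 / g$rg) / (n * residue_mass * 1000)
  }, numeric(1))
  mean(ratios)
}

#' Buffer subtraction
#'
#' @param sample,buffer [saxs_profile()] objects on identical q grids
#'   (no silent interpolation).
#' @return A [saxs_profile()] with `I = I_s - I_b` and
#'   `sigma = sqrt(sigma_s^2 + sigma_b^2)`.
#' @export
subtract_buffer <- function(sample, buffer) {
  if (length(sample$q) != length(buffer$q) ||
      any(sample$q != buffer$q)) {
    stop("sample and buffer q grids differ", call. = FALSE)
  }
  saxs_profile(sample$q, sample$intensity - buffer$intensity,
               sqrt(sample$sigma^2 + buffer$sigma^2))
}

#' SEC-SAXS frame analysis
#'
#' Buffer frames are taken as the user-specified range or auto-selected as
#' the lowest-integral contiguous window; every frame is buffer-subtracted
#' and Guinier-fitted; peak frames (`i0 >= peak_threshold` of the maximum)
#' are averaged with propagated uncertainties.
#'
#' @param series A [frame_series()] with at least 20 frames.
#' @param buffer_frames Optional integer vector of frame ids to use as
#'   buffer; `NULL` auto-selects.
#' @param buffer_window Width of the auto-selected buffer window.
#' @param peak_threshold Fraction of the maximum i0 defining peak frames.
#' @param qrg_limit Passed to [guinier_fit()].
#' @return A `sec_saxs_result`: `frames` (data.frame frame, i0, rg,
#'   rg_sigma), `buffer_frames`, `peak_frames`, `average` (averaged peak
#'   [saxs_profile()]), `buffer` (mean buffer profile).
#' @export
sec_saxs_analyze <- function(series, buffer_frames = NULL,
                             buffer_window = 10L, peak_threshold = 0.5,
                             qrg_limit = 1.3) {
  n <- length(series$frames)
  if (n < 20L) stop("need at least 20 frames", call. = FALSE)
  q <- series$q
  Imat <- vapply(series$frames, function(f) f$intensity, numeric(length(q)))
  Smat <- vapply(series$frames, function(f) f$sigma, numeric(length(q)))
  integrals <- apply(Imat, 2, function(I) pracma::trapz(q, I))
  if (is.null(buffer_frames)) {
    w <- min(buffer_window, n - 1L)
    roll <- vapply(seq_len(n - w + 1L), function(i) {
      sum(integrals[i:(i + w - 1L)])
    }, numeric(1))
    i0_ <- which.min(roll)
    buffer_frames <- series$frame_ids[i0_:(i0_ + w - 1L)]
  }
  bsel <- series$frame_ids %in% buffer_frames
  if (!any(bsel)) stop("buffer frames not found in series", call. = FALSE)
  nb <- sum(bsel)
  buffer <- saxs_profile(q, rowMeans(Imat[, bsel, drop = FALSE]),
                         sqrt(rowSums(Smat[, bsel, drop = FALSE]^2)) / nb)
  fits <- lapply(seq_len(n), function(j) {
    sub <- subtract_buffer(series$frames[[j]], buffer)
    g <- tryCatch(guinier_fit(sub, qrg_limit = qrg_limit),
                  error = function(e) NULL)
    list(sub = sub,
         i0 = if (is.null(g)) NA_real_ else g$i0,
         rg = if (is.null(g)) NA_real_ else g$rg,
         rg_sigma = if (is.null(g)) NA_real_ else g$rg_sigma)
  })
  tab <- data.frame(frame = series$frame_ids,
                    i0 = vapply(fits, `[[`, numeric(1), "i0"),
                    rg = vapply(fits, `[[`, numeric(1), "rg"),
                    rg_sigma = vapply(fits, `[[`, numeric(1), "rg_sigma"))
  tab$i0[bsel] <- NA_real_; tab$rg[bsel] <- NA_real_
  if (all(is.na(tab$i0))) stop("no frames above threshold", call. = FALSE)
  peak <- which(!is.na(tab$i0) &
                  tab$i0 >= peak_threshold * max(tab$i0, na.rm = TRUE))
  if (!length(peak)) stop("no frames above threshold", call. = FALSE)
  np <- length(peak)
  Isub <- vapply(fits[peak], function(f) f$sub$intensity, numeric(length(q)))
  Ssub <- vapply(fits[peak], function(f) f$sub$sigma, numeric(length(q)))
  average <- saxs_profile(q, rowMeans(Isub), sqrt(rowSums(Ssub^2)) / np)
  structure(list(frames = tab, buffer_frames = series$frame_ids[bsel],
                 peak_frames = series$frame_ids[peak], average = average,
                 buffer = buffer),
            class = "sec_saxs_result")
}

#' Write a p(r) curve / per-frame table
#'
#' `write_pr()` writes two-column text with `#` header metadata (dmax,
#' alpha); `write_frame_table()` writes the per-frame TSV of a
#' [sec_saxs_analyze()] result.
#'
#' @param pr A `pr_curve`.
#' @param result A `sec_saxs_result`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pr <- function(pr, path) {
  writeLines(c(sprintf("# dmax %.6g", pr$dmax),
               if (!is.null(pr$alpha)) sprintf("# alpha %.6g", pr$alpha),
               "# r(A) p(r)",
               sprintf("%.6e %.6e", pr$r, pr$p)), path)
  invisible(path)
}

#' @rdname write_pr
#' @export
write_frame_table <- function(result, path) {
  utils::write.table(result$frames, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
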