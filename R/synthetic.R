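# Synthetic conformer pools with known ground truth.  Bead-level (one bead
# per residue) emulation of an MD-derived pool: two self-avoiding globular
# domains at a state-dependent separation, a self-avoiding disordered
# C-terminal tail, and C2-symmetric tetramers whose tails point at the
# symmetry axis leaving an axial channel.  Every generator is a pure
# function of (spec, seed).

CA_BOND <- 3.8  # successive-bead (virtual C-alpha) distance, Angstrom

#' Specification of the synthetic conformer generator
#'
#' Defaults emulate an scFv-scale two-domain monomer: 115-residue globular
#' domains at protein packing density, a 39-residue disordered tail, a
#' closed state with associated domains and an open state with fully
#' dissociated domains.  The closed/open generation separations sit on
#' opposite sides of the classifier thresholds with a deliberate gap, so
#' state labels are unambiguous ground truth.
#'
#' @param n_res_domain Residues per globular domain.
#' @param tail_length Residues in the disordered C-terminal tail.
#' @param closed_separation,open_separation Mean domain-centroid separation
#'   (Angstrom) used when generating each state; each conformer samples a
#'   uniform +/-10 percent jitter.
#' @param closed_threshold,open_threshold Classifier thresholds (Angstrom):
#'   closed conformers are generated at separations <= `closed_threshold`,
#'   open ones at separations >= `open_threshold`.
#' @param bead_radius Bead hard-core radius (Angstrom); clash distance is
#'   `2 * bead_radius`.
#' @param residue_volume Apparent residue volume (Angstrom^3) setting the
#'   globule radius.
#' @param channel_width Tetramer axial channel width (Angstrom): the minimum
#'   bead-to-symmetry-axis distance.
#' @return An object of class `conformer_spec`.
#' @export
conformer_spec <- function(n_res_domain = 115L, tail_length = 39L,
                           closed_separation = 25, open_separation = 50,
                           closed_threshold = 30, open_threshold = 45,
                           bead_radius = 1.9, residue_volume = 134,
                           channel_width = 12) {
  stopifnot(n_res_domain >= 1, tail_length >= 0, bead_radius > 0,
            residue_volume > 0, channel_width > 0,
            closed_separation > 0, open_separation > 0)
  if (!(closed_separation * 1.1 <= closed_threshold &&
        closed_threshold < open_threshold &&
        open_threshold <= open_separation * 0.9)) {
    stop("closed/open generation separations must fall on opposite sides ",
         "of the classifier thresholds (including the +/-10% jitter)",
         call. = FALSE)
  }
  structure(list(n_res_domain = as.integer(n_res_domain),
                 tail_length = as.integer(tail_length),
                 closed_separation = closed_separation,
                 open_separation = open_separation,
                 closed_threshold = closed_threshold,
                 open_threshold = open_threshold,
                 bead_radius = bead_radius,
                 residue_volume = residue_volume,
                 channel_width = channel_width),
            class = "conformer_spec")
}

domain_radius <- function(spec) {
  (3 * spec$n_res_domain * spec$residue_volume / (4 * pi))^(1 / 3)
}

# Random sequential insertion of n beads in a sphere of radius `radius`
# centred at `centre`, keeping min_sep from everything already placed.
grow_globule <- function(n, radius, centre = c(0, 0, 0), min_sep = CA_BOND,
                         existing = NULL, max_fail = 5000L) {
  placed <- matrix(numeric(0), ncol = 3)
  fails <- 0L
  while (nrow(placed) < n) {
    u <- random_unit_vectors(1L)
    cand <- centre + radius * stats::runif(1)^(1 / 3) * as.numeric(u)
    others <- rbind(placed, existing)
    ok <- !nrow(others) ||
      min(sqrt(colSums((t(others) - cand)^2))) >= min_sep
    if (ok) {
      placed <- rbind(placed, cand)
      fails <- 0L
    } else {
      fails <- fails + 1L
      if (fails > max_fail) {
        stop("generation error: self-avoidance unsatisfiable for globule",
             call. = FALSE)
      }
    }
  }
  unname(placed)
}

# Self-avoiding random walk of n beads from `start` (exclusive) with fixed
# step CA_BOND.  Optional drift toward the symmetry axis and a hard lower
# bound on the cylindrical radius about z (used for tetramer tails).
tail_walk <- function(start, n, existing, bead_radius,
                      bias_strength = 0, min_cyl_radius = NULL,
                      step_retries = 300L, restarts = 25L) {
  clash <- 2 * bead_radius - 1e-9
  for (attempt in seq_len(restarts)) {
    walk <- matrix(numeric(0), ncol = 3)
    pos <- start
    stuck <- FALSE
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try_ in seq_len(step_retries)) {
        dir_ <- as.numeric(random_unit_vectors(1L))
        if (bias_strength > 0) {
          to_axis <- c(-pos[1], -pos[2], 0)
          nrm <- sqrt(sum(to_axis^2))
          if (nrm > 1e-9) {
            dir_ <- dir_ + bias_strength * to_axis / nrm
            dir_ <- dir_ / sqrt(sum(dir_^2))
          }
        }
        cand <- pos + CA_BOND * dir_
        if (!is.null(min_cyl_radius) &&
            sqrt(cand[1]^2 + cand[2]^2) < min_cyl_radius) next
        obstacles <- rbind(existing, walk)
        # the predecessor bead sits at exactly one bond length; exclude it
        d <- sqrt(colSums((t(obstacles) - cand)^2))
        d <- d[d > 1e-9]
        prev_ok <- sqrt(sum((cand - pos)^2)) >= CA_BOND - 1e-9
        if (prev_ok && (!length(d) || min(d) >= clash)) {
          walk <- rbind(walk, cand)
          pos <- cand
          placed <- TRUE
          break
        }
      }
      if (!placed) { stuck <- TRUE; break }
    }
    if (!stuck) return(unname(walk))
  }
  stop("generation error: self-avoiding tail walk unsatisfiable",
       call. = FALSE)
}

beads_to_atoms <- function(xyz, chain = "A", resno_start = 1L) {
  n <- nrow(xyz)
  data.frame(type = "ATOM", eleno = seq_len(n), elety = "CA",
             resid = "ALA", chain = chain,
             resno = seq.int(resno_start, length.out = n), insert = "",
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3], o = 1, b = 0,
             elesy = "C", stringsAsFactors = FALSE)
}

#' Generate a synthetic two-domain monomer
#'
#' Builds two self-avoiding bead globules at the state-appropriate
#' centroid separation (closed: associated, open: dissociated) and appends
#' the disordered C-terminal tail.  Deterministic for a fixed
#' `(spec, state, seed)`.
#'
#' @param spec A [conformer_spec()].
#' @param state `"closed"` or `"open"`.
#' @param seed Integer seed.
#' @param tail Logical: append the tail (default) or return the bare
#'   two-domain body.
#' @return A [structure_model()] with one chain; residues
#'   `1..n_res_domain` (first domain), then the second domain, then the tail.
#' @export
build_monomer <- function(spec = conformer_spec(),
                          state = c("closed", "open"), seed = 1L,
                          tail = TRUE) {
  state <- match.arg(state)
  with_seed(seed, {
    base_sep <- if (state == "closed") spec$closed_separation else
      spec$open_separation
    sep <- base_sep * stats::runif(1, 0.9, 1.1)
    R <- domain_radius(spec)
    d1 <- grow_globule(spec$n_res_domain, R, centre = c(-sep / 2, 0, 0),
                       min_sep = 2 * spec$bead_radius)
    # recentre so the realised centroid separation equals the sampled one
    # exactly (RSA centroids fluctuate by ~R/sqrt(n) otherwise)
    d1 <- sweep(d1, 2, colMeans(d1) - c(-sep / 2, 0, 0))
    d2 <- grow_globule(spec$n_res_domain, R, centre = c(sep / 2, 0, 0),
                       min_sep = 2 * spec$bead_radius, existing = d1)
    d2 <- sweep(d2, 2, colMeans(d2) - c(sep / 2, 0, 0))
    # tail anchor is the last residue of the second domain: reorder so it
    # is the outward-facing surface bead, giving the walk room to start
    d2 <- d2[order(d2[, 1]), , drop = FALSE]
    atoms <- beads_to_atoms(rbind(d1, d2))
    model <- structure_model(atoms)
    if (tail && spec$tail_length > 0) {
      model <- append_tail_impl(model, spec$tail_length, spec$bead_radius)
    }
    model
  })
}

append_tail_impl <- function(model, n_res, bead_radius,
                             bias_strength = 0, min_cyl_radius = NULL) {
  xyz <- model_coords(model)
  anchor <- xyz[nrow(xyz), ]
  walk <- tail_walk(anchor, n_res, existing = xyz, bead_radius = bead_radius,
                    bias_strength = bias_strength,
                    min_cyl_radius = min_cyl_radius)
  last <- model$atoms[nrow(model$atoms), ]
  tail_atoms <- beads_to_atoms(walk, chain = last$chain,
                               resno_start = last$resno + 1L)
  out <- rbind(model$atoms, tail_atoms)
  out$eleno <- seq_len(nrow(out))
  structure_model(out, assembly_ops = model$assembly_ops)
}

#' Append a disordered tail to a bead model
#'
#' Grows a self-avoiding random walk of `n_res` beads from the last residue
#' of the model (the C-terminus of the second domain), with successive-bead
#' distance fixed at 3.8 Angstrom and a clash distance of twice the bead
#' radius against the parent model and the walk itself.
#'
#' @param model A bead-level [structure_model()].
#' @param n_res Number of tail residues; `0` returns the model unchanged.
#' @param seed Integer seed.
#' @param bead_radius Bead radius, Angstrom.
#' @return The extended [structure_model()].
#' @export
append_tail <- function(model, n_res, seed = 1L, bead_radius = 1.9) {
  stopifnot(n_res >= 0)
  if (n_res == 0) return(model)
  with_seed(seed, append_tail_impl(model, n_res, bead_radius))
}

#' Generate a synthetic C2-symmetric tetramer
#'
#' Places one closed-state protomer at a radial offset from the z axis,
#' grows its tail with a drift toward the axis (emulating a central
#' tag-mediated core) under a hard cylindrical bound, and expands four
#' copies by rotations about z.  The resulting assembly is exactly
#' C2-symmetric (indeed fourfold) about z, and no bead approaches the axis
#' closer than the configured channel width.
#'
#' @param spec A [conformer_spec()].
#' @param seed Integer seed.
#' @return A [structure_model()] with 4 chains (`A`, `A-2`, `A-3`, `A-4`).
#' @export
build_tetramer <- function(spec = conformer_spec(), seed = 1L) {
  with_seed(seed, {
    w <- spec$channel_width
    R <- domain_radius(spec)
    sep <- spec$closed_separation * stats::runif(1, 0.9, 1.1)
    # protomer long axis along z, centred on the x axis
    d1 <- grow_globule(spec$n_res_domain, R, centre = c(0, 0, -sep / 2),
                       min_sep = 2 * spec$bead_radius)
    d2 <- grow_globule(spec$n_res_domain, R, centre = c(0, 0, sep / 2),
                       min_sep = 2 * spec$bead_radius, existing = d1)
    # anchor (last residue of the second domain) faces the symmetry axis,
    # i.e. the most negative x once the protomer is shifted to +x
    d2 <- d2[order(-d2[, 1]), , drop = FALSE]
    body <- rbind(d1, d2)
    # radial placement: minimum body cylindrical radius at one bead radius
    # outside the channel, so the tails define the channel surface
    x0 <- w + R + 2 * spec$bead_radius
    for (iter in 1:4) {
      shifted <- body
      shifted[, 1] <- shifted[, 1] + x0
      rmin <- min(sqrt(shifted[, 1]^2 + shifted[, 2]^2))
      x0 <- x0 + (w + 2 * spec$bead_radius - rmin)
    }
    body[, 1] <- body[, 1] + x0
    model <- structure_model(beads_to_atoms(body))
    if (spec$tail_length > 0) {
      model <- append_tail_impl(model, spec$tail_length, spec$bead_radius,
                                bias_strength = 0.5, min_cyl_radius = w)
    }
    build_assembly(model, lapply(0:3, function(k) {
      rigid_transform(rotation_z(k * pi / 2))
    }))
  })
}

#' Generate a labelled conformer pool
#'
#' @param counts Named integer vector with entries `closed_monomer`,
#'   `open_monomer`, `tetramer` (missing entries are 0).
#' @param spec A [conformer_spec()].
#' @param seed Integer seed; per-conformer seeds are drawn once from this
#'   stream and recorded.
#' @param q_grid q values on which theoretical profiles are precomputed.
#' @param profiles Logical: precompute Debye profiles (default TRUE).
#' @return An `ensemble_pool`: conformers, labels, per-conformer seeds and
#'   Rg, profile matrix (`length(q_grid)` x n) and the q grid.
#' @export
generate_pool <- function(counts, spec = conformer_spec(), seed = 1L,
                          q_grid = default_q_grid(), profiles = TRUE) {
  labels_all <- c("closed_monomer", "open_monomer", "tetramer")
  n_by <- stats::setNames(rep(0L, 3), labels_all)
  bad <- setdiff(names(counts), labels_all)
  if (length(bad)) stop("unknown label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  n_by[names(counts)] <- as.integer(counts)
  if (any(n_by < 0)) stop("counts must be >= 0", call. = FALSE)
  total <- sum(n_by)
  if (total == 0L) stop("empty pool requested", call. = FALSE)
  labels <- rep(labels_all, n_by)
  seeds <- with_seed(seed, sample.int(2^30, total))
  conformers <- vector("list", total)
  for (i in seq_len(total)) {
    conformers[[i]] <- switch(labels[i],
      closed_monomer = build_monomer(spec, "closed", seeds[i]),
      open_monomer = build_monomer(spec, "open", seeds[i]),
      tetramer = build_tetramer(spec, seeds[i]))
  }
  rg <- vapply(conformers, coordinate_rg, numeric(1))
  prof <- NULL
  if (profiles) {
    prof <- vapply(conformers, function(m) {
      debye_profile(m, q_grid, method = "binned")$intensity
    }, numeric(length(q_grid)))
  }
  structure(list(conformers = conformers, labels = labels,
                 profiles = prof, q = q_grid, seeds = seeds, rg = rg,
                 spec = spec, seed = seed),
            class = "ensemble_pool")
}

#' @export
print.ensemble_pool <- function(x, ...) {
  cat(sprintf("<ensemble_pool> %d conformers (%s)%s\n", length(x$labels),
              paste(sprintf("%s: %d", names(table(x$labels)),
                            table(x$labels)), collapse = ", "),
              if (is.null(x$profiles)) "" else ", profiles precomputed"))
  invisible(x)
}

#' Serialise / load a conformer pool
#'
#' Pools are written as a directory of PDB files plus a TSV manifest
#' (conformer id, file, label, seed, Rg) and, when present, the profile
#' matrix and q grid as TSV.
#'
#' @param pool An `ensemble_pool`.
#' @param dir Directory (created if needed).
#' @return `dir` (write) or an `ensemble_pool` (read).
#' @export
write_pool <- function(pool, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(pool$labels)
  files <- sprintf("conformer_%04d.pdb", seq_len(n))
  for (i in seq_len(n)) {
    m <- pool$conformers[[i]]
    chains <- m$atoms$chain
    m$atoms$chain <- LETTERS[match(chains, unique(chains))]
    write_structure(m, file.path(dir, files[i]), format = "pdb")
  }
  manifest <- data.frame(id = seq_len(n), file = files, label = pool$labels,
                         seed = pool$seeds, rg = pool$rg)
  utils::write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  if (!is.null(pool$profiles)) {
    utils::write.table(cbind(q = pool$q, pool$profiles),
                       file.path(dir, "profiles.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_pool
#' @export
read_pool <- function(dir) {
  manifest <- utils::read.table(file.path(dir, "manifest.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  conformers <- lapply(file.path(dir, manifest$file), read_structure)
  prof <- NULL; q <- NULL
  pf <- file.path(dir, "profiles.tsv")
  if (file.exists(pf)) {
    m <- as.matrix(utils::read.table(pf, sep = "\t", header = TRUE))
    q <- m[, 1]
    prof <- m[, -1, drop = FALSE]
    dimnames(prof) <- NULL
  }
  structure(list(conformers = conformers, labels = manifest$label,
                 profiles = prof, q = q, seeds = manifest$seed,
                 rg = manifest$rg, spec = NULL, seed = NA),
            class = "ensemble_pool")
}

#' Mixture ground truth for simulated experiments
#'
#' @param weights Named non-negative fractions (by pool label) summing to 1
#'   within 1e-12.
#' @param noise_a_frac,noise_b,noise_c Noise model parameters: the per-point
#'   uncertainty is `sigma(q) = (a + b I(q)) (1 + c q)` with
#'   `a = noise_a_frac * I(q_min)`; `noise_c` in Angstrom.
#' @param seed Integer seed for the noise stream.
#' @return An object of class `mixture_truth`.
#' @export
mixture_truth <- function(weights, noise_a_frac = 0.002, noise_b = 0.01,
                          noise_c = 2, seed = 1L) {
  if (is.null(names(weights)) || any(!nzchar(names(weights)))) {
    stop("weights must be named by pool label", call. = FALSE)
  }
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be non-negative and sum to 1", call. = FALSE)
  }
  structure(list(weights = weights, noise_a_frac = noise_a_frac,
                 noise_b = noise_b, noise_c = noise_c, seed = seed),
            class = "mixture_truth")
}

#' Simulate a SAXS measurement of a known mixture
#'
#' The noiseless curve is the weight-average of the per-label mean
#' theoretical profiles of the pool; Gaussian noise with
#' `sigma(q) = (a + b I(q)) (1 + c q)` is added when `noise = TRUE`, and the
#' sigma column always carries the true sigma(q).
#'
#' @param pool An `ensemble_pool` with precomputed profiles.
#' @param truth A [mixture_truth()].
#' @param noise Logical; `FALSE` returns the exact mixture curve (sigma
#'   still populated).
#' @return A [saxs_profile()].
#' @export
simulate_experiment <- function(pool, truth, noise = TRUE) {
  if (is.null(pool$profiles)) {
    stop("pool has no precomputed profiles", call. = FALSE)
  }
  missing_lab <- setdiff(names(truth$weights), unique(pool$labels))
  if (length(missing_lab)) {
    stop("labels absent from pool: ", paste(missing_lab, collapse = ", "),
         call. = FALSE)
  }
  I <- numeric(length(pool$q))
  for (lab in names(truth$weights)) {
    sel <- pool$labels == lab
    I <- I + truth$weights[[lab]] * rowMeans(pool$profiles[, sel, drop = FALSE])
  }
  a <- truth$noise_a_frac * I[1]
  sigma <- (a + truth$noise_b * I) * (1 + truth$noise_c * pool$q)
  if (noise) {
    I <- I + with_seed(truth$seed, stats::rnorm(length(I), 0, sigma))
  }
  saxs_profile(pool$q, I, sigma)
}

#' Ordered series of SAXS frames (SEC-SAXS)
#'
#' @param frames List of [saxs_profile()] objects on one common q grid.
#' @param frame_ids Integer frame numbers.
#' @param uv_trace Optional per-frame scalar (e.g. UV absorbance).
#' @return An object of class `frame_series`.
#' @export
frame_series <- function(frames, frame_ids = seq_along(frames),
                         uv_trace = NULL) {
  stopifnot(length(frames) >= 1, length(frame_ids) == length(frames))
  q0 <- frames[[1]]$q
  same <- vapply(frames, function(f) {
    length(f$q) == length(q0) && all(f$q == q0)
  }, logical(1))
  if (!all(same)) stop("all frames must share one q grid", call. = FALSE)
  structure(list(frames = frames, frame_ids = frame_ids,
                 uv_trace = uv_trace, q = q0),
            class = "frame_series")
}

#' Simulate a SEC-SAXS frame series
#'
#' Frames carry a constant buffer background plus a per-frame weighted sum
#' of component curves (e.g. a Gaussian elution peak), with the same noise
#' model as [simulate_experiment()].
#'
#' @param components Matrix of component intensities
#'   (`length(q) x n_components`) or a single numeric vector.
#' @param q The q grid.
#' @param amplitudes `n_frames x n_components` matrix of per-frame component
#'   amplitudes (zero rows are pure buffer frames).
#' @param buffer_intensity Buffer background: scalar or vector over q.
#' @param noise_a_frac,noise_b,noise_c As in [mixture_truth()]; `a` scales
#'   with the largest frame's peak intensity.
#' @param seed Integer seed.
#' @return A [frame_series()].
#' @export
simulate_sec_series <- function(components, q, amplitudes,
                                buffer_intensity = 0.05,
                                noise_a_frac = 0.002, noise_b = 0.01,
                                noise_c = 2, seed = 1L) {
  components <- as.matrix(components)
  amplitudes <- as.matrix(amplitudes)
  stopifnot(nrow(components) == length(q),
            ncol(amplitudes) == ncol(components))
  bg <- rep_len(buffer_intensity, length(q))
  signal <- components %*% t(amplitudes)  # q x frames
  a <- noise_a_frac * max(signal[1, ])
  with_seed(seed, {
    frames <- lapply(seq_len(nrow(amplitudes)), function(j) {
      I <- bg + signal[, j]
      sigma <- (a + noise_b * I) * (1 + noise_c * q)
      saxs_profile(q, I + stats::rnorm(length(q), 0, sigma), sigma)
    })
    frame_series(frames)
  })
}
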