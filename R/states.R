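# Conformer state calls (closed monomer / open monomer / tetramer) and
# conversion of selected-ensemble multiplicities into population fractions
# with bootstrap uncertainties.

#' Classification thresholds
#'
#' @param open_separation Minimum domain-centroid separation (Angstrom)
#'   for an open call.
#' @param contact_distance Bead/heavy-atom contact distance (Angstrom);
#'   open additionally requires zero inter-domain contacts.
#' @param tetramer_chains Protomer count that defines a tetramer.
#' @param domain_ranges List of two residue-number ranges (`c(from, to)`)
#'   partitioning the monomer into its two framework domains; `NULL` uses
#'   the synthetic generator's layout from the model's residue numbering
#'   (first half / second half of the non-tail body).
#' @return An object of class `state_thresholds`.
#' @export
state_thresholds <- function(open_separation = 45, contact_distance = 5,
                             tetramer_chains = 4L, domain_ranges = NULL) {
  structure(list(open_separation = open_separation,
                 contact_distance = contact_distance,
                 tetramer_chains = as.integer(tetramer_chains),
                 domain_ranges = domain_ranges),
            class = "state_thresholds")
}

#' Classify a conformer as closed monomer, open monomer or tetramer
#'
#' A model with `tetramer_chains` (or more) chains is a tetramer.
#' Otherwise the model is partitioned into its two framework domains (by
#' the configured residue ranges) and called open iff the domains make no
#' contact at `contact_distance` AND their centroid separation is at least
#' `open_separation`; closed otherwise.  Two conditions are required so
#' borderline conformers cannot flap between calls.  The call is invariant
#' to rigid motion and chain relabelling.
#'
#' @param model A [structure_model()].
#' @param thresholds A [state_thresholds()].
#' @return A `state_call`: `label`, `metric` (centroid separation in
#'   Angstrom for monomers, chain count for tetramers), `n_contacts`.
#' @export
classify_conformer <- function(model, thresholds = state_thresholds()) {
  n_chains <- length(model_chains(model))
  if (n_chains >= thresholds$tetramer_chains) {
    return(structure(list(label = "tetramer", metric = n_chains,
                          n_contacts = NA_integer_),
                     class = "state_call"))
  }
  resno <- model$atoms$resno
  rng <- thresholds$domain_ranges
  if (is.null(rng)) {
    # synthetic layout: two equal domains then a tail; split the body in two
    counts <- table(resno)
    if (any(counts > 1)) {
      stop("domain ranges are required for multi-atom residues",
           call. = FALSE)
    }
    body <- sort(unique(resno))
    # generator default layout: two equal domains plus a 39/269 tail
    n_body <- 2L * round(length(body) * 115 / 269)
    half <- n_body %/% 2L
    rng <- list(c(body[1], body[half]), c(body[half + 1L], body[n_body]))
  }
  in1 <- resno >= rng[[1]][1] & resno <= rng[[1]][2]
  in2 <- resno >= rng[[2]][1] & resno <= rng[[2]][2]
  if (!any(in1) || !any(in2)) {
    stop("domain ranges do not cover the model", call. = FALSE)
  }
  xyz <- model_coords(model)
  a <- xyz[in1, , drop = FALSE]; b <- xyz[in2, , drop = FALSE]
  sep <- sqrt(sum((colMeans(a) - colMeans(b))^2))
  # inter-domain contacts at the configured cutoff
  cd2 <- thresholds$contact_distance^2
  n_contacts <- 0L
  for (i in seq_len(nrow(a))) {
    n_contacts <- n_contacts +
      sum(colSums((t(b) - a[i, ])^2) <= cd2)
  }
  label <- if (n_contacts == 0L && sep >= thresholds$open_separation) {
    "open_monomer"
  } else {
    "closed_monomer"
  }
  structure(list(label = label, metric = sep, n_contacts = n_contacts),
            class = "state_call")
}

#' State calls for every conformer of a pool
#'
#' @param pool An `ensemble_pool`.
#' @param thresholds A [state_thresholds()].
#' @return Character vector of labels (one per conformer).
#' @export
classify_pool <- function(pool, thresholds = state_thresholds()) {
  if (is.null(thresholds$domain_ranges) && !is.null(pool$spec)) {
    nd <- pool$spec$n_res_domain
    thresholds$domain_ranges <- list(c(1L, nd), c(nd + 1L, 2L * nd))
  }
  vapply(pool$conformers, function(m) {
    classify_conformer(m, thresholds)$label
  }, character(1))
}

#' Population fractions from an EOM result
#'
#' Converts selected-ensemble multiplicities into per-state fractions
#' (`sum(multiplicity) / ensemble_size` per label, quantised at
#' `1/ensemble_size`) with bootstrap confidence intervals over the
#' independent GA repeats — the dominant source of selection uncertainty.
#'
#' @param result An `eom_result`.
#' @param calls Character vector of state labels for every pool conformer
#'   (e.g. from [classify_pool()]).
#' @param n_boot Bootstrap resamples.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @return A `population_estimate`: `fractions` (named, sum 1), `ci_low`,
#'   `ci_high`, `n_repeats`.
#' @export
population_fractions <- function(result, calls, n_boot = 1000L, seed = 1L,
                                 level = 0.95) {
  npool <- length(result$pool_labels)
  if (length(calls) != npool) {
    sel_ids <- as.integer(names(result$multiplicities))
    missing_ids <- sel_ids[sel_ids > length(calls)]
    stop("missing state call(s) for conformer id(s): ",
         paste(missing_ids %||% "(length mismatch)", collapse = ", "),
         call. = FALSE)
  }
  labels <- c("closed_monomer", "open_monomer", "tetramer")
  frac_of <- function(counts) {
    v <- vapply(labels, function(l) sum(counts[calls == l]), numeric(1))
    v / sum(counts)
  }
  best_counts <-
    result$per_repeat_counts[[which.min(result$per_repeat_chis)]]
  fractions <- frac_of(best_counts)
  reps <- result$per_repeat_counts
  boot <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      pick <- sample.int(length(reps), length(reps), replace = TRUE)
      rowMeans(vapply(reps[pick], frac_of, numeric(length(labels))))
    }, numeric(length(labels)))
  })
  alpha <- (1 - level) / 2
  ci <- apply(boot, 1, stats::quantile, probs = c(alpha, 1 - alpha))
  structure(list(fractions = fractions,
                 ci_low = pmin(ci[1, ], fractions),
                 ci_high = pmax(ci[2, ], fractions),
                 n_repeats = length(reps)),
            class = "population_estimate")
}

#' @export
print.population_estimate <- function(x, ...) {
  cat("<population_estimate>\n")
  for (l in names(x$fractions)) {
    cat(sprintf("  %-15s %3.0f%%  [%.0f%%, %.0f%%]\n", l,
                100 * x$fractions[l], 100 * x$ci_low[l], 100 * x$ci_high[l]))
  }
  invisible(x)
}

#' Write state calls / population estimates
#'
#' @param calls Labels from [classify_pool()].
#' @param estimate A `population_estimate`.
#' @param path Output path (TSV for calls, JSON for estimates).
#' @return `path`, invisibly.
#' @export
write_state_calls <- function(calls, path) {
  utils::write.table(data.frame(id = seq_along(calls), label = calls),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_state_calls
#' @export
write_population_estimate <- function(estimate, path) {
  jsonlite::write_json(
    list(fractions = as.list(estimate$fractions),
         ci_low = as.list(estimate$ci_low),
         ci_high = as.list(estimate$ci_high),
         n_repeats = estimate$n_repeats),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
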