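# End-to-end orchestration from a single YAML config: synthetic pool (or
# user pool) -> forward profiles -> target -> ensemble optimisation ->
# state populations, plus optional structure reports and hull
# hydrodynamics.  Every stage output is stamped with the config hash and
# seeds in a run manifest.

PIPELINE_SCHEMA <- list(
  seed = c("integer"),
  output_dir = c("character"),
  q_grid = c("min", "max", "n"),
  pool = c("counts", "dir", "spec"),
  target = c("file", "weights", "noise_a_frac", "noise_b", "noise_c",
             "seed", "noise"),
  ga = c("ensemble_size", "population", "generations", "patience",
         "mutation_rate", "crossover_rate", "elitism", "repeats", "seed",
         "fit_offset"),
  classifier = c("open_separation", "contact_distance", "tetramer_chains"),
  structure = c("file", "metals", "cutoff", "interface_chains",
                "hbond_da_max"),
  hydro = c("enabled", "n_models"))
SPEC_KEYS <- c("n_res_domain", "tail_length", "closed_separation",
               "open_separation", "closed_threshold", "open_threshold",
               "bead_radius", "residue_volume", "channel_width")

#' Validate a pipeline configuration
#'
#' @param config A named list (e.g. from [yaml::read_yaml()]).
#' @return The config, invisibly, or an error naming the unknown key.
#' @export
validate_config <- function(config) {
  if (!is.list(config)) stop("config must be a list", call. = FALSE)
  bad <- setdiff(names(config), names(PIPELINE_SCHEMA))
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  for (section in setdiff(intersect(names(config), names(PIPELINE_SCHEMA)),
                          c("seed", "output_dir"))) {
    bad <- setdiff(names(config[[section]]), PIPELINE_SCHEMA[[section]])
    if (length(bad)) {
      stop(sprintf("unknown config key(s) in '%s': %s", section,
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  if (!is.null(config$pool$spec)) {
    bad <- setdiff(names(config$pool$spec), SPEC_KEYS)
    if (length(bad)) {
      stop("unknown config key(s) in 'pool.spec': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  invisible(config)
}

#' Run the full analysis pipeline
#'
#' Stages, in dependency order: conformer pool (generated or loaded),
#' target curve (read or simulated with known ground truth), ensemble
#' optimisation, state classification and population estimation, optional
#' structure report (metal sites, His-motif scan, optional interface) and
#' optional hull hydrodynamics.  All outputs land in `output_dir` together
#' with `manifest.json` recording the config, its hash and every seed;
#' rerunning the same config reproduces the outputs.
#'
#' @param config Path to a YAML file or a config list (see
#'   [validate_config()]).
#' @param output_dir Overrides `config$output_dir`.
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) {
    config_text <- readLines(config, warn = FALSE)
    config <- yaml::read_yaml(text = paste(config_text, collapse = "\n"))
  }
  validate_config(config)
  out <- output_dir %||% config$output_dir %||%
    stop("no output_dir configured", call. = FALSE)
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  seed <- config$seed %||% 1L
  cfg_file <- file.path(out, "config_used.yaml")
  yaml::write_yaml(config, cfg_file)
  cfg_hash <- unname(tools::md5sum(cfg_file))
  manifest <- list(config_hash = cfg_hash, seed = seed, stages = list())
  stage <- function(name, code) {
    message(sprintf("[%s] seed=%d", name, seed))
    tryCatch(code, error = function(e) {
      jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  qg <- config$q_grid
  q_grid <- if (is.null(qg)) default_q_grid() else
    seq(qg$min, qg$max, length.out = qg$n)

  pool <- stage("pool", {
    if (!is.null(config$pool$dir)) {
      read_pool(config$pool$dir)
    } else {
      spec <- do.call(conformer_spec, config$pool$spec %||% list())
      counts <- unlist(config$pool$counts %||%
                         list(closed_monomer = 30L, open_monomer = 15L,
                              tetramer = 15L))
      p <- generate_pool(counts, spec, seed = seed, q_grid = q_grid)
      write_pool(p, file.path(out, "pool"))
      p
    }
  })
  manifest$stages$pool <- list(n = length(pool$labels),
                               labels = as.list(table(pool$labels)))

  truth <- NULL
  target <- stage("target", {
    tc <- config$target %||% list()
    if (!is.null(tc$file)) {
      read_saxs_profile(tc$file)
    } else {
      weights <- unlist(tc$weights %||%
                          list(closed_monomer = 0.55, open_monomer = 0.15,
                               tetramer = 0.30))
      truth <- mixture_truth(weights,
                              noise_a_frac = tc$noise_a_frac %||% 0.002,
                              noise_b = tc$noise_b %||% 0.01,
                              noise_c = tc$noise_c %||% 2,
                              seed = tc$seed %||% seed)
      prof <- simulate_experiment(pool, truth,
                                  noise = tc$noise %||% TRUE)
      write_saxs_profile(prof, file.path(out, "target.dat"),
                         header = "simulated mixture target")
      jsonlite::write_json(list(weights = as.list(weights),
                                seed = truth$seed),
                           file.path(out, "ground_truth.json"),
                           auto_unbox = TRUE, digits = NA)
      prof
    }
  })
  manifest$stages$target <- list(n_points = length(target$q),
                                 simulated = is.null(config$target$file))

  eom <- stage("eom", {
    params <- do.call(ga_params, utils::modifyList(
      list(seed = seed), config$ga %||% list()))
    res <- run_eom(pool, target, params)
    write_eom_result(res, file.path(out, "eom"))
    res
  })
  manifest$stages$eom <- list(chi_eom = eom$chi_eom,
                              repeats = length(eom$per_repeat_chis))

  populations <- stage("states", {
    thr <- do.call(state_thresholds, config$classifier %||% list())
    calls <- classify_pool(pool, thr)
    write_state_calls(calls, file.path(out, "state_calls.tsv"))
    est <- population_fractions(eom, calls, seed = seed)
    write_population_estimate(est, file.path(out, "populations.json"))
    est
  })
  manifest$stages$states <- list(fractions = as.list(populations$fractions))

  if (!is.null(config$structure$file)) {
    manifest$stages$structure <- stage("structure", {
      model <- read_structure(config$structure$file)
      sites <- find_metal_sites(model,
                                metals = config$structure$metals %||%
                                  METAL_ELEMENTS,
                                cutoff = config$structure$cutoff %||% 2.8)
      scan <- his_motif_scan(model)
      report <- list(
        n_metal_sites = length(sites),
        n_unique_classes = length(attr(sites, "classes")),
        residue_counts = vapply(sites, `[[`, integer(1),
                                "n_protein_residues"),
        geometries = vapply(sites, function(s) s$geometry$label,
                            character(1)),
        his_runs = scan)
      if (!is.null(config$structure$interface_chains)) {
        ch <- config$structure$interface_chains
        report$buried_area <- interface_area(model, ch[[1]], ch[[2]])
        report$n_hbonds <- nrow(hydrogen_bonds(
          model, ch[[1]], ch[[2]],
          hbond_criteria(da_max = config$structure$hbond_da_max %||% 3.5)))
      }
      jsonlite::write_json(report, file.path(out, "structure_report.json"),
                           auto_unbox = TRUE, digits = NA, force = TRUE)
      report[c("n_metal_sites", "n_unique_classes")]
    })
  }

  if (isTRUE(config$hydro$enabled %||% TRUE)) {
    manifest$stages$hydro <- stage("hydro", {
      nm <- min(config$hydro$n_models %||% 10L, length(pool$labels))
      idx <- seq_len(nm)
      tab <- data.frame(
        id = idx, label = pool$labels[idx],
        rh = vapply(pool$conformers[idx],
                    function(m) hull_rh(m)$rh, numeric(1)))
      utils::write.table(tab, file.path(out, "hydro.tsv"), sep = "\t",
                         row.names = FALSE, quote = FALSE)
      list(mean_rh_by_label = as.list(tapply(tab$rh, tab$label, mean)))
    })
  }

  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(manifest)
}
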