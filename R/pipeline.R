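#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the full configuration of a simulate/analyze
#' run. Every instrument and decision constant is a config default rather than
#' a hard-coded value: the 14 um single-time-point set height, the wedged-lever
#' heights (12/10/8 um), the 0.3 N/m spring constant, the 0.05 significance
#' level, the 20%/10% effect gates, and the 12-cell minimum.
#'
#' @param ... Named overrides, merged (recursively) into the defaults.
#' @return A nested list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  defaults <- list(
    seed = 1L,
    geometry = list(convention = "circle"),
    cantilever = list(k = 0.3, tilt_deg = 10, wedged = TRUE,
                      deflection_sensitivity = NULL),
    equilibrium = list(window_s = 10, slope_tol = NULL, rel_slope_tol = 1e-3),
    image = list(band_um = 0.7, n_rays = 72, sigma = 1),
    thresholds = list(alpha = 0.05, effect_gate_force = 0.2,
                      effect_gate_pressure = 0.2, effect_gate_volume = 0.1,
                      min_cells = 12, min_rounds = 2,
                      success_threshold = 0.5),
    simulate = list(
      kind = "cells",
      cells = list(n_cells = 1, P_true = 150, V_true = 2500, MLR_true = 2,
                   ALR_true = 1.5, tau = 8, noise_cv = 0, drift_rate = 0,
                   pixel_size = 0.2, h_set = 10, x_um = 0,
                   duration_s = 60, rate_hz = 10),
      screen = list(n_genes = 100, n_cells_per_round = 12, n_rounds = 2,
                    control_cv = 0.2, day_effect_sd = 0.1, baseline_nN = 60,
                    effects = NULL)
    )
  )
  cfg <- modify_deep(defaults, list(...))
  validate_config(cfg)
}

modify_deep <- function(base, new) {
  for (nm in names(new)) {
    if (is.list(base[[nm]]) && is.list(new[[nm]]) &&
        !is.null(names(new[[nm]]))) {
      base[[nm]] <- modify_deep(base[[nm]], new[[nm]])
    } else {
      base[[nm]] <- new[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  th <- cfg$thresholds
  do.call(screen_thresholds, th)   # validates (0,1) ranges
  if (!cfg$geometry$convention %in% c("circle", "as_printed")) {
    abort("geometry convention must be 'circle' or 'as_printed'.",
          class = "mitomech_config_error")
  }
  if (is.null(cfg$seed)) {
    abort("config must carry a seed.", class = "mitomech_config_error")
  }
  structure(cfg, class = "pipeline_config")
}

#' @param path YAML file path.
#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("config not found: ", path), class = "mitomech_config_error")
  }
  do.call(pipeline_config, yaml::yaml.load_file(path))
}

#' @param config A `pipeline_config`.
#' @rdname pipeline_config
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

config_spec <- function(cfg) {
  cantilever_spec(k = cfg$cantilever$k, tilt_deg = cfg$cantilever$tilt_deg,
                  wedged = isTRUE(cfg$cantilever$wedged),
                  deflection_sensitivity = cfg$cantilever$deflection_sensitivity)
}

#' Simulate a dataset to disk
#'
#' Writes a complete synthetic dataset in the same dialects the analysis
#' stage reads. For `simulate$kind = "cells"`: one force-trace TSV and one
#' midplane TIFF per cell plus `metadata.csv` and `truth.csv`. For
#' `simulate$kind = "screen"`: a per-cell `cells.csv` plus `truth.csv`.
#' Deterministic for a fixed config seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
pipeline_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- config_spec(config)
  if (config$simulate$kind == "screen") {
    sc <- config$simulate$screen
    effects <- if (!is.null(sc$effects)) dplyr::bind_rows(sc$effects)
    design <- screen_design(n_genes = sc$n_genes, effects = effects,
                            n_cells_per_round = sc$n_cells_per_round,
                            n_rounds = sc$n_rounds, control_cv = sc$control_cv,
                            day_effect_sd = sc$day_effect_sd,
                            baseline_nN = sc$baseline_nN,
                            seed = config$seed)
    scr <- simulate_screen(design)
    readr::write_csv(scr$cells, file.path(out_dir, "cells.csv"))
    readr::write_csv(scr$truth, file.path(out_dir, "truth.csv"))
    readr::write_csv(scr$day_effects, file.path(out_dir, "day_effects.csv"))
  } else if (config$simulate$kind == "cells") {
    cc <- config$simulate$cells
    dir.create(file.path(out_dir, "traces"), showWarnings = FALSE)
    dir.create(file.path(out_dir, "images"), showWarnings = FALSE)
    rows <- purrr::map_dfr(seq_len(cc$n_cells), function(i) {
      params <- true_cell_params(P_true = cc$P_true, V_true = cc$V_true,
                                 MLR_true = cc$MLR_true, ALR_true = cc$ALR_true,
                                 tau = cc$tau, noise_cv = cc$noise_cv,
                                 drift_rate = cc$drift_rate,
                                 pixel_size = cc$pixel_size)
      cell <- simulate_confined_cell(params, h_set = cc$h_set, spec = spec,
                                     x_um = cc$x_um,
                                     duration_s = cc$duration_s,
                                     rate_hz = cc$rate_hz,
                                     seed = config$seed + i)
      id <- sprintf("cell%04d", i)
      write_force_trace(cell$trace,
                        file.path(out_dir, "traces", paste0(id, ".tsv")),
                        h_set_um = cc$h_set)
      write_midplane_tiff(cell$image,
                          file.path(out_dir, "images", paste0(id, ".tif")))
      dplyr::mutate(cell$truth, cell_id = id, .before = 1)
    })
    meta <- dplyr::transmute(rows,
                             cell_id = .data$cell_id,
                             gene = "F-Luc", condition = "control",
                             round_id = "round01",
                             k_N_per_m = spec$k,
                             h_set_um = .data$h_set_um,
                             wedged = spec$wedged,
                             x_um = .data$x_um,
                             A_m_um2 = .data$A_m_um2,
                             pixel_size_um = .data$pixel_size)
    readr::write_csv(meta, file.path(out_dir, "metadata.csv"))
    readr::write_csv(rows, file.path(out_dir, "truth.csv"))
  } else {
    abort("simulate$kind must be 'cells' or 'screen'.",
          class = "mitomech_config_error")
  }
  invisible(out_dir)
}

#' Analyze a dataset
#'
#' Runs the full chain on a dataset directory. For a per-cell dataset
#' (`metadata.csv` + `traces/`): trace -> equilibrium force -> geometry ->
#' pressure and volume, written to `mechanics.csv`. For a screen dataset
#' (`cells.csv`): control normalization -> per-round tests -> hit calls,
#' written to `rounds.csv` and `hits.csv`. Every derived row keeps its input
#' `cell_id`/`gene`.
#'
#' @param config A [pipeline_config()].
#' @param data_dir Dataset directory (from [pipeline_simulate()] or real
#'   exported data in the same dialects).
#' @param out_dir Output directory (default: `data_dir`).
#' @return A list of the result tibbles, invisibly; files are written to
#'   `out_dir`.
#' @export
pipeline_analyze <- function(config, data_dir, out_dir = data_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  meta_path <- file.path(data_dir, "metadata.csv")
  cells_path <- file.path(data_dir, "cells.csv")
  if (!file.exists(meta_path) && !file.exists(cells_path)) {
    abort("no dataset found: need metadata.csv (cells) or cells.csv (screen).",
          class = "mitomech_data_error")
  }
  if (file.exists(meta_path)) {
    meta <- readr::read_csv(meta_path, show_col_types = FALSE)
    eq <- purrr::map_dfr(meta$cell_id, function(id) {
      tr <- read_force_trace(file.path(data_dir, "traces",
                                       paste0(id, ".tsv")))
      if ("Vd_V" %in% names(tr)) tr <- deflection_to_force(tr)
      dplyr::mutate(
        extract_equilibrium_force(
          tr,
          window_s = config$equilibrium$window_s,
          slope_tol = config$equilibrium$slope_tol,
          rel_slope_tol = config$equilibrium$rel_slope_tol %||% 1e-3),
        cell_id = id, .before = 1)
    })
    cells <- dplyr::left_join(meta, eq, by = "cell_id")
    mech <- compute_mechanics(cells, config_spec(config),
                              convention = config$geometry$convention)
    readr::write_csv(mech, file.path(out_dir, "mechanics.csv"))
    results$mechanics <- mech
  }
  if (file.exists(cells_path)) {
    cells <- readr::read_csv(cells_path, show_col_types = FALSE)
    th <- do.call(screen_thresholds, config$thresholds)
    normalized <- normalize_to_control(cells)
    hits <- call_hits(cells, thresholds = th)
    readr::write_csv(tidy(hits, per_round = TRUE),
                     file.path(out_dir, "rounds.csv"))
    readr::write_csv(tidy(hits), file.path(out_dir, "hits.csv"))
    results$normalized <- normalized
    results$hits <- hits
  }
  invisible(results)
}

#' Write a human-readable analysis report
#'
#' Summarizes an analyzed dataset directory as plain text: per-cell mechanics
#' (when present), and for screens the hit genes, their success rates and
#' directions, with every threshold that was applied recorded for audit.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Directory holding the [pipeline_analyze()] outputs.
#' @param path Report path (default `report.txt` in `out_dir`).
#' @return `path`, invisibly.
#' @export
pipeline_report <- function(config, out_dir, path = file.path(out_dir, "report.txt")) {
  stopifnot(inherits(config, "pipeline_config"))
  lines <- c("mitomech analysis report", strrep("=", 24), "")
  th <- config$thresholds
  lines <- c(lines, "thresholds applied:",
             sprintf("  alpha = %g (p <= alpha passes)", th$alpha),
             sprintf("  effect gates: force/pressure > %g%%, volume > %g%%",
                     100 * th$effect_gate_force, 100 * th$effect_gate_volume),
             sprintf("  min cells per round = %d; min rounds = %d; success rate > %g%%",
                     th$min_cells, th$min_rounds, 100 * th$success_threshold),
             "")
  mech_path <- file.path(out_dir, "mechanics.csv")
  if (file.exists(mech_path)) {
    mech <- readr::read_csv(mech_path, show_col_types = FALSE)
    lines <- c(lines,
               sprintf("per-cell mechanics: %d cells", nrow(mech)),
               sprintf("  mean F_eq = %.1f nN; mean P = %.1f Pa; mean V = %.0f um^3",
                       mean(mech$F_eq_N) * 1e9, mean(mech$P_Pa),
                       mean(mech$V_um3)),
               "")
  }
  hits_path <- file.path(out_dir, "hits.csv")
  if (file.exists(hits_path)) {
    hits <- readr::read_csv(hits_path, show_col_types = FALSE)
    n_hit <- sum(hits$is_primary_hit)
    lines <- c(lines, sprintf("screen: %d genes tested, %d primary hits",
                              nrow(hits), n_hit))
    if (n_hit == 0) {
      lines <- c(lines, "  zero hits.")
    } else {
      hh <- dplyr::arrange(dplyr::filter(hits, .data$is_primary_hit),
                           .data$mean_relative)
      lines <- c(lines, purrr::map_chr(seq_len(nrow(hh)), function(i) {
        sprintf("  %s: relative force %.2f, success rate %.0f%% (%s)",
                hh$gene[i], hh$mean_relative[i], 100 * hh$success_rate[i],
                hh$direction[i])
      }))
    }
  }
  if (!file.exists(mech_path) && !file.exists(hits_path)) {
    abort("no analysis outputs found in out_dir.",
          class = "mitomech_data_error")
  }
  writeLines(lines, path)
  invisible(path)
}
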