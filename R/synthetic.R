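# Run code with a private RNG stream, leaving the caller's RNG state intact.
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Ground-truth parameters of a simulated confined cell
#'
#' The generative counterparts of the quantities the pipeline estimates:
#' intracellular pressure, cell volume, cortical localization ratios, the
#' force-relaxation time constant, trace noise and drift, and the imaging
#' pixel size. Defaults describe a typical STC-arrested mitotic HeLa cell
#' under plate confinement.
#'
#' @param P_true Intracellular pressure in Pa (default 150).
#' @param V_true Cell volume in um^3 (default 2500).
#' @param MLR_true,ALR_true Cortex-to-cytoplasm localization ratios for the
#'   myosin and actin channels (default 2 and 1.5).
#' @param tau Force-relaxation time constant in s (default 8; equilibrium is
#'   then reached within tens of seconds).
#' @param noise_cv Within-trace force noise, as a fraction of the equilibrium
#'   force (default 0).
#' @param drift_rate Linear force drift in N/s (default 0).
#' @param pixel_size Imaging pixel size in um/px (default 0.2).
#' @return A list of class `true_cell_params`.
#' @export
true_cell_params <- function(P_true = 150, V_true = 2500,
                             MLR_true = 2, ALR_true = 1.5,
                             tau = 8, noise_cv = 0, drift_rate = 0,
                             pixel_size = 0.2) {
  if (P_true <= 0 || V_true <= 0 || tau <= 0 || noise_cv < 0 ||
      pixel_size <= 0) {
    abort("invalid true-cell parameters.", class = "mitomech_config_error")
  }
  structure(list(P_true = P_true, V_true = V_true, MLR_true = MLR_true,
                 ALR_true = ALR_true, tau = tau, noise_cv = noise_cv,
                 drift_rate = drift_rate, pixel_size = pixel_size),
            class = "true_cell_params")
}

# Self-consistent confined geometry for prescribed pressure and volume.
# Height depends (weakly) on force through the cantilever deflection and tilt
# terms, and force depends on height through the contact area; resolved by
# fixed-point iteration. Vectorized over `P`.
solve_confined_state <- function(P, V, h_set, spec, x = 0,
                                 tol = 1e-9, max_iter = 200) {
  h <- rep(h_set, length(P))
  for (i in seq_len(max_iter)) {
    r_c <- invert_volume(V, h)
    r_m <- r_c + h / 2
    F <- P * pi * r_c^2 * 1e-12            # Pa * um^2 -> N
    h_new <- cell_height(h_set, F, spec, r_m = r_m, x = x)
    if (max(abs(h_new - h) / h) < tol) {
      h <- h_new
      break
    }
    h <- h_new
  }
  r_c <- invert_volume(V, h)
  r_m <- r_c + h / 2
  tibble(h_um = h, r_c_um = r_c, r_m_um = r_m,
         A_c_um2 = pi * r_c^2,
         A_m_um2 = pi * r_m^2,
         F_N = P * pi * r_c^2 * 1e-12)
}

# Render a midplane image of a confined cell: a disk of the midplane radius
# with a thin cortical ring just inside the boundary. `ratios` maps channel
# name -> cortex/cytoplasm ratio (ratio 1 = no ring, e.g. a membrane channel).
render_midplane <- function(r_m_um, pixel_size, ratios = c(membrane = 1),
                            I_cyto = 100, ring_um = 0.7, poisson = FALSE) {
  R <- r_m_um / pixel_size
  w <- ring_um / pixel_size
  n <- 2L * ceiling(1.3 * R) + 1L
  ctr <- (n + 1) / 2
  d <- sqrt(outer((seq_len(n) - ctr)^2, (seq_len(n) - ctr)^2, "+"))
  channels <- lapply(ratios, function(ratio) {
    m <- matrix(0, n, n)
    m[d <= R] <- I_cyto
    m[d <= R & d > R - w] <- ratio * I_cyto
    if (poisson) m[] <- rpois(length(m), m)
    m
  })
  midplane_image(channels, pixel_size)
}

#' Simulate one confined-cell measurement
#'
#' Forward model of the single-time-point confinement assay. The prescribed
#' pressure and volume are turned into a self-consistent confined geometry
#' (height, midplane and contact radii, equilibrium force), from which an
#' exponentially relaxing force trace `F(t) = F_eq (1 - exp(-t/tau))` with
#' additive Gaussian noise and linear drift, and a midplane image with
#' cortical rings at the prescribed localization ratios, are rendered.
#'
#' @param params A [true_cell_params()].
#' @param h_set Preset cantilever height in um (default 10, a typical wedged
#'   set height; the default cell volume of 2500 um^3 comfortably spans it).
#'   Non-wedged configurations at larger set heights need correspondingly
#'   larger cell volumes to remain feasible after the tilt correction.
#' @param spec A [cantilever_spec()] (default wedged, k = 0.3 N/m).
#' @param x_um Tip-to-cell-edge distance in um (non-wedged levers; forced to
#'   0 for wedged levers).
#' @param duration_s,rate_hz Trace length and sampling rate (default 60 s at
#'   10 Hz).
#' @param seed Seed for the noise draws (required when `noise_cv > 0`).
#' @param poisson_image Add Poisson noise to the image (default FALSE).
#' @return A list with elements `trace` ([force_trace()]), `image`
#'   ([midplane_image()] with channels `membrane`, `myosin`, `actin`), and
#'   `truth` (one-row tibble of every generating parameter and the derived
#'   geometry).
#' @examples
#' cell <- simulate_confined_cell(true_cell_params(), seed = 1)
#' cell$truth
#' @export
simulate_confined_cell <- function(params = true_cell_params(),
                                   h_set = 10,
                                   spec = cantilever_spec(k = 0.3, wedged = TRUE),
                                   x_um = 0,
                                   duration_s = 60, rate_hz = 10,
                                   seed = NULL,
                                   poisson_image = FALSE) {
  stopifnot(inherits(params, "true_cell_params"),
            inherits(spec, "cantilever_spec"))
  if (spec$wedged) x_um <- 0
  state <- solve_confined_state(params$P_true, params$V_true, h_set, spec,
                                x = x_um)
  F_eq <- state$F_N
  t <- seq(0, duration_s, by = 1 / rate_hz)
  f_clean <- F_eq * (1 - exp(-t / params$tau)) + params$drift_rate * t
  noisy <- params$noise_cv > 0 || isTRUE(poisson_image)
  if (noisy && is.null(seed)) {
    abort("`seed` is required for stochastic simulation.",
          class = "mitomech_config_error")
  }
  sim <- with_seed(seed %||% 0L, {
    f <- f_clean
    if (params$noise_cv > 0) {
      f <- f + rnorm(length(t), sd = params$noise_cv * F_eq)
    }
    img <- render_midplane(state$r_m_um, params$pixel_size,
                           ratios = c(membrane = 1,
                                      myosin = params$MLR_true,
                                      actin = params$ALR_true),
                           poisson = poisson_image)
    list(f = f, img = img)
  })
  truth <- dplyr::bind_cols(
    tibble(P_true = params$P_true, V_true = params$V_true,
           MLR_true = params$MLR_true, ALR_true = params$ALR_true,
           tau = params$tau, noise_cv = params$noise_cv,
           drift_rate = params$drift_rate, pixel_size = params$pixel_size,
           h_set_um = h_set, x_um = x_um, F_eq_N = F_eq),
    state[, c("h_um", "r_m_um", "r_c_um", "A_c_um2", "A_m_um2")]
  )
  list(trace = force_trace(t, F_N = sim$f, spec = spec),
       image = sim$img,
       truth = truth)
}

#' Simulate a trans-mitotic confinement recording
#'
#' Renders a cell progressing through mitosis under constant-height
#' confinement: low pressure before nuclear envelope breakdown, a linear rise
#' to the metaphase plateau as the cell rounds, the plateau until anaphase
#' onset, then a drop back. The pressure schedule is pushed through the same
#' self-consistent forward model as [simulate_confined_cell()], so the force
#' trace and the per-frame geometry are mutually consistent.
#'
#' @param P_base,P_meta Pressure before rounding and at the metaphase plateau
#'   (Pa; defaults 30 and 150).
#' @param nebd_s,nebd_to_plate_s,plate_to_anaphase_s Event schedule: NEBD
#'   time, and the two phase durations, in seconds.
#' @param V_true Cell volume in um^3 (held constant).
#' @param h_set Preset height in um (default 10, wedged).
#' @param spec A [cantilever_spec()] (default wedged, k = 0.3).
#' @param duration_s,rate_hz Trace length and sampling rate.
#' @param frame_interval_s Imaging frame interval for the geometry series
#'   (default 120 s).
#' @param noise_cv Force noise as a fraction of the plateau force.
#' @param seed Seed (required when `noise_cv > 0`).
#' @return A list: `trace` (annotated [force_trace()]), `geometry` (per-frame
#'   tibble with `t_s`, `P_Pa`, `h_um`, `r_m_um`, `r_c_um`, `A_c_um2`,
#'   `A_m_um2`), and `truth` (scheduled parameters).
#' @export
simulate_transmitotic <- function(P_base = 30, P_meta = 150,
                                  nebd_s = 120, nebd_to_plate_s = 720,
                                  plate_to_anaphase_s = 1080,
                                  V_true = 2500, h_set = 10,
                                  spec = cantilever_spec(k = 0.3, wedged = TRUE),
                                  duration_s = NULL, rate_hz = 0.5,
                                  frame_interval_s = 120,
                                  noise_cv = 0, seed = NULL) {
  if (nebd_to_plate_s <= 0 || plate_to_anaphase_s <= 0 || nebd_s < 0) {
    abort("phase schedule must be ordered NEBD < plate < anaphase.",
          class = "mitomech_invalid_input")
  }
  t_plate <- nebd_s + nebd_to_plate_s
  t_ana <- t_plate + plate_to_anaphase_s
  duration_s <- duration_s %||% (t_ana + 300)
  if (duration_s <= t_ana) {
    abort("trace must extend past anaphase onset.",
          class = "mitomech_invalid_input")
  }
  pressure_at <- function(tt) {
    p <- numeric(length(tt))
    p[tt < nebd_s] <- P_base
    ramp <- tt >= nebd_s & tt < t_plate
    p[ramp] <- P_base + (P_meta - P_base) * (tt[ramp] - nebd_s) / nebd_to_plate_s
    p[tt >= t_plate & tt <= t_ana] <- P_meta
    post <- tt > t_ana
    p[post] <- P_base + (P_meta - P_base) * exp(-(tt[post] - t_ana) / 60)
    p
  }
  t <- seq(0, duration_s, by = 1 / rate_hz)
  state <- solve_confined_state(pressure_at(t), V_true, h_set, spec)
  f <- state$F_N
  if (noise_cv > 0) {
    if (is.null(seed)) {
      abort("`seed` is required for stochastic simulation.",
            class = "mitomech_config_error")
    }
    F_plateau <- P_meta * pi * solve_confined_state(P_meta, V_true, h_set,
                                                    spec)$r_c_um^2 * 1e-12
    f <- with_seed(seed, f + rnorm(length(t), sd = noise_cv * F_plateau))
  }
  ann <- c(NEBD = nebd_s, metaphase_plate = t_plate, anaphase_onset = t_ana,
           release = duration_s)
  frame_idx <- seq(1L, length(t), by = max(1L, round(frame_interval_s * rate_hz)))
  frames_t <- t[frame_idx]
  geometry <- dplyr::bind_cols(
    tibble(t_s = frames_t, P_Pa = pressure_at(frames_t)),
    state[frame_idx, c("h_um", "r_m_um", "r_c_um", "A_c_um2", "A_m_um2")]
  )
  list(trace = force_trace(t, F_N = f, spec = spec, annotations = ann),
       geometry = geometry,
       truth = tibble(P_base = P_base, P_meta = P_meta, V_true = V_true,
                      h_set_um = h_set, nebd_s = nebd_s,
                      nebd_to_plate_s = nebd_to_plate_s,
                      plate_to_anaphase_s = plate_to_anaphase_s,
                      noise_cv = noise_cv))
}

#' Screen design for the simulator
#'
#' Describes a multi-round RNAi mechanophenotyping screen: how many genes,
#' their true multiplicative effects on force (optionally pressure and
#' volume), cells per round, rounds, the across-cell coefficient of
#' variation, and a log-scale day effect shared by all cells measured in the
#' same round.
#'
#' @param n_genes Number of screened genes (effects default to 1 = no effect).
#' @param effects Optional tibble with columns `gene`, `effect_force` and
#'   optionally `effect_pressure`, `effect_volume`; genes not listed get
#'   effect 1. Multiplicative, > 0.
#' @param n_cells_per_round Treated (and control) cells per round (default 12,
#'   the screen's sample size).
#' @param n_rounds Measurement rounds (default 2).
#' @param control_cv Across-cell coefficient of variation (default 0.2).
#' @param day_effect_sd Log-scale standard deviation of the per-round day
#'   effect (default 0.1).
#' @param baseline_nN Control equilibrium rounding force in nN (default 60).
#' @param include_positive_control Add an `MYH9`-like positive control with
#'   force effect 0.2 (default TRUE).
#' @param seed Seed (mandatory).
#' @return A list of class `screen_design`.
#' @export
screen_design <- function(n_genes = 100, effects = NULL,
                          n_cells_per_round = 12, n_rounds = 2,
                          control_cv = 0.2, day_effect_sd = 0.1,
                          baseline_nN = 60,
                          include_positive_control = TRUE,
                          seed) {
  if (missing(seed) || is.null(seed)) {
    abort("`seed` is mandatory for a screen design.",
          class = "mitomech_config_error")
  }
  genes <- sprintf("gene%04d", seq_len(n_genes))
  tbl <- tibble(gene = genes, effect_force = 1,
                effect_pressure = 1, effect_volume = 1)
  if (!is.null(effects)) {
    effects <- as_tibble(effects)
    if (any(effects$effect_force <= 0)) {
      abort("effects must be positive multiplicative factors.",
            class = "mitomech_config_error")
    }
    for (col in intersect(c("effect_force", "effect_pressure", "effect_volume"),
                          names(effects))) {
      idx <- match(effects$gene, tbl$gene)
      bad <- is.na(idx)
      if (any(bad)) {
        tbl <- dplyr::bind_rows(
          tbl, tibble(gene = effects$gene[bad], effect_force = 1,
                      effect_pressure = 1, effect_volume = 1))
        idx <- match(effects$gene, tbl$gene)
      }
      tbl[[col]][idx] <- effects[[col]]
    }
  }
  if (include_positive_control && !"MYH9" %in% tbl$gene) {
    tbl <- dplyr::bind_rows(
      tbl, tibble(gene = "MYH9", effect_force = 0.2,
                  effect_pressure = 0.2, effect_volume = 1))
  }
  structure(list(effects = tbl,
                 n_cells_per_round = as.integer(n_cells_per_round),
                 n_rounds = as.integer(n_rounds),
                 control_cv = control_cv,
                 day_effect_sd = day_effect_sd,
                 baseline_nN = baseline_nN,
                 seed = as.integer(seed)),
            class = "screen_design")
}

#' Simulate a multi-round screen
#'
#' Draws per-cell equilibrium rounding forces (and matched pressures and
#' volumes) for every gene and round of a [screen_design()]. Within a round,
#' a shared log-normal day effect multiplies all cells (treated and control
#' alike, so control normalization removes it exactly in expectation); across
#' cells, forces are log-normal around `baseline * day_effect * gene_effect`
#' with the design's coefficient of variation. Each round carries an `F-Luc`
#' control group of the same size.
#'
#' @param design A [screen_design()].
#' @return A list: `cells` (tibble with `cell_id`, `gene`, `condition`,
#'   `round_id`, `F_eq_nN`, `P_Pa`, `V_um3`) and `truth` (the design's effect
#'   table plus the drawn day effects).
#' @examples
#' scr <- simulate_screen(screen_design(n_genes = 5, seed = 1))
#' head(scr$cells)
#' @export
simulate_screen <- function(design) {
  stopifnot(inherits(design, "screen_design"))
  sdlog <- sqrt(log(1 + design$control_cv^2))
  baseline_P <- 150    # Pa
  baseline_V <- 2500   # um^3
  vol_cv <- 0.08       # volumes vary less than forces across cells
  sdlog_v <- sqrt(log(1 + vol_cv^2))
  with_seed(design$seed, {
    day <- exp(rnorm(design$n_rounds, 0, design$day_effect_sd))
    genes <- dplyr::bind_rows(
      tibble(gene = "F-Luc", effect_force = 1, effect_pressure = 1,
             effect_volume = 1, condition = "control"),
      dplyr::mutate(design$effects, condition = "treated")
    )
    idx <- rep(seq_len(nrow(genes)), each = design$n_cells_per_round)
    rounds <- purrr::map_dfr(seq_len(design$n_rounds), function(r) {
      m <- length(idx)
      tibble(
        gene = genes$gene[idx],
        condition = genes$condition[idx],
        round_id = sprintf("round%02d", r),
        F_eq_nN = design$baseline_nN * day[r] * genes$effect_force[idx] *
          exp(rnorm(m, -sdlog^2 / 2, sdlog)),
        P_Pa = baseline_P * day[r] * genes$effect_pressure[idx] *
          exp(rnorm(m, -sdlog^2 / 2, sdlog)),
        V_um3 = baseline_V * genes$effect_volume[idx] *
          exp(rnorm(m, -sdlog_v^2 / 2, sdlog_v))
      )
    })
    cells <- dplyr::mutate(rounds,
                           cell_id = sprintf("cell%06d", dplyr::row_number()),
                           .before = 1)
    truth <- dplyr::mutate(design$effects)
    list(cells = cells,
         truth = truth,
         day_effects = tibble(round_id = sprintf("round%02d",
                                                 seq_len(design$n_rounds)),
                              day_effect = day))
  })
}
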