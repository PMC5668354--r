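#' Default thresholds for screen hit calling
#'
#' The screen's decision rules in one place: significance level for the
#' per-round Student t-test, minimal relative change gates for force and
#' pressure (20%) and volume (10%), the minimal number of treated cells for a
#' round to count (12), the minimal number of countable rounds (2), and the
#' success-rate threshold across rounds (strictly more than 50%).
#'
#' @param alpha Per-round significance level (p <= alpha passes; default 0.05).
#' @param effect_gate_force,effect_gate_pressure Relative-change gates for
#'   force and pressure (strict; default 0.20).
#' @param effect_gate_volume Relative-change gate for volume (strict;
#'   default 0.10).
#' @param min_cells Minimum treated cells per countable round (default 12).
#' @param min_rounds Minimum countable rounds for a hit call (default 2).
#' @param success_threshold Success-rate threshold, strict (default 0.5).
#' @return A named list of thresholds.
#' @export
screen_thresholds <- function(alpha = 0.05,
                              effect_gate_force = 0.20,
                              effect_gate_pressure = 0.20,
                              effect_gate_volume = 0.10,
                              min_cells = 12L,
                              min_rounds = 2L,
                              success_threshold = 0.5) {
  th <- list(alpha = alpha,
             effect_gate_force = effect_gate_force,
             effect_gate_pressure = effect_gate_pressure,
             effect_gate_volume = effect_gate_volume,
             min_cells = as.integer(min_cells),
             min_rounds = as.integer(min_rounds),
             success_threshold = success_threshold)
  gates <- unlist(th[c("alpha", "effect_gate_force", "effect_gate_pressure",
                       "effect_gate_volume", "success_threshold")])
  if (any(gates <= 0 | gates >= 1)) {
    abort("thresholds must lie in (0, 1).", class = "mitomech_config_error")
  }
  th
}

#' Normalize measurements to same-round controls
#'
#' Every measurement day (round) carries its own control group; raw values
#' are only comparable within a round. This divides each cell's force (and
#' pressure/volume, when present) by the mean of the same round's control
#' cells, so a relative value of 1 means "like control". Control cells are
#' normalized against their own round mean as well.
#'
#' @param cells Data frame of per-cell measurements with columns `gene`,
#'   `condition` (`"treated"` or `"control"`), `round_id`, `F_eq_nN` and
#'   optionally `P_Pa`, `V_um3`.
#' @return The input tibble with `rel_F` (and `rel_P`, `rel_V` when the raw
#'   columns are present) appended.
#' @export
normalize_to_control <- function(cells) {
  stopifnot(is.data.frame(cells))
  needed <- c("gene", "condition", "round_id", "F_eq_nN")
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols)) {
    abort(paste0("missing columns: ", paste(missing_cols, collapse = ", ")),
          class = "mitomech_invalid_input")
  }
  cells <- as_tibble(cells)
  ctrl <- dplyr::filter(cells, .data$condition == "control")
  if (nrow(ctrl) == 0L ||
      !all(unique(cells$round_id) %in% unique(ctrl$round_id))) {
    abort("every round needs at least one control cell.",
          class = "mitomech_normalization_error")
  }
  vars <- intersect(c("F_eq_nN", "P_Pa", "V_um3"), names(cells))
  ctrl_means <- dplyr::summarise(
    dplyr::group_by(ctrl, .data$round_id),
    dplyr::across(dplyr::all_of(vars), ~ mean(.x, na.rm = TRUE),
                  .names = "ctrl_{.col}"),
    .groups = "drop"
  )
  out <- dplyr::left_join(cells, ctrl_means, by = "round_id")
  rel_names <- c(F_eq_nN = "rel_F", P_Pa = "rel_P", V_um3 = "rel_V")
  for (v in vars) {
    out[[rel_names[[v]]]] <- out[[v]] / out[[paste0("ctrl_", v)]]
  }
  dplyr::select(out, -dplyr::starts_with("ctrl_"))
}

#' Per-round two-sample test against control
#'
#' One round of the screen compares treated cells to the same-round controls
#' with a two-sided two-sample t-test (classic equal-variance Student by
#' default, matching the screen's use after confirming control normality;
#' Welch optionally). A round passes when the p-value is at or below `alpha`
#' AND the treated-to-control mean ratio deviates from 1 by strictly more
#' than `effect_gate`.
#'
#' @param treated,control Numeric vectors of raw measurements (same units).
#' @param variant `"student"` (equal variance, default) or `"welch"`.
#' @param alpha Significance level (inclusive; default 0.05).
#' @param effect_gate Relative-change gate (strict; default 0.20).
#' @return A one-row tibble: `n_treated`, `n_control`, `mean_relative`,
#'   `p_value`, `passes`, `direction` (`"up"`/`"down"`).
#' @examples
#' round_test(c(5, 6, 7, 5, 6, 7), c(10, 11, 12, 10, 11, 12))
#' @export
round_test <- function(treated, control, variant = c("student", "welch"),
                       alpha = 0.05, effect_gate = 0.20) {
  variant <- match.arg(variant)
  if (length(treated) < 2L || length(control) < 2L) {
    abort("need at least 2 observations per group.",
          class = "mitomech_invalid_input")
  }
  mean_relative <- mean(treated) / mean(control)
  if (var(treated) == 0 && var(control) == 0) {
    # degenerate: no variance; identical means give p = 1 by convention
    p <- if (mean(treated) == mean(control)) 1 else 0
  } else {
    p <- t.test(treated, control, var.equal = (variant == "student"))$p.value
  }
  tibble(n_treated = length(treated),
         n_control = length(control),
         mean_relative = mean_relative,
         p_value = p,
         passes = (p <= alpha) && (abs(mean_relative - 1) > effect_gate),
         direction = if (mean_relative >= 1) "up" else "down")
}

#' Per-gene, per-round summaries for a whole screen
#'
#' Runs [round_test()] for every gene x round combination of a per-cell
#' measurement table against the same-round controls.
#'
#' @inheritParams normalize_to_control
#' @param value Column to test (default `F_eq_nN`).
#' @param thresholds A [screen_thresholds()] list.
#' @param effect_gate Relative-change gate; defaults to the force gate of
#'   `thresholds`.
#' @param variant t-test variant, see [round_test()].
#' @return A tibble with one row per gene x round: the [round_test()] columns
#'   plus `gene` and `round_id`.
#' @export
summarize_rounds <- function(cells, value = "F_eq_nN",
                             thresholds = screen_thresholds(),
                             effect_gate = thresholds$effect_gate_force,
                             variant = "student") {
  stopifnot(is.data.frame(cells), value %in% names(cells))
  cells <- as_tibble(cells)
  ctrl <- dplyr::filter(cells, .data$condition == "control")
  treated <- dplyr::filter(cells, .data$condition == "treated")
  if (nrow(ctrl) == 0L) {
    abort("no control cells in the table.",
          class = "mitomech_normalization_error")
  }
  ctrl_by_round <- split(ctrl[[value]], ctrl$round_id)
  grp <- dplyr::group_by(treated, .data$gene, .data$round_id)
  dplyr::ungroup(dplyr::reframe(grp, {
    cv <- ctrl_by_round[[as.character(.data$round_id[1])]]
    if (is.null(cv)) {
      abort(sprintf("round '%s' has no control cells.", .data$round_id[1]),
            class = "mitomech_normalization_error")
    }
    round_test(.data[[value]], cv, variant = variant,
               alpha = thresholds$alpha, effect_gate = effect_gate)
  }))
}

#' Primary hit call for one gene
#'
#' A gene is a primary hit when, over at least `min_rounds` countable rounds
#' (rounds with at least `min_cells` treated cells), the same phenotype
#' (significant change in the same direction, past the effect gate) recurred
#' at a success rate strictly above `success_threshold`. Rounds passing in
#' opposite directions with equal counts make the call ambiguous and the gene
#' is not a hit.
#'
#' @param rounds A data frame of per-round summaries for one gene
#'   ([round_test()] rows, needing `n_treated`, `passes`, `direction`).
#' @param thresholds A [screen_thresholds()] list.
#' @return A one-row tibble: `n_rounds` (countable), `n_passing`,
#'   `success_rate`, `direction`, `is_primary_hit`, `ambiguous`.
#' @export
call_primary_hit <- function(rounds, thresholds = screen_thresholds()) {
  stopifnot(is.data.frame(rounds), nrow(rounds) >= 1L)
  countable <- dplyr::filter(rounds, .data$n_treated >= thresholds$min_cells)
  n_countable <- nrow(countable)
  passing <- dplyr::filter(countable, .data$passes)
  n_up <- sum(passing$direction == "up")
  n_down <- sum(passing$direction == "down")
  ambiguous <- n_up > 0 && n_up == n_down
  direction <- if (nrow(passing) == 0L || ambiguous) NA_character_
               else if (n_up > n_down) "up" else "down"
  n_same <- max(n_up, n_down)
  success_rate <- if (n_countable > 0L) n_same / n_countable else NA_real_
  is_hit <- !ambiguous &&
    n_countable >= thresholds$min_rounds &&
    isTRUE(success_rate > thresholds$success_threshold)
  tibble(n_rounds = n_countable,
         n_passing = nrow(passing),
         success_rate = success_rate,
         direction = direction,
         is_primary_hit = is_hit,
         ambiguous = ambiguous)
}

#' Call primary hits for a whole screen
#'
#' Chains [summarize_rounds()] and [call_primary_hit()] over all genes in a
#' per-cell measurement table and attaches the mean relative force across
#' countable rounds. The result is a `screen_hits` object with [tidy()],
#' [glance()] and [autoplot()] methods. An optional Benjamini-Hochberg
#' adjusted p-value column (`p_bh`, per round, across genes) is appended to
#' the round summaries for transparency; it plays no part in the calls, which
#' reproduce the screen's uncorrected procedure.
#'
#' @inheritParams summarize_rounds
#' @return A `screen_hits` object: a tibble with one row per gene
#'   (`gene`, `mean_relative`, [call_primary_hit()] columns), with the
#'   per-round summary table in attribute `rounds` and the thresholds in
#'   attribute `thresholds`.
#' @export
call_hits <- function(cells, value = "F_eq_nN",
                      thresholds = screen_thresholds(),
                      effect_gate = thresholds$effect_gate_force,
                      variant = "student") {
  rounds <- summarize_rounds(cells, value = value, thresholds = thresholds,
                             effect_gate = effect_gate, variant = variant)
  rounds <- dplyr::mutate(dplyr::group_by(rounds, .data$round_id),
                          p_bh = p.adjust(.data$p_value, "BH"))
  rounds <- dplyr::ungroup(rounds)
  per_gene <- dplyr::group_by(rounds, .data$gene)
  hits <- dplyr::ungroup(dplyr::reframe(per_gene, {
    df <- dplyr::pick(dplyr::everything())
    res <- call_primary_hit(df, thresholds)
    countable <- df$n_treated >= thresholds$min_cells
    res$mean_relative <- mean(df$mean_relative[countable])
    dplyr::relocate(res, "mean_relative")
  }))
  structure(hits,
            rounds = rounds,
            thresholds = thresholds,
            class = c("screen_hits", class(hits)))
}

#' Secondary confirmation and phenotype classification
#'
#' A primary hit is confirmed as a mitotic cell mechanics gene when an
#' independent reagent reproduces a force reduction of strictly more than the
#' force gate under the same per-round significance and success-rate rules.
#' Confirmed genes are classified by which additional channels moved:
#' `pressure` when the relative pressure change is significant and exceeds
#' the 20% gate, `volume` when the relative volume change is significant and
#' exceeds the 10% gate, `both` when both do, `force_only` otherwise.
#'
#' @param force_rounds Per-round summaries for the secondary reagent's force
#'   readout ([round_test()] rows).
#' @param pressure_rounds,volume_rounds Optional per-round summaries for the
#'   pressure and volume readouts (tested with their own gates).
#' @param thresholds A [screen_thresholds()] list.
#' @return A one-row tibble: `is_mechanics_gene`, `phenotype_class`
#'   (`"pressure"`, `"volume"`, `"both"`, `"force_only"` or `"none"`),
#'   `force_success_rate`, `incomplete` (flag: some channels missing).
#' @export
call_secondary <- function(force_rounds, pressure_rounds = NULL,
                           volume_rounds = NULL,
                           thresholds = screen_thresholds()) {
  force_call <- call_primary_hit(force_rounds, thresholds)
  confirmed <- force_call$is_primary_hit &&
    identical(force_call$direction, "down")
  channel_hit <- function(rounds) {
    if (is.null(rounds)) return(NA)
    call_primary_hit(rounds, thresholds)$is_primary_hit
  }
  p_hit <- channel_hit(pressure_rounds)
  v_hit <- channel_hit(volume_rounds)
  incomplete <- is.na(p_hit) || is.na(v_hit)
  class_ <- if (!confirmed) {
    "none"
  } else if (isTRUE(p_hit) && isTRUE(v_hit)) {
    "both"
  } else if (isTRUE(p_hit)) {
    "pressure"
  } else if (isTRUE(v_hit)) {
    "volume"
  } else {
    "force_only"
  }
  tibble(is_mechanics_gene = confirmed,
         phenotype_class = class_,
         force_success_rate = force_call$success_rate,
         incomplete = incomplete)
}

#' Mann-Whitney U test
#'
#' Two-sided nonparametric comparison used for post-screen experiments. The
#' exact null distribution of U is enumerated (by the standard
#' count-of-rank-sums recursion) when the combined sample size is at most 20
#' and there are no ties; otherwise a tie-corrected normal approximation with
#' continuity correction is used. `mode` forces one or the other.
#'
#' @param a,b Numeric vectors.
#' @param mode `"auto"` (default), `"exact"` or `"normal_approx"`.
#' @return A one-row tibble: `U`, `p_value`, `method`.
#' @examples
#' mannwhitney_u(c(1, 2, 3), c(4, 5, 6))   # exact p = 0.1
#' @export
mannwhitney_u <- function(a, b, mode = c("auto", "exact", "normal_approx")) {
  mode <- match.arg(mode)
  if (length(a) < 1L || length(b) < 1L) {
    abort("both groups must be non-empty.", class = "mitomech_invalid_input")
  }
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  ties <- any(duplicated(c(a, b)))
  U1 <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- min(U1, U2)
  if (mode == "exact" && ties) {
    abort("exact mode is not available with ties.",
          class = "mitomech_invalid_input")
  }
  use_exact <- mode == "exact" ||
    (mode == "auto" && (n1 + n2) <= 20 && !ties)
  if (use_exact) {
    # exact null distribution of U1 via the count recursion
    cnt <- u_count_table(n1, n2)
    total <- sum(cnt)
    p <- 2 * sum(cnt[seq_len(U + 1L)]) / total
    p <- min(p, 1)
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(r)
    tie_term <- sum(tie_tab^3 - tie_tab) / ((n1 + n2) * (n1 + n2 - 1))
    sigma2 <- n1 * n2 / 12 * ((n1 + n2 + 1) - tie_term)
    if (sigma2 <= 0) {
      return(tibble(U = U, p_value = 1, method = "normal_approx"))
    }
    z <- (U - mu + 0.5) / sqrt(sigma2)   # continuity-corrected, U = min side
    p <- min(2 * pnorm(z), 1)
    method <- "normal_approx"
  }
  tibble(U = U, p_value = p, method = method)
}

# Exact null counts of the U statistic for group sizes n1, n2 (no ties),
# via the recursion f(u; i, j) = f(u - j; i - 1, j) + f(u; i, j - 1).
u_count_table <- function(n1, n2) {
  umax <- n1 * n2
  g <- replicate(n2 + 1L, c(1, numeric(umax)), simplify = FALSE)  # i = 0
  for (i in seq_len(n1)) {
    gnew <- vector("list", n2 + 1L)
    gnew[[1L]] <- c(1, numeric(umax))                             # j = 0
    for (j in seq_len(n2)) {
      shifted <- c(numeric(j), head(g[[j + 1L]], umax + 1L - j))
      gnew[[j + 1L]] <- shifted + gnew[[j]]
    }
    g <- gnew
  }
  g[[n2 + 1L]]
}
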