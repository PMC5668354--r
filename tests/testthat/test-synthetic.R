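wedged <- cantilever_spec(k = 0.3, wedged = TRUE)

test_that("noiseless simulate-then-analyze returns the generating truth", {
  cell <- simulate_confined_cell(true_cell_params(), duration_s = 240, seed = 1)
  eq <- extract_equilibrium_force(cell$trace, rel_slope_tol = 1e-9)
  mech <- compute_mechanics(
    tibble::tibble(F_eq_N = eq$F_eq_N, A_m_um2 = cell$truth$A_m_um2,
                   h_set_um = 10),
    wedged)
  expect_equal(mech$P_Pa, 150, tolerance = 1e-6)
  expect_equal(mech$V_um3, 2500, tolerance = 1e-6)
})

test_that("the forward model is self-consistent and respects geometry bounds", {
  for (P in c(50, 150, 400)) {
    for (V in c(1500, 2500, 4000)) {
      cell <- simulate_confined_cell(true_cell_params(P_true = P, V_true = V),
                                     h_set = 10, seed = 1)
      tr <- cell$truth
      expect_gte(tr$r_m_um, tr$h_um / 2)
      # prescribed pressure: F_eq over the contact area
      expect_equal(tr$F_eq_N / (tr$A_c_um2 * 1e-12), P, tolerance = 1e-9)
      # prescribed volume at the realized height
      expect_equal(cell_volume(tr$r_m_um, tr$h_um), V, tolerance = 1e-9)
      # deflection feedback: realized height exceeds the set height
      expect_gt(tr$h_um, 10)
    }
  }
  expect_error(
    simulate_confined_cell(true_cell_params(V_true = 300), h_set = 10),
    class = "mitomech_height_unreachable")
  expect_error(
    simulate_confined_cell(true_cell_params(noise_cv = 0.05)),
    class = "mitomech_config_error")   # stochastic run needs a seed
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_confined_cell(true_cell_params(noise_cv = 0.05), seed = 33)
  b <- simulate_confined_cell(true_cell_params(noise_cv = 0.05), seed = 33)
  expect_identical(a$trace$F_N, b$trace$F_N)
  c_ <- simulate_confined_cell(true_cell_params(noise_cv = 0.05), seed = 34)
  expect_false(identical(a$trace$F_N, c_$trace$F_N))
  s1 <- simulate_screen(screen_design(n_genes = 4, seed = 5))
  s2 <- simulate_screen(screen_design(n_genes = 4, seed = 5))
  expect_identical(s1$cells, s2$cells)
})

test_that("trans-mitotic recordings reproduce the scheduled plateau and timing", {
  tm <- simulate_transmitotic()
  # noiseless plateau equals the scheduled metaphase pressure
  expect_equal(plateau_pressure(tm$trace, tm$geometry), 150, tolerance = 1e-9)
  d <- phase_durations(tm$trace)
  expect_equal(d$nebd_to_plate_min, 12)
  expect_equal(d$plate_to_anaphase_min, 18)
  # with 5% force noise the plateau mean stays within 3%
  errs <- sapply(1:20, function(s) {
    tmn <- simulate_transmitotic(noise_cv = 0.05, seed = s)
    plateau_pressure(tmn$trace, tmn$geometry) / 150 - 1
  })
  expect_lt(median(abs(errs)), 0.03)
  expect_error(simulate_transmitotic(nebd_to_plate_s = -5),
               class = "mitomech_invalid_input")
})

test_that("null screens stay quiet and strong effects are detected", {
  null_scr <- simulate_screen(screen_design(n_genes = 40,
                                            include_positive_control = FALSE,
                                            seed = 8))
  norm <- normalize_to_control(null_scr$cells)
  rel_means <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(norm, condition == "treated"), gene),
    m = mean(rel_F))
  # per-round control means are drawn from 12 cells at CV 20%, so relative
  # means share that sampling noise across genes: bound at ~2.5 sigma
  expect_equal(mean(rel_means$m), 1, tolerance = 0.1)
  expect_equal(sum(tidy(call_hits(null_scr$cells))$is_primary_hit), 0)

  # an effect-0.5 gene is called in (nearly) every replicate screen
  calls <- sapply(1:40, function(s) {
    scr <- simulate_screen(screen_design(
      n_genes = 1,
      effects = tibble::tibble(gene = "gene0001", effect_force = 0.5),
      include_positive_control = FALSE, seed = 1000 + s))
    td <- tidy(call_hits(scr$cells))
    td$is_primary_hit[td$gene == "gene0001"]
  })
  expect_gt(mean(calls), 0.95)
})

test_that("hit calls are invariant to per-round rescaling (day effects)", {
  scr <- simulate_screen(screen_design(
    n_genes = 10,
    effects = tibble::tibble(gene = "gene0002", effect_force = 0.4),
    seed = 13))
  scale_by_round <- dplyr::mutate(
    scr$cells,
    F_eq_nN = F_eq_nN * ifelse(round_id == "round01", 3.7, 0.4))
  expect_equal(tidy(call_hits(scale_by_round)),
               tidy(call_hits(scr$cells)))
})

test_that("screen designs validate their inputs", {
  expect_error(screen_design(n_genes = 5), class = "mitomech_config_error")
  expect_error(
    screen_design(n_genes = 5, seed = 1,
                  effects = tibble::tibble(gene = "gene0001",
                                           effect_force = -1)),
    class = "mitomech_config_error")
  d <- screen_design(n_genes = 5, seed = 1)
  expect_true("MYH9" %in% d$effects$gene)
  expect_equal(d$effects$effect_force[d$effects$gene == "MYH9"], 0.2)
})
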