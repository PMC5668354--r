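spec_v <- cantilever_spec(k = 0.3, deflection_sensitivity = 5e-8)

test_that("voltage converts to force through the optical-lever calibration", {
  t <- 0:9
  tr0 <- force_trace(t, Vd_V = rep(0, 10), spec = spec_v)
  expect_equal(deflection_to_force(tr0)$F_N, rep(0, 10))
  tr2 <- force_trace(t, Vd_V = rep(2, 10), spec = spec_v)
  expect_equal(deflection_to_force(tr2)$F_N, rep(30e-9, 10))
  # linearity
  v <- sin(t / 3)
  expect_equal(deflection_to_force(3 * v, spec_v),
               3 * deflection_to_force(v, spec_v))
  tr_nospec <- force_trace(t, Vd_V = v, spec = cantilever_spec(k = 0.3))
  expect_error(deflection_to_force(tr_nospec), class = "mitomech_config_error")
})

test_that("linear drift correction inverts a constructed drift", {
  t <- seq(0, 100, 0.5)
  base <- force_trace(t, F_N = rep(8e-8, length(t)))
  # zero rates: identity
  same <- correct_linear_drift(base, drift_estimate())
  expect_equal(same$F_N, base$F_N)
  # constructed inverse: F0 + 0.1 nN/s * t corrected at exactly that rate
  drifted <- force_trace(t, F_N = 8e-8 + 0.1e-9 * t)
  fixed <- correct_linear_drift(drifted, drift_estimate(0.1e-9))
  expect_equal(fixed$F_N, rep(8e-8, length(t)), tolerance = 1e-12)
  # simulator trace with injected drift and noise: residual trend is small
  cell <- simulate_confined_cell(
    true_cell_params(noise_cv = 0.02, drift_rate = 0.05e-9),
    duration_s = 120, seed = 11)
  corrected <- correct_linear_drift(cell$trace, drift_estimate(0.05e-9))
  tail_idx <- corrected$t_s >= 60   # past the relaxation transient
  slope <- coef(lm(corrected$F_N[tail_idx] ~ corrected$t_s[tail_idx]))[[2]]
  expect_lt(abs(slope), 0.005e-9)
})

test_that("drift rate is recovered from a trailing glass-probe segment", {
  t <- seq(0, 120, 0.5)
  rate <- 0.08e-9
  f <- 6e-8 + rate * t
  f[t >= 100] <- rate * t[t >= 100]   # lever on bare glass: only drift left
  est <- estimate_drift_from_probe(force_trace(t, F_N = f), probe_start = 100)
  expect_equal(est$force_offset_rate, rate, tolerance = 1e-9)
})

test_that("equilibrium extraction finds the plateau and flags ramps", {
  t <- seq(0, 60, 0.1)
  flat <- force_trace(t, F_N = rep(80e-9, length(t)))
  eq <- extract_equilibrium_force(flat)
  expect_true(eq$equilibrated)
  expect_equal(eq$F_eq_N, 80e-9)
  # exponential relaxation: asymptote 100 nN recovered within 1%
  expo <- force_trace(t, F_N = 100e-9 * (1 - exp(-t / 5)))
  eq2 <- extract_equilibrium_force(expo)
  expect_true(eq2$equilibrated)
  expect_equal(eq2$F_eq_N, 100e-9, tolerance = 0.01)
  # a pure ramp never plateaus
  ramp <- force_trace(t, F_N = 1e-9 * t)
  eq3 <- extract_equilibrium_force(ramp, slope_tol = 0.01e-9)
  expect_false(eq3$equilibrated)
  # invariance to shifting the time origin
  eq4 <- extract_equilibrium_force(force_trace(t + 1000, F_N = expo$F_N))
  expect_equal(eq4$F_eq_N, eq2$F_eq_N)
  expect_error(extract_equilibrium_force(force_trace(0:5, F_N = rep(1e-9, 6)),
                                         window_s = 10),
               class = "mitomech_invalid_input")
})

test_that("plateau pressure averages frames between the annotated events", {
  t <- seq(0, 100, 1)
  ann <- c(metaphase_plate = 40, anaphase_onset = 80)
  tr <- force_trace(t, F_N = rep(30e-9, length(t)), annotations = ann)
  geom <- tibble::tibble(t_s = c(50, 60), A_c_um2 = c(100, 100))
  expect_equal(plateau_pressure(tr, geom), 30e-9 / 100e-12)
  # single frame in phase
  expect_equal(plateau_pressure(tr, geom[1, ]), 30e-9 / 100e-12)
  # no frames inside the phase
  expect_error(plateau_pressure(tr, tibble::tibble(t_s = 90, A_c_um2 = 100)),
               class = "mitomech_annotation_error")
  no_ann <- force_trace(t, F_N = rep(30e-9, length(t)))
  expect_error(plateau_pressure(no_ann, geom),
               class = "mitomech_annotation_error")
})

test_that("phase durations are the event differences in minutes", {
  d <- phase_durations(c(NEBD = 0, metaphase_plate = 720,
                         anaphase_onset = 1800))
  expect_equal(d$nebd_to_plate_min, 12)
  expect_equal(d$plate_to_anaphase_min, 18)
  expect_error(phase_durations(c(NEBD = 720, metaphase_plate = 0,
                                 anaphase_onset = 1800)),
               class = "mitomech_annotation_error")
  expect_error(phase_durations(c(NEBD = 0, metaphase_plate = 720)),
               class = "mitomech_annotation_error")
})

test_that("force traces and annotations round-trip through disk", {
  dir <- withr::local_tempdir()
  t <- seq(0, 30, 0.1)
  tr <- force_trace(t, F_N = 5e-8 * (1 - exp(-t / 6)), spec = spec_v)
  path <- file.path(dir, "trace.tsv")
  write_force_trace(tr, path, h_set_um = 14)
  back <- read_force_trace(path)
  expect_equal(back$t_s, tr$t_s)
  expect_equal(back$F_N, tr$F_N, tolerance = 1e-10)
  expect_equal(attr(back, "spec")$k, 0.3)
  expect_equal(attr(back, "spec")$deflection_sensitivity, 5e-8)
  expect_equal(attr(back, "h_set_um"), 14)

  ann <- tibble::tibble(cell_id = c("c1", "c1", "c1"),
                        event = c("NEBD", "metaphase_plate", "anaphase_onset"),
                        t_s = c(0, 700, 1700))
  apath <- file.path(dir, "ann.csv")
  write_annotations(ann, apath)
  back_ann <- annotations_for_cell(read_annotations(apath), "c1")
  expect_equal(back_ann[["metaphase_plate"]], 700)
})
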