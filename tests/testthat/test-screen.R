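make_cells <- function(...) tibble::tibble(...)

test_that("normalization divides by same-round control means", {
  cells <- make_cells(
    gene = c(rep("F-Luc", 3), rep("geneA", 3)),
    condition = c(rep("control", 3), rep("treated", 3)),
    round_id = "r1",
    F_eq_nN = c(90, 100, 110, 70, 80, 90)
  )
  out <- normalize_to_control(cells)
  expect_equal(mean(out$rel_F[out$condition == "treated"]), 0.8)
  expect_equal(mean(out$rel_F[out$condition == "control"]), 1)
  # proportional rounds give identical relative values
  two <- dplyr::bind_rows(cells,
                          dplyr::mutate(cells, round_id = "r2",
                                        F_eq_nN = F_eq_nN / 2))
  out2 <- normalize_to_control(two)
  by_round <- split(out2$rel_F, out2$round_id)
  expect_equal(by_round$r1, by_round$r2)
  # a round without controls is an error
  broken <- dplyr::mutate(cells, condition = "treated")
  expect_error(normalize_to_control(broken),
               class = "mitomech_normalization_error")
})

test_that("per-round test combines significance with the strict effect gate", {
  same <- round_test(c(10, 12, 14), c(10, 12, 14))
  expect_equal(same$p_value, 1)
  expect_false(same$passes)
  # exactly -20% change: the strict gate excludes the boundary
  ctrl <- c(95, 100, 105, 98, 102, 100, 97, 103, 99, 101, 100, 100)
  boundary <- round_test(0.8 * ctrl, ctrl)
  expect_equal(boundary$mean_relative, 0.8)
  expect_lt(boundary$p_value, 0.05)
  expect_false(boundary$passes)
  # clear knockdown phenotype, checked against a longhand Student t oracle
  treated <- rep(c(5, 6, 7), 4)
  control <- rep(c(10, 11, 12), 4)
  res <- round_test(treated, control)
  expect_lt(res$p_value, 1e-6)
  expect_equal(res$p_value, oracle_student_t_p(treated, control))
  expect_equal(res$mean_relative, 6 / 11, tolerance = 1e-12)
  expect_true(res$passes)
  expect_equal(res$direction, "down")
  expect_error(round_test(5, c(1, 2, 3)), class = "mitomech_invalid_input")
})

test_that("primary hit calls demand repeated same-direction success", {
  row <- function(n, passes, dir) {
    tibble::tibble(n_treated = n, passes = passes, direction = dir,
                   mean_relative = ifelse(dir == "down", 0.7, 1.3),
                   p_value = 0.01)
  }
  both <- dplyr::bind_rows(row(12, TRUE, "down"), row(12, TRUE, "down"))
  hit <- call_primary_hit(both)
  expect_true(hit$is_primary_hit)
  expect_equal(hit$success_rate, 1)
  # 1 of 2: success rate exactly 50% is not strictly above the threshold
  half <- dplyr::bind_rows(row(12, TRUE, "down"), row(12, FALSE, "down"))
  expect_false(call_primary_hit(half)$is_primary_hit)
  expect_equal(call_primary_hit(half)$success_rate, 0.5)
  # under-powered rounds are not countable
  thin <- dplyr::bind_rows(row(8, TRUE, "down"), row(12, TRUE, "down"))
  expect_false(call_primary_hit(thin)$is_primary_hit)   # only 1 countable round
  # opposite directions in equal numbers: ambiguous, not a hit
  flip <- dplyr::bind_rows(row(12, TRUE, "down"), row(12, TRUE, "up"))
  amb <- call_primary_hit(flip)
  expect_false(amb$is_primary_hit)
  expect_true(amb$ambiguous)
})

test_that("secondary confirmation classifies pressure and volume phenotypes", {
  row <- function(rel, passes, n = 12) {
    tibble::tibble(n_treated = n, passes = passes,
                   direction = ifelse(rel < 1, "down", "up"),
                   mean_relative = rel, p_value = ifelse(passes, 0.01, 0.5))
  }
  force_ok <- dplyr::bind_rows(row(0.7, TRUE), row(0.7, TRUE))
  sig <- function(rel) dplyr::bind_rows(row(rel, TRUE), row(rel, TRUE))
  ns <- function(rel) dplyr::bind_rows(row(rel, FALSE), row(rel, FALSE))
  # pressure down 25%, volume down 5%: pressure phenotype
  res <- call_secondary(force_ok, pressure_rounds = sig(0.75),
                        volume_rounds = ns(0.95))
  expect_true(res$is_mechanics_gene)
  expect_equal(res$phenotype_class, "pressure")
  # both gates crossed
  res2 <- call_secondary(force_ok, pressure_rounds = sig(0.75),
                         volume_rounds = sig(0.88))
  expect_equal(res2$phenotype_class, "both")
  # only the force gate crossed
  res3 <- call_secondary(force_ok, pressure_rounds = ns(0.9),
                         volume_rounds = ns(0.95))
  expect_equal(res3$phenotype_class, "force_only")
  # an unconfirmed gene is classified none
  res4 <- call_secondary(ns(0.9), pressure_rounds = sig(0.75),
                         volume_rounds = sig(0.88))
  expect_false(res4$is_mechanics_gene)
  expect_equal(res4$phenotype_class, "none")
  # missing channels flag the decision incomplete
  res5 <- call_secondary(force_ok)
  expect_true(res5$incomplete)
  expect_equal(res5$phenotype_class, "force_only")
})

test_that("Mann-Whitney agrees with enumeration and with wilcox.test", {
  res <- mannwhitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_equal(res$p_value, oracle_mwu_p(c(1, 2, 3), c(4, 5, 6)))
  # identical multisets (ties force the normal approximation)
  same <- mannwhitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$p_value, 1, tolerance = 1e-9)
  # random tie-free samples: exact equals wilcox.test's exact p
  set.seed(9)
  for (i in 1:5) {
    a <- rnorm(8); b <- rnorm(7) + 0.5
    expect_equal(mannwhitney_u(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value)
    expect_equal(mannwhitney_u(a, b)$p_value, oracle_mwu_p(a, b))
  }
  # exact and normal approximation agree closely at n = 10 vs 10
  set.seed(10)
  a <- rnorm(10); b <- rnorm(10) + 0.8
  expect_lt(abs(mannwhitney_u(a, b, "exact")$p_value -
                  mannwhitney_u(a, b, "normal_approx")$p_value), 0.02)
  expect_error(mannwhitney_u(numeric(0), 1:3),
               class = "mitomech_invalid_input")
})

test_that("call_hits ties the machinery together with tidy accessors", {
  scr <- simulate_screen(screen_design(
    n_genes = 6,
    effects = tibble::tibble(gene = "gene0001", effect_force = 0.5),
    seed = 21))
  hits <- call_hits(scr$cells)
  td <- tidy(hits)
  expect_true(td$is_primary_hit[td$gene == "gene0001"])
  expect_true(td$is_primary_hit[td$gene == "MYH9"])
  expect_false(any(td$is_primary_hit[!td$gene %in% c("gene0001", "MYH9")]))
  rounds <- tidy(hits, per_round = TRUE)
  expect_true(all(c("p_value", "p_bh", "mean_relative") %in% names(rounds)))
  g <- glance(hits)
  expect_equal(g$n_hits, 2)
  expect_equal(g$n_down, 2)
  # hit calls are invariant to row shuffling
  set.seed(1)
  shuffled <- scr$cells[sample(nrow(scr$cells)), ]
  expect_equal(tidy(call_hits(shuffled))[order(td$gene), ],
               td[order(td$gene), ])
  # plot method returns a ggplot without error
  expect_s3_class(autoplot(hits), "ggplot")
})
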