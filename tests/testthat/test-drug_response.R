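toy_surface <- function(surv, afa = c(0, 1e-9), osi = c(0, 1e-8),
                        id = "toy") {
  dimnames(surv) <- list(as.character(afa), as.character(osi))
  structure(list(variant_id = id, survival = surv,
                 inhibition = 1 - pmin(surv, 1), afatinib = afa,
                 osimertinib = osi,
                 missing_cells = matrix(integer(), 0, 2)),
            class = "response_surface")
}

test_that("the default grid spans the tested ranges with 72 combinations", {
  g <- dose_grid()
  expect_equal(g$n_combinations, 72)
  expect_equal(range(g$afatinib), c(500e-12, 50e-9))
  expect_equal(range(g$osimertinib), c(100e-12, 10e-6))
  expect_error(dose_grid(afatinib = c(2e-9, 1e-9)), "strictly")
  expect_error(dose_grid(afatinib = c(-1, 1)), "afatinib > 0")
  # conditions table covers (n_a + 1)(n_o + 1) cells incl. vehicle
  expect_equal(nrow(grid_conditions(g)), 9 * 10)
})

test_that("surfaces place inhibition values on the grid and flag gaps", {
  g <- dose_grid(afatinib = c(1e-9, 1e-8), osimertinib = c(1e-8, 1e-7))
  conds <- grid_conditions(g)
  vals <- matrix(1, 1, nrow(conds),
                 dimnames = list("V1", conds$condition))
  gi <- structure(list(values = vals), class = "growth_inhibition")
  surf <- build_surface(gi, g, "V1")
  expect_true(all(surf$survival == 1))
  expect_equal(nrow(surf$missing_cells), 0)
  expect_error(build_surface(gi, g, "nope"), "absent")
  # drop one condition -> that cell is NA and flagged, not imputed
  gi2 <- structure(list(values = vals[, -2, drop = FALSE]),
                   class = "growth_inhibition")
  surf2 <- build_surface(gi2, g, "V1")
  expect_equal(sum(is.na(surf2$survival)), 1)
  expect_equal(nrow(surf2$missing_cells), 1)
})

test_that("sensitivity calls follow the survival thresholds monotonically", {
  surv <- matrix(1, 2, 2)
  expect_equal(as.character(
    classify_sensitivity(toy_surface(surv), "afatinib")$category),
    "resistant")
  surv0 <- surv; surv0[2, 1] <- 0
  expect_equal(as.character(
    classify_sensitivity(toy_surface(surv0), "afatinib")$category),
    "sensitive")
  survp <- surv; survp[2, 1] <- 0.35
  expect_equal(as.character(
    classify_sensitivity(toy_surface(survp), "afatinib")$category),
    "partially_resistant")
  # boundary values land on the non-sensitive side (monotone thresholds)
  for (s in c(0, 0.1999, 0.2, 0.49, 0.5, 0.9, 1.5)) {
    survb <- surv; survb[2, 1] <- s
    cat_s <- classify_sensitivity(toy_surface(survb), "afatinib")$category
    expected <- if (s < 0.2) "sensitive" else if (s < 0.5)
      "partially_resistant" else "resistant"
    expect_equal(as.character(cat_s), expected)
  }
  # raising survival never moves a call toward sensitive
  grid_s <- seq(0, 1.2, by = 0.05)
  ranks <- vapply(grid_s, function(s) {
    survb <- surv; survb[2, 1] <- s
    as.integer(classify_sensitivity(toy_surface(survb), "afatinib")$category)
  }, integer(1))
  expect_true(all(diff(ranks) >= 0))
  # missing reference-dose cell -> undetermined
  survna <- surv; survna[2, 1] <- NA
  expect_equal(as.character(
    classify_sensitivity(toy_surface(survna), "afatinib")$category),
    "undetermined")
})

test_that("cross-resistance summary reproduces the screen composition", {
  calls <- simulate_call_table()
  s <- cross_resistance_summary(calls)
  expect_equal(s$n, 282)
  expect_equal(s$any_nonsensitive_n, 50)
  expect_equal(s$any_nonsensitive_pct, 17.7)
  expect_equal(s$afatinib_nonsensitive_n, 25)
  expect_equal(s$afatinib_nonsensitive_osimertinib_sensitive_n, 4)
  expect_equal(s$afatinib_nonsensitive_osimertinib_sensitive_pct, 16)
  expect_equal(s$osimertinib_nonsensitive_n, 46)
  expect_equal(s$osimertinib_nonsensitive_afatinib_sensitive_n, 25)
  expect_equal(s$osimertinib_nonsensitive_afatinib_sensitive_pct, 54.3)
  expect_equal(s$both_resistant_n, 3)
  expect_equal(s$both_resistant_pct, 1.1)
  expect_equal(s$both_nonsensitive_n, 21)
  expect_equal(s$both_nonsensitive_pct, 7.4)
})

test_that("cross-resistance counts are conserved and undetermined excluded", {
  calls <- simulate_call_table(n = 40, n_both_resistant = 2,
                               n_both_partial = 3, n_afa_only = 4,
                               n_osi_only = 5)
  calls$afatinib[1:3] <- "undetermined"
  s <- cross_resistance_summary(calls)
  expect_equal(s$n + s$n_undetermined, 40)
  expect_equal(sum(s$table), s$n)
  # cells partition the determined variants
  both_sensitive <- s$n - s$any_nonsensitive_n
  expect_equal(both_sensitive + s$both_nonsensitive_n +
                 s$afatinib_nonsensitive_osimertinib_sensitive_n +
                 s$osimertinib_nonsensitive_afatinib_sensitive_n, s$n)
  # empty input
  expect_equal(cross_resistance_summary(
    simulate_call_table(n = 0, 0, 0, 0, 0))$n, 0)
})

test_that("Bliss identities hold on constructed surfaces", {
  # E_a = 0.5, E_o = 0.4, observed combined inhibition 0.70 -> score 0
  surv <- matrix(c(1, 0.5, 0.6, 0.30), 2, 2)
  syn <- bliss_synergy(toy_surface(surv))
  expect_equal(unname(syn$scores[1, 1]), 0)
  expect_equal(syn$mean_score, 0)
  # inactive drug A: expected equals E_o, score measures pure deviation
  surv2 <- matrix(c(1, 1, 0.6, 0.5), 2, 2)
  syn2 <- bliss_synergy(toy_surface(surv2))
  expect_equal(unname(syn2$expected[1, 1]), 0.4)
  expect_equal(unname(syn2$scores[1, 1]), 100 * (0.5 - 0.4))
  # survival above 1 (growth stimulation) is clipped with a warning
  surv3 <- matrix(c(1, 1.4, 0.6, 0.62), 2, 2)
  expect_warning(syn3 <- bliss_synergy(toy_surface(surv3)), "clipped")
  expect_equal(unname(syn3$expected[1, 1]), 0.4)
})

test_that("per-cell scores match a brute-force oracle on random surfaces", {
  surfs <- simulate_bliss_surfaces(50, epsilon = 0.15, noise_sd = 0.05,
                                   seed = 99)
  for (s in surfs[seq(1, 50, by = 7)]) {
    got <- suppressWarnings(bliss_synergy(s))
    expect_lt(max(abs(got$scores - oracle_bliss(s))), 1e-12)
  }
  # multiplicative-survival surfaces score identically zero
  null_surfs <- simulate_bliss_surfaces(20, epsilon = 0, seed = 100)
  max_dev <- max(vapply(null_surfs, function(s)
    max(abs(bliss_synergy(s)$scores)), numeric(1)))
  expect_lt(max_dev, 1e-12)
})

test_that("an injected synergy deviation shifts Bliss scores positive", {
  null_mean <- mean(vapply(simulate_bliss_surfaces(30, epsilon = 0,
                                                   noise_sd = 0.02, seed = 5),
                           function(s)
                             suppressWarnings(bliss_synergy(s))$mean_score,
                           numeric(1)))
  syn_mean <- mean(vapply(simulate_bliss_surfaces(30, epsilon = 0.3,
                                                  noise_sd = 0.02, seed = 5),
                          function(s)
                            suppressWarnings(bliss_synergy(s))$mean_score,
                          numeric(1)))
  expect_lt(abs(null_mean), 2)
  expect_gt(syn_mean, null_mean + 2)
})

test_that("4PL fitting recovers exact curves and the midpoint identity", {
  d <- exp(seq(log(1e-10), log(1e-6), length.out = 8))
  y <- 0 + (1 - 0) / (1 + (d / 1e-8)^1)
  f <- fit_4pl(d, y)
  expect_true(f$converged)
  expect_lt(abs(f$ic50 - 1e-8) / 1e-8, 1e-3)
  expect_equal(f$hill, 1, tolerance = 1e-4)
  # response at dose = ic50 is (top + bottom) / 2
  expect_equal(predict(f, f$ic50), 0.5, tolerance = 1e-6)
  expect_true(f$in_range)
  # steep curve with offset asymptotes
  y2 <- 0.1 + (0.9 - 0.1) / (1 + (d / 5e-9)^2.5)
  f2 <- fit_4pl(d, y2)
  expect_lt(abs(f2$ic50 - 5e-9) / 5e-9, 1e-3)
  expect_equal(f2$bottom, 0.1, tolerance = 1e-3)
  expect_error(fit_4pl(d[1:3], y[1:3]), "unique")
})

test_that("noisy 4PL fits keep the median IC50 error under 5%", {
  set.seed(77)
  d <- exp(seq(log(1e-10), log(1e-6), length.out = 8))
  errs <- replicate(40, {
    ic50 <- 10^runif(1, -9, -7.5)
    y <- 1 / (1 + (d / ic50)^runif(1, 0.8, 2)) + rnorm(8, 0, 0.01)
    f <- fit_4pl(d, y)
    abs(f$ic50 - ic50) / ic50
  })
  expect_lt(median(errs), 0.05)
})
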