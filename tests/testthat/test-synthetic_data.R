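test_that("Hill inhibition obeys its limits and the midpoint identity", {
  # c = ic50, imax = 1: survival factor exactly 0.5 for any slope
  for (h in c(0.5, 1, 2, 4)) {
    expect_equal(1 - hill_inhibition(3e-9, 3e-9, h), 0.5)
  }
  expect_equal(hill_inhibition(0, 1e-9, 1), 0)
  expect_equal(hill_inhibition(1e-3, 1e-9, 1, imax = 0.8), 0.8,
               tolerance = 1e-5)
  # vectorises over clones (ic50 vector, scalar dose)
  expect_equal(hill_inhibition(1e-9, c(1e-9, 1e-6), 1),
               c(0.5, 1 / (1 + 1e3)))
  expect_error(hill_inhibition(1, -1, 1), "ic50")
})

test_that("panels are deterministic, unique-barcoded, and archetype-faithful", {
  p1 <- make_panel(n_variants = 10, seed = 42)
  p2 <- make_panel(n_variants = 10, seed = 42)
  expect_identical(p1, p2)
  expect_false(identical(p1, make_panel(n_variants = 10, seed = 43)))
  expect_false(anyDuplicated(p1$barcode) > 0)
  expect_true(all(nchar(p1$barcode) == 10))
  expect_true(all(c("KRAS_G12V", "GFP") %in% p1$variant_id))
  expect_equal(sum(!duplicated(p1$variant_id)), 12)  # 10 + 2 references
  # degenerate mix: everything sensitive to both
  p3 <- make_panel(n_variants = 6, archetype_mix = c(sensitive_both = 1),
                   include_references = FALSE, seed = 1)
  expect_true(all(p3$archetype == "sensitive_both"))
  expect_lt(max(p3$afa_ic50), 50e-9)  # inside the tested range
})

test_that("screens are seed-reproducible and equal-rate pools stay uniform", {
  p <- make_panel(n_variants = 5, seed = 2)
  s1 <- simulate_screen(p, depth = 1e4, replicates = 1, seed = 7)
  s2 <- simulate_screen(p, depth = 1e4, replicates = 1, seed = 7)
  expect_identical(s1$counts, s2$counts)
  # all concentrations zero + equal growth rates -> uniform expected pool
  p_eq <- p
  p_eq$growth_rate <- 0.6
  sim <- simulate_screen(p_eq, depth = 1e6, replicates = 1, seed = 8)
  veh <- sim$samples$sample_id[sim$samples$afatinib == 0 &
                                 sim$samples$osimertinib == 0]
  frac <- sim$counts[, veh] / 1e6
  expect_lt(max(abs(frac - 1 / nrow(p_eq))), 5 * sqrt(0.047 * 0.953 / 1e6))
  # read totals match the requested depth
  expect_true(all(colSums(sim$counts) == 1e6))
})

test_that("recovered inhibition converges to the closed-form growth model", {
  p <- make_panel(n_variants = 4, seed = 11)
  sim <- simulate_screen(p, depth = 1e6, seed = 12)
  gi <- run_screen_pipeline(sim)
  truth <- sim$truth$relative_survival
  # compare on a mid-grid monotherapy column for all panel variants
  cond <- sim$samples$condition[sim$samples$afatinib == 0 &
                                  sim$samples$osimertinib ==
                                  sim$grid$osimertinib[5]][1]
  rel_err <- abs(gi$values[rownames(truth), cond] - truth[, cond]) /
    truth[, cond]
  expect_lt(max(rel_err), 0.01)
})

test_that("overdispersion widens replicate scatter without moving the mean", {
  p <- make_panel(n_variants = 6, seed = 3)
  tight <- simulate_screen(p, depth = 1e5, replicates = 3,
                           overdispersion = Inf, seed = 4)
  loose <- simulate_screen(p, depth = 1e5, replicates = 3,
                           overdispersion = 200, seed = 4)
  cv_of <- function(sim) {
    gi <- run_screen_pipeline(sim)
    mean(gi$replicate_cv, na.rm = TRUE)
  }
  expect_gt(cv_of(loose), 2 * cv_of(tight))
})

test_that("emitted FASTQ round-trips losslessly without errors", {
  set.seed(5)
  p <- make_panel(n_variants = 5, seed = 5)
  counts <- setNames(rep(c(10L, 25L, 3L), length.out = nrow(p)), p$barcode)
  r1 <- tempfile(fileext = ".fastq")
  r2 <- tempfile(fileext = ".fastq")
  n <- emit_fastq(counts, read_length = 150, error_rate = 0,
                  r1 = r1, r2 = r2, seed = 6)
  expect_equal(n, sum(counts))
  ct <- count_fastq(r1, r2, map = panel_map(p), sample_ids = "s1")
  expect_identical(ct$counts[names(counts), "s1"], counts)
  expect_equal(unname(ct$unassigned), 0)
  expect_equal(unname(ct$no_context), 0)
  # byte-identical regeneration under the same seed
  r1b <- tempfile(fileext = ".fastq")
  r2b <- tempfile(fileext = ".fastq")
  emit_fastq(counts, read_length = 150, error_rate = 0,
             r1 = r1b, r2 = r2b, seed = 6)
  expect_identical(readLines(r1), readLines(r1b))
  expect_identical(readLines(r2), readLines(r2b))
  expect_error(emit_fastq(counts, read_length = 20, r1 = r1), "read_length")
  unlink(c(r1, r2, r1b, r2b))
})

test_that("substitution errors cost at most ~1% of reads at 0.1% error rate", {
  set.seed(9)
  p <- make_panel(n_variants = 10, seed = 9)
  counts <- setNames(rep(100L, nrow(p)), p$barcode)
  r1 <- tempfile(fileext = ".fastq.gz")
  emit_fastq(counts, read_length = 100, error_rate = 0.001,
             r1 = r1, seed = 10)
  ct <- count_fastq(r1, map = panel_map(p),
                    context = barcode_context(max_flank_mismatches = 1),
                    sample_ids = "s1")
  recovered <- ct$counts[names(counts), "s1"]
  expect_true(all(recovered <= counts))
  # ~1% of reads carry a barcode substitution (1 - 0.999^10); allow 3 binomial
  # standard errors around that budget in aggregate and per barcode
  total_loss <- sum(counts - recovered) / sum(counts)
  expect_lt(total_loss, 0.01 + 3 * sqrt(0.01 * 0.99 / sum(counts)))
  unlink(r1)
})

test_that("regimen schedules are contiguous and expose the right drugs", {
  r <- regimen("AO")
  expect_equal(r$schedule$from[-1], head(r$schedule$to, -1)[])
  expect_equal(drugs_at_day(r, 3), character())
  expect_equal(drugs_at_day(r, 10), "afatinib")
  expect_equal(drugs_at_day(r, 20), "osimertinib")
  combo <- regimen("A+O")
  expect_setequal(drugs_at_day(combo, 10), c("afatinib", "osimertinib"))
  alt <- regimen("AO3")
  expect_equal(drugs_at_day(alt, 7), "afatinib")
  expect_equal(drugs_at_day(alt, 10), "osimertinib")
  expect_equal(max(alt$schedule$to), 30)
  expect_error(regimen("AO", switch_day = 40), "switch_day")
  expect_error(drugs_at_day(r, 31), "outside")
  # simulate_invivo refuses days beyond the schedule
  p <- make_panel(n_variants = 3, seed = 1)
  expect_error(simulate_invivo(p, r, kill_days = 40), "cover")
})

test_that("in vivo simulations are seed-reproducible with conserved reads", {
  p <- make_tumor_panel(n_variants = 8, seed = 13)
  s1 <- simulate_invivo(p, regimen("OA"), n_mice_per_kill_day = 2,
                        kill_days = 30, measure_days = c(15, 30),
                        depth = 5e4, seed = 14)
  s2 <- simulate_invivo(p, regimen("OA"), n_mice_per_kill_day = 2,
                        kill_days = 30, measure_days = c(15, 30),
                        depth = 5e4, seed = 14)
  expect_identical(s1$clone_counts, s2$clone_counts)
  expect_identical(s1$observations, s2$observations)
  expect_true(all(colSums(s1$clone_counts) == 5e4))
  # dual-resistant clones start below 0.5% of the pool
  dual <- s1$panel$archetype == "resistant_both"
  expect_lt(sum(s1$panel$init_mass[dual]) / sum(s1$panel$init_mass), 0.005)
})
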