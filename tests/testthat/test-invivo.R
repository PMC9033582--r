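test_that("tumor volume follows the ellipsoid formula", {
  # sphere limit: large = small = d gives pi/6 d^3
  expect_equal(tumor_volume(4, 4), pi / 6 * 64)
  expect_equal(tumor_volume(6, 5), 25 * pi)
  # doubling both diameters multiplies volume by 8
  expect_equal(tumor_volume(12, 10), 8 * tumor_volume(6, 5))
  # vectorised and exact
  L <- c(5, 7, 9.5); S <- c(3, 6.5, 9.5)
  expect_equal(tumor_volume(L, S), pi / 6 * L * S^2)
  # swapped diameters are corrected with a warning
  expect_warning(v <- tumor_volume(5, 6), "swapped")
  expect_equal(v, tumor_volume(6, 5))
  expect_error(tumor_volume(-1, 1), "large > 0")
})

test_that("variant proportions normalise per tumor and scale to GFP", {
  map <- barcode_map(c("AAAAAAAAAA", "CCCCCCCCCC", "GGGGGGGGGG"),
                     c("V1", "V2", "GFP"), c(1, 1, 1),
                     reference_ids = "GFP")
  cnt <- matrix(c(100, 100, 50), 3, 1,
                dimnames = list(map$barcode, "t1"))
  vp <- variant_proportions(cnt, map)
  expect_equal(unname(colSums(vp$proportions)), 1)
  expect_equal(vp$proportions["V1", 1], vp$proportions["V2", 1])
  expect_equal(unname(vp$scaled["V1", ]), 100.5 / 50.5)
  expect_equal(unname(vp$scaled["GFP", ]), 1)
})

test_that("RTV is the proportion x volume decomposition ratio", {
  props <- matrix(c(0.5, 0.3, 0.2), 3, 2,
                  dimnames = list(c("V1", "V2", "V3"), c("m1", "m2")))
  vols <- c(80, 120)
  # treated identical to vehicle -> rtv 1 everywhere
  rtv <- relative_tumor_volume(props, props, vols, vols)
  expect_equal(rtv$rtv, rep(1, 3))
  # eliminated variant -> rtv 0
  pt <- props; pt[1, ] <- 0; pt <- sweep(pt, 2, colSums(pt), "/")
  rtv2 <- relative_tumor_volume(pt, props, vols, vols)
  expect_equal(rtv2$rtv[rtv2$variant_id == "V1"], 0)
  # resistant clone: total volume halves, its proportion doubles -> rtv 1
  pt3 <- props; pt3[1, ] <- 1.0; pt3[2:3, ] <- 0.5 * props[2:3, ] * 2
  pt3 <- matrix(c(1, 0.3, 0.2) / 1.5, 3, 2, dimnames = dimnames(props))
  rtv3 <- relative_tumor_volume(pt3, props, vols * 1.5 / 2 / 1, vols)
  # proportion_v,treated * vol_treated = 0.5 * 0.75*vols: construct exactly:
  # treated arm: V1 mass unchanged (0.5*vols), others halved -> total 0.75
  expect_equal(rtv3$rtv[rtv3$variant_id == "V1"], 1)
  expect_equal(rtv3$rtv[rtv3$variant_id == "V2"], 0.5)
})

test_that("abundance-weighted mean RTV equals the total volume ratio", {
  set.seed(12)
  pt <- matrix(runif(8), 4, 2); pt <- sweep(pt, 2, colSums(pt), "/")
  pv <- matrix(runif(8), 4, 2); pv <- sweep(pv, 2, colSums(pv), "/")
  rownames(pt) <- rownames(pv) <- paste0("V", 1:4)
  vt <- c(40, 60); vv <- c(100, 140)
  rtv <- relative_tumor_volume(pt, pv, vt, vv)
  # sum of decomposed per-variant volumes reproduces each arm's mean total
  expect_equal(sum(rtv$treated_volume), mean(vt))
  expect_equal(sum(rtv$vehicle_volume), mean(vv))
  w <- rtv$vehicle_volume / sum(rtv$vehicle_volume)
  expect_equal(sum(w * rtv$rtv), mean(vt) / mean(vv))
})

test_that("concordance counts matching calls symmetrically", {
  a <- data.frame(variant_id = paste0("V", 1:4),
                  category = c("sensitive", "resistant", "sensitive",
                               "partially_resistant"))
  expect_equal(call_concordance(a, a)$pct, 100)
  b <- a; b$category <- c("resistant", "sensitive", "resistant",
                          "sensitive")
  expect_equal(call_concordance(a, b)$pct, 0)
  c2 <- a; c2$category[1] <- "resistant"
  expect_equal(call_concordance(a, c2)$pct, 75)
  # symmetric and order-invariant
  expect_equal(call_concordance(c2, a)$pct,
               call_concordance(a, c2[sample(4), ])$pct)
  expect_error(call_concordance(a, data.frame(variant_id = "X",
                                              category = "sensitive")),
               "overlap")
})

test_that("invivo calls reuse the in vitro thresholds on RTV", {
  rtv <- data.frame(variant_id = c("a", "b", "c", "d"),
                    rtv = c(0.05, 0.3, 0.8, NA))
  calls <- invivo_calls(rtv)
  expect_equal(as.character(calls$category),
               c("sensitive", "partially_resistant", "resistant",
                 "undetermined"))
})

test_that("paired test handles identity, degeneracy, and matched keys", {
  x <- c(3, 4, 5, 6)
  r <- paired_group_test(x, x)
  expect_true(r$degenerate)
  expect_true(is.na(r$p))
  r2 <- paired_group_test(x + 1, x)  # constant difference, sd 0
  expect_true(r2$degenerate)
  expect_equal(r2$mean_difference, 1)
  # keys align unordered observations
  set.seed(4)
  y <- x + rnorm(4, 1)
  ord <- c(3, 1, 4, 2)
  r3 <- paired_group_test(x, y[ord], keys_x = letters[1:4],
                          keys_y = letters[1:4][ord])
  r4 <- paired_group_test(x, y)
  expect_equal(r3$t, r4$t)
  expect_equal(r3$p, r4$p)
  expect_error(paired_group_test(1, 2), "2 complete pairs")
})

test_that("paired test keeps its nominal type-I error rate", {
  set.seed(202)
  n_sim <- 10000
  p_vals <- replicate(n_sim,
    paired_group_test(rnorm(10), rnorm(10))$p)
  expect_lt(abs(mean(p_vals < 0.05) - 0.05), 0.01)
  # closed-form oracle for the statistic on a worked example
  x <- c(1, 3, 2, 5); y <- c(0, 1, 4, 2)
  d <- x - y
  r <- paired_group_test(x, y)
  expect_equal(r$t, mean(d) / (sd(d) / sqrt(4)))
  expect_equal(r$p, 2 * pt(-abs(r$t), df = 3))
})

test_that("vehicle tumors become dominated by their fastest clones", {
  set.seed(31)
  p <- make_panel(n_variants = 22, seed = 31)
  ids <- unique(p$variant_id)
  # two exon-20-insertion-like strong growers
  strong <- p$variant_id %in% ids[1:2]
  p$growth_rate[strong] <- 1.1
  p$growth_rate[!strong & p$archetype != "reference"] <- 0.55
  sim <- simulate_invivo(p, regimen("vehicle"),
                         n_mice_per_kill_day = 2,
                         kill_days = c(10, 20, 30),
                         measure_days = c(10, 20, 30), seed = 32)
  vp <- variant_proportions(sim$clone_counts, sim$map)
  comb <- colSums(vp$proportions[ids[1:2], ])
  by_day <- tapply(comb, sim$kill_info$day, mean)
  # monotone rise to dominance (> 80% late)
  expect_true(all(diff(by_day) > 0))
  expect_gt(by_day["20"], 0.8)
  # proportions conserved per tumor
  expect_equal(unname(colSums(vp$proportions)),
               rep(1, ncol(vp$proportions)))
})

test_that("sequential regimens reshape clonal composition around the switch", {
  p <- make_tumor_panel(seed = 5)
  dom <- attr(p, "dominant_variant")
  sim <- simulate_invivo(p, regimen("AO"), n_mice_per_kill_day = 2,
                         kill_days = c(10, 16, 24, 30),
                         measure_days = seq(6, 30, 2), seed = 6)
  vp <- variant_proportions(sim$clone_counts, sim$map)
  traj <- tapply(vp$proportions[dom, ], sim$kill_info$day, mean)
  # afatinib-resistant dominant clone rises under afatinib ...
  expect_gt(traj["16"], traj["10"])
  # ... and collapses after the switch to osimertinib
  expect_lt(traj["30"], 0.5 * traj["16"])
  # volume formula agreement on emitted observations
  obs <- sim$observations
  expect_equal(obs$volume, pi / 6 * obs$large * obs$small^2)
  expect_true(all(obs$large >= obs$small))
})
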