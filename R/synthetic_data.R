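#' Hill inhibition at a concentration
#'
#' `I(c) = imax / (1 + (ic50 / c)^hill)`, with `I(0) = 0`. At `c = ic50`
#' and `imax = 1` the survival factor `1 - I` is exactly 0.5 for any slope.
#'
#' @param conc Molar concentration (vectorised, 0 allowed).
#' @param ic50 Half-maximal concentration (molar, > 0).
#' @param hill Hill slope.
#' @param imax Maximal fractional inhibition in \[0, 1\].
#' @return Fractional inhibition in \[0, imax\].
#' @export
hill_inhibition <- function(conc, ic50, hill, imax = 1) {
  stopifnot(all(ic50 > 0), all(imax >= 0), all(imax <= 1))
  n <- max(length(conc), length(ic50), length(hill), length(imax))
  conc <- rep_len(conc, n)
  out <- rep_len(imax, n) / (1 + (rep_len(ic50, n) / conc)^rep_len(hill, n))
  out[conc <= 0] <- 0
  out
}

# Combined survival multiplier on the growth rate for one clone (one row of
# a clone panel) under an afatinib/osimertinib concentration pair. epsilon
# deviates from Bliss independence of the rate multiplier (positive =
# extra killing = synergy).
.survival_factor <- function(clone, afatinib, osimertinib,
                             gefitinib = 0) {
  i_a <- hill_inhibition(afatinib, clone$afa_ic50, clone$afa_hill,
                         clone$afa_imax)
  i_g <- hill_inhibition(gefitinib, clone$afa_ic50, clone$afa_hill,
                         clone$afa_imax)
  i_o <- hill_inhibition(osimertinib, clone$osi_ic50, clone$osi_hill,
                         clone$osi_imax)
  s <- (1 - i_a) * (1 - i_g) * (1 - i_o) -
    clone$epsilon * pmax(i_a, i_g) * i_o
  pmin(pmax(s, 0), 1)
}

.random_barcodes <- function(n, length = 10L, max_tries = 50L) {
  bases <- c("A", "C", "G", "T")
  bc <- character(0)
  for (i in seq_len(max_tries)) {
    need <- n - length(bc)
    if (need <= 0L) break
    new <- apply(matrix(sample(bases, need * length, replace = TRUE),
                        need, length), 1L, paste, collapse = "")
    bc <- unique(c(bc, new))
  }
  if (length(bc) < n) stop("could not generate ", n, " unique barcodes")
  bc[seq_len(n)]
}

.archetypes <- c("sensitive_both", "resistant_both",
                 "afatinib_resistant", "osimertinib_resistant")

#' Expected sensitivity calls per simulator archetype
#'
#' @return data.frame mapping each archetype to the (afatinib, osimertinib)
#'   categories a correct classifier should recover.
#' @export
archetype_expected_calls <- function() {
  data.frame(
    archetype = .archetypes,
    afatinib = c("sensitive", "resistant", "resistant", "sensitive"),
    osimertinib = c("sensitive", "resistant", "sensitive", "resistant"),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic clone panel
#'
#' Builds barcoded clones for `n_variants` variants drawn from four drug
#' response archetypes mirroring the canonical EGFR-TKI patterns:
#' sensitive to both drugs (L858R-like), resistant to both (exon-20
#' insertion / L858R_T790M_C797S-like), afatinib-only resistant
#' (T790M-like) and osimertinib-only resistant (L718V/V802F-like).
#' Sensitive IC50s sit well inside the tested ranges (afatinib ~2 nM,
#' osimertinib ~20 nM); resistant IC50s sit ~40x above the top tested dose.
#' Two drug-insensitive reference clones (`KRAS_G12V`, `GFP`) are appended
#' by default. Growth rates are per-day natural-log rates (~0.6/day,
#' a Ba/F3-like doubling time of ~28 h).
#'
#' @param n_variants Number of (non-reference) variants.
#' @param archetype_mix Named fractions over the four archetypes (must sum
#'   to 1).
#' @param clones_per_variant 1-3 barcoded clones per variant.
#' @param epsilon Bliss-deviation of the rate multiplier (0 = independent
#'   drug action).
#' @param include_references Append `KRAS_G12V` and `GFP` control clones.
#' @param ic50_sdlog,growth_sd Between-variant lognormal jitter on IC50s and
#'   normal jitter on growth rates.
#' @param seed RNG seed (calls `set.seed`).
#' @return A `clone_panel` data.frame, one row per clone: `variant_id`,
#'   `archetype`, `clone_index`, `barcode`, `growth_rate`, Hill parameters
#'   per drug (`afa_ic50`, `afa_hill`, `afa_imax`, `osi_*`), `epsilon`,
#'   `init_mass`.
#' @export
make_panel <- function(n_variants = 40L,
                       archetype_mix = c(sensitive_both = 0.25,
                                         resistant_both = 0.25,
                                         afatinib_resistant = 0.25,
                                         osimertinib_resistant = 0.25),
                       clones_per_variant = 3L,
                       epsilon = 0,
                       include_references = TRUE,
                       ic50_sdlog = 0.25, growth_sd = 0.05,
                       seed = 1L) {
  stopifnot(abs(sum(archetype_mix) - 1) < 1e-8,
            all(names(archetype_mix) %in% .archetypes),
            clones_per_variant >= 1L, clones_per_variant <= 3L)
  set.seed(seed)
  counts <- round(archetype_mix * n_variants)
  while (sum(counts) > n_variants) counts[which.max(counts)] <-
    counts[which.max(counts)] - 1L
  while (sum(counts) < n_variants) counts[which.max(archetype_mix)] <-
    counts[which.max(archetype_mix)] + 1L
  arch <- rep(names(counts), counts)
  sens_afa <- 2e-9;  res_afa <- 2e-6   # top afatinib dose 50 nM
  sens_osi <- 2e-8;  res_osi <- 4e-4   # top osimertinib dose 10 uM
  afa_ic50 <- ifelse(arch %in% c("resistant_both", "afatinib_resistant"),
                     res_afa, sens_afa) * exp(stats::rnorm(n_variants, 0, ic50_sdlog))
  osi_ic50 <- ifelse(arch %in% c("resistant_both", "osimertinib_resistant"),
                     res_osi, sens_osi) * exp(stats::rnorm(n_variants, 0, ic50_sdlog))
  g <- stats::rnorm(n_variants, 0.6, growth_sd)
  ids <- sprintf("VAR%03d_%s", seq_len(n_variants), arch)
  variants <- data.frame(
    variant_id = ids, archetype = arch, growth_rate = g,
    afa_ic50 = afa_ic50, afa_hill = 1.5, afa_imax = 1,
    osi_ic50 = osi_ic50, osi_hill = 1.5, osi_imax = 1,
    epsilon = epsilon, stringsAsFactors = FALSE)
  if (include_references) {
    refs <- data.frame(
      variant_id = c("KRAS_G12V", "GFP"), archetype = "reference",
      growth_rate = 0.6,
      afa_ic50 = 1, afa_hill = 1, afa_imax = 0,
      osi_ic50 = 1, osi_hill = 1, osi_imax = 0,
      epsilon = 0, stringsAsFactors = FALSE)
    variants <- rbind(variants, refs)
  }
  panel <- variants[rep(seq_len(nrow(variants)), each = clones_per_variant), ]
  panel$clone_index <- rep(seq_len(clones_per_variant), nrow(variants))
  panel$barcode <- .random_barcodes(nrow(panel))
  panel$init_mass <- 1
  rownames(panel) <- NULL
  structure(panel, class = c("clone_panel", "data.frame"))
}

#' Heterogeneous-tumor panel with a dominant resistant clone
#'
#' Builds the xenograft study condition: a mostly TKI-sensitive pool carrying
#' one dominant afatinib-resistant/osimertinib-sensitive variant (T790M-like,
#' `dominant_mass` times the unit inoculum) and rare dual-resistant variants
#' at a combined initial frequency below 0.5%.
#'
#' @param n_variants Panel size (excluding references).
#' @param dominant_mass Initial mass multiple of the dominant clone's
#'   variant.
#' @param dual_resistant_freq Combined initial frequency of the
#'   dual-resistant clones.
#' @param seed RNG seed.
#' @return A `clone_panel` with adjusted `init_mass`; the dominant variant id
#'   is stored in the `dominant_variant` attribute.
#' @export
make_tumor_panel <- function(n_variants = 20L, dominant_mass = 10,
                             dual_resistant_freq = 0.003, seed = 1L) {
  p <- make_panel(n_variants,
                  archetype_mix = c(sensitive_both = 0.9,
                                    afatinib_resistant = 0.05,
                                    resistant_both = 0.05),
                  seed = seed)
  dom <- p$variant_id[p$archetype == "afatinib_resistant"][1]
  p$init_mass[p$variant_id == dom] <- dominant_mass
  dual <- p$archetype == "resistant_both"
  rest <- sum(p$init_mass[!dual])
  p$init_mass[dual] <- dual_resistant_freq * rest /
    (1 - dual_resistant_freq) / sum(dual)
  attr(p, "dominant_variant") <- dom
  p
}

#' Barcode map of a clone panel
#'
#' @param panel A [make_panel()] result.
#' @return A [barcode_map()] with the panel's reference clones flagged.
#' @export
panel_map <- function(panel) {
  barcode_map(panel$barcode, panel$variant_id, panel$clone_index,
              reference_ids = intersect(c("KRAS_G12V", "GFP"),
                                        panel$variant_id))
}

.dirmult_probs <- function(p, concentration) {
  if (!is.finite(concentration)) return(p)
  w <- stats::rgamma(length(p), shape = concentration * p)
  if (sum(w) == 0) return(p)
  w / sum(w)
}

#' Simulate a pooled in vitro drug screen
#'
#' Clones are mixed in equal amounts and grown for `days` under every
#' condition of the dose grid (including monotherapies and vehicle),
#' following the deterministic growth law
#' `N(t) = N0 * exp(g * s(c) * t)` with survival multiplier
#' `s(c) = prod_d [1 - Imax_d / (1 + (ic50_d/c_d)^h_d)]` (plus the clone's
#' epsilon deviation). Sequencing reads are drawn multinomially (optionally
#' Dirichlet-overdispersed) from the final clone proportions.
#'
#' @param panel A [make_panel()] clone panel.
#' @param grid A [dose_grid()].
#' @param days Treatment duration in days.
#' @param depth Reads per sample.
#' @param replicates Replicates per condition.
#' @param overdispersion Dirichlet concentration (Inf = pure multinomial).
#' @param seed RNG seed.
#' @return A `screen_sim`: list with `counts` (barcode x sample), `samples`
#'   (sample sheet), `truth` (variant x condition matrices
#'   `survival_factor` and `relative_survival = exp(g*(s-1)*days)`, the
#'   value the analysis should recover), `panel`, `map`, `grid`, `days`,
#'   `depth`.
#' @export
simulate_screen <- function(panel, grid = dose_grid(), days = 4,
                            depth = 1e6, replicates = 3,
                            overdispersion = Inf, seed = 1L) {
  set.seed(seed)
  conds <- grid_conditions(grid)
  samples <- do.call(rbind, lapply(seq_len(replicates), function(r)
    data.frame(sample_id = paste0(conds$condition, "_rep", r), conds,
               replicate = r, stringsAsFactors = FALSE)))
  s_mat <- vapply(seq_len(nrow(conds)), function(i)
    .survival_factor(panel, conds$afatinib[i], conds$osimertinib[i]),
    numeric(nrow(panel)))
  mass <- panel$init_mass * exp(panel$growth_rate * s_mat * days)
  counts <- matrix(0L, nrow(panel), nrow(samples),
                   dimnames = list(panel$barcode, samples$sample_id))
  for (j in seq_len(nrow(samples))) {
    ci <- match(samples$condition[j], conds$condition)
    p <- mass[, ci] / sum(mass[, ci])
    p <- .dirmult_probs(p, overdispersion)
    counts[, j] <- stats::rmultinom(1L, size = depth, prob = p)
  }
  first <- !duplicated(panel$variant_id)
  truth_s <- s_mat[first, , drop = FALSE]
  rownames(truth_s) <- panel$variant_id[first]
  colnames(truth_s) <- conds$condition
  truth_rel <- exp(panel$growth_rate[first] * (truth_s - 1) * days)
  structure(list(counts = counts, samples = samples,
                 truth = list(survival_factor = truth_s,
                              relative_survival = truth_rel),
                 panel = panel, map = panel_map(panel), grid = grid,
                 days = days, depth = depth),
            class = "screen_sim")
}

#' Simulate a growth competition assay (no drug)
#'
#' The pool is mixed on day 0 and sampled at each requested day; clone
#' masses follow `exp(g * t)` and reads are drawn multinomially per day.
#'
#' @param panel A clone panel.
#' @param days Sampling days (default `c(0, 2, 4, 7)`).
#' @param depth Reads per sample.
#' @param overdispersion Dirichlet concentration (Inf = none).
#' @param seed RNG seed.
#' @return List with `counts` (barcode x day matrix), `days`, `panel`,
#'   `map`, and `truth_slopes` (per-variant true log-proportion slope
#'   `g_v - weighted mean g`, up to the common normalisation).
#' @export
simulate_competition <- function(panel, days = c(0, 2, 4, 7), depth = 1e6,
                                 overdispersion = Inf, seed = 1L) {
  set.seed(seed)
  counts <- vapply(days, function(d) {
    mass <- panel$init_mass * exp(panel$growth_rate * d)
    p <- .dirmult_probs(mass / sum(mass), overdispersion)
    stats::rmultinom(1L, size = depth, prob = p)[, 1]
  }, integer(nrow(panel)))
  dimnames(counts) <- list(panel$barcode, as.character(days))
  first <- !duplicated(panel$variant_id)
  structure(list(counts = counts, days = days, panel = panel,
                 map = panel_map(panel),
                 growth_rates = stats::setNames(panel$growth_rate[first],
                                                panel$variant_id[first])),
            class = "competition_sim")
}

#' Simulate a heterogeneous-tumor xenograft experiment
#'
#' Per-mouse clone masses follow the same exponential growth law with the
#' day-varying drug set of the regimen evaluated at fixed effective in vivo
#' concentrations (gefitinib reuses each clone's afatinib Hill parameters at
#' its own concentration, matching the near-identical variant spectra of
#' first- and second-generation TKIs). Total tumor volume is
#' `cell_volume_mm3 * total cells` with lognormal measurement noise, split
#' into large/small caliper diameters by inverting `pi/6*L*S^2` with a
#' lognormal eccentricity. At its kill day each mouse's tumor is sequenced:
#' barcode counts are Dirichlet-multinomial draws from clone masses.
#'
#' @param panel A clone panel (clone `init_mass` sets initial cell numbers
#'   in units of `init_cells`).
#' @param reg A [regimen()].
#' @param n_mice_per_kill_day Mice killed at each kill day.
#' @param kill_days Days at which mice are killed and sequenced.
#' @param measure_days Caliper measurement days (clipped to each mouse's
#'   kill day).
#' @param init_cells Cells per unit `init_mass` at injection.
#' @param depth Sequencing reads per resected tumor.
#' @param afatinib_conc,osimertinib_conc,gefitinib_conc Effective molar
#'   concentrations during administration.
#' @param growth_scale Multiplier on the panel's in-culture growth rates
#'   (default 0.5: xenograft doubling is roughly half the in-culture pace).
#' @param cell_volume_mm3 Tumor volume per cell (default 1e-6: 1 mm^3 per
#'   million cells).
#' @param eccentricity_sd sdlog of the large/small diameter ratio.
#' @param volume_noise_sd sdlog of volume measurement noise.
#' @param init_jitter_sd sdlog of per-mouse initial clone-mass jitter.
#' @param overdispersion Dirichlet concentration for sequencing counts.
#' @param seed RNG seed.
#' @return An `invivo_sim`: list with `observations` (mouse_id, group, day,
#'   large, small, volume), `clone_counts` (barcode x killed-mouse matrix),
#'   `kill_info` (mouse_id, day), `truth_masses` (clone x day expected
#'   masses, noise-free), `panel`, `map`, `regimen`.
#' @export
simulate_invivo <- function(panel, reg,
                            n_mice_per_kill_day = 3L,
                            kill_days = c(16, 30),
                            measure_days = seq(6, 30, by = 3),
                            init_cells = 1e5, depth = 1e5,
                            afatinib_conc = 2e-8,
                            osimertinib_conc = 2e-7,
                            gefitinib_conc = 2e-8,
                            growth_scale = 0.5,
                            cell_volume_mm3 = 1e-6,
                            eccentricity_sd = 0.1,
                            volume_noise_sd = 0.1,
                            init_jitter_sd = 0.2,
                            overdispersion = Inf,
                            seed = 1L) {
  stopifnot(inherits(reg, "regimen"))
  if (max(kill_days, measure_days) > reg$duration)
    stop("regimen schedule does not cover the requested days")
  set.seed(seed)
  sched <- reg$schedule
  conc <- c(afatinib = afatinib_conc, osimertinib = osimertinib_conc,
            gefitinib = gefitinib_conc)
  # per-clone rate (log mass / day) in each schedule segment
  seg_rate <- vapply(seq_len(nrow(sched)), function(i) {
    d <- sched$drugs[[i]]
    s <- .survival_factor(panel,
                          afatinib = if ("afatinib" %in% d) conc["afatinib"] else 0,
                          osimertinib = if ("osimertinib" %in% d) conc["osimertinib"] else 0,
                          gefitinib = if ("gefitinib" %in% d) conc["gefitinib"] else 0)
    panel$growth_rate * growth_scale * s
  }, numeric(nrow(panel)))
  log_mass_at <- function(day) {
    len <- pmax(0, pmin(day, sched$to) - sched$from)
    log(panel$init_mass * init_cells) + as.vector(seg_rate %*% len)
  }
  all_days <- sort(unique(c(measure_days, kill_days)))
  truth <- vapply(all_days, function(d) exp(log_mass_at(d)),
                  numeric(nrow(panel)))
  dimnames(truth) <- list(panel$barcode, as.character(all_days))
  obs <- list(); kills <- list(); counts <- list()
  mouse_no <- 0L
  for (kd in kill_days) {
    for (m in seq_len(n_mice_per_kill_day)) {
      mouse_no <- mouse_no + 1L
      id <- sprintf("%s_m%02d", reg$name, mouse_no)
      jit <- exp(stats::rnorm(nrow(panel), 0, init_jitter_sd))
      mdays <- sort(unique(c(measure_days[measure_days <= kd], kd)))
      for (d in mdays) {
        mass <- exp(log_mass_at(d)) * jit
        vol <- sum(mass) * cell_volume_mm3 *
          exp(stats::rnorm(1, 0, volume_noise_sd))
        ecc <- exp(abs(stats::rnorm(1, 0, eccentricity_sd)))
        small <- (6 * vol / (pi * ecc))^(1 / 3)
        obs[[length(obs) + 1L]] <- data.frame(
          mouse_id = id, group = reg$name, day = d,
          large = ecc * small, small = small, volume = vol,
          stringsAsFactors = FALSE)
      }
      mass_kill <- exp(log_mass_at(kd)) * jit
      p <- .dirmult_probs(mass_kill / sum(mass_kill), overdispersion)
      counts[[id]] <- stats::rmultinom(1L, size = depth, prob = p)[, 1]
      kills[[length(kills) + 1L]] <- data.frame(mouse_id = id, day = kd,
                                                stringsAsFactors = FALSE)
    }
  }
  cc <- do.call(cbind, counts)
  dimnames(cc) <- list(panel$barcode, names(counts))
  structure(list(observations = do.call(rbind, obs),
                 clone_counts = cc,
                 kill_info = do.call(rbind, kills),
                 truth_masses = truth,
                 panel = panel, map = panel_map(panel), regimen = reg),
            class = "invivo_sim")
}

#' Emit synthetic paired FASTQ reads for a barcode count vector
#'
#' Each read embeds `flank5 + barcode + flank3` at a random offset inside
#' random background sequence; mate 2 is the reverse complement of the
#' (error-free) fragment, and substitution errors are applied independently
#' to each mate at `error_rate` per base.
#'
#' @param counts Named integer vector: reads to emit per barcode.
#' @param context A [barcode_context()].
#' @param read_length Read length in bases (must fit the insert).
#' @param error_rate Per-base substitution probability.
#' @param r1,r2 Output FASTQ paths (`.gz` supported); `r2 = NULL` emits
#'   single-end reads.
#' @param shuffle Permute read order (default TRUE).
#' @param seed RNG seed.
#' @return Invisibly, the number of read (pairs) written.
#' @export
emit_fastq <- function(counts, context = barcode_context(),
                       read_length = 150L, error_rate = 0,
                       r1, r2 = NULL, shuffle = TRUE, seed = 1L) {
  set.seed(seed)
  bl <- context$barcode_length
  ins_len <- nchar(context$flank5) + bl + nchar(context$flank3)
  if (read_length < ins_len)
    stop("read_length must be >= flank5 + barcode + flank3 = ", ins_len)
  bcs <- rep(names(counts), counts)
  if (shuffle && length(bcs) > 1L) bcs <- sample(bcs)
  n <- length(bcs)
  if (!n) stop("no reads to emit")
  bases <- c("A", "C", "G", "T")
  frag <- matrix(sample(bases, n * read_length, replace = TRUE),
                 n, read_length)
  ins <- matrix(unlist(strsplit(paste0(context$flank5, bcs, context$flank3),
                                "")),
                n, ins_len, byrow = TRUE)
  offset <- sample.int(read_length - ins_len + 1L, n, replace = TRUE)
  for (j in seq_len(ins_len))
    frag[cbind(seq_len(n), offset + j - 1L)] <- ins[, j]
  add_errors <- function(m) {
    if (error_rate <= 0) return(m)
    idx <- which(stats::runif(length(m)) < error_rate)
    if (!length(idx)) return(m)
    alt <- matrix(c("C", "G", "T", "A", "G", "T", "A", "C", "T",
                    "A", "C", "G"), 4L, 3L, byrow = TRUE)
    m[idx] <- alt[cbind(match(m[idx], bases),
                        sample.int(3L, length(idx), replace = TRUE))]
    m
  }
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  write_reads <- function(m, path, mate) {
    seqs <- do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
    qual <- strrep("I", read_length)
    lines <- as.vector(rbind(sprintf("@read_%d/%d", seq_len(n), mate),
                             seqs, "+", qual))
    con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
    on.exit(close(con))
    writeLines(lines, con)
  }
  write_reads(add_errors(frag), r1, 1L)
  if (!is.null(r2)) {
    rc <- matrix(unname(comp[frag[, rev(seq_len(read_length))]]),
                 n, read_length)
    write_reads(add_errors(rc), r2, 2L)
  }
  invisible(n)
}

#' Simulate response surfaces that are exactly Bliss-independent
#'
#' Draws random monotherapy Hill inhibition profiles for both drugs and sets
#' every combination cell's survival to the product of the monotherapy
#' survivals (multiplicative survival = Bliss independence of the measured
#' quantity), optionally shifted by a synergy deviation `epsilon` (added to
#' the combination inhibition as `epsilon * E_a * E_o`) and by Gaussian
#' noise on survival.
#'
#' @param n Number of surfaces.
#' @param grid A [dose_grid()].
#' @param epsilon Synergy deviation (0 = exact independence).
#' @param noise_sd Gaussian noise sd on survival values.
#' @param seed RNG seed.
#' @return List of `response_surface` objects.
#' @export
simulate_bliss_surfaces <- function(n = 10L, grid = dose_grid(),
                                    epsilon = 0, noise_sd = 0, seed = 1L) {
  set.seed(seed)
  a <- c(0, grid$afatinib)
  o <- c(0, grid$osimertinib)
  lapply(seq_len(n), function(i) {
    ic50_a <- exp(stats::runif(1, log(min(grid$afatinib)),
                               log(max(grid$afatinib))))
    ic50_o <- exp(stats::runif(1, log(min(grid$osimertinib)),
                               log(max(grid$osimertinib))))
    h_a <- stats::runif(1, 0.8, 2.5); h_o <- stats::runif(1, 0.8, 2.5)
    imax_a <- stats::runif(1, 0.6, 1); imax_o <- stats::runif(1, 0.6, 1)
    e_a <- hill_inhibition(a, ic50_a, h_a, imax_a)
    e_o <- hill_inhibition(o, ic50_o, h_o, imax_o)
    surv <- outer(1 - e_a, 1 - e_o)
    inh <- 1 - surv
    dev <- epsilon * outer(e_a, e_o)
    dev[1, ] <- 0; dev[, 1] <- 0   # monotherapy/vehicle cells untouched
    surv <- 1 - pmin(pmax(inh + dev, 0), 1)
    if (noise_sd > 0) {
      noise <- matrix(stats::rnorm(length(surv), 0, noise_sd), nrow(surv))
      noise[1, 1] <- 0
      surv <- pmax(surv + noise, 0)
    }
    dimnames(surv) <- list(as.character(a), as.character(o))
    structure(list(variant_id = sprintf("SIM%03d", i), survival = surv,
                   inhibition = 1 - pmin(surv, 1), afatinib = a,
                   osimertinib = o,
                   missing_cells = matrix(integer(), 0, 2)),
              class = "response_surface")
  })
}

#' Synthetic variant annotation catalog
#'
#' Emulates the schema and marginal composition of the study-style variant
#' table: 357 variants with FFA scores distributed (213, 29, 50, 65) over
#' scores 1-4, 282 Ba/F3-transforming variants (all FFA >= 2 transformers
#' plus the strongest remaining score-1 records), and 26 strong transformers
#' (FFA 3-4) left unannotated in OncoKB ("novel oncogenic"). All records are
#' synthetic; protein changes and database counts are cosmetic.
#'
#' @param ffa_counts Integer counts for FFA scores 1-4.
#' @param n_baf3 Number of Ba/F3-transforming variants.
#' @param n_novel Number of FFA >= 3 records annotated as VUS.
#' @param seed RNG seed.
#' @return A `variant_catalog` data.frame.
#' @export
simulate_catalog <- function(ffa_counts = c(213L, 29L, 50L, 65L),
                             n_baf3 = 282L, n_novel = 26L, seed = 1L) {
  set.seed(seed)
  n <- sum(ffa_counts)
  stopifnot(n_baf3 <= n, n_novel <= sum(ffa_counts[3:4]))
  score <- rep(1:4, ffa_counts)
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  pos <- sample(30:1200, n, replace = TRUE)
  protein_change <- paste0(sample(aa, n, TRUE), pos, sample(aa, n, TRUE))
  mutation_type <- sample(c("missense", "insertion", "deletion", "compound"),
                          n, TRUE, prob = c(0.7, 0.12, 0.1, 0.08))
  exon <- sample(18:28, n, TRUE,
                 prob = c(5, 4, 6, 4, rep(1, 7)))
  domain <- sample(c("ECD", "TMD", "TKD", "RD"), n, TRUE,
                   prob = c(0.2, 0.05, 0.55, 0.2))
  baf3 <- rep(FALSE, n)
  baf3[score >= 2] <- TRUE
  need <- n_baf3 - sum(baf3)
  if (need > 0) baf3[sample(which(score == 1), need)] <- TRUE
  if (need < 0) baf3[sample(which(baf3), -need)] <- FALSE
  oncokb <- rep("VUS", n)
  strong <- which(score >= 3)
  annotated <- sample(strong, length(strong) - n_novel)
  oncokb[annotated] <- sample(c("oncogenic", "likely_oncogenic"),
                              length(annotated), TRUE, prob = c(0.7, 0.3))
  mild <- which(score == 2)
  oncokb[sample(mild, round(length(mild) / 3))] <- "likely_oncogenic"
  cosmic <- stats::rnbinom(n, mu = 2 + 30 * (score - 1), size = 0.5)
  genie <- stats::rnbinom(n, mu = 1 + 15 * (score - 1), size = 0.5)
  validate_catalog(data.frame(
    variant_id = sprintf("EGFR_%s", make.unique(protein_change, sep = "_")),
    protein_change = protein_change, mutation_type = mutation_type,
    exon = exon, domain = domain, ffa_score = score,
    baf3_transforming = baf3, oncokb = oncokb,
    cosmic_count = cosmic, genie_count = genie,
    stringsAsFactors = FALSE))
}

#' Synthetic two-drug sensitivity call table
#'
#' Emulates the published composition of the in vitro screen: of `n`
#' variants, 3 fully resistant to both drugs, 18 further nonsensitive
#' (resistant or partially resistant) to both, 4 afatinib-nonsensitive but
#' osimertinib-sensitive, 25 osimertinib-nonsensitive but
#' afatinib-sensitive, and the remainder sensitive to both — giving 25
#' afatinib-nonsensitive, 46 osimertinib-nonsensitive and 50 nonsensitive to
#' at least one drug. The three dual-resistant records carry the canonical
#' exon-20-insertion / triple-mutant labels; all others are synthetic ids.
#'
#' @param n Total variants.
#' @param n_both_resistant,n_both_partial,n_afa_only,n_osi_only Cell sizes
#'   (see description for defaults).
#' @param seed RNG seed (shuffles row order only).
#' @return A `call_table` data.frame (`variant_id`, `afatinib`,
#'   `osimertinib`).
#' @export
simulate_call_table <- function(n = 282L, n_both_resistant = 3L,
                                n_both_partial = 18L, n_afa_only = 4L,
                                n_osi_only = 25L, seed = 1L) {
  set.seed(seed)
  stopifnot(n_both_resistant + n_both_partial + n_afa_only + n_osi_only <= n)
  nonsens <- c("partially_resistant", "resistant")
  block <- function(ids, afa, osi)
    data.frame(variant_id = ids, afatinib = rep_len(afa, length(ids)),
               osimertinib = rep_len(osi, length(ids)),
               stringsAsFactors = FALSE)
  both_res <- block(
    c("D770_N771insSVD", "N771_P772insV", "L858R_T790M_C797S")[
      seq_len(n_both_resistant)],
    "resistant", "resistant")
  mix <- function(k, offset) nonsens[1 + (seq_len(k) + offset) %% 2]
  both_part <- block(sprintf("DUAL_NS_%02d", seq_len(n_both_partial)),
                     mix(n_both_partial, 0), mix(n_both_partial, 1))
  # keep both_part free of resistant/resistant rows
  clash <- both_part$afatinib == "resistant" &
    both_part$osimertinib == "resistant"
  both_part$osimertinib[clash] <- "partially_resistant"
  afa_only <- block(sprintf("AFA_NS_%02d", seq_len(n_afa_only)),
                    "resistant", "sensitive")
  osi_only <- block(sprintf("OSI_NS_%02d", seq_len(n_osi_only)),
                    "sensitive", mix(n_osi_only, 0))
  n_sens <- n - nrow(both_res) - nrow(both_part) - nrow(afa_only) -
    nrow(osi_only)
  sens <- block(sprintf("SENS_%03d", seq_len(n_sens)),
                "sensitive", "sensitive")
  out <- rbind(both_res, both_part, afa_only, osi_only, sens)
  if (nrow(out)) out <- out[sample.int(nrow(out)), , drop = FALSE]
  out$afatinib <- factor(out$afatinib, levels = .call_levels)
  out$osimertinib <- factor(out$osimertinib, levels = .call_levels)
  rownames(out) <- NULL
  structure(out, class = c("call_table", "data.frame"))
}

#' Synthetic in vivo call set concordant with an in vitro table
#'
#' Samples `n` variants from an in vitro call table for one drug and flips
#' `n_discordant` of their categories, emulating an in vivo re-assessment
#' with known concordance `(n - n_discordant) / n`.
#'
#' @param invitro A `call_table`.
#' @param drug Which drug's calls to carry over.
#' @param n Number of variants assessed in vivo.
#' @param n_discordant Calls flipped to a different category.
#' @param seed RNG seed.
#' @return List with `invivo` and `invitro` call data.frames
#'   (`variant_id`, `category`) ready for [call_concordance()].
#' @export
simulate_invivo_calls <- function(invitro, drug = "osimertinib", n = 34L,
                                  n_discordant = 2L, seed = 1L) {
  set.seed(seed)
  stopifnot(n <= nrow(invitro), n_discordant <= n)
  rows <- invitro[sample.int(nrow(invitro), n), ]
  vitro <- data.frame(variant_id = rows$variant_id,
                      category = as.character(rows[[drug]]),
                      stringsAsFactors = FALSE)
  vivo <- vitro
  flip <- sample.int(n, n_discordant)
  others <- function(cat) setdiff(.call_levels[1:3], cat)
  vivo$category[flip] <- vapply(vivo$category[flip],
                                function(cat) sample(others(cat), 1L), "")
  list(invivo = vivo, invitro = vitro)
}
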