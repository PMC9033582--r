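#' Afatinib x osimertinib dose grid
#'
#' Default grid: 8 log-spaced afatinib levels spanning 500 pM-50 nM and 9
#' log-spaced osimertinib levels spanning 100 pM-10 uM, i.e. 72 combination
#' cells, plus the vehicle row/column (concentration 0) when surfaces are
#' built. All concentrations are molar.
#'
#' @param afatinib,osimertinib Strictly increasing positive molar
#'   concentration vectors.
#' @return A `dose_grid` object.
#' @export
dose_grid <- function(afatinib = exp(seq(log(500e-12), log(50e-9),
                                         length.out = 8)),
                      osimertinib = exp(seq(log(100e-12), log(10e-6),
                                            length.out = 9))) {
  stopifnot(all(afatinib > 0), all(osimertinib > 0),
            !is.unsorted(afatinib, strictly = TRUE),
            !is.unsorted(osimertinib, strictly = TRUE))
  structure(list(afatinib = afatinib, osimertinib = osimertinib,
                 n_combinations = length(afatinib) * length(osimertinib)),
            class = "dose_grid")
}

#' @export
print.dose_grid <- function(x, ...) {
  cat(sprintf("dose grid: %d afatinib x %d osimertinib levels (%d combinations)\n",
              length(x$afatinib), length(x$osimertinib), x$n_combinations))
  invisible(x)
}

#' All conditions of a grid (including monotherapies and vehicle)
#'
#' @param grid A [dose_grid()].
#' @return data.frame with `condition`, `afatinib`, `osimertinib`.
#' @export
grid_conditions <- function(grid) {
  cells <- expand.grid(afatinib = c(0, grid$afatinib),
                       osimertinib = c(0, grid$osimertinib),
                       KEEP.OUT.ATTRS = FALSE)
  data.frame(condition = .condition_id(cells$afatinib, cells$osimertinib),
             cells, stringsAsFactors = FALSE)
}

#' Build a per-variant dose-response surface
#'
#' Arranges a variant's relative growth inhibition values on the
#' afatinib x osimertinib grid (vehicle row/column included). Survival is
#' the treated/vehicle relative abundance (1 = vehicle-equivalent growth);
#' inhibition is `1 - min(survival, 1)`. Missing cells stay `NA` and are
#' flagged, never imputed.
#'
#' @param gi A `growth_inhibition` object from
#'   [relative_growth_inhibition()].
#' @param grid The [dose_grid()] the screen used.
#' @param variant_id Variant to extract.
#' @return A `response_surface`: list with `survival` and `inhibition`
#'   matrices (rows = afatinib incl. 0, cols = osimertinib incl. 0),
#'   `afatinib`, `osimertinib`, `variant_id`, `missing_cells`.
#' @export
build_surface <- function(gi, grid, variant_id) {
  stopifnot(inherits(gi, "growth_inhibition"))
  if (!variant_id %in% rownames(gi$values))
    stop("variant '", variant_id, "' absent from the inhibition matrix")
  a <- c(0, grid$afatinib)
  o <- c(0, grid$osimertinib)
  surv <- matrix(NA_real_, length(a), length(o),
                 dimnames = list(as.character(a), as.character(o)))
  for (j in seq_along(o)) {
    ids <- .condition_id(a, rep(o[j], length(a)))
    hit <- match(ids, colnames(gi$values))
    surv[, j] <- ifelse(is.na(hit), NA_real_, gi$values[variant_id, hit])
  }
  surv["0", "0"] <- 1
  inhib <- 1 - pmin(surv, 1)
  miss <- which(is.na(surv), arr.ind = TRUE)
  structure(list(variant_id = variant_id, survival = surv,
                 inhibition = inhib, afatinib = a, osimertinib = o,
                 missing_cells = miss),
            class = "response_surface")
}

.call_levels <- c("sensitive", "partially_resistant", "resistant",
                  "undetermined")

.call_category <- function(survival, thresholds = c(0.2, 0.5)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] < thresholds[2])
  out <- ifelse(is.na(survival), "undetermined",
                ifelse(survival < thresholds[1], "sensitive",
                       ifelse(survival < thresholds[2], "partially_resistant",
                              "resistant")))
  factor(out, levels = .call_levels)
}

#' Classify a variant's sensitivity to one drug
#'
#' Survival at the reference monotherapy dose (default: the top tested dose
#' of the drug) mapped through thresholds: survival < 0.2 is `sensitive`,
#' 0.2-0.5 `partially_resistant`, >= 0.5 `resistant`. The mapping is monotone:
#' raising survival can never move a variant toward `sensitive`.
#'
#' @param surface A [build_surface()] result.
#' @param drug `"afatinib"` or `"osimertinib"`.
#' @param thresholds Two increasing cutpoints on survival.
#' @param reference_dose Molar dose at which to read survival (default top
#'   tested).
#' @return List with `variant_id`, `drug`, `category` (factor; `undetermined`
#'   when the reference-dose cell is missing), `survival`, `reference_dose`,
#'   `thresholds`.
#' @export
classify_sensitivity <- function(surface, drug = c("afatinib", "osimertinib"),
                                 thresholds = c(0.2, 0.5),
                                 reference_dose = NULL) {
  drug <- match.arg(drug)
  doses <- surface[[drug]]
  if (is.null(reference_dose)) reference_dose <- max(doses)
  i <- match(as.character(reference_dose), as.character(doses))
  if (is.na(i)) stop("reference dose not on the surface's ", drug, " axis")
  s <- if (drug == "afatinib") surface$survival[i, "0"]
       else surface$survival["0", i]
  list(variant_id = surface$variant_id, drug = drug,
       category = .call_category(s, thresholds),
       survival = unname(s), reference_dose = reference_dose,
       thresholds = thresholds)
}

#' Call both drugs for every variant of a screen
#'
#' @param gi A `growth_inhibition` object.
#' @param grid The screen's [dose_grid()].
#' @param thresholds Survival cutpoints passed to [classify_sensitivity()].
#' @return A `call_table` data.frame: `variant_id`, `afatinib`,
#'   `osimertinib` (category factors), `afatinib_survival`,
#'   `osimertinib_survival`.
#' @export
call_variants <- function(gi, grid, thresholds = c(0.2, 0.5)) {
  ids <- rownames(gi$values)
  rows <- lapply(ids, function(v) {
    surf <- build_surface(gi, grid, v)
    a <- classify_sensitivity(surf, "afatinib", thresholds)
    o <- classify_sensitivity(surf, "osimertinib", thresholds)
    data.frame(variant_id = v, afatinib = a$category,
               osimertinib = o$category,
               afatinib_survival = a$survival,
               osimertinib_survival = o$survival,
               stringsAsFactors = FALSE)
  })
  structure(do.call(rbind, rows), class = c("call_table", "data.frame"))
}

#' Cross-resistance contingency summary for two drugs
#'
#' "Nonsensitive" means resistant or partially resistant. Reports, over the
#' variants with determined calls for both drugs: the number nonsensitive to
#' at least one drug, the fully-resistant-to-both and nonsensitive-to-both
#' cells, and the escape routes (afatinib-nonsensitive variants that remain
#' osimertinib-sensitive, and vice versa). Percentages are rounded to one
#' decimal.
#'
#' @param calls A data.frame with `variant_id`, `afatinib`, `osimertinib`
#'   category columns (e.g. a `call_table`).
#' @return List of counts and percentages plus the full 3x3 contingency
#'   `table`; `n_undetermined` counts variants excluded for an undetermined
#'   call on either drug.
#' @export
cross_resistance_summary <- function(calls) {
  if (!nrow(calls))
    return(list(n = 0L, n_undetermined = 0L, table = table(NULL)))
  a <- as.character(calls$afatinib)
  o <- as.character(calls$osimertinib)
  undet <- a == "undetermined" | o == "undetermined"
  a <- a[!undet]; o <- o[!undet]
  n <- length(a)
  lev <- .call_levels[1:3]
  tab <- table(factor(a, lev), factor(o, lev), dnn = c("afatinib", "osimertinib"))
  a_ns <- a != "sensitive"
  o_ns <- o != "sensitive"
  pct <- function(num, den) if (den > 0) round(100 * num / den, 1) else NA_real_
  list(
    n = n,
    n_undetermined = sum(undet),
    table = tab,
    any_nonsensitive_n = sum(a_ns | o_ns),
    any_nonsensitive_pct = pct(sum(a_ns | o_ns), n),
    both_nonsensitive_n = sum(a_ns & o_ns),
    both_nonsensitive_pct = pct(sum(a_ns & o_ns), n),
    both_resistant_n = sum(a == "resistant" & o == "resistant"),
    both_resistant_pct = pct(sum(a == "resistant" & o == "resistant"), n),
    afatinib_nonsensitive_n = sum(a_ns),
    afatinib_nonsensitive_osimertinib_sensitive_n = sum(a_ns & !o_ns),
    afatinib_nonsensitive_osimertinib_sensitive_pct =
      pct(sum(a_ns & !o_ns), sum(a_ns)),
    osimertinib_nonsensitive_n = sum(o_ns),
    osimertinib_nonsensitive_afatinib_sensitive_n = sum(o_ns & !a_ns),
    osimertinib_nonsensitive_afatinib_sensitive_pct =
      pct(sum(o_ns & !a_ns), sum(o_ns))
  )
}

#' Bliss-independence synergy score of a response surface
#'
#' For every combination cell (a > 0, o > 0) the expected inhibition under
#' Bliss independence is `E = E_a + E_o - E_a * E_o`, computed from the
#' monotherapy inhibitions at the same doses; the per-cell score is
#' `100 * (observed inhibition - E)` percentage points (positive = synergy,
#' negative = antagonism). The summary score is the arithmetic mean over all
#' combination cells; monotherapy and vehicle cells do not contribute.
#' Inhibition values outside \[0, 1\] are clipped (with a warning) before the
#' Bliss formula.
#'
#' @param surface A [build_surface()] result (monotherapy row and column must
#'   be present).
#' @return A `synergy_result`: list with `scores` (combination-cell matrix,
#'   percentage points), `expected` (Bliss-expected inhibition),
#'   `mean_score`, `variant_id`.
#' @export
bliss_synergy <- function(surface) {
  inhib <- surface$inhibition
  if (any(surface$survival > 1 + 1e-12, na.rm = TRUE) ||
      any(inhib < -1e-12 | inhib > 1 + 1e-12, na.rm = TRUE))
    warning("inhibition outside [0, 1] (growth stimulation) clipped for ",
            "Bliss scoring")
  inhib <- pmin(pmax(inhib, 0), 1)
  e_a <- inhib[, "0"][-1]          # monotherapy afatinib (rows a > 0)
  e_o <- inhib["0", ][-1]          # monotherapy osimertinib (cols o > 0)
  if (anyNA(e_a) || anyNA(e_o))
    stop("monotherapy rows/columns are required for Bliss scoring")
  expected <- outer(e_a, e_o, function(x, y) x + y - x * y)
  observed <- inhib[-1, -1, drop = FALSE]
  scores <- 100 * (observed - expected)
  structure(list(variant_id = surface$variant_id, scores = scores,
                 expected = expected,
                 mean_score = mean(scores, na.rm = TRUE)),
            class = "synergy_result")
}

#' Fit a four-parameter logistic dose-response curve
#'
#' `response = bottom + (top - bottom) / (1 + (dose / ic50)^hill)`,
#' fitted by Levenberg-Marquardt least squares with a deterministic
#' multi-start over log-spaced IC50 seeds spanning the tested dose range.
#'
#' @param dose Positive molar doses (>= 4 levels).
#' @param response Viability/response values, same length.
#' @param n_starts Number of IC50 seeds.
#' @return A `four_pl_fit`: list with `top`, `bottom`, `ic50` (molar),
#'   `hill`, `rss`, `converged`, `in_range` (IC50 inside the tested dose
#'   range) and `fitted` values. Non-convergence from every start is flagged
#'   with `rss = Inf`.
#' @export
fit_4pl <- function(dose, response, n_starts = 7L) {
  stopifnot(length(dose) == length(response), all(dose > 0),
            length(unique(dose)) >= 4L)
  df <- data.frame(ld = log(dose), y = response)
  top0 <- max(response); bot0 <- min(response)
  seeds <- seq(log(min(dose)), log(max(dose)), length.out = n_starts)
  best <- NULL
  for (lic50 in seeds) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ bottom + (top - bottom) / (1 + exp(hill * (ld - lic))),
        data = df,
        start = list(top = top0, bottom = bot0, hill = 1, lic = lic50),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    rss <- sum(stats::residuals(fit)^2)
    if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
  }
  if (is.null(best))
    return(structure(list(top = NA_real_, bottom = NA_real_, ic50 = NA_real_,
                          hill = NA_real_, rss = Inf, converged = FALSE,
                          in_range = NA, fitted = rep(NA_real_, length(dose))),
                     class = "four_pl_fit"))
  p <- stats::coef(best$fit)
  ic50 <- exp(unname(p["lic"]))
  structure(list(top = unname(p["top"]), bottom = unname(p["bottom"]),
                 ic50 = ic50, hill = unname(p["hill"]), rss = best$rss,
                 converged = TRUE,
                 in_range = ic50 >= min(dose) && ic50 <= max(dose),
                 fitted = stats::fitted(best$fit)),
            class = "four_pl_fit")
}

#' Predict from a 4PL fit
#'
#' @param object A `four_pl_fit`.
#' @param dose Doses at which to evaluate the curve.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.four_pl_fit <- function(object, dose, ...) {
  object$bottom + (object$top - object$bottom) /
    (1 + (dose / object$ic50)^object$hill)
}
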