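#' Collapse clone-level counts to variant level
#'
#' Each variant is represented by 1-3 independently barcoded clones; this
#' aggregates their counts per sample. `sum` (default) treats clones as
#' parallel draws of the same variant; `mean` is useful when clone numbers
#' differ between variants.
#'
#' @param counts Barcode x sample numeric matrix, or a `count_table`.
#' @param map A [barcode_map()] (taken from the `count_table` if omitted).
#' @param mode `"sum"` or `"mean"`.
#' @return Variant x sample numeric matrix with a `clone_counts` attribute
#'   keeping the clone-level matrix for dispersion diagnostics.
#' @export
collapse_clones <- function(counts, map = NULL, mode = c("sum", "mean")) {
  mode <- match.arg(mode)
  if (inherits(counts, "count_table")) {
    if (is.null(map)) map <- counts$map
    counts <- counts$counts
  }
  stopifnot(inherits(map, "barcode_map"))
  keep <- rownames(counts) %in% map$barcode
  counts <- counts[keep, , drop = FALSE]
  vid <- map$variant_id[match(rownames(counts), map$barcode)]
  agg <- rowsum(counts, group = vid)
  if (mode == "mean") {
    nclone <- as.vector(table(vid)[rownames(agg)])
    agg <- agg / nclone
  }
  structure(agg, clone_counts = counts, mode = mode)
}

#' Scale variant counts to a reference control
#'
#' Every sample column is expressed relative to the designated
#' drug-insensitive reference clone in the same sample (KRAS G12V in vitro,
#' the GFP clone in vivo), which cancels sequencing depth. Values are
#' `(count + pseudocount) / (reference count + pseudocount)` so the reference
#' row is exactly 1 in every sample.
#'
#' @param variant_counts Variant x sample numeric matrix.
#' @param reference_id Row name of the reference variant.
#' @param pseudocount Added to numerator and denominator; guards against
#'   zero-count cells.
#' @return A `scaled_abundance` matrix (variant x sample) with attributes
#'   `reference_id`, `pseudocount` and `zero_reference_samples` (samples in
#'   which the reference had zero reads and the pseudocount carried the
#'   division).
#' @export
scale_to_reference <- function(variant_counts, reference_id = "KRAS_G12V",
                               pseudocount = 0.5) {
  if (!reference_id %in% rownames(variant_counts))
    stop("reference '", reference_id, "' absent from the count matrix")
  ref <- variant_counts[reference_id, ]
  if (all(ref == 0)) stop("reference has zero counts in every sample")
  flagged <- colnames(variant_counts)[ref == 0]
  if (length(flagged) && pseudocount <= 0)
    stop("reference count is 0 in some samples and pseudocount is 0")
  scaled <- sweep(variant_counts + pseudocount, 2, ref + pseudocount, "/")
  structure(scaled, reference_id = reference_id, pseudocount = pseudocount,
            zero_reference_samples = flagged, class = "scaled_abundance")
}

.condition_id <- function(afatinib, osimertinib) {
  paste0("afa", as.character(afatinib), "_osi", as.character(osimertinib))
}

#' Relative growth inhibition under treatment
#'
#' For each variant and drug condition, the mean reference-scaled abundance
#' across treated replicates divided by the mean across vehicle replicates:
#' 1 means growth indistinguishable from vehicle, values near 0 mean the
#' variant was depleted by the drug. Replicates of a condition are averaged
#' flat (biological and technical replicates pooled).
#'
#' @param scaled A `scaled_abundance` matrix from [scale_to_reference()].
#' @param samples data.frame with columns `sample_id`, `afatinib`,
#'   `osimertinib` (molar concentrations; 0/0 marks vehicle) and `replicate`;
#'   `sample_id` must match the columns of `scaled`.
#' @return A `growth_inhibition` object: list with `values` (variant x
#'   condition matrix; vehicle column is identically 1), `replicate_cv`
#'   (coefficient of variation of the scaled abundance across replicates),
#'   and `conditions` (condition metadata).
#' @export
relative_growth_inhibition <- function(scaled, samples) {
  stopifnot(all(samples$sample_id %in% colnames(scaled)))
  cond <- .condition_id(samples$afatinib, samples$osimertinib)
  conds <- unique(data.frame(condition = cond,
                             afatinib = samples$afatinib,
                             osimertinib = samples$osimertinib,
                             stringsAsFactors = FALSE))
  vehicle <- conds$condition[conds$afatinib == 0 & conds$osimertinib == 0]
  if (length(vehicle) != 1L)
    stop("exactly one vehicle condition (afatinib = osimertinib = 0) required")
  sc <- unclass(scaled)[, samples$sample_id, drop = FALSE]
  means <- t(apply(sc, 1L, function(r) tapply(r, cond, mean)))
  cvs <- t(apply(sc, 1L, function(r)
    tapply(r, cond, function(x) stats::sd(x) / mean(x))))
  rownames(means) <- rownames(cvs) <- rownames(sc)
  means <- means[, conds$condition, drop = FALSE]
  cvs <- cvs[, conds$condition, drop = FALSE]
  veh_mean <- means[, vehicle]
  values <- means / veh_mean
  values[veh_mean == 0, ] <- NA_real_
  structure(list(values = values, replicate_cv = cvs, conditions = conds,
                 vehicle_condition = vehicle,
                 undefined_variants = rownames(means)[veh_mean == 0]),
            class = "growth_inhibition")
}

#' Competition-assay proliferation trajectories
#'
#' Normalises per-day variant counts to pool proportions and fits, per
#' variant, a least-squares slope of log proportion against day: the relative
#' proliferation rate in the mixed culture (day units, natural log scale).
#'
#' @param variant_counts Variant x day numeric matrix (columns ordered as
#'   `days`); counts or scaled abundances.
#' @param days Numeric sampling days, e.g. `c(0, 2, 4, 7)`.
#' @return A `competition_trajectory`: list with `proportions` (columns sum
#'   to 1), `relative_proliferation` (per-variant slope; `NA`, flagged, for
#'   variants with a zero count at any day) and `days`.
#' @export
competition_trajectory <- function(variant_counts, days) {
  stopifnot(ncol(variant_counts) == length(days), length(days) >= 2L)
  props <- sweep(variant_counts, 2, colSums(variant_counts), "/")
  colnames(props) <- as.character(days)
  dc <- days - mean(days)
  denom <- sum(dc^2)
  slope <- apply(props, 1L, function(p) {
    if (any(p <= 0)) return(NA_real_)
    sum(dc * (log(p) - mean(log(p)))) / denom
  })
  structure(list(proportions = props, relative_proliferation = slope,
                 days = days,
                 flagged = rownames(props)[is.na(slope)]),
            class = "competition_trajectory")
}
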