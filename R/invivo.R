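#' Ellipsoidal tumor volume from caliper diameters
#'
#' `V = pi/6 * L * S^2` (mm^3) for large diameter L and small diameter S in
#' mm. Inputs with `small > large` are swapped with a warning.
#'
#' @param large,small Caliper diameters in mm (vectorised).
#' @return Tumor volumes in mm^3.
#' @export
tumor_volume <- function(large, small) {
  stopifnot(all(large > 0), all(small > 0))
  swap <- small > large
  if (any(swap)) {
    warning(sum(swap), " observation(s) had small > large diameter; swapped")
    tmp <- large[swap]; large[swap] <- small[swap]; small[swap] <- tmp
  }
  pi / 6 * large * small^2
}

#' Intratumoral variant proportions and reference-scaled abundance
#'
#' Collapses per-tumor barcode counts to variant level, normalises to
#' proportions (summing to 1 per tumor) and scales to the in vivo reference
#' clone (the GFP clone by default).
#'
#' @param counts Barcode x tumor count matrix (or a `count_table`).
#' @param map A [barcode_map()].
#' @param reference_id Reference variant for scaling.
#' @param pseudocount Passed to [scale_to_reference()].
#' @return List with `proportions` (variant x tumor, columns sum to 1),
#'   `scaled` (reference-scaled abundance), `variant_counts`.
#' @export
variant_proportions <- function(counts, map = NULL, reference_id = "GFP",
                                pseudocount = 0.5) {
  vc <- collapse_clones(counts, map)
  props <- sweep(vc, 2, colSums(vc), "/")
  scaled <- scale_to_reference(vc, reference_id, pseudocount)
  list(proportions = props, scaled = scaled, variant_counts = vc)
}

#' Per-variant relative tumor volume (RTV)
#'
#' Decomposes each arm's tumor burden into per-variant "volumes"
#' (mean variant proportion x mean total tumor volume) and ratios treated
#' over vehicle at a fixed day:
#' `rtv_v = (mean prop_treated_v * mean vol_treated) /
#'          (mean prop_vehicle_v * mean vol_vehicle)`.
#' Summed over variants the decomposition reproduces each arm's mean total
#' volume, so the abundance-weighted mean RTV equals the total-volume ratio.
#'
#' @param prop_treated,prop_vehicle Variant x mouse proportion matrices for
#'   the two arms at the comparison day.
#' @param vol_treated,vol_vehicle Total tumor volumes (mm^3) of the same
#'   mice.
#' @return A `rtv_table` data.frame: `variant_id`, `rtv`,
#'   `treated_volume`, `vehicle_volume` (the per-variant decomposed
#'   volumes); variants absent from the vehicle arm get `NA` and are kept,
#'   flagged by the `undefined` column.
#' @export
relative_tumor_volume <- function(prop_treated, prop_vehicle,
                                  vol_treated, vol_vehicle) {
  shared <- intersect(rownames(prop_treated), rownames(prop_vehicle))
  if (!length(shared)) stop("no shared variants between arms")
  pt <- rowMeans(prop_treated[shared, , drop = FALSE])
  pv <- rowMeans(prop_vehicle[shared, , drop = FALSE])
  tv <- pt * mean(vol_treated)
  vv <- pv * mean(vol_vehicle)
  rtv <- ifelse(vv > 0, tv / vv, NA_real_)
  structure(data.frame(variant_id = shared, rtv = rtv,
                       treated_volume = tv, vehicle_volume = vv,
                       undefined = vv <= 0,
                       row.names = NULL, stringsAsFactors = FALSE),
            class = c("rtv_table", "data.frame"))
}

#' Threshold RTVs into in vivo sensitivity categories
#'
#' Reuses the in vitro survival cutpoints on RTV for comparability:
#' rtv < 0.2 `sensitive`, 0.2-0.5 `partially_resistant`, >= 0.5 `resistant`.
#'
#' @param rtv A `rtv_table` (or data.frame with `variant_id` and `rtv`).
#' @param thresholds Two increasing cutpoints.
#' @return data.frame `variant_id`, `category`.
#' @export
invivo_calls <- function(rtv, thresholds = c(0.2, 0.5)) {
  data.frame(variant_id = rtv$variant_id,
             category = .call_category(rtv$rtv, thresholds),
             stringsAsFactors = FALSE)
}

#' Concordance between two sensitivity call tables
#'
#' Fraction of shared variants with identical categories (undetermined calls
#' excluded). Symmetric in its arguments and invariant to variant order.
#'
#' @param calls_a,calls_b data.frames with `variant_id` and `category`.
#' @return List with `n_compared`, `n_matching`, `pct` (rounded to one
#'   decimal).
#' @export
call_concordance <- function(calls_a, calls_b) {
  shared <- intersect(calls_a$variant_id, calls_b$variant_id)
  if (!length(shared)) stop("no overlapping variants to compare")
  a <- as.character(calls_a$category[match(shared, calls_a$variant_id)])
  b <- as.character(calls_b$category[match(shared, calls_b$variant_id)])
  keep <- a != "undetermined" & b != "undetermined"
  a <- a[keep]; b <- b[keep]
  list(n_compared = length(a), n_matching = sum(a == b),
       pct = round(100 * sum(a == b) / length(a), 1))
}

#' Paired two-sided t test between matched groups
#'
#' Standard paired t test on per-variant (or per-mouse) values matched by a
#' pairing key. Zero variance of the paired differences is flagged instead
#' of producing a spurious p value.
#'
#' @param x,y Numeric vectors of matched observations.
#' @param keys_x,keys_y Optional pairing keys; when given, observations are
#'   matched on the shared keys.
#' @return List with `t`, `df`, `p`, `mean_difference`, `n_pairs`,
#'   `degenerate` (TRUE when the differences have zero variance; `t`/`p` are
#'   then `NA`).
#' @export
paired_group_test <- function(x, y, keys_x = NULL, keys_y = NULL) {
  if (!is.null(keys_x) || !is.null(keys_y)) {
    stopifnot(length(keys_x) == length(x), length(keys_y) == length(y))
    shared <- intersect(keys_x, keys_y)
    x <- x[match(shared, keys_x)]
    y <- y[match(shared, keys_y)]
  }
  stopifnot(length(x) == length(y))
  d <- x - y
  d <- d[stats::complete.cases(d)]
  if (length(d) < 2L) stop("at least 2 complete pairs required")
  if (stats::sd(d) == 0) {
    return(list(t = NA_real_, df = length(d) - 1L, p = NA_real_,
                mean_difference = mean(d), n_pairs = length(d),
                degenerate = TRUE))
  }
  tt <- stats::t.test(d)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_difference = mean(d), n_pairs = length(d),
       degenerate = FALSE)
}
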