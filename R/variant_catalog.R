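#' Read a variant annotation catalog
#'
#' TSV with one row per variant: `variant_id`, `protein_change`,
#' `mutation_type` (missense/insertion/deletion/compound), `exon`, `domain`
#' (ECD/TMD/TKD/RD), `ffa_score` (1-4, focus formation assay),
#' `baf3_transforming` (logical: confers IL-3-independent growth on Ba/F3),
#' `oncokb` (oncogenic / likely_oncogenic / VUS), `cosmic_count`,
#' `genie_count`.
#'
#' @param path TSV path.
#' @return A validated `variant_catalog` data.frame.
#' @export
read_variant_catalog <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_catalog(df)
}

#' Validate a variant catalog
#'
#' @param catalog data.frame with the columns documented in
#'   [read_variant_catalog()].
#' @return The catalog with class `variant_catalog`, or an error naming the
#'   first offending record.
#' @export
validate_catalog <- function(catalog) {
  needed <- c("variant_id", "ffa_score", "baf3_transforming", "oncokb")
  missing <- setdiff(needed, names(catalog))
  if (length(missing))
    stop("catalog lacks columns: ", paste(missing, collapse = ", "))
  bad <- which(!catalog$ffa_score %in% 1:4)
  if (length(bad))
    stop("ffa_score outside 1-4 for record(s): ",
         paste(catalog$variant_id[utils::head(bad, 5)], collapse = ", "))
  if (any(c(catalog$cosmic_count, catalog$genie_count) < 0, na.rm = TRUE))
    stop("database counts must be non-negative")
  structure(catalog, class = unique(c("variant_catalog", class(catalog))))
}

#' Distribution of focus-formation-assay scores
#'
#' @param catalog A variant catalog.
#' @return data.frame with `ffa_score` (1-4), `n`, `pct` (of all records,
#'   rounded to one decimal).
#' @export
ffa_distribution <- function(catalog) {
  catalog <- validate_catalog(catalog)
  n <- as.integer(table(factor(catalog$ffa_score, levels = 1:4)))
  data.frame(ffa_score = 1:4, n = n,
             pct = round(100 * n / nrow(catalog), 1))
}

#' Fractions of variants transforming 3T3 and Ba/F3 cells
#'
#' 3T3 transformation is defined as FFA score >= 2 (any focus formation);
#' Ba/F3 transformation is the recorded IL-3-independence flag.
#'
#' @param catalog A variant catalog.
#' @return List with `n`, `n_3t3`, `pct_3t3`, `n_baf3`, `pct_baf3`
#'   (percentages rounded to one decimal).
#' @export
transformation_summary <- function(catalog) {
  catalog <- validate_catalog(catalog)
  n <- nrow(catalog)
  n3 <- sum(catalog$ffa_score >= 2)
  nb <- sum(catalog$baf3_transforming)
  list(n = n, n_3t3 = n3, pct_3t3 = round(100 * n3 / n, 1),
       n_baf3 = nb, pct_baf3 = round(100 * nb / n, 1))
}

#' FFA-score composition per OncoKB annotation group
#'
#' Cross-tabulates FFA score against OncoKB status and lists the "novel
#' oncogenic" records: strong transformers (FFA score 3 or 4) not annotated
#' as (likely) oncogenic in OncoKB.
#'
#' @param catalog A variant catalog.
#' @return List with `crosstab` (oncokb x ffa_score contingency table) and
#'   `novel_oncogenic` (the qualifying catalog rows).
#' @export
oncokb_crosstab <- function(catalog) {
  catalog <- validate_catalog(catalog)
  tab <- table(oncokb = catalog$oncokb,
               ffa_score = factor(catalog$ffa_score, levels = 1:4))
  novel <- catalog[catalog$ffa_score >= 3 &
                     !catalog$oncokb %in% c("oncogenic", "likely_oncogenic"), ,
                   drop = FALSE]
  list(crosstab = tab, novel_oncogenic = novel)
}
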