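#!/usr/bin/env Rscript
# Dose-response analysis of the quantified screen: per-variant surfaces,
# three-way sensitivity calls for both drugs, the cross-resistance summary,
# Bliss synergy scores, and 4PL IC50 fits for two osimertinib-resistant
# archetype variants.

suppressPackageStartupMessages(library(manoscreen))

gi_df <- read.delim("results/growth_inhibition.tsv", row.names = 1,
                    check.names = FALSE)
gi <- structure(list(values = as.matrix(gi_df)), class = "growth_inhibition")
grid <- dose_grid()

calls <- call_variants(gi, grid)
write.table(calls, "results/sensitivity_calls.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
print(table(afatinib = calls$afatinib, osimertinib = calls$osimertinib))

cr <- cross_resistance_summary(calls)
message(sprintf("nonsensitive to >=1 drug: %d/%d (%.1f%%)",
                cr$any_nonsensitive_n, cr$n, cr$any_nonsensitive_pct))
jsonlite::write_json(cr[setdiff(names(cr), "table")],
                     "results/cross_resistance.json", auto_unbox = TRUE)

# Bliss synergy per variant; the growth-rate model is Bliss-independent in
# the rate domain, so measured scores sit near (slightly below) zero
syn <- vapply(rownames(gi$values), function(v)
  suppressWarnings(bliss_synergy(build_surface(gi, grid, v)))$mean_score,
  numeric(1))
message("mean Bliss synergy score across variants: ",
        signif(mean(syn), 3), " points (no synergy expected)")
write.table(data.frame(variant_id = names(syn), mean_score = syn),
            "results/bliss_scores.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# 4PL fits of the osimertinib monotherapy axis: sensitive variants yield
# effective IC50s inside the tested range; resistant variants have no
# transition in range and their fits are flagged (in_range = FALSE)
map_df <- read.delim("results/barcode_map.tsv")
pick <- c(unique(map_df$variant_id[map_df$archetype == "sensitive_both"])[1:2],
          unique(map_df$variant_id[map_df$archetype ==
                                     "osimertinib_resistant"])[1])
fits <- lapply(pick, function(v) {
  surf <- build_surface(gi, grid, v)
  fit_4pl(surf$osimertinib[-1], surf$survival["0", -1])
})
for (i in seq_along(pick))
  message(sprintf("%s osimertinib effective IC50: %s nM (in range: %s)",
                  pick[i], signif(fits[[i]]$ic50 * 1e9, 3),
                  fits[[i]]$in_range))
write.table(data.frame(variant_id = pick,
                       ic50_molar = vapply(fits, `[[`, 1, "ic50"),
                       hill = vapply(fits, `[[`, 1, "hill"),
                       top = vapply(fits, `[[`, 1, "top"),
                       bottom = vapply(fits, `[[`, 1, "bottom"),
                       rss = vapply(fits, `[[`, 1, "rss"),
                       in_range = vapply(fits, `[[`, TRUE, "in_range")),
            "results/fourpl_fits.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
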