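#!/usr/bin/env Rscript
# Simulate the pooled in vitro drug screen: a 40-variant barcoded clone
# panel (plus KRAS_G12V / GFP reference clones) treated for 4 days on the
# 8 x 9 afatinib x osimertinib grid, sequenced at 1e6 reads per sample in
# triplicate. Also emits one vehicle sample as paired FASTQ to exercise the
# read-level pipeline downstream.

suppressPackageStartupMessages(library(manoscreen))
dir.create("results", showWarnings = FALSE)

panel <- make_panel(n_variants = 40, seed = 101)
message("panel: ", nrow(panel), " clones / ",
        length(unique(panel$variant_id)), " variants")

sim <- simulate_screen(panel, grid = dose_grid(), days = 4, depth = 1e6,
                       replicates = 3, seed = 102)
message("screen: ", nrow(sim$samples), " samples over ",
        sim$grid$n_combinations, " drug combinations (+ monotherapies and ",
        "vehicle)")

# persist the count table, sample sheet, barcode map and ground truth
write_count_table(sim, tsv = "results/screen_counts.tsv")
write.table(sim$samples, "results/screen_samples.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(cbind(sim$map, init_mass = panel$init_mass,
                  archetype = panel$archetype),
            "results/barcode_map.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(data.frame(variant_id = rownames(sim$truth$relative_survival),
                       sim$truth$relative_survival, check.names = FALSE),
            "results/screen_truth.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

# one vehicle replicate as raw reads (down-sampled to 1e5 pairs)
veh <- sim$samples$sample_id[sim$samples$afatinib == 0 &
                               sim$samples$osimertinib == 0][1]
cnt <- sim$counts[, veh]
cnt <- setNames(as.integer(rmultinom(1, 1e5, cnt / sum(cnt))), names(cnt))
emit_fastq(cnt, read_length = 150, error_rate = 0.001,
           r1 = "results/vehicle_R1.fastq.gz",
           r2 = "results/vehicle_R2.fastq.gz", seed = 103)
message("emitted 1e5 read pairs for vehicle sample ", veh)
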