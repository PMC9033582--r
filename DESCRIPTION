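Package: manoscreen
Title: Pooled Barcoded Variant Drug-Sensitivity Screening by the MANO Method
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for pooled competition screens of barcoded
    variant-expressing clones (the "mixed-all-nominated-in-one", MANO,
    method). Extracts 10-bp DNA barcodes embedded in fixed flanking context
    from paired-end FASTQ reads, builds per-sample count tables,
    reference-scales clone abundances, computes relative growth inhibition
    under drug treatment, builds two-drug dose-response surfaces with
    sensitivity classification and Bliss-independence synergy scoring, fits
    four-parameter logistic viability curves, analyses heterogeneous-tumor
    xenograft clonal dynamics under sequential drug regimens (tumor volumes,
    intratumoral variant proportions, per-variant relative tumor volume,
    in vitro/in vivo concordance), summarises variant annotation catalogs,
    and generates fully synthetic screens (clone panels, count tables,
    FASTQ reads, xenograft trajectories) with known ground truth for
    end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
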