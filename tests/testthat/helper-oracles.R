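# Independent oracles used to cross-check the implementation.

# Plain regular-expression scan for flank5-barcode-flank3 (exact match,
# forward orientation only). Deliberately does not share code with
# extract_barcodes().
oracle_scan <- function(reads, flank5 = "CTAGACTGCC", flank3 = "GGATCACTCT",
                        barcode_length = 10L) {
  pat <- paste0(flank5, "([ACGTN]{", barcode_length, "})", flank3)
  vapply(reads, function(r) {
    m <- regexec(pat, r)[[1]]
    if (m[1] == -1L) return(NA_character_)
    substr(r, m[2], m[2] + attr(m, "match.length")[2] - 1L)
  }, character(1), USE.NAMES = FALSE)
}

# Base-R reverse complement, independent of Biostrings.
oracle_revcomp <- function(seqs) {
  vapply(seqs, function(s) {
    chartr("ACGT", "TGCA",
           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

# Brute-force per-cell Bliss score recomputation with explicit loops.
oracle_bliss <- function(surface) {
  inh <- pmin(pmax(surface$inhibition, 0), 1)
  na <- length(surface$afatinib); no <- length(surface$osimertinib)
  scores <- matrix(NA_real_, na - 1L, no - 1L)
  for (i in 2:na) {
    for (j in 2:no) {
      ea <- inh[i, 1]; eo <- inh[1, j]
      scores[i - 1L, j - 1L] <- 100 * (inh[i, j] - (ea + eo - ea * eo))
    }
  }
  scores
}

# Random background reads with the context planted at a known offset.
plant_reads <- function(barcodes, read_length = 80L,
                        flank5 = "CTAGACTGCC", flank3 = "GGATCACTCT") {
  n <- length(barcodes)
  vapply(seq_len(n), function(i) {
    ins <- paste0(flank5, barcodes[i], flank3)
    pad <- read_length - nchar(ins)
    left <- sample.int(pad + 1L, 1L) - 1L
    paste0(paste(sample(c("A", "C", "G", "T"), left, TRUE), collapse = ""),
           ins,
           paste(sample(c("A", "C", "G", "T"), pad - left, TRUE),
                 collapse = ""))
  }, character(1))
}

random_barcode_set <- function(n, length = 10L) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, paste(sample(c("A", "C", "G", "T"), length,
                                      replace = TRUE), collapse = "")))
  }
  out
}

# Small screen pipeline: simulated counts -> variant-level inhibition.
run_screen_pipeline <- function(sim) {
  vc <- collapse_clones(sim$counts, sim$map)
  sa <- scale_to_reference(vc, "KRAS_G12V")
  relative_growth_inhibition(sa, sim$samples)
}
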