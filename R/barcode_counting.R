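#' Barcode extraction context
#'
#' Describes where the clone barcode sits inside a sequencing read: a fixed
#' 5' flank, `barcode_length` arbitrary bases, then a fixed 3' flank
#' (`5'-CTAGACTGCC-XXXXXXXXXX-GGATCACTCT-3'` by default, the amplicon design
#' used by the MANO method). Flanks may be matched with up to
#' `max_flank_mismatches` substitutions each; the barcode itself is taken
#' verbatim (any 10-mer is a priori a valid barcode, so errors inside it are
#' unrecoverable and surface later as unassigned barcodes).
#'
#' @param flank5,flank3 Fixed upstream/downstream DNA context, uppercase ACGT.
#' @param barcode_length Number of barcode bases between the flanks.
#' @param max_flank_mismatches Maximum Hamming distance tolerated per flank.
#' @param search_reverse_complement Also scan the reverse complement of each
#'   read.
#' @return An object of class `barcode_context`.
#' @export
barcode_context <- function(flank5 = "CTAGACTGCC",
                            flank3 = "GGATCACTCT",
                            barcode_length = 10L,
                            max_flank_mismatches = 0L,
                            search_reverse_complement = TRUE) {
  stopifnot(is.character(flank5), length(flank5) == 1L, nzchar(flank5),
            is.character(flank3), length(flank3) == 1L, nzchar(flank3))
  if (grepl("[^ACGT]", flank5) || grepl("[^ACGT]", flank3))
    stop("flank sequences must be uppercase DNA over {A,C,G,T}")
  barcode_length <- as.integer(barcode_length)
  max_flank_mismatches <- as.integer(max_flank_mismatches)
  if (barcode_length < 1L) stop("barcode_length must be >= 1")
  if (max_flank_mismatches < 0L ||
      max_flank_mismatches >= min(nchar(flank5), nchar(flank3)))
    stop("max_flank_mismatches must be in [0, min(flank lengths))")
  structure(list(flank5 = flank5, flank3 = flank3,
                 barcode_length = barcode_length,
                 max_flank_mismatches = max_flank_mismatches,
                 search_reverse_complement = isTRUE(search_reverse_complement)),
            class = "barcode_context")
}

#' @export
print.barcode_context <- function(x, ...) {
  cat(sprintf("barcode context: 5'-%s-[%d bp]-%s-3' (<=%d mismatch/flank%s)\n",
              x$flank5, x$barcode_length, x$flank3, x$max_flank_mismatches,
              if (x$search_reverse_complement) ", both strands" else ""))
  invisible(x)
}

.as_char_reads <- function(x) {
  if (inherits(x, "DNAStringSet")) return(as.character(x))
  if (is.character(x)) return(toupper(x))
  stop("reads must be a character vector or DNAStringSet")
}

.revcomp <- function(seqs) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seqs)))
}

# Scan one orientation of a set of reads for flank5-barcode-flank3.
# Returns the barcode of the leftmost valid placement per read, NA otherwise.
.scan_reads <- function(seqs, context) {
  out <- rep(NA_character_, length(seqs))
  if (!length(seqs)) return(out)
  subj <- Biostrings::DNAStringSet(seqs)
  m <- Biostrings::vmatchPattern(context$flank5, subj,
                                 max.mismatch = context$max_flank_mismatches)
  ends <- Biostrings::endIndex(m)
  bl <- context$barcode_length
  l3 <- nchar(context$flank3)
  p3 <- charToRaw(context$flank3)
  k <- context$max_flank_mismatches
  nc <- nchar(seqs)
  for (i in which(lengths(ends) > 0L)) {
    e5s <- ends[[i]]
    if (length(e5s) > 1L) e5s <- sort(e5s)
    for (e5 in e5s) {
      e_bc <- e5 + bl
      if (e_bc + l3 > nc[i] || e5 < 1L) next
      cand3 <- charToRaw(substr(seqs[i], e_bc + 1L, e_bc + l3))
      if (sum(cand3 != p3) <= k) {
        out[i] <- substr(seqs[i], e5 + 1L, e_bc)
        break
      }
    }
  }
  out
}

#' Extract clone barcodes from (paired) reads
#'
#' Locates the fixed flanking context in each read pair and pulls out the
#' intervening barcode. Search order: mate 1 forward, mate 1 reverse
#' complement, mate 2 forward, mate 2 reverse complement (reverse-complement
#' stages only when enabled in the context); the first stage that yields a
#' valid placement wins, and within a read the leftmost valid placement is
#' used.
#'
#' @param reads1 Character vector or `Biostrings::DNAStringSet` of mate-1
#'   sequences.
#' @param reads2 Optional mate-2 sequences (same length as `reads1`).
#' @param context A [barcode_context()].
#' @return Character vector, one element per read pair: the extracted barcode
#'   or `NA` when no placement matches (`no_context`).
#' @export
extract_barcodes <- function(reads1, reads2 = NULL,
                             context = barcode_context()) {
  stopifnot(inherits(context, "barcode_context"))
  r1 <- .as_char_reads(reads1)
  stages <- list(r1)
  if (context$search_reverse_complement) stages <- c(stages, list(.revcomp(r1)))
  if (!is.null(reads2)) {
    r2 <- .as_char_reads(reads2)
    if (length(r2) != length(r1))
      stop("reads1 and reads2 must have the same length")
    stages <- c(stages, list(r2))
    if (context$search_reverse_complement)
      stages <- c(stages, list(.revcomp(r2)))
  }
  bc <- rep(NA_character_, length(r1))
  for (stage in stages) {
    todo <- which(is.na(bc))
    if (!length(todo)) break
    hit <- .scan_reads(stage[todo], context)
    bc[todo] <- hit
  }
  bc
}

#' Read a barcode map table
#'
#' Three-column TSV with header `barcode`, `variant_id`, `clone_index`.
#' Reference (control) variants such as `KRAS_G12V` or `GFP` may be flagged
#' through `reference_ids`.
#'
#' @param path TSV file path.
#' @param reference_ids Character vector of control variant ids.
#' @return A `barcode_map` data.frame.
#' @export
read_barcode_map <- function(path, reference_ids = character()) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  barcode_map(df$barcode, df$variant_id, df$clone_index, reference_ids)
}

#' Construct a barcode map
#'
#' @param barcode,variant_id,clone_index Parallel vectors (one row per clone).
#' @param reference_ids Control variant ids (must be a subset of
#'   `variant_id`).
#' @return A data.frame of class `barcode_map`.
#' @export
barcode_map <- function(barcode, variant_id, clone_index,
                        reference_ids = character()) {
  stopifnot(length(barcode) == length(variant_id),
            length(barcode) == length(clone_index))
  if (anyDuplicated(barcode)) stop("barcodes must be unique")
  clones_per_variant <- table(variant_id)
  if (any(clones_per_variant > 3L))
    stop("each variant may have at most 3 clones")
  if (!all(reference_ids %in% variant_id))
    stop("reference_ids must be present among variant ids")
  structure(data.frame(barcode = as.character(barcode),
                       variant_id = as.character(variant_id),
                       clone_index = as.integer(clone_index),
                       stringsAsFactors = FALSE),
            reference_ids = as.character(reference_ids),
            class = c("barcode_map", "data.frame"))
}

#' Tally extracted barcodes for one sample
#'
#' @param barcodes Output of [extract_barcodes()] (extracted barcode or `NA`
#'   per read pair).
#' @param map A [barcode_map()].
#' @return List with `counts` (named integer vector over the map's barcodes),
#'   `unassigned` (valid context, unknown barcode), `no_context`, and `total`;
#'   `assigned + unassigned + no_context == total` always.
#' @export
count_sample <- function(barcodes, map) {
  stopifnot(inherits(map, "barcode_map"), nrow(map) > 0L)
  if (!length(barcodes)) warning("no reads in input; empty count column")
  f <- factor(barcodes, levels = map$barcode)
  counts <- table(f)
  counts <- stats::setNames(as.integer(counts), map$barcode)
  no_context <- sum(is.na(barcodes))
  unassigned <- length(barcodes) - no_context - sum(counts)
  list(counts = counts, unassigned = unassigned,
       no_context = no_context, total = length(barcodes))
}

#' Count barcodes across samples into a count table
#'
#' @param read_sets Named list; each element is a list with `reads1` and
#'   optionally `reads2` (character vectors or `DNAStringSet`s), one element
#'   per sample.
#' @param map A [barcode_map()].
#' @param context A [barcode_context()].
#' @param samples Optional data.frame of sample descriptors with a
#'   `sample_id` column matching `names(read_sets)`.
#' @return A `count_table`: list with `counts` (barcode x sample integer
#'   matrix), `unassigned`, `no_context`, `total` (per-sample vectors), `map`
#'   and `samples`.
#' @export
count_table <- function(read_sets, map, context = barcode_context(),
                        samples = NULL) {
  stopifnot(is.list(read_sets), length(read_sets) > 0L,
            !is.null(names(read_sets)))
  cols <- lapply(read_sets, function(rs) {
    bc <- extract_barcodes(rs$reads1, rs$reads2, context)
    count_sample(bc, map)
  })
  counts <- vapply(cols, function(x) x$counts, integer(nrow(map)))
  dimnames(counts) <- list(map$barcode, names(read_sets))
  structure(list(counts = counts,
                 unassigned = vapply(cols, `[[`, numeric(1), "unassigned"),
                 no_context = vapply(cols, `[[`, numeric(1), "no_context"),
                 total = vapply(cols, `[[`, numeric(1), "total"),
                 map = map, samples = samples),
            class = "count_table")
}

#' Count barcodes directly from FASTQ files
#'
#' @param r1,r2 FASTQ(.gz) paths (`r2` optional), one pair per sample.
#' @param sample_ids Sample names (defaults to `basename(r1)`).
#' @inheritParams count_table
#' @return A `count_table` (see [count_table()]).
#' @export
count_fastq <- function(r1, r2 = NULL, map, context = barcode_context(),
                        sample_ids = NULL, samples = NULL) {
  if (is.null(sample_ids)) sample_ids <- basename(r1)
  read_sets <- lapply(seq_along(r1), function(i) {
    rs <- list(reads1 = read_fastq_seqs(r1[i]))
    if (!is.null(r2)) rs$reads2 <- read_fastq_seqs(r2[i])
    rs
  })
  names(read_sets) <- sample_ids
  count_table(read_sets, map, context, samples)
}

#' Read the sequences of a FASTQ(.gz) file
#'
#' Thin wrapper over `Biostrings::readDNAStringSet(format = "fastq")` that
#' names the offending file on malformed input.
#'
#' @param path FASTQ or gzipped FASTQ file.
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) stop("malformed FASTQ input '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  as.character(seqs)
}

#' @export
print.count_table <- function(x, ...) {
  cat(sprintf("count_table: %d barcodes x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat(sprintf("  reads: %s assigned / %s unassigned / %s no-context\n",
              format(sum(x$counts)), format(sum(x$unassigned)),
              format(sum(x$no_context))))
  invisible(x)
}

#' Write a count table and its conservation sidecar
#'
#' @param ct A `count_table`.
#' @param tsv Output TSV path (rows = barcodes, columns = samples).
#' @param json Optional JSON sidecar with per-sample assigned / unassigned /
#'   no-context tallies.
#' @return Invisibly, `ct`.
#' @export
write_count_table <- function(ct, tsv, json = NULL) {
  df <- data.frame(barcode = rownames(ct$counts), ct$counts,
                   check.names = FALSE)
  utils::write.table(df, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(json)) {
    side <- list(samples = colnames(ct$counts),
                 assigned = unname(colSums(ct$counts)),
                 unassigned = unname(ct$unassigned),
                 no_context = unname(ct$no_context),
                 total = unname(ct$total))
    jsonlite::write_json(side, json, auto_unbox = FALSE, digits = NA)
  }
  invisible(ct)
}
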