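#' Read a FASTQ file into read records
#'
#' @param path FASTQ file (optionally gzipped).
#' @return list of read records, each a list with `id`, `sequence`, and
#'   integer `qualities` (Phred scores).
#' @export
read_fastq <- function(path) {
  # (Biostrings warns about dropping its own metadata columns here)
  seqs <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(path))
  quals <- methods::as(Biostrings::quality(seqs), "IntegerList")
  lapply(seq_along(seqs), function(i) {
    list(id = names(seqs)[i], sequence = as.character(seqs[[i]]),
         qualities = as.integer(quals[[i]]))
  })
}

#' Trim a 3' adapter from a read
#'
#' Removes the first occurrence of the adapter found in the read, or an
#' adapter prefix of at least `min_overlap` nt matching the read's 3' end
#' (the adapter running off the end of the read). Trimming is repeated until
#' no match remains, which makes the operation idempotent. Matching is exact
#' (no mismatches).
#'
#' @param read a read record (`id`, `sequence`, `qualities`).
#' @param adapter adapter sequence (non-empty).
#' @param min_len reads shorter than this after trimming are discarded
#'   (`NULL` returned).
#' @param min_overlap minimum adapter prefix length matched at the 3' end.
#' @return the trimmed read record, or `NULL` if discarded.
#' @export
trim_adapter <- function(read, adapter, min_len = 15L, min_overlap = 3L) {
  stopifnot(nzchar(adapter))
  seq <- read$sequence
  repeat {
    cut <- NA_integer_
    hit <- regexpr(adapter, seq, fixed = TRUE)
    if (hit > 0L) {
      cut <- as.integer(hit) - 1L  # keep bases before the adapter
    } else {
      for (k in seq(min(nchar(adapter) - 1L, nchar(seq)), min_overlap)) {
        if (k < min_overlap) break
        if (substr(seq, nchar(seq) - k + 1L, nchar(seq)) ==
            substr(adapter, 1L, k)) {
          cut <- nchar(seq) - k
          break
        }
      }
    }
    if (is.na(cut)) break
    seq <- substr(seq, 1L, cut)
  }
  if (nchar(seq) < min_len) return(NULL)
  read$sequence <- seq
  read$qualities <- read$qualities[seq_len(nchar(seq))]
  read
}

#' Quality-filter a read
#'
#' Keeps a read when its Phred quality exceeds the threshold. The published
#' cutoff ("Phred quality score > 33") does not say whether it is per-base
#' or averaged; the default interprets it as the mean base quality, with
#' `mode = "min"` requiring every base to exceed the threshold.
#'
#' @param read a read record.
#' @param threshold Phred threshold (default 33).
#' @param mode `"mean"` (default) or `"min"`.
#' @return `TRUE` (keep) or `FALSE` (discard); empty reads are discarded.
#' @export
filter_quality <- function(read, threshold = 33, mode = c("mean", "min")) {
  mode <- match.arg(mode)
  q <- read$qualities
  if (!length(q)) return(FALSE)
  if (mode == "mean") mean(q) > threshold else min(q) > threshold
}

#' Layered contaminant and multimapper filtering
#'
#' Reproduces the layered alignment bookkeeping: reads aligning to rRNA,
#' tRNA or snRNA are discarded first, then only reads with exactly one
#' transcriptome alignment are kept. Contaminant status and alignment counts
#' are inputs (precomputed flags); no alignment is performed here.
#'
#' @param alignments data frame of candidate fragments.
#' @param contaminant flags, logical vector (TRUE = rRNA/tRNA/snRNA hit).
#' @param n_hits integer vector, number of transcriptome alignments per read.
#' @return list with `fragments` (the survivors) and `stats`, a
#'   `library_stats` list (`total_reads`, `reads_after_contaminant_removal`,
#'   `unique_mapped_reads`).
#' @export
layered_filter <- function(alignments, contaminant, n_hits) {
  stopifnot(nrow(alignments) == length(contaminant),
            nrow(alignments) == length(n_hits))
  keep1 <- !contaminant
  keep2 <- keep1 & n_hits == 1L
  stats <- structure(list(total_reads = nrow(alignments),
                          reads_after_contaminant_removal = sum(keep1),
                          unique_mapped_reads = sum(keep2)),
                     class = "library_stats")
  list(fragments = alignments[keep2, , drop = FALSE], stats = stats)
}

#' @export
print.library_stats <- function(x, ...) {
  cat(sprintf("reads: %d total, %d after rRNA/tRNA/snRNA removal, %d uniquely mapped\n",
              x$total_reads, x$reads_after_contaminant_removal,
              x$unique_mapped_reads))
  invisible(x)
}

#' Write library statistics as JSON
#'
#' @param stats a `library_stats` object (or named list of them).
#' @param path output path.
#' @export
write_library_stats <- function(stats, path) {
  jsonlite::write_json(unclass(stats), path, auto_unbox = TRUE)
  invisible(path)
}
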