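#' Transcript models
#'
#' A `transcript_set` holds one canonical transcript model per gene: the
#' spliced transcript sequence together with the extents of its functional
#' regions (5'UTR, CDS, 3'UTR) in transcript coordinates. All coordinates in
#' the package are 0-based, half-open: the CDS occupies
#' `[utr5_len, utr5_len + cds_len)` and codon `k` of the CDS occupies
#' nucleotides `[3k, 3k + 3)` relative to the CDS start.
#'
#' @param gene_id character vector of gene identifiers (unique).
#' @param sequence character vector of transcript sequences (A/C/G/T).
#' @param utr5_len,cds_len,utr3_len integer region lengths; `cds_len` must be
#'   a multiple of 3 and at least 6 (start codon plus stop codon).
#' @return A data frame of class `transcript_set` with one row per gene.
#' @export
transcript_set <- function(gene_id, sequence, utr5_len, cds_len, utr3_len) {
  sequence <- toupper(gsub("U", "T", sequence, fixed = TRUE))
  ts <- data.frame(
    gene_id = as.character(gene_id),
    sequence = as.character(sequence),
    utr5_len = as.integer(utr5_len),
    cds_len = as.integer(cds_len),
    utr3_len = as.integer(utr3_len),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(ts$gene_id)) stop("duplicated gene_id in transcript_set")
  if (any(ts$cds_len < 6L)) stop("cds_len must be at least 6 nt")
  if (any(ts$cds_len %% 3L != 0L)) stop("cds_len must be a multiple of 3")
  if (any(nchar(ts$sequence) != ts$utr5_len + ts$cds_len + ts$utr3_len))
    stop("sequence length must equal utr5_len + cds_len + utr3_len")
  if (any(grepl("[^ACGT]", ts$sequence)))
    stop("sequences may only contain A, C, G, T (or U)")
  class(ts) <- c("transcript_set", "data.frame")
  ts
}

#' @export
print.transcript_set <- function(x, ...) {
  cat(sprintf("transcript_set: %d transcripts\n", nrow(x)))
  if (nrow(x)) {
    cat(sprintf("  5'UTR %d-%d nt, CDS %d-%d nt, 3'UTR %d-%d nt\n",
                min(x$utr5_len), max(x$utr5_len),
                min(x$cds_len), max(x$cds_len),
                min(x$utr3_len), max(x$utr3_len)))
  }
  invisible(x)
}

# transcript length in nt
tx_length <- function(ts) ts$utr5_len + ts$cds_len + ts$utr3_len

#' Select one canonical isoform per gene
#'
#' Collapses a multi-isoform annotation to one transcript per gene. A tagged
#' canonical isoform wins; otherwise the longest CDS, then the longest
#' transcript, then the lexicographically smallest transcript id.
#'
#' @param isoforms data frame with columns `gene_id`, `transcript_id`,
#'   `cds_len`, `tx_len`, and optionally a logical `canonical` tag.
#' @return data frame with one row per gene (same columns).
#' @export
select_canonical <- function(isoforms) {
  stopifnot(all(c("gene_id", "transcript_id", "cds_len", "tx_len") %in%
                  names(isoforms)))
  iso <- isoforms[!is.na(isoforms$transcript_id), , drop = FALSE]
  dropped <- setdiff(unique(isoforms$gene_id), unique(iso$gene_id))
  if (length(dropped))
    warning(sprintf("%d gene(s) with zero isoforms excluded: %s",
                    length(dropped), paste(dropped, collapse = ", ")))
  pick <- function(d) {
    if ("canonical" %in% names(d) && any(d$canonical %in% TRUE))
      d <- d[d$canonical %in% TRUE, , drop = FALSE]
    d <- d[order(-d$cds_len, -d$tx_len, d$transcript_id), , drop = FALSE]
    d[1L, , drop = FALSE]
  }
  out <- do.call(rbind, lapply(split(iso, iso$gene_id), pick))
  rownames(out) <- NULL
  out
}

#' Write transcript models to FASTA + region table
#'
#' @param ts a [transcript_set].
#' @param fasta,tsv output paths for the sequence FASTA and the BED-like
#'   region table (`gene_id`, `utr5_len`, `cds_len`, `utr3_len`).
#' @return invisibly, the paths.
#' @export
write_transcripts <- function(ts, fasta, tsv) {
  seqs <- Biostrings::DNAStringSet(ts$sequence)
  names(seqs) <- ts$gene_id
  Biostrings::writeXStringSet(seqs, fasta)
  utils::write.table(ts[, c("gene_id", "utr5_len", "cds_len", "utr3_len")],
                     tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(fasta = fasta, tsv = tsv))
}

#' Read transcript models from FASTA + region table
#'
#' @param fasta,tsv paths written by [write_transcripts()].
#' @return a [transcript_set].
#' @export
read_transcripts <- function(fasta, tsv) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  reg <- utils::read.delim(tsv, stringsAsFactors = FALSE)
  i <- match(reg$gene_id, names(seqs))
  if (anyNA(i)) stop("gene_id mismatch between FASTA and region table")
  transcript_set(reg$gene_id, as.character(seqs[i]),
                 reg$utr5_len, reg$cds_len, reg$utr3_len)
}
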