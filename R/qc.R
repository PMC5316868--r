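# QC positions: ribosome footprints are located by their A-site, RNA reads
# by their 5' end (RNA reads have no ribosome geometry to offset).
qc_positions <- function(fragments, transcripts) {
  i <- match(fragments$transcript_id, transcripts$gene_id)
  if (anyNA(i)) stop("fragments refer to unknown transcripts")
  pos <- ifelse(fragments$library == "Ribo",
                fragments$pos5 + asite_offset(fragments$length),
                fragments$pos5)
  list(pos = as.integer(pos), tx = i)
}

#' Fragment length histogram
#'
#' @param fragments fragment data frame.
#' @return named integer vector of counts per observed fragment length
#'   (names are lengths, ascending); sums to the number of fragments.
#' @export
length_histogram <- function(fragments) {
  if (!nrow(fragments)) return(integer(0))
  tab <- table(fragments$length)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' Read distribution over functional regions
#'
#' Fraction of assigned positions (A-site for Ribo, 5' end for RNA) falling
#' in the 5'UTR, CDS and 3'UTR. Positions outside the transcript are
#' excluded and counted in `attr(,"n_excluded")`.
#'
#' @param fragments fragment data frame.
#' @param transcripts a [transcript_set].
#' @return named numeric vector of fractions (sums to 1 when any fragment is
#'   assigned).
#' @export
region_distribution <- function(fragments, transcripts) {
  qp <- qc_positions(fragments, transcripts)
  L <- tx_length(transcripts)[qp$tx]
  ok <- qp$pos >= 0L & qp$pos < L
  pos <- qp$pos[ok]; tx <- qp$tx[ok]
  u5 <- transcripts$utr5_len[tx]
  cdse <- u5 + transcripts$cds_len[tx]
  region <- ifelse(pos < u5, "utr5", ifelse(pos < cdse, "cds", "utr3"))
  n <- c(utr5 = sum(region == "utr5"), cds = sum(region == "cds"),
         utr3 = sum(region == "utr3"))
  out <- if (sum(n)) n / sum(n) else n * 0
  attr(out, "n_excluded") <- sum(!ok)
  out
}

#' Triplet periodicity of A-sites within the CDS
#'
#' Frame of each Ribo fragment's A-site relative to the CDS start,
#' `(asite - cds_start) mod 3`; only A-sites inside the CDS are used.
#'
#' @inheritParams region_distribution
#' @return numeric vector of fractions over frames 0/1/2 (sums to 1).
#' @export
frame_periodicity <- function(fragments, transcripts) {
  fr <- fragments[fragments$library == "Ribo", , drop = FALSE]
  qp <- qc_positions(fr, transcripts)
  u5 <- transcripts$utr5_len[qp$tx]
  cdse <- u5 + transcripts$cds_len[qp$tx]
  ok <- qp$pos >= u5 & qp$pos < cdse
  frame <- (qp$pos[ok] - u5[ok]) %% 3L
  n <- tabulate(frame + 1L, nbins = 3L)
  out <- if (sum(n)) n / sum(n) else numeric(3)
  names(out) <- c("frame0", "frame1", "frame2")
  out
}

#' Metagene profile around CDS boundaries
#'
#' Average normalized read density near the start (last 30 nt of the 5'UTR
#' and first 150 nt of the CDS) and the stop (last 150 nt of the CDS and
#' first 30 nt of the 3'UTR). Genes enter the profile only when the 5'UTR
#' and 3'UTR are each at least `min_utr5`/`min_utr3` nt, the CDS at least
#' `min_cds` nt, and at least `min_reads` reads are assigned anywhere on the
#' transcript. Each gene's per-nucleotide read counts are divided by its
#' total mapped reads before averaging, so the profile is invariant to any
#' single gene's depth.
#'
#' @inheritParams region_distribution
#' @param min_utr5,min_utr3,min_cds,min_reads gene filters (defaults 50, 50,
#'   500 nt and 300 reads; all boundaries inclusive).
#' @return object of class `metagene_profile`: list with `start_window` and
#'   `stop_window` (numeric length 180, positions -30..+149 around the CDS
#'   start and -150..+29 around the CDS end) and `n_genes_used`.
#' @export
metagene <- function(fragments, transcripts, min_utr5 = 50L, min_utr3 = 50L,
                     min_cds = 500L, min_reads = 300L) {
  pass_len <- transcripts$utr5_len >= min_utr5 &
    transcripts$utr3_len >= min_utr3 & transcripts$cds_len >= min_cds
  qp <- qc_positions(fragments, transcripts)
  L <- tx_length(transcripts)[qp$tx]
  ok <- qp$pos >= 0L & qp$pos < L
  pos <- qp$pos[ok]; tx <- qp$tx[ok]
  reads_per_gene <- tabulate(tx, nbins = nrow(transcripts))
  use <- which(pass_len & reads_per_gene >= min_reads)
  start_w <- numeric(180L); stop_w <- numeric(180L)
  if (!length(use)) {
    message("metagene: no gene passes the length and read filters")
  } else {
    for (g in use) {
      p <- pos[tx == g]
      dens <- tabulate(p + 1L, nbins = tx_length(transcripts)[g]) / length(p)
      cs <- transcripts$utr5_len[g]
      ce <- cs + transcripts$cds_len[g]
      start_w <- start_w + dens[(cs - 30L):(cs + 149L) + 1L]
      stop_w <- stop_w + dens[(ce - 150L):(ce + 29L) + 1L]
    }
    start_w <- start_w / length(use)
    stop_w <- stop_w / length(use)
  }
  structure(list(start_window = start_w, stop_window = stop_w,
                 n_genes_used = length(use)),
            class = "metagene_profile")
}

#' @export
print.metagene_profile <- function(x, ...) {
  cat(sprintf("metagene_profile over %d gene(s); windows -30..+149 (start), -150..+29 (stop)\n",
              x$n_genes_used))
  invisible(x)
}

#' @export
#' @method plot metagene_profile
plot.metagene_profile <- function(x, ...) {
  graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(mfrow = c(1, 1)))
  graphics::plot(-30:149, x$start_window, type = "h", xlab = "nt from CDS start",
                 ylab = "mean normalized density", main = "CDS start", ...)
  graphics::plot(-150:29, x$stop_window, type = "h", xlab = "nt from CDS end",
                 ylab = "mean normalized density", main = "CDS end", ...)
  invisible(x)
}

#' Library QC report
#'
#' Convenience wrapper computing the four library diagnostics at once.
#'
#' @inheritParams region_distribution
#' @param json optional path; when given, the report is also written as JSON.
#' @return list with `length_histogram`, `region_distribution`,
#'   `frame_periodicity` and `metagene`.
#' @export
qc_report <- function(fragments, transcripts, json = NULL) {
  rep <- list(length_histogram = length_histogram(fragments),
              region_distribution = region_distribution(fragments, transcripts),
              frame_periodicity = frame_periodicity(fragments, transcripts),
              metagene = unclass(metagene(fragments, transcripts)))
  if (!is.null(json))
    jsonlite::write_json(rep, json, auto_unbox = TRUE, digits = NA)
  rep
}
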