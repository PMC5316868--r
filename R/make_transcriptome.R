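STOP_CODONS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(apply(expand.grid(c("A","C","G","T"), c("A","C","G","T"),
                                          c("A","C","G","T")), 1, paste0,
                              collapse = ""), STOP_CODONS)

rand_nt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# positions (0-based) of all ATG occurrences in a sequence
atg_positions <- function(seq) {
  m <- gregexpr("ATG", seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m) - 1L
}

# scrub every ATG not in `keep` (0-based) by replacing its middle base;
# the replacement (T -> C) cannot create a new ATG
scrub_atg <- function(seq, keep = integer(0)) {
  repeat {
    bad <- setdiff(atg_positions(seq), keep)
    if (!length(bad)) return(seq)
    for (p in bad) substr(seq, p + 2L, p + 2L) <- "C"
  }
}

#' Generate a synthetic transcriptome with planted upstream AUGs
#'
#' Builds `n_genes` transcript models with random region lengths. Each CDS
#' begins with AUG, ends with a stop codon and contains no internal in-frame
#' stop. 5'UTRs are scrubbed of accidental AUGs, then a Poisson-distributed
#' number of uAUGs is planted at recorded positions, so that an upstream-ORF
#' scan recovers exactly the planted canonical sites (ground truth stored in
#' `attr(,"uaug_positions")`).
#'
#' @param n_genes number of transcripts to generate.
#' @param length_params list with `utr5`, `cds`, `utr3`, each a `c(min, max)`
#'   nucleotide range. CDS lengths are rounded to codons.
#' @param uorf_params list with `mean_uaugs`, the expected number of planted
#'   uAUGs per 5'UTR (Poisson).
#' @param seed integer seed.
#' @return a [transcript_set] with attribute `uaug_positions` (named list of
#'   0-based uAUG offsets within each 5'UTR).
#' @export
make_transcriptome <- function(n_genes,
                               length_params = list(utr5 = c(60, 300),
                                                    cds = c(300, 1500),
                                                    utr3 = c(60, 300)),
                               uorf_params = list(mean_uaugs = 2),
                               seed = 1L) {
  n_genes <- as.integer(n_genes)
  stopifnot(n_genes >= 0L)
  if (length_params$cds[1] < 6)
    stop("invalid length_params: CDS minimum must be at least 6 nt")
  set.seed(seed)
  if (n_genes == 0L)
    return(structure(transcript_set(character(), character(), integer(),
                                    integer(), integer()),
                     uaug_positions = list()))
  ids <- sprintf("gene%04d", seq_len(n_genes))
  u5 <- integer(n_genes); u3 <- integer(n_genes); cl <- integer(n_genes)
  seqs <- character(n_genes)
  truth <- vector("list", n_genes)
  cod_rng <- pmax(floor(length_params$cds / 3), 2L)
  for (g in seq_len(n_genes)) {
    u5[g] <- sample(length_params$utr5[1]:length_params$utr5[2], 1L)
    u3[g] <- sample(length_params$utr3[1]:length_params$utr3[2], 1L)
    ncod <- sample(cod_rng[1]:cod_rng[2], 1L)
    cl[g] <- 3L * ncod
    cds <- paste0("ATG",
                  paste(sample(SENSE_CODONS, ncod - 2L, replace = TRUE),
                        collapse = ""),
                  sample(STOP_CODONS, 1L))
    utr5 <- scrub_atg(rand_nt(u5[g]))
    # plant uAUGs at positions spaced >= 3 nt so sites cannot overlap
    n_plant <- min(stats::rpois(1L, uorf_params$mean_uaugs),
                   max((u5[g] - 2L) %/% 3L, 0L))
    planted <- integer(0)
    if (n_plant > 0L && u5[g] >= 3L) {
      cand <- sample(0:(u5[g] - 3L))
      for (p in cand) {
        if (length(planted) == n_plant) break
        if (!length(planted) || all(abs(planted - p) >= 3L))
          planted <- c(planted, p)
      }
      planted <- sort(planted)
      for (p in planted) substr(utr5, p + 1L, p + 3L) <- "ATG"
      utr5 <- scrub_atg(utr5, keep = planted)
    }
    truth[[g]] <- planted
    seqs[g] <- paste0(utr5, cds, rand_nt(u3[g]))
  }
  names(truth) <- ids
  structure(transcript_set(ids, seqs, u5, cl, u3), uaug_positions = truth)
}
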