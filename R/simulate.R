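#' Simulation design for paired Ribo-Seq/RNA-Seq counts
#'
#' Describes a synthetic experiment mirroring a developmental ribosome
#' profiling study: `n_replicates` biological replicates, two library types
#' (Ribo, RNA) and one or two tissues. Gene counts are negative-binomial with
#' mean `s_j * mean_expression_g * 2^(log2_te_g)` in Ribo libraries (the
#' mean/dispersion parameterization, `Var = mu + alpha * mu^2`; `alpha = 0`
#' degenerates to Poisson).
#'
#' @param n_genes number of genes.
#' @param n_replicates biological replicates per tissue (default 3).
#' @param tissues character vector of 1 or 2 tissue labels.
#' @param mean_expression per-gene expected RNA CDS count (recycled);
#'   may be a matrix with one column per tissue.
#' @param log2_te per-gene log2 translational efficiency; vector, or a
#'   matrix with one column per tissue when two tissues are simulated.
#' @param dispersion per-gene NB dispersion alpha >= 0 (recycled).
#' @param size_factors per-library positive scaling factors, in the library
#'   order of the design (default all 1).
#' @param seed integer seed fully determining the simulated counts.
#' @return an object of class `sim_design`.
#' @export
sim_design <- function(n_genes, n_replicates = 3L, tissues = "mesoderm",
                       mean_expression = 200, log2_te = 0, dispersion = 0.05,
                       size_factors = NULL, seed = 1L) {
  n_genes <- as.integer(n_genes)
  n_replicates <- as.integer(n_replicates)
  stopifnot(n_genes >= 0L, n_replicates >= 1L,
            length(tissues) %in% 1:2, !anyDuplicated(tissues))
  n_t <- length(tissues)
  mat <- function(x, what) {
    m <- if (is.matrix(x)) x else matrix(rep_len(x, n_genes * n_t), n_genes, n_t)
    if (nrow(m) != n_genes || ncol(m) != n_t)
      stop(sprintf("%s must have n_genes rows and one column per tissue", what))
    m
  }
  mean_expression <- mat(mean_expression, "mean_expression")
  log2_te <- mat(log2_te, "log2_te")
  dispersion <- rep_len(dispersion, n_genes)
  if (any(mean_expression <= 0)) stop("mean_expression must be positive")
  if (any(dispersion < 0)) stop("dispersion must be >= 0")
  libs <- expand.grid(replicate = paste0("rep", seq_len(n_replicates)),
                      library = c("RNA", "Ribo"), tissue = tissues,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  libs$sample <- paste(libs$tissue, libs$library, libs$replicate, sep = "_")
  if (is.null(size_factors)) size_factors <- rep(1, nrow(libs))
  if (length(size_factors) != nrow(libs))
    stop(sprintf("need %d size_factors (one per library)", nrow(libs)))
  if (any(size_factors <= 0)) stop("size_factors must be > 0")
  libs$size_factor <- size_factors
  structure(list(n_genes = n_genes, n_replicates = n_replicates,
                 tissues = tissues, mean_expression = mean_expression,
                 log2_te = log2_te, dispersion = dispersion,
                 libraries = libs, seed = as.integer(seed)),
            class = "sim_design")
}

#' @export
print.sim_design <- function(x, ...) {
  cat(sprintf("sim_design: %d genes, %d replicates x 2 library types x %d tissue(s) = %d libraries\n",
              x$n_genes, x$n_replicates, length(x$tissues), nrow(x$libraries)))
  invisible(x)
}

#' Simulate a gene-by-library count table
#'
#' Draws `K_gj ~ NB(mu = s_j * mean_expression_g * 2^(log2_te_g *
#' is_ribo_j), alpha_g)` for every gene and library of the design. With two
#' tissues, `mean_expression` and `log2_te` are taken per tissue. The RNG is
#' fully determined by `design$seed`.
#'
#' @param design a [sim_design].
#' @return a [count_table].
#' @export
simulate_counts <- function(design) {
  stopifnot(inherits(design, "sim_design"))
  set.seed(design$seed)
  libs <- design$libraries
  G <- design$n_genes
  K <- matrix(0L, G, nrow(libs), dimnames = list(
    if (G) sprintf("gene%04d", seq_len(G)) else NULL, libs$sample))
  for (j in seq_len(nrow(libs))) {
    ti <- match(libs$tissue[j], design$tissues)
    mu <- libs$size_factor[j] * design$mean_expression[, ti] *
      2^(design$log2_te[, ti] * (libs$library[j] == "Ribo"))
    a <- design$dispersion
    k <- numeric(G)
    pois <- a == 0
    if (any(pois)) k[pois] <- stats::rpois(sum(pois), mu[pois])
    if (any(!pois)) k[!pois] <- stats::rnbinom(sum(!pois), mu = mu[!pois],
                                               size = 1 / a[!pois])
    K[, j] <- as.integer(k)
  }
  count_table(K, libs[, c("sample", "library", "replicate", "tissue")])
}

#' Positional profile of simulated ribosome footprints
#'
#' Controls the qualitative hallmarks of a good Ribo-Seq library that the
#' fragment simulator reproduces: a discrete footprint length mode near
#' 30 nt, triplet (3-nt) periodicity of A-sites within the CDS, a majority
#' of footprints on the CDS, and elevated density over the first 15 codons
#' (the start-proximal pileup seen under cycloheximide).
#'
#' @param length_weights named numeric vector of fragment-length
#'   probabilities (names are lengths in nt); default spans 26-36 nt with the
#'   mode at 30.
#' @param frame_bias probabilities of A-site frames 0/1/2 within the CDS.
#' @param ramp_fold relative A-site density over the first 15 codons
#'   (>= 1).
#' @param cds_fraction probability that a Ribo fragment's A-site lies in the
#'   CDS.
#' @return an object of class `fragment_profile`.
#' @export
fragment_profile <- function(length_weights = NULL,
                             frame_bias = c(0.7, 0.15, 0.15),
                             ramp_fold = 3.0, cds_fraction = 0.8) {
  if (is.null(length_weights)) {
    lw <- stats::dnorm(26:36, mean = 30, sd = 1.6)
    names(lw) <- 26:36
    length_weights <- lw / sum(lw)
  }
  if (is.null(names(length_weights)))
    stop("length_weights must be named by fragment length")
  length_weights <- length_weights / sum(length_weights)
  frame_bias <- frame_bias / sum(frame_bias)
  stopifnot(length(frame_bias) == 3L, ramp_fold >= 1,
            cds_fraction >= 0, cds_fraction <= 1)
  structure(list(length_weights = length_weights, frame_bias = frame_bias,
                 ramp_fold = ramp_fold, cds_fraction = cds_fraction),
            class = "fragment_profile")
}

# sample A-site positions for Ribo fragments with a fixed CDS/UTR stratum
# per fragment (0-based transcript positions)
sample_asites <- function(in_cds, utr5, cds, utr3, profile) {
  pos <- integer(length(in_cds))
  ncod <- cds %/% 3L
  if (any(in_cds)) {
    nramp <- min(15L, ncod)
    w <- c(rep(profile$ramp_fold, nramp), rep(1, ncod - nramp))
    codon <- sample.int(ncod, sum(in_cds), replace = TRUE, prob = w) - 1L
    frame <- sample.int(3L, sum(in_cds), replace = TRUE,
                        prob = profile$frame_bias) - 1L
    pos[in_cds] <- utr5 + 3L * codon + frame
  }
  if (any(!in_cds)) {
    # uniform over the UTRs
    nutr <- utr5 + utr3
    u <- sample.int(nutr, sum(!in_cds), replace = TRUE) - 1L
    pos[!in_cds] <- ifelse(u < utr5, u, utr5 + cds + (u - utr5))
  }
  pos
}

#' Simulate positional aligned fragments
#'
#' Expands a count table into per-read aligned fragments on the given
#' transcripts. Ribo fragments are placed so that their A-site (per
#' [asite_offset()]) reproduces the profile's CDS fraction, frame bias and
#' start-proximal ramp; RNA fragments are uniform over the transcript.
#' Fragments that would extend past either transcript end are resampled,
#' never emitted, so the number of fragments per gene and library equals the
#' count table entry exactly.
#'
#' @param transcripts a [transcript_set].
#' @param counts a [count_table] whose genes all appear in `transcripts`.
#' @param profile a [fragment_profile].
#' @param seed integer seed.
#' @return data frame of fragments: `transcript_id`, `pos5` (0-based),
#'   `length`, `library`, `replicate`, `tissue`.
#' @export
simulate_fragments <- function(transcripts, counts, profile = fragment_profile(),
                               seed = 1L) {
  stopifnot(inherits(transcripts, "transcript_set"), inherits(counts, "count_table"))
  idx <- match(rownames(counts$counts), transcripts$gene_id)
  if (anyNA(idx)) stop("count table contains genes absent from transcripts")
  set.seed(seed)
  lens <- as.integer(names(profile$length_weights))
  out <- vector("list", nrow(counts$design) * nrow(counts$counts))
  k <- 0L
  for (j in seq_len(nrow(counts$design))) {
    lib <- counts$design$library[j]
    for (g in seq_len(nrow(counts$counts))) {
      n <- counts$counts[g, j]
      if (n == 0L) next
      tr <- transcripts[idx[g], ]
      L <- tr$utr5_len + tr$cds_len + tr$utr3_len
      len <- sample(lens, n, replace = TRUE, prob = profile$length_weights)
      # the CDS/UTR stratum of each Ribo fragment is drawn once and kept
      # through resampling, so the realized CDS fraction is unbiased
      in_cds <- if (lib == "Ribo") stats::runif(n) < profile$cds_fraction
      if (lib == "Ribo") {
        asite <- sample_asites(in_cds, tr$utr5_len, tr$cds_len, tr$utr3_len,
                               profile)
        pos5 <- asite - asite_offset(len)
      } else {
        pos5 <- floor(stats::runif(n, 0, pmax(L - len, 0) + 1))
      }
      bad <- pos5 < 0L | pos5 + len > L
      it <- 0L
      while (any(bad)) {
        it <- it + 1L
        if (it > 100L) stop("transcript too short for the fragment profile")
        nb <- sum(bad)
        len[bad] <- sample(lens, nb, replace = TRUE,
                           prob = profile$length_weights)
        if (lib == "Ribo") {
          asite <- sample_asites(in_cds[bad], tr$utr5_len, tr$cds_len,
                                 tr$utr3_len, profile)
          pos5[bad] <- asite - asite_offset(len[bad])
        } else {
          pos5[bad] <- floor(stats::runif(nb, 0, pmax(L - len[bad], 0) + 1))
        }
        bad <- pos5 < 0L | pos5 + len > L
      }
      k <- k + 1L
      out[[k]] <- data.frame(transcript_id = tr$gene_id,
                             pos5 = as.integer(pos5), length = as.integer(len),
                             library = lib,
                             replicate = counts$design$replicate[j],
                             tissue = counts$design$tissue[j],
                             stringsAsFactors = FALSE)
    }
  }
  if (k == 0L)
    return(data.frame(transcript_id = character(), pos5 = integer(),
                      length = integer(), library = character(),
                      replicate = character(), tissue = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out[seq_len(k)])
}

#' Write / read aligned fragments as TSV
#'
#' @param fragments fragment data frame (see [simulate_fragments()]).
#' @param path file path.
#' @return `write_fragments` returns the path invisibly; `read_fragments`
#'   the fragment data frame.
#' @export
write_fragments <- function(fragments, path) {
  utils::write.table(fragments, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_fragments
#' @export
read_fragments <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}
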