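# Build the model matrix from the library design: intercept, Ribo indicator,
# replicate adjustments (within tissue), and for two tissues a tissue main
# effect plus the Ribo x tissue interaction whose coefficient is delta TE.
te_design_matrix <- function(design, interaction = FALSE) {
  tissues <- sort(unique(design$tissue))
  ribo <- as.numeric(design$library == "Ribo")
  X <- cbind(intercept = 1, ribo = ribo)
  for (t in tissues) {
    reps <- sort(unique(design$replicate[design$tissue == t]))
    for (r in reps[-1]) {
      col <- as.numeric(design$tissue == t & design$replicate == r)
      X <- cbind(X, col)
      colnames(X)[ncol(X)] <- paste0("rep_", t, "_", r)
    }
  }
  if (interaction) {
    if (length(tissues) != 2L)
      stop("interaction model needs exactly 2 tissues")
    t2 <- as.numeric(design$tissue == tissues[2])
    X <- cbind(X, tissue = t2, ribo_tissue = ribo * t2)
  }
  if (qr(X)$rank < ncol(X)) stop("design matrix is rank deficient")
  X
}

#' Fit the translational-efficiency model
#'
#' The central model of the package: per-gene negative-binomial GLMs with
#' log link over the paired Ribo-Seq/RNA-Seq count table, with
#' `log(size factor)` offsets. For a single tissue the model is
#' `log mu = intercept + beta_lib * is_ribo + replicate effects`, and
#' `log2 TE = beta_lib / log(2)` - the library-type coefficient, Ribo over
#' RNA. Each gene's log2 TE is tested against the across-gene median with a
#' Wald z statistic (the median treated as fixed), BH-adjusted, and
#' classified TE-low/TE-high at `fdr_max` and `min_fold` (defaults: FDR <
#' 0.05 and at least threefold from the median).
#'
#' With two tissues (the default when the count table has two), the model
#' adds a tissue main effect and the library-by-tissue interaction; the
#' interaction coefficient is the change in log2 TE between tissues
#' (`delta log2 TE = TE[tissue2] - TE[tissue1]`, tissues ordered
#' alphabetically so the sign convention does not depend on column order;
#' it is recorded in `$convention`), Wald-tested against zero and
#' classified at `delta_fdr_max`
#' and `delta_min_abs_log2` (defaults: FDR < 0.2 and at least twofold).
#'
#' Genes with zero counts in every library of either library type have
#' undefined TE and are excluded from fitting (returned with `NA` results).
#'
#' @param counts a [count_table].
#' @param dispersion dispersion method passed to [estimate_dispersion()].
#' @param fixed_alpha dispersion constant for `dispersion = "fixed"`.
#' @param interaction logical; fit the library-by-tissue interaction
#'   (default: yes iff two tissues are present).
#' @param size_factors optional per-library size factors (median-of-ratios
#'   computed when missing).
#' @param fdr_max,min_fold TE-class thresholds (see [classify_te()]).
#' @param delta_fdr_max,delta_min_abs_log2 differential-TE thresholds (see
#'   [classify_delta()]).
#' @param ... further arguments to [estimate_dispersion()].
#' @return an object of class `te_fit`; see [print.te_fit()],
#'   [summary.te_fit()], [coef.te_fit()], [plot.te_fit()]. `$results` is a
#'   data frame with one row per gene: `gene_id`, `base_mean`, `log2_te`
#'   (or `delta_log2_te`), `se`, `wald_p`, `fdr`, `te_class` (or
#'   `delta_class`).
#' @export
te_fit <- function(counts, dispersion = c("trend", "per-gene", "fixed"),
                   fixed_alpha = NULL, interaction = NULL,
                   size_factors = NULL, fdr_max = 0.05, min_fold = 3,
                   delta_fdr_max = 0.2, delta_min_abs_log2 = 1, ...) {
  stopifnot(inherits(counts, "count_table"))
  dispersion <- match.arg(dispersion)
  design <- counts$design
  tissues <- sort(unique(design$tissue))
  if (is.null(interaction)) interaction <- length(tissues) == 2L
  mode <- if (interaction) "delta" else "te"
  if (mode == "delta" && length(tissues) != 2L)
    stop("differential TE needs a count table with exactly 2 tissues")
  cells <- unique(design[, c("library", "tissue")])
  if (mode == "delta" && nrow(cells) != 4L)
    stop("both tissues need both library types")
  K <- counts$counts
  sf <- if (is.null(size_factors)) .size_factors(counts) else size_factors
  if (length(sf) != ncol(K)) stop("one size factor per library required")
  ribo <- design$library == "Ribo"
  fitted_ok <- rowSums(K[, ribo, drop = FALSE]) > 0 &
    rowSums(K[, !ribo, drop = FALSE]) > 0
  alpha <- estimate_dispersion(counts, size_factors = sf, method = dispersion,
                               fixed_alpha = fixed_alpha, ...)
  X <- te_design_matrix(design, interaction = interaction)
  coef_name <- if (mode == "delta") "ribo_tissue" else "ribo"
  G <- nrow(K)
  est <- se <- rep(NA_real_, G)
  conv <- rep(NA, G)
  if (any(fitted_ok)) {
    fit <- nb_glm_batch(K[fitted_ok, , drop = FALSE], X, log(sf),
                        alpha[fitted_ok])
    est[fitted_ok] <- fit$beta[, coef_name] / log(2)
    se[fitted_ok] <- fit$se[, coef_name] / log(2)
    conv[fitted_ok] <- fit$converged
  }
  est[fitted_ok & !conv] <- NA_real_
  se[fitted_ok & !conv] <- NA_real_
  base_mean <- rowMeans(sweep(K, 2, sf, "/"))
  res <- data.frame(gene_id = rownames(K), base_mean = base_mean,
                    stringsAsFactors = FALSE, row.names = NULL)
  if (mode == "te") {
    med <- stats::median(est, na.rm = TRUE)
    z <- (est - med) / se
    p <- 2 * stats::pnorm(-abs(z))
    fdr <- rep(NA_real_, G)
    fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    res$log2_te <- est
    res$se <- se
    res$wald_p <- p
    res$fdr <- fdr
    res$te_class <- classify_te(est, fdr, median_log2_te = med,
                                fdr_max = fdr_max, min_fold = min_fold)
  } else {
    med <- NA_real_
    z <- est / se
    p <- 2 * stats::pnorm(-abs(z))
    fdr <- rep(NA_real_, G)
    fdr[!is.na(p)] <- stats::p.adjust(p[!is.na(p)], method = "BH")
    res$delta_log2_te <- est
    res$se <- se
    res$wald_p <- p
    res$fdr <- fdr
    res$delta_class <- classify_delta(est, fdr, tissues = tissues,
                                      fdr_max = delta_fdr_max,
                                      min_abs_log2 = delta_min_abs_log2)
  }
  structure(list(results = res, mode = mode, tissues = tissues,
                 median_log2_te = med, size_factors = sf, dispersion = alpha,
                 dispersion_method = dispersion, design_matrix = X,
                 libraries = design, n_excluded = sum(!fitted_ok),
                 convention = if (mode == "delta")
                   sprintf("delta_log2_te = log2 TE(%s) - log2 TE(%s)",
                           tissues[2], tissues[1]) else
                             "log2_te = log2(Ribo/RNA)",
                 call = match.call()),
            class = "te_fit")
}

#' Classify genes as TE-low / TE-high
#'
#' A gene is TE-low when its TE is significantly below the transcriptome
#' median (FDR below `fdr_max`) and at least `min_fold`-fold lower;
#' TE-high symmetrically. Everything else (including unfitted genes) is
#' "none".
#'
#' @param log2_te,fdr per-gene estimates and BH-adjusted p-values.
#' @param median_log2_te the across-gene median TE.
#' @param fdr_max FDR cutoff (default 0.05).
#' @param min_fold minimum fold distance from the median (default 3).
#' @return character vector in `{"TE-low", "TE-high", "none"}`.
#' @export
classify_te <- function(log2_te, fdr,
                        median_log2_te = stats::median(log2_te, na.rm = TRUE),
                        fdr_max = 0.05, min_fold = 3) {
  lo <- !is.na(fdr) & fdr < fdr_max & log2_te <= median_log2_te - log2(min_fold)
  hi <- !is.na(fdr) & fdr < fdr_max & log2_te >= median_log2_te + log2(min_fold)
  ifelse(lo, "TE-low", ifelse(hi, "TE-high", "none"))
}

#' Classify between-tissue differential TE
#'
#' A gene has higher TE in the first tissue when `delta_log2_te <=
#' -min_abs_log2` at FDR below `fdr_max`, and higher TE in the second
#' tissue when `delta_log2_te >= +min_abs_log2` (`delta_log2_te` follows
#' the convention `TE[tissue2] - TE[tissue1]`). Defaults: FDR < 0.2 and at
#' least a twofold TE change.
#'
#' @param delta_log2_te,fdr per-gene interaction estimates and BH-adjusted
#'   p-values.
#' @param tissues the two tissue labels, in design order.
#' @param fdr_max FDR cutoff (default 0.2).
#' @param min_abs_log2 minimum |delta log2 TE| (default 1).
#' @return character vector: `"<tissue>-TE-higher"` or `"none"`.
#' @export
classify_delta <- function(delta_log2_te, fdr, tissues = c("A", "B"),
                           fdr_max = 0.2, min_abs_log2 = 1) {
  a <- !is.na(fdr) & fdr < fdr_max & delta_log2_te <= -min_abs_log2
  b <- !is.na(fdr) & fdr < fdr_max & delta_log2_te >= min_abs_log2
  ifelse(a, paste0(tissues[1], "-TE-higher"),
         ifelse(b, paste0(tissues[2], "-TE-higher"), "none"))
}

#' @export
print.te_fit <- function(x, ...) {
  r <- x$results
  if (x$mode == "te") {
    cat(sprintf("te_fit: %d genes (%d fitted), %d libraries, tissue: %s\n",
                nrow(r), sum(!is.na(r$log2_te)), nrow(x$libraries),
                paste(x$tissues, collapse = ", ")))
    cat(sprintf("  median log2 TE: %.3f\n", x$median_log2_te))
    cat(sprintf("  TE-low: %d, TE-high: %d (FDR and fold thresholds of the call)\n",
                sum(r$te_class == "TE-low"), sum(r$te_class == "TE-high")))
  } else {
    cat(sprintf("te_fit (differential): %d genes (%d fitted); %s\n",
                nrow(r), sum(!is.na(r$delta_log2_te)), x$convention))
    for (cl in setdiff(unique(r$delta_class), "none"))
      cat(sprintf("  %s: %d\n", cl, sum(r$delta_class == cl)))
  }
  invisible(x)
}

#' @export
#' @method summary te_fit
summary.te_fit <- function(object, ...) {
  r <- object$results
  cls <- if (object$mode == "te") r$te_class else r$delta_class
  out <- list(mode = object$mode, n_genes = nrow(r),
              n_fitted = sum(!is.na(r$se)),
              n_excluded = object$n_excluded,
              median_log2_te = object$median_log2_te,
              class_counts = table(cls),
              dispersion_summary = summary(object$dispersion),
              convention = object$convention)
  class(out) <- "summary.te_fit"
  out
}

#' @export
print.summary.te_fit <- function(x, ...) {
  cat(sprintf("TE model (%s mode): %d genes, %d fitted, %d excluded\n",
              x$mode, x$n_genes, x$n_fitted, x$n_excluded))
  if (x$mode == "te")
    cat(sprintf("median log2 TE: %.3f\n", x$median_log2_te))
  cat(x$convention, "\n")
  cat("class counts:\n")
  print(x$class_counts)
  cat("per-gene dispersion:\n")
  print(x$dispersion_summary)
  invisible(x)
}

#' @export
#' @method coef te_fit
coef.te_fit <- function(object, ...) {
  r <- object$results
  est <- if (object$mode == "te") r$log2_te else r$delta_log2_te
  stats::setNames(est, r$gene_id)
}

#' @export
#' @method plot te_fit
plot.te_fit <- function(x, ...) {
  r <- x$results
  est <- if (x$mode == "te") r$log2_te else r$delta_log2_te
  cls <- if (x$mode == "te") r$te_class else r$delta_class
  col <- ifelse(cls == "none", grDevices::adjustcolor("grey40", 0.5), "red3")
  graphics::plot(log2(r$base_mean + 0.5), est, pch = 16, cex = 0.4, col = col,
                 xlab = "log2 mean normalized count",
                 ylab = if (x$mode == "te") "log2 TE" else "delta log2 TE",
                 ...)
  if (x$mode == "te")
    graphics::abline(h = x$median_log2_te, lty = 2)
  else graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Compare 5'UTR features between TE classes
#'
#' Summarizes 5'UTR length, 3'UTR length and uAUG count per TE class and
#' tests each feature in each class against all remaining genes with a
#' two-sided Mann-Whitney test. Classes with fewer than 2 members get
#' summaries only.
#'
#' @param te_class character vector of TE classes (one per transcript).
#' @param transcripts a [transcript_set] in the same order.
#' @param uaug_counts optional per-gene uAUG counts; when missing, the
#'   5'UTRs are scanned for canonical upstream AUGs.
#' @return list with `summary` (per-class medians and n) and `tests`
#'   (class, feature, Mann-Whitney p).
#' @export
utr_feature_comparison <- function(te_class, transcripts, uaug_counts = NULL) {
  stopifnot(length(te_class) == nrow(transcripts))
  if (is.null(uaug_counts)) {
    uaug_counts <- vapply(seq_len(nrow(transcripts)), function(i) {
      utr <- substr(transcripts$sequence[i], 1L, transcripts$utr5_len[i])
      length(atg_positions(utr))
    }, integer(1))
  }
  feats <- data.frame(utr5_len = transcripts$utr5_len,
                      utr3_len = transcripts$utr3_len,
                      uaug_count = uaug_counts)
  classes <- unique(te_class)
  summ <- do.call(rbind, lapply(classes, function(cl) {
    i <- te_class == cl
    data.frame(class = cl, n = sum(i),
               median_utr5_len = stats::median(feats$utr5_len[i]),
               median_utr3_len = stats::median(feats$utr3_len[i]),
               median_uaug_count = stats::median(feats$uaug_count[i]),
               stringsAsFactors = FALSE)
  }))
  tests <- NULL
  for (cl in setdiff(classes, "none")) {
    i <- te_class == cl
    if (sum(i) < 2L || sum(!i) < 2L) next
    for (f in names(feats)) {
      # exact for small tie-free samples, normal approximation otherwise
      p <- suppressWarnings(stats::wilcox.test(feats[[f]][i], feats[[f]][!i],
                                               alternative = "two.sided")$p.value)
      tests <- rbind(tests, data.frame(class = cl, feature = f,
                                       mann_whitney_p = p,
                                       stringsAsFactors = FALSE))
    }
  }
  list(summary = summ, tests = tests)
}
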