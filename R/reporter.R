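#' Relative translational efficiency of a dual-luciferase reporter
#'
#' For each construct and batch, reporter TE is the Firefly/Renilla
#' activity ratio divided by the Firefly/Renilla RNA ratio, expressed
#' relative to the same quantity for the reference construct (the HBB
#' 5'UTR control) of the same batch; the reference therefore maps to 1.
#' Per-construct values are then averaged over batches (biological
#' replicates) with their SD.
#'
#' @param data data frame with columns `construct`, `batch`,
#'   `fluc_activity`, `rluc_activity`, `fluc_rna`, `rluc_rna` (all
#'   positive).
#' @param reference reference construct label (default `"HBB"`).
#' @return data frame: `construct`, `te_mean`, `te_sd`, `n_batches`.
#' @export
reporter_te <- function(data, reference = "HBB") {
  need <- c("construct", "batch", "fluc_activity", "rluc_activity",
            "fluc_rna", "rluc_rna")
  stopifnot(all(need %in% names(data)))
  num <- data[, need[-(1:2)]]
  if (any(!is.finite(as.matrix(num))) || any(as.matrix(num) <= 0))
    stop("all reporter quantities must be positive")
  if (!reference %in% data$construct)
    stop(sprintf("reference construct '%s' absent from data", reference))
  raw <- (data$fluc_activity / data$rluc_activity) /
    (data$fluc_rna / data$rluc_rna)
  per_batch <- NULL
  for (b in unique(data$batch)) {
    i <- data$batch == b
    ref <- raw[i & data$construct == reference]
    if (length(ref) != 1L)
      stop(sprintf("batch '%s' needs exactly one reference measurement", b))
    per_batch <- rbind(per_batch,
                       data.frame(construct = data$construct[i], batch = b,
                                  te = raw[i] / ref, stringsAsFactors = FALSE))
  }
  agg <- lapply(split(per_batch$te, per_batch$construct), function(v)
    c(mean(v), stats::sd(v), length(v)))
  out <- data.frame(construct = names(agg),
                    te_mean = vapply(agg, `[`, numeric(1), 1),
                    te_sd = vapply(agg, `[`, numeric(1), 2),
                    n_batches = vapply(agg, `[`, numeric(1), 3),
                    stringsAsFactors = FALSE, row.names = NULL)
  out[order(match(out$construct, unique(data$construct))), , drop = FALSE]
}

#' Percentage of an mRNA in heavy polysome fractions
#'
#' Each sucrose-gradient fraction's qPCR quantity is corrected by its
#' spike-in (in-vitro-transcribed luciferase RNA) recovery, and the
#' percentage associated with actively translating polysomes is the
#' corrected signal summed over heavy fractions, divided by the corrected
#' total, times 100.
#'
#' @param qpcr per-fraction qPCR quantities (positive).
#' @param spikein per-fraction spike-in quantities (positive).
#' @param heavy logical, which fractions are heavy polysomes (at least one
#'   heavy and one non-heavy).
#' @return percentage in `[0, 100]`.
#' @export
heavy_polysome_fraction <- function(qpcr, spikein, heavy) {
  stopifnot(length(qpcr) == length(spikein), length(qpcr) == length(heavy),
            length(qpcr) >= 2L)
  if (any(spikein <= 0)) stop("spike-in quantities must be positive")
  if (!any(heavy) || all(heavy))
    stop("need at least one heavy and one non-heavy fraction")
  corrected <- qpcr / spikein
  100 * sum(corrected[heavy]) / sum(corrected)
}

#' Mark heavy fractions by index
#'
#' Fractionation geometry is apparatus-specific; by convention here,
#' fractions from `first_heavy` onward are heavy.
#'
#' @param n_fractions number of gradient fractions.
#' @param first_heavy index of the first heavy fraction.
#' @return logical vector.
#' @export
mark_heavy <- function(n_fractions, first_heavy) {
  seq_len(n_fractions) >= first_heavy
}

#' Log2 change in heavy-polysome association
#'
#' @param percent_a,percent_b heavy-polysome percentages (positive), e.g.
#'   from [heavy_polysome_fraction()] in two tissues.
#' @return `log2(percent_a / percent_b)`.
#' @export
delta_log2_heavy <- function(percent_a, percent_b) {
  if (any(c(percent_a, percent_b) <= 0))
    stop("percentages must be positive")
  log2(percent_a / percent_b)
}

#' Two-group comparison with significance stars
#'
#' Two-sided two-sample Student's t-test (equal variances by default,
#' Welch with `var_equal = FALSE`), with the conventional star coding:
#' `**` for p < 0.01, `*` for p < 0.05, `NS` otherwise.
#'
#' @param values_a,values_b numeric vectors (each n >= 2).
#' @param var_equal assume equal variances (default TRUE).
#' @return list with `p_value`, `stars`, `t`, `df`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(values_a) == 0 && stats::sd(values_b) == 0) {
    # degenerate: no within-group variability
    same <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    return(list(p_value = if (same) 1 else 0,
                stars = if (same) "NS" else "**",
                t = if (same) 0 else Inf,
                df = length(values_a) + length(values_b) - 2L))
  }
  ht <- stats::t.test(values_a, values_b, var.equal = var_equal)
  p <- ht$p.value
  stars <- if (is.na(p)) "NS" else if (p < 0.01) "**" else
    if (p < 0.05) "*" else "NS"
  list(p_value = p, stars = stars, t = unname(ht$statistic),
       df = unname(ht$parameter))
}
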