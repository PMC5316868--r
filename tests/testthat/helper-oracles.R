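# Independent brute-force oracles. These deliberately share no code with the
# package: explicit loops, character vectors, and textbook definitions.

STOPS <- c("TAA", "TAG", "TGA")
NEAR <- c("CTG", "GTG", "TTG", "ACG", "AGG", "AAG", "ATA", "ATC", "ATT")

# enumerate every upstream initiation site by trying every UTR position,
# walking triplets one by one to the first stop, and classifying by frame
oracle_start_sites <- function(utr, cds) {
  utr <- toupper(chartr("U", "T", utr)); cds <- toupper(chartr("U", "T", cds))
  full <- strsplit(paste0(utr, cds), "")[[1]]
  ulen <- nchar(utr)
  rows <- list()
  for (p0 in seq_len(max(ulen - 2L, 0L))) {    # 1-based codon start
    cod <- paste(full[p0:(p0 + 2L)], collapse = "")
    # Kozak (adjacent-context rule): G at -1 and A/G at +3, codon occupying 0-2
    kz <- FALSE
    if (p0 - 1L >= 1L && p0 + 3L <= length(full))
      kz <- full[p0 - 1L] == "G" && full[p0 + 3L] %in% c("A", "G")
    is_aug <- cod == "ATG"
    if (!(is_aug || (cod %in% NEAR && kz))) next
    # walk triplets to the first stop
    q <- p0; stop0 <- NA_integer_
    while (q + 2L <= length(full)) {
      if (paste(full[q:(q + 2L)], collapse = "") %in% STOPS) {
        stop0 <- q - 1L   # 0-based
        break
      }
      q <- q + 3L
    }
    frame0 <- ((ulen - (p0 - 1L)) %% 3L) == 0L
    cls <- if (!is.na(stop0) && stop0 < ulen) "uORF" else
      if (frame0) "in-frame-extension" else "oORF"
    rows[[length(rows) + 1L]] <- data.frame(
      position = p0 - 1L, codon = cod, canonical = is_aug,
      kozak_favourable = kz, orf_class = cls, stop_position = stop0,
      in_frame_with_main = frame0, stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(position = integer(), codon = character(),
                      canonical = logical(), kozak_favourable = logical(),
                      orf_class = character(), stop_position = integer(),
                      in_frame_with_main = logical(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# textbook median-of-ratios size factors, via explicit loops
oracle_size_factors <- function(K) {
  G <- nrow(K); n <- ncol(K)
  gm <- numeric(G)
  for (g in 1:G) gm[g] <- prod(K[g, ])^(1 / n)
  usable <- which(gm > 0)
  sf <- numeric(n)
  for (j in 1:n) {
    ratios <- numeric(0)
    for (g in usable) ratios <- c(ratios, K[g, j] / gm[g])
    sf[j] <- median(ratios)
  }
  sf
}

# Benjamini-Hochberg step-up, from the definition
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    val <- min(prev, p[o[i]] * m / i)
    adj[o[i]] <- val
    prev <- val
  }
  adj
}

# longest adapter prefix matching the read suffix (or full occurrence),
# by exhaustive scan
oracle_trim <- function(seq, adapter, min_overlap = 3L) {
  n <- nchar(seq); m <- nchar(adapter)
  for (i in 1:max(n - m + 1L, 1L)) {
    if (i + m - 1L <= n && substr(seq, i, i + m - 1L) == adapter)
      return(substr(seq, 1L, i - 1L))
  }
  best <- 0L
  for (k in min(m - 1L, n):1) {
    if (k < min_overlap) break
    if (substr(seq, n - k + 1L, n) == substr(adapter, 1L, k)) {
      best <- k
      break
    }
  }
  substr(seq, 1L, n - best)
}

# exact two-sided Mann-Whitney p by enumerating all group assignments
oracle_mann_whitney <- function(x, y) {
  pooled <- c(x, y)
  n1 <- length(x)
  idx <- utils::combn(length(pooled), n1)
  ustat <- function(a, b) {
    u <- 0
    for (i in a) for (j in b) u <- u + (i > j) + 0.5 * (i == j)
    u
  }
  obs <- ustat(x, y)
  center <- n1 * length(y) / 2
  hits <- 0
  for (c in seq_len(ncol(idx))) {
    a <- pooled[idx[, c]]; b <- pooled[-idx[, c]]
    if (abs(ustat(a, b) - center) >= abs(obs - center) - 1e-12) hits <- hits + 1
  }
  hits / ncol(idx)
}

# random nucleotide string
random_utr <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# small simulated mesoderm-style experiment used across tests
quick_sim <- function(n_genes = 200, log2_te = 0, dispersion = 0.05,
                      mean_expression = 200, n_replicates = 3, seed = 1,
                      tissues = "mesoderm") {
  d <- sim_design(n_genes, n_replicates = n_replicates, tissues = tissues,
                  mean_expression = mean_expression, log2_te = log2_te,
                  dispersion = dispersion, seed = seed)
  simulate_counts(d)
}
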