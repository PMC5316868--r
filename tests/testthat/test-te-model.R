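make_ct <- function(K, library = rep(c("RNA", "Ribo"), each = ncol(K) / 2),
                    replicate = rep(paste0("rep", 1:(ncol(K) / 2)), 2),
                    tissue = "meso") {
  design <- data.frame(sample = paste(tissue, library, replicate, sep = "_"),
                       library = library, replicate = replicate,
                       tissue = tissue)
  rownames(K) <- sprintf("g%03d", seq_len(nrow(K)))
  count_table(K, design)
}

test_that("size factors follow the median-of-ratios definition", {
  K <- matrix(c(10, 20, 30, 40, 10, 20, 30, 40), ncol = 2)
  expect_equal(unname(size_factors(K)), c(1, 1))
  K2 <- cbind(c(10, 20, 30, 40), 2 * c(10, 20, 30, 40))
  sf <- size_factors(K2)
  expect_equal(unname(sf[2] / sf[1]), 2)
  # brute-force oracle on a random 50-gene table
  set.seed(3)
  K3 <- matrix(rnbinom(50 * 6, mu = 100, size = 10), ncol = 6)
  K3[3, 2] <- 0   # gene with a zero is excluded from the median
  expect_equal(unname(size_factors(K3)), oracle_size_factors(K3))
  # scale equivariance of relative factors
  K4 <- K3; K4[, 1] <- K4[, 1] * 5
  sf3 <- size_factors(K3); sf4 <- size_factors(K4)
  expect_equal(unname(sf4[1] / sf4[2]), unname(5 * sf3[1] / sf3[2]),
               tolerance = 1e-10)
  # no gene nonzero everywhere -> informative error
  K5 <- matrix(c(0, 5, 5, 0), 2, 2)
  expect_error(size_factors(K5), "pseudo-reference")
})

test_that("dispersion estimation recovers the truth and floors degenerate cases", {
  # Poisson limit: per-gene estimates concentrate near zero
  ct <- quick_sim(n_genes = 200, dispersion = 0, n_replicates = 50, seed = 2)
  a <- estimate_dispersion(ct, method = "per-gene")
  expect_lte(median(a), 0.01)
  # recovery at alpha = 0.1 with 20 replicates
  ct2 <- quick_sim(n_genes = 500, dispersion = 0.1, n_replicates = 20, seed = 3)
  a2 <- estimate_dispersion(ct2, method = "per-gene")
  expect_gte(median(a2), 0.05)
  expect_lte(median(a2), 0.2)
  # trend sharing also lands near the truth
  a2t <- estimate_dispersion(ct2, method = "trend")
  expect_gte(median(a2t), 0.05)
  expect_lte(median(a2t), 0.2)
  # constant counts across replicates: floored at alpha_floor
  K <- matrix(100, 4, 6)
  ctc <- make_ct(K)
  ac <- estimate_dispersion(ctc, size_factors = rep(1, 6), method = "per-gene")
  expect_equal(unname(ac), rep(1e-8, 4))
  # single replicate refuses without a fixed value
  ct1 <- quick_sim(n_genes = 10, n_replicates = 1, seed = 1)
  expect_error(estimate_dispersion(ct1), "2 replicates")
  expect_equal(estimate_dispersion(ct1, method = "fixed", fixed_alpha = 0.1),
               rep(0.1, 10))
})

test_that("the NB GLM matches the closed form on saturated balanced designs", {
  X <- cbind(intercept = 1, ribo = rep(c(0, 1), each = 3))
  y <- c(100, 100, 100, 200, 200, 200)
  fit <- nb_glm(y, X, alpha = 0.1)
  expect_equal(unname(fit$coefficients["ribo"]), log(2), tolerance = 1e-6)
  expect_true(fit$converged)
  # null case
  fit0 <- nb_glm(rep(150, 6), X, alpha = 0.1)
  expect_equal(unname(fit0$coefficients["ribo"]), 0, tolerance = 1e-8)
  # closed form: on the saturated balanced design the group coefficient is
  # the log ratio of group means, for any dispersion
  y2 <- c(100, 240, 110, 420, 180, 350)
  fit2 <- nb_glm(y2, X, alpha = 0.05)
  expect_equal(unname(fit2$coefficients["ribo"]),
               log(mean(y2[4:6]) / mean(y2[1:3])), tolerance = 1e-6)
  # with offsets the Poisson MLE group mean is the ratio of totals
  sf <- c(1, 2, 1, 1, 0.5, 1)
  fit3 <- nb_glm(y2, X, offset = log(sf), alpha = 0)
  expect_equal(unname(fit3$coefficients["ribo"]),
               log((sum(y2[4:6]) / sum(sf[4:6])) /
                     (sum(y2[1:3]) / sum(sf[1:3]))), tolerance = 1e-6)
})

test_that("the NB GLM agrees with an independent IRLS implementation", {
  skip_if_not_installed("MASS")
  set.seed(10)
  X <- cbind(intercept = 1, ribo = rep(c(0, 1), each = 3),
             rep2 = rep(c(0, 1, 0), 2), rep3 = rep(c(0, 0, 1), 2))
  off <- log(c(0.9, 1.1, 1.0, 1.2, 0.8, 1.0))
  for (i in 1:5) {
    mu <- exp(5 + 0.7 * X[, "ribo"] + off)
    y <- rnbinom(6, mu = mu, size = 1 / 0.08)
    if (any(y == 0)) next
    ours <- nb_glm(y, X, offset = off, alpha = 0.08)
    ref <- glm(y ~ 0 + X + offset(off),
               family = MASS::negative.binomial(theta = 1 / 0.08, link = "log"))
    expect_equal(unname(ours$coefficients), unname(coef(ref)),
                 tolerance = 1e-5)
    se_ref <- summary(ref, dispersion = 1)$coefficients[, 2]
    expect_equal(unname(ours$se), unname(se_ref), tolerance = 1e-4)
  }
})

test_that("te_fit estimates log2 TE, tests against the median, and applies BH", {
  G <- 300
  set.seed(5)
  lt <- c(rep(-2, 40), rep(0, 220), rep(2, 40))
  d <- sim_design(G, mean_expression = rlnorm(G, log(200) - 0.5, 1),
                  log2_te = lt, dispersion = 0.05, seed = 21)
  fit <- te_fit(simulate_counts(d))
  r <- fit$results
  expect_s3_class(fit, "te_fit")
  expect_equal(nrow(r), G)
  expect_lt(abs(mean(r$log2_te[lt == -2]) - (-2)), 0.15)
  expect_lt(abs(mean(r$log2_te[lt == 2]) - 2), 0.15)
  # BH equals the brute-force step-up
  expect_equal(r$fdr, oracle_bh(r$wald_p), tolerance = 1e-12)
  expect_true(all(r$fdr >= 0 & r$fdr <= 1))
  # planted strata are called in the right direction
  expect_gt(mean(r$te_class[lt == -2] == "TE-low"), 0.5)
  expect_gt(mean(r$te_class[lt == 2] == "TE-high"), 0.5)
  expect_lt(mean(r$te_class[lt == 0] != "none"), 0.05)
  # S3 surface
  expect_equal(unname(coef(fit)), r$log2_te)
  expect_output(print(fit), "TE-low")
  expect_s3_class(summary(fit), "summary.te_fit")
})

test_that("identical Ribo and RNA counts give TE 0 with p = 1 everywhere", {
  K <- matrix(rep(c(100, 150, 120, 100, 150, 120), 5), ncol = 6, byrow = TRUE)
  fit <- te_fit(make_ct(K), dispersion = "fixed", fixed_alpha = 0.05)
  expect_equal(fit$results$log2_te, rep(0, 5), tolerance = 1e-6)
  expect_equal(fit$results$wald_p, rep(1, 5), tolerance = 1e-6)
  expect_equal(fit$results$fdr, rep(1, 5), tolerance = 1e-6)
  expect_true(all(fit$results$te_class == "none"))
})

test_that("swapping library labels negates every log2 TE", {
  ct <- quick_sim(n_genes = 50, log2_te = rnorm(50), seed = 9)
  fit1 <- te_fit(ct, dispersion = "fixed", fixed_alpha = 0.05)
  ct2 <- ct
  ct2$design$library <- ifelse(ct2$design$library == "Ribo", "RNA", "Ribo")
  fit2 <- te_fit(ct2, dispersion = "fixed", fixed_alpha = 0.05)
  expect_equal(fit2$results$log2_te, -fit1$results$log2_te, tolerance = 1e-6)
})

test_that("genes with an all-zero library type are excluded with NA results", {
  ct <- quick_sim(n_genes = 20, seed = 4)
  ct$counts[3, ct$design$library == "Ribo"] <- 0L
  fit <- te_fit(ct, dispersion = "fixed", fixed_alpha = 0.05)
  expect_true(is.na(fit$results$log2_te[3]))
  expect_identical(fit$results$te_class[3], "none")
  expect_equal(fit$n_excluded, 1)
  expect_false(anyNA(fit$results$log2_te[-3]))
})

test_that("TE classification applies the FDR and threefold gates", {
  expect_identical(classify_te(-2, 0.01, median_log2_te = 0), "TE-low")
  expect_identical(classify_te(-1, 0.01, median_log2_te = 0), "none")
  expect_identical(classify_te(-3, 0.2, median_log2_te = 0), "none")
  expect_identical(classify_te(2, 0.01, median_log2_te = 0), "TE-high")
  # exactly threefold is included ("at least threefold")
  expect_identical(classify_te(-log2(3), 0.01, median_log2_te = 0), "TE-low")
  # monotone: at fixed fdr, decreasing log2_te never un-calls TE-low
  grid <- seq(0, -4, by = -0.25)
  calls <- classify_te(grid, rep(0.01, length(grid)), median_log2_te = 0)
  first_low <- match("TE-low", calls)
  expect_true(all(calls[first_low:length(calls)] == "TE-low"))
})

test_that("differential-TE classification applies the FDR and twofold gates", {
  tis <- c("NT", "FL")
  expect_identical(classify_delta(-1.5, 0.1, tis), "NT-TE-higher")
  expect_identical(classify_delta(-0.9, 0.01, tis), "none")
  expect_identical(classify_delta(-3, 0.5, tis), "none")
  expect_identical(classify_delta(1.5, 0.1, tis), "FL-TE-higher")
})

test_that("the interaction model is null on duplicated tissues and antisymmetric in labels", {
  ct <- quick_sim(n_genes = 30, seed = 14)
  K <- cbind(ct$counts, ct$counts)
  design <- rbind(ct$design, ct$design)
  design$tissue <- rep(c("NT", "FL"), each = nrow(ct$design))
  design$sample <- paste(design$tissue, design$library, design$replicate,
                         sep = "_")
  ct2 <- count_table(K, design)
  fit <- te_fit(ct2, dispersion = "fixed", fixed_alpha = 0.05)
  expect_identical(fit$mode, "delta")
  expect_equal(fit$results$delta_log2_te, rep(0, 30), tolerance = 1e-6)
  # swapped tissue labels negate the interaction
  ct3 <- quick_sim(n_genes = 40, tissues = c("NT", "FL"),
                   log2_te = cbind(rnorm(40), rnorm(40)), seed = 15)
  fitA <- te_fit(ct3, dispersion = "fixed", fixed_alpha = 0.05)
  ct4 <- ct3
  ct4$design$tissue <- ifelse(ct4$design$tissue == "NT", "FL", "NT")
  fitB <- te_fit(ct4, dispersion = "fixed", fixed_alpha = 0.05)
  i <- TRUE
  expect_equal(fitB$results$delta_log2_te, -fitA$results$delta_log2_te,
               tolerance = 1e-6)
  # a missing design cell is refused
  ct5 <- ct3
  keep <- !(ct5$design$tissue == "FL" & ct5$design$library == "Ribo")
  ct5$counts <- ct5$counts[, keep]
  ct5$design <- ct5$design[keep, ]
  expect_error(te_fit(ct5), "both library types")
})

test_that("planted between-tissue TE differences are recovered", {
  G <- 400
  delta <- c(rep(2, 40), rep(0, 360))
  lt <- cbind(rep(0, G), delta)   # tissue 2 carries the shift
  d <- sim_design(G, tissues = c("NT", "FL"), mean_expression = 500,
                  log2_te = lt, dispersion = 0.05, seed = 33)
  fit <- te_fit(simulate_counts(d))
  est <- fit$results$delta_log2_te
  # convention: delta = TE(NT) - TE(FL) (alphabetical order), so genes with
  # TE planted on FL sit at -2
  expect_match(fit$convention, "TE\\(NT\\) - log2 TE\\(FL\\)")
  expect_lt(abs(mean(est[delta == 2]) + 2), 0.15)
  expect_lt(abs(mean(est[delta == 0])), 0.1)
  expect_gt(mean(fit$results$delta_class[delta == 2] == "FL-TE-higher"), 0.8)
})

test_that("5'UTR feature comparison reports planted differences and exact Mann-Whitney p-values", {
  # planted effect: TE-low genes get ~+200 nt UTRs
  tx <- make_transcriptome(60, seed = 8)
  cls <- rep("none", 60); cls[1:15] <- "TE-low"
  tx$utr5_len[1:15] <- tx$utr5_len[1:15] + 200L
  tx$sequence[1:15] <- paste0(strrep("C", 200), tx$sequence[1:15])
  out <- utr_feature_comparison(cls, tx)
  s <- out$summary
  diff <- s$median_utr5_len[s$class == "TE-low"] -
    s$median_utr5_len[s$class == "none"]
  expect_gt(diff, 120)
  expect_lt(out$tests$mann_whitney_p[out$tests$feature == "utr5_len"], 0.001)
  # identical sets: p near 1
  cls2 <- rep(c("TE-low", "none"), 30)
  out2 <- utr_feature_comparison(cls2, make_transcriptome(60, seed = 8))
  expect_gt(min(out2$tests$mann_whitney_p), 0.05)
  # 6-element toy equals exhaustive rank enumeration
  tx6 <- transcript_set(paste0("g", 1:6), rep(strrep("A", 30 + 9 + 10), 6),
                        rep(30, 6), rep(9, 6), rep(10, 6))
  tx6$utr5_len <- c(31L, 55L, 47L, 28L, 36L, 41L)
  tx6$sequence <- vapply(seq_len(6), function(i)
    strrep("A", tx6$utr5_len[i] + 9L + 10L), character(1))
  cls6 <- c("TE-low", "TE-low", "TE-low", "none", "none", "none")
  out6 <- utr_feature_comparison(cls6, tx6, uaug_counts = rep(0L, 6))
  p_pkg <- out6$tests$mann_whitney_p[out6$tests$feature == "utr5_len"]
  p_oracle <- oracle_mann_whitney(tx6$utr5_len[1:3], tx6$utr5_len[4:6])
  expect_equal(p_pkg, p_oracle, tolerance = 1e-12)
})
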