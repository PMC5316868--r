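#' DESeq-style median-of-ratios size factors
#'
#' Effective library size of each sequencing library: the median, over genes
#' with nonzero counts in every library, of the ratio of the gene's count to
#' its across-library geometric mean.
#'
#' @param counts a [count_table] or a genes-by-libraries count matrix.
#' @return numeric vector of per-library size factors.
#' @export
size_factors <- function(counts) .size_factors(counts)

.size_factors <- function(counts) {
  K <- if (inherits(counts, "count_table")) counts$counts else as.matrix(counts)
  logK <- log(K)
  loggm <- rowMeans(logK)
  use <- is.finite(loggm)
  if (!any(use))
    stop(paste("no gene has nonzero counts in all libraries; supply size",
               "factors computed against a pseudo-reference instead"))
  gm <- exp(loggm[use])
  apply(K[use, , drop = FALSE], 2, function(k) stats::median(k / gm))
}

#' Per-gene NB dispersion estimation
#'
#' Method-of-moments estimate of the negative-binomial dispersion `alpha`
#' (`Var = mu + alpha * mu^2`) from normalized counts, computed within
#' replicate groups (library type x tissue) and corrected for the
#' shot-noise term contributed by counting. With the default
#' `method = "trend"` a parametric mean-dispersion trend
#' `alpha(mu) = a0 + a1 / mu` is fitted across genes by gamma regression
#' and each gene receives the larger of its own estimate and the trend
#' value ("maximum" sharing), which guards the Wald tests against
#' underestimated variances at small replicate numbers.
#' `method = "per-gene"` uses the raw per-gene estimates (floored), and
#' `method = "fixed"` uses a supplied constant.
#'
#' @param counts a [count_table] (or matrix with `design` supplied).
#' @param size_factors per-library size factors (computed if missing).
#' @param method `"trend"` (default), `"per-gene"`, or `"fixed"`.
#' @param sharing for `"trend"`: `"maximum"` (default) or `"fit-only"`.
#' @param alpha_floor lower bound for returned dispersions.
#' @param fixed_alpha constant used when `method = "fixed"`.
#' @param design library design data frame when `counts` is a bare matrix.
#' @return numeric vector of per-gene dispersions (attribute `trend` holds
#'   the fitted trend coefficients when applicable).
#' @export
estimate_dispersion <- function(counts, size_factors = NULL,
                                method = c("trend", "per-gene", "fixed"),
                                sharing = c("maximum", "fit-only"),
                                alpha_floor = 1e-8, fixed_alpha = NULL,
                                design = NULL) {
  method <- match.arg(method)
  sharing <- match.arg(sharing)
  if (inherits(counts, "count_table")) {
    design <- counts$design
    K <- counts$counts
  } else K <- as.matrix(counts)
  G <- nrow(K)
  if (method == "fixed") {
    if (is.null(fixed_alpha)) stop("method = 'fixed' needs fixed_alpha")
    return(rep(pmax(fixed_alpha, alpha_floor), G))
  }
  if (is.null(size_factors)) size_factors <- .size_factors(counts)
  grp <- factor(paste(design$library, design$tissue))
  n_i <- table(grp)
  if (any(n_i < 2L))
    stop("dispersion estimation needs >= 2 replicates per condition; use method = 'fixed' otherwise")
  q <- sweep(K, 2, size_factors, "/")
  # group means per gene, mapped back to libraries
  m <- vapply(levels(grp), function(g) rowMeans(q[, grp == g, drop = FALSE]),
              numeric(G))
  mfull <- m[, as.integer(grp), drop = FALSE]
  df <- ncol(K) - nlevels(grp)
  w <- rowSums((q - mfull)^2) / df
  xim <- rowMeans(sweep(mfull, 2, size_factors, "/"))  # shot-noise term
  msq <- rowMeans(mfull^2)
  raw <- ifelse(msq > 0, (w - xim) / msq, NA_real_)
  if (method == "per-gene") return(pmax(raw, alpha_floor, na.rm = FALSE))
  base_mean <- rowMeans(q)
  usable <- which(is.finite(raw) & raw > 0 & base_mean > 0)
  trend <- c(a0 = NA_real_, a1 = NA_real_)
  fitted_alpha <- rep(NA_real_, G)
  if (length(usable) >= 10L) {
    fit <- tryCatch(
      stats::glm(raw[usable] ~ I(1 / base_mean[usable]),
                 family = stats::Gamma(link = "identity"),
                 start = c(stats::median(raw[usable]), 1)),
      error = function(e) NULL, warning = function(w2) NULL)
    if (!is.null(fit) && all(is.finite(stats::coef(fit)))) {
      trend <- stats::setNames(stats::coef(fit), c("a0", "a1"))
    }
  }
  if (!is.finite(trend["a0"])) {
    # fallback: flat trend at the median positive estimate
    trend <- c(a0 = if (length(usable)) stats::median(raw[usable]) else
      alpha_floor, a1 = 0)
  }
  fitted_alpha <- trend["a0"] + trend["a1"] / base_mean
  fitted_alpha[!is.finite(fitted_alpha) | fitted_alpha < 0] <- alpha_floor
  alpha <- if (sharing == "maximum") pmax(raw, fitted_alpha, na.rm = TRUE)
  else fitted_alpha
  alpha <- pmax(alpha, alpha_floor)
  attr(alpha, "trend") <- trend
  alpha
}

#' Fit a negative-binomial GLM with log link and known dispersion
#'
#' Maximizes the NB likelihood for one gene by iteratively reweighted least
#' squares, with a `log(size factor)` offset and fixed dispersion `alpha`.
#' The returned covariance is the inverse expected information.
#'
#' @param y non-negative integer response (one library per element).
#' @param X design matrix (full column rank).
#' @param offset linear-predictor offset, typically `log(size_factors)`.
#' @param alpha NB dispersion (>= 0; 0 is Poisson).
#' @param max_iter,tol IRLS controls.
#' @return list with `coefficients`, `se`, `vcov`, `fitted` (means), and
#'   `converged`.
#' @export
nb_glm <- function(y, X, offset = rep(0, length(y)), alpha = 0,
                   max_iter = 50L, tol = 1e-8) {
  fit <- nb_glm_batch(matrix(y, nrow = 1), X, offset, alpha,
                      max_iter = max_iter, tol = tol, keep_vcov = TRUE)
  list(coefficients = stats::setNames(fit$beta[1, ], colnames(X)),
       se = stats::setNames(fit$se[1, ], colnames(X)),
       vcov = fit$vcov[[1]],
       fitted = fit$mu[1, ],
       converged = fit$converged[1])
}

# Vectorized IRLS across genes sharing one design matrix.
# Y: G x n counts; X: n x p; offset: length n; alpha: length G (recycled).
nb_glm_batch <- function(Y, X, offset, alpha, max_iter = 50L, tol = 1e-8,
                         keep_vcov = FALSE) {
  Y <- as.matrix(Y)
  G <- nrow(Y); n <- ncol(Y); p <- ncol(X)
  alpha <- rep_len(alpha, G)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  off <- matrix(offset, G, n, byrow = TRUE)
  # products X_a * X_b for the upper triangle, to assemble X'WX per gene
  pairs <- which(upper.tri(diag(p), diag = TRUE), arr.ind = TRUE)
  XX <- X[, pairs[, 1], drop = FALSE] * X[, pairs[, 2], drop = FALSE]
  mu <- pmax(Y, 0.5)
  eta <- log(mu) - off
  beta <- matrix(0, G, p, dimnames = list(rownames(Y), colnames(X)))
  converged <- rep(FALSE, G)
  active <- rep(TRUE, G)
  M <- matrix(0, p, p)
  for (it in seq_len(max_iter)) {
    W <- mu / (1 + alpha * mu)            # mu^2 / (mu + alpha mu^2)
    z <- eta + (Y - mu) / mu
    A <- W %*% XX                          # G x npairs
    B <- (W * z) %*% X                     # G x p
    newbeta <- beta
    for (g in which(active)) {
      M[cbind(pairs[, 1], pairs[, 2])] <- A[g, ]
      M[cbind(pairs[, 2], pairs[, 1])] <- A[g, ]
      bg <- tryCatch(solve(M, B[g, ]), error = function(e) rep(NA_real_, p))
      newbeta[g, ] <- bg
    }
    bad <- active & !is.finite(rowSums(newbeta))
    newbeta[bad, ] <- beta[bad, ]
    active[bad] <- FALSE
    delta <- abs(newbeta - beta)
    just_conv <- active & apply(delta, 1, max) < tol & it > 1L
    converged[just_conv] <- TRUE
    active[just_conv] <- FALSE
    beta <- newbeta
    eta <- pmin(pmax(beta %*% t(X), -30), 30)
    mu <- exp(eta + off)
    mu <- pmin(pmax(mu, 1e-10), 1e12)
    if (!any(active)) break
  }
  # standard errors from the final expected information
  W <- mu / (1 + alpha * mu)
  A <- W %*% XX
  se <- matrix(NA_real_, G, p, dimnames = dimnames(beta))
  vcovs <- if (keep_vcov) vector("list", G) else NULL
  for (g in seq_len(G)) {
    M[cbind(pairs[, 1], pairs[, 2])] <- A[g, ]
    M[cbind(pairs[, 2], pairs[, 1])] <- A[g, ]
    V <- tryCatch(solve(M), error = function(e) matrix(NA_real_, p, p))
    se[g, ] <- sqrt(pmax(diag(V), 0))
    if (keep_vcov) vcovs[[g]] <- V
  }
  list(beta = beta, se = se, mu = mu, converged = converged,
       vcov = if (keep_vcov) vcovs else
         lapply(seq_len(G), function(g) NULL))
}
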