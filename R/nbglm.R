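## Negative-binomial GLM engine: size factors, dispersion estimation, IRLS
## fitting, Wald and likelihood-ratio tests, and BH adjustment. This is the
## single count-model engine shared by the expression designs and by the
## windowed chromatin-accessibility test.

#' Median-of-ratios size factors
#'
#' Per-sample scaling constants computed as the median, over reference
#' features (features with a positive count in every sample), of the ratio of
#' the sample's count to the feature's geometric mean. Factors are rescaled to
#' have geometric mean 1.
#'
#' @param counts Integer matrix, features x samples, or a `count_matrix`.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
size_factors <- function(counts) {
  m <- as_count_mat(counts)
  if (ncol(m) < 1) stop_gutreg("no samples")
  ref <- rowSums(m > 0) == ncol(m)
  if (!any(ref)) {
    warning("no feature with positive counts in all samples; falling back to total-count scaling")
    sf <- colSums(m)
    if (any(sf <= 0)) stop_gutreg("sample with zero total count")
  } else {
    sub <- m[ref, , drop = FALSE]
    geo <- exp(rowMeans(log(sub)))
    sf <- apply(sub / geo, 2, median)
  }
  sf <- sf / exp(mean(log(sf)))
  setNames(sf, colnames(m))
}

as_count_mat <- function(counts) {
  if (inherits(counts, "count_matrix")) counts <- counts$counts
  if (inherits(counts, "taxon_table")) counts <- counts$counts
  m <- as.matrix(counts)
  if (!is_count(m)) stop_gutreg("counts must be nonnegative integers")
  storage.mode(m) <- "double"
  m
}

## One NB IRLS fit with log link and log(size factor) offset; alpha fixed.
## Internal scale is natural log; callers convert to log2 for reporting.
nb_irls <- function(y, X, offset = rep(0, length(y)), alpha, tol = 1e-8,
                    maxit = 50L) {
  n <- length(y); p <- ncol(X)
  alpha <- max(alpha, 1e-12)
  mu <- pmax(y, 0.5)
  beta <- rep(0, p)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    eta <- log(mu)
    z <- (eta - offset) + (y - mu) / mu
    w <- mu / (1 + alpha * mu)
    XtW <- t(X * w)
    beta_new <- tryCatch(solve(XtW %*% X, XtW %*% z)[, 1],
                         error = function(e) NULL)
    if (is.null(beta_new)) break
    eta <- pmin(pmax(drop(X %*% beta_new) + offset, -30), 30)
    mu <- exp(eta)
    if (max(abs(beta_new - beta)) < tol) {
      beta <- beta_new; converged <- TRUE; break
    }
    beta <- beta_new
  }
  w <- mu / (1 + alpha * mu)
  info <- t(X * w) %*% X
  cov <- tryCatch(solve(info), error = function(e) matrix(NA_real_, p, p))
  ll <- sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE))
  list(beta = setNames(beta, colnames(X)), cov = cov, mu = mu, loglik = ll,
       converged = converged, alpha = alpha)
}

#' Fit a negative-binomial GLM to one feature
#'
#' Maximizes the NB log-likelihood with a log link and `log(size_factors)`
#' offset, for a known dispersion `alpha`. Coefficients and standard errors
#' are reported on the log2 scale; optimization is on the natural-log scale.
#'
#' @param y Nonnegative integer count vector for one feature.
#' @param X Full-column-rank design matrix (rows = samples).
#' @param size_factors Positive per-sample size factors (default all 1).
#' @param alpha NB dispersion (variance = mu + alpha * mu^2).
#' @return An object of class `nb_fit` with elements `coefficients` and `se`
#'   (log2 scale), `loglik`, `converged`, `mu`, `alpha`, `df`.
#' @export
fit_nb_glm <- function(y, X, size_factors = rep(1, length(y)), alpha) {
  if (!is_count(y)) stop_gutreg("y must be nonnegative integer counts")
  X <- as.matrix(X)
  if (qr(X)$rank < ncol(X)) stop_gutreg("design matrix is not full column rank")
  if (any(size_factors <= 0)) stop_gutreg("size factors must be positive")
  fit <- nb_irls(y, X, offset = log(size_factors), alpha = alpha)
  se <- sqrt(pmax(diag(fit$cov), 0))
  out <- list(coefficients = fit$beta / log(2),
              se = setNames(se / log(2), names(fit$beta)),
              loglik = fit$loglik, converged = fit$converged,
              mu = fit$mu, alpha = fit$alpha, df = ncol(X), X = X)
  class(out) <- "nb_fit"
  out
}

#' @export
print.nb_fit <- function(x, ...) {
  cat("NB GLM fit (log2 scale), alpha =", signif(x$alpha, 3),
      if (!x$converged) "[NOT CONVERGED]" else "", "\n")
  print(cbind(estimate = x$coefficients, se = x$se))
  invisible(x)
}

#' @export
coef.nb_fit <- function(object, ...) object$coefficients

#' @export
logLik.nb_fit <- function(object, ...) {
  structure(object$loglik, df = object$df, class = "logLik")
}

## Cox-Reid adjusted profile log-likelihood for alpha, at fitted means mu.
cr_apl <- function(log_alpha, y, X, mu) {
  alpha <- exp(log_alpha)
  w <- mu / (1 + alpha * mu)
  ld <- determinant(t(X * w) %*% X, logarithm = TRUE)$modulus
  sum(dnbinom(y, size = 1 / alpha, mu = mu, log = TRUE)) - 0.5 * as.numeric(ld)
}

#' Per-feature NB dispersion estimation
#'
#' Maximizes the Cox-Reid adjusted profile likelihood over the dispersion,
#' with fitted means re-estimated once at the optimum. With `shrink = TRUE`
#' (the default when at least 20 features are present) the per-feature
#' estimates are moderated toward a mean-dispersion trend by an
#' empirical-Bayes normal prior on the log dispersion, with the prior width
#' estimated from the spread of the raw estimates around the trend (the
#' expected sampling variance, approximately `trigamma((n - p)/2)`, is
#' subtracted). Features far above the trend keep their raw estimate.
#' Estimates are floored at `alpha_min`; all-zero features are `NA` and
#' flagged.
#'
#' @param counts Features x samples count matrix or `count_matrix`.
#' @param X Design matrix.
#' @param size_factors Optional size factors (computed if missing).
#' @param alpha_min Dispersion floor (default 1e-8).
#' @param shrink Moderate estimates toward the trend (default TRUE).
#' @return Numeric vector of dispersions (NA for all-zero features), with
#'   attributes `excluded` (all-zero flag) and, when shrinking, `raw`,
#'   `trend`, `prior_sd`.
#' @export
estimate_dispersion <- function(counts, X, size_factors = NULL,
                                alpha_min = 1e-8, shrink = TRUE) {
  m <- as_count_mat(counts)
  X <- as.matrix(X)
  if (nrow(m) == 0) return(numeric(0))
  if (nrow(X) - ncol(X) < 1) stop_gutreg("no residual degrees of freedom")
  sf <- size_factors %||% size_factors(m)
  off <- log(sf)
  nfeat <- nrow(m)
  alphas <- rep(NA_real_, nfeat)
  mus <- vector("list", nfeat)
  lo <- log(alpha_min); hi <- log(30)
  for (i in seq_len(nfeat)) {
    y <- m[i, ]
    if (all(y == 0)) next
    mu <- nb_irls(y, X, off, alpha = 0.1)$mu
    opt <- optimize(cr_apl, c(lo, hi), y = y, X = X, mu = mu,
                    maximum = TRUE, tol = 1e-4)
    mu <- nb_irls(y, X, off, alpha = exp(opt$maximum))$mu
    mus[[i]] <- mu
    opt <- optimize(cr_apl, c(lo, hi), y = y, X = X, mu = mu,
                    maximum = TRUE, tol = 1e-4)
    alphas[i] <- max(exp(opt$maximum), alpha_min)
  }
  ok <- which(!is.na(alphas))
  if (shrink && length(ok) >= 20) {
    raw <- alphas
    la <- log(pmax(alphas[ok], 1e-6))
    lmean <- log(vapply(ok, function(i) mean(m[i, ] / sf), 0) + 0.5)
    trend <- if (length(ok) >= 50) {
      fitl <- stats::lowess(lmean, la, f = 1)
      stats::approx(fitl$x, fitl$y, xout = lmean, rule = 2,
                    ties = mean)$y
    } else rep(median(la), length(ok))
    samp_var <- trigamma(max((nrow(X) - ncol(X)) / 2, 0.6))
    spread <- stats::mad(la - trend)^2
    prior_sd <- sqrt(max(spread - samp_var, 0.0625))
    for (k in seq_along(ok)) {
      i <- ok[k]
      if (la[k] > trend[k] + 2 * prior_sd) next  # dispersion outlier: keep raw
      post <- function(lal) cr_apl(lal, m[i, ], X, mus[[i]]) +
        stats::dnorm(lal, trend[k], prior_sd, log = TRUE)
      o <- optimize(post, c(lo, hi), maximum = TRUE, tol = 1e-4)
      alphas[i] <- max(exp(o$maximum), alpha_min)
    }
    attr(alphas, "raw") <- raw
    attr(alphas, "trend") <- exp(trend)
    attr(alphas, "prior_sd") <- prior_sd
  }
  names(alphas) <- rownames(m)
  attr(alphas, "excluded") <- is.na(alphas)
  alphas
}

#' Wald test on one coefficient of an NB fit
#'
#' The statistic is coefficient / SE; the two-sided p-value uses a t
#' reference with the fit's residual degrees of freedom (`n - p`), which
#' keeps the test calibrated at the small replicate numbers typical of
#' these designs (the normal reference is anticonservative below ~10
#' samples per group).
#'
#' @param fit An `nb_fit`.
#' @param contrast Name or index of the coefficient to test.
#' @param df Degrees of freedom of the t reference; defaults to the fit's
#'   residual df. When the dispersion was moderated, the information
#'   contributed by the prior is credited as extra df (see [nb_de()]).
#' @return One-row data.frame: `log2FC`, `SE`, `stat` (= log2FC/SE),
#'   two-sided `p`.
#' @export
wald_test <- function(fit, contrast, df = NULL) {
  stopifnot(inherits(fit, "nb_fit"))
  b <- fit$coefficients[contrast]
  s <- fit$se[contrast]
  if (length(b) != 1 || is.na(b)) stop_gutreg("unknown contrast: ", contrast)
  stat <- if (isTRUE(s > 0) && fit$converged) unname(b / s) else NA_real_
  df <- df %||% max(length(fit$mu) - fit$df, 1)
  data.frame(log2FC = unname(b), SE = unname(s), stat = stat,
             p = if (is.na(stat)) NA_real_ else 2 * stats::pt(-abs(stat), df))
}

## Reduced design must be nested in the full design (column space inclusion).
check_nested <- function(X_full, X_red) {
  fitc <- qr(X_full)
  resid <- X_red - X_full %*% qr.coef(fitc, X_red)
  resid[is.na(resid)] <- 1
  bad <- colSums(abs(resid)) > 1e-8
  if (any(bad))
    stop_gutreg("reduced design not nested in full design; offending columns: ",
                paste(colnames(X_red)[bad] %||% which(bad), collapse = ", "))
  qr(X_full)$rank - qr(X_red)$rank
}

#' Likelihood-ratio test between nested NB fits
#'
#' @param fit_full,fit_reduced `nb_fit` objects fitted to the same counts with
#'   the same dispersion; the reduced design must be nested in the full one.
#' @return One-row data.frame: `stat` (2 * delta log-likelihood, clamped at 0),
#'   `df` (rank difference) and chi-square `p` (p = 1 when df = 0).
#' @export
lrt_test <- function(fit_full, fit_reduced) {
  stopifnot(inherits(fit_full, "nb_fit"), inherits(fit_reduced, "nb_fit"))
  df <- check_nested(fit_full$X, fit_reduced$X)
  stat <- max(0, 2 * (fit_full$loglik - fit_reduced$loglik))
  p <- if (df == 0) 1 else pchisq(stat, df = df, lower.tail = FALSE)
  if (!fit_full$converged || !fit_reduced$converged) {
    stat <- NA_real_; p <- NA_real_
  }
  data.frame(stat = stat, df = df, p = p)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement; `NA` entries are excluded from
#' the family and propagated as `NA`.
#'
#' @param p Numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Adjusted p-values, same length and names as `p`.
#' @export
bh_adjust <- function(p) {
  if (!is.numeric(p)) stop_gutreg("p must be numeric")
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop_gutreg("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  out[ok] <- p.adjust(p[ok], method = "BH")
  names(out) <- names(p)
  out
}

#' Differential test across all features of a count matrix
#'
#' Runs the full engine for one design: size factors, per-feature Cox-Reid
#' dispersion (estimated under the full design), NB GLM fits and either a Wald
#' test on a named coefficient or an LRT against a reduced design, followed by
#' BH adjustment across features.
#'
#' @param counts Features x samples count matrix or `count_matrix`.
#' @param X Full design matrix.
#' @param contrast Coefficient name for the Wald test (reported `log2FC`
#'   refers to this coefficient for both test types).
#' @param X_reduced Reduced design matrix; if supplied, an LRT is performed.
#' @param size_factors Optional precomputed size factors.
#' @param design,contrast_label Labels copied into the result.
#' @return data.frame with columns `feature`, `log2FC`, `SE`, `stat`, `p`,
#'   `padj`, `design`, `contrast`.
#' @export
nb_de <- function(counts, X, contrast = NULL, X_reduced = NULL,
                  size_factors = NULL, design = "custom",
                  contrast_label = contrast %||% "LRT") {
  if (is.null(contrast) && is.null(X_reduced))
    stop_gutreg("either a Wald contrast or a reduced design is required")
  m <- as_count_mat(counts)
  X <- as.matrix(X)
  sf <- size_factors %||% size_factors(m)
  alphas <- estimate_dispersion(m, X, sf)
  rdf <- max(nrow(X) - ncol(X), 1)
  df_test <- rdf
  psd <- attr(alphas, "prior_sd")
  if (!is.null(psd) && is.finite(psd) && psd > 0)
    df_test <- rdf + rdf * trigamma(rdf / 2) / psd^2
  nfeat <- nrow(m)
  res <- data.frame(feature = rownames(m) %||% as.character(seq_len(nfeat)),
                    log2FC = NA_real_, SE = NA_real_, stat = NA_real_,
                    p = NA_real_, padj = NA_real_,
                    design = design, contrast = contrast_label,
                    stringsAsFactors = FALSE)
  for (i in seq_len(nfeat)) {
    if (is.na(alphas[i])) next
    fit <- fit_nb_glm(m[i, ], X, sf, alphas[i])
    if (is.null(X_reduced)) {
      w <- wald_test(fit, contrast, df = df_test)
      res[i, c("log2FC", "SE", "stat", "p")] <- w
    } else {
      fit0 <- fit_nb_glm(m[i, ], X_reduced, sf, alphas[i])
      l <- lrt_test(fit, fit0)
      res$stat[i] <- l$stat; res$p[i] <- l$p
      if (!is.null(contrast) && contrast %in% names(fit$coefficients)) {
        res$log2FC[i] <- fit$coefficients[contrast]
        res$SE[i] <- fit$se[contrast]
      }
    }
  }
  res$padj <- bh_adjust(res$p)
  res
}
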