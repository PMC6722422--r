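## Taxon-table processing: rarefaction, Gini-Simpson diversity, abundance
## filters, and the coculture-effect likelihood-ratio test (does the presence
## of colonocytes change a taxon's abundance trajectory?).

#' Rarefy a taxon table
#'
#' Subsamples every sample's counts without replacement (multivariate
#' hypergeometric) to exactly `depth` reads. Samples whose total is below
#' `depth` are dropped with a warning; samples exactly at `depth` are
#' returned unchanged.
#'
#' @param x A `taxon_table`.
#' @param depth Target depth (positive integer).
#' @param seed RNG seed for reproducibility.
#' @return A rarefied `taxon_table`.
#' @export
rarefy <- function(x, depth, seed = NULL) {
  stopifnot(inherits(x, "taxon_table"))
  if (!is.numeric(depth) || depth <= 0) stop_gutreg("depth must be positive")
  depth <- as.integer(depth)
  tot <- colSums(x$counts)
  keep <- tot >= depth
  if (!all(keep))
    warning(sum(!keep), " sample(s) below depth ", depth, " dropped: ",
            paste(colnames(x$counts)[!keep], collapse = ", "))
  m <- x$counts[, keep, drop = FALSE]
  with_seed(seed, {
    for (j in seq_len(ncol(m))) {
      if (sum(m[, j]) == depth) next
      pool <- rep.int(seq_len(nrow(m)), m[, j])
      take <- sample(pool, depth, replace = FALSE)
      m[, j] <- tabulate(take, nbins = nrow(m))
    }
  })
  taxon_table(m, x$samples[keep, , drop = FALSE])
}

#' Gini-Simpson diversity index
#'
#' Returns `1 - sum(p^2)`: the probability that two random reads come from
#' different taxa. Maximal (`1 - 1/k`) for the uniform distribution over `k`
#' taxa.
#'
#' @param p Vector of taxon proportions summing to 1 within 1e-6.
#' @return Numeric scalar in `[0, 1]`.
#' @export
simpson_index <- function(p) {
  if (any(p < 0)) stop_gutreg("proportions must be nonnegative")
  if (abs(sum(p) - 1) > 1e-6) stop_gutreg("proportions must sum to 1")
  1 - sum(p^2)
}

#' Gini-Simpson diversity per sample
#' @param x A `taxon_table`.
#' @return Named numeric vector, one index per sample.
#' @export
sample_diversity <- function(x) {
  stopifnot(inherits(x, "taxon_table"))
  apply(x$counts, 2, function(cnt) simpson_index(cnt / sum(cnt)))
}

#' Abundance/prevalence filtering of taxa
#'
#' `mode = "association"` keeps taxa whose relative abundance strictly
#' exceeds `min_fraction` in at least one baseline (0h, uncultured) sample;
#' this is the filter feeding the taxon-covariate expression model.
#' `mode = "dynamics"` keeps taxa at relative abundance `>= min_fraction` in
#' at least `min_prevalence` of all samples; this feeds the coculture test.
#'
#' @param x A `taxon_table`.
#' @param min_fraction Relative-abundance threshold in `(0, 1)` (0 allowed,
#'   meaning no abundance filter).
#' @param min_prevalence Fraction of samples (dynamics mode only).
#' @param mode `"association"` or `"dynamics"`.
#' @return Filtered `taxon_table`.
#' @export
filter_taxa_abundance <- function(x, min_fraction = 0.001,
                                  min_prevalence = 0.25,
                                  mode = c("association", "dynamics")) {
  stopifnot(inherits(x, "taxon_table"))
  mode <- match.arg(mode)
  if (min_fraction < 0 || min_fraction >= 1)
    stop_gutreg("min_fraction must be in [0, 1)")
  props <- sweep(x$counts, 2, pmax(colSums(x$counts), 1), "/")
  if (mode == "association") {
    base <- x$samples$time == "0h"
    if (!any(base)) stop_gutreg("no baseline (0h) samples present")
    keep <- apply(props[, base, drop = FALSE] > min_fraction, 1, any)
  } else {
    keep <- rowMeans(props >= min_fraction) >= min_prevalence
  }
  message(sum(keep), " of ", nrow(x$counts), " taxa retained (", mode, ")")
  taxon_table(x$counts[keep, , drop = FALSE], x$samples)
}

#' Coculture-effect likelihood-ratio test for one taxon
#'
#' Gaussian linear models on `log(relative abundance + pseudo)` over the
#' cultured samples (times 1h/2h/4h, both with and without colonocytes):
#' full model `~ time + cocultured`, reduced `~ time`; the LRT statistic is
#' twice the log-likelihood difference, with 1 degree of freedom. Because
#' the models are Gaussian and nested, the LRT statistic is a monotone
#' function of the F statistic, whose null distribution is exact at finite
#' sample size; the reported p-value uses that exact reference (the
#' chi-square approximation is anticonservative at these sample sizes).
#'
#' @param x A `taxon_table`.
#' @param taxon Taxon id.
#' @param pseudo Pseudo-abundance added before the log; default
#'   `0.5 / median(sample depth)`.
#' @param interaction If TRUE, tests `time * cocultured` vs `~ time`
#'   (df = number of time levels).
#' @return One-row data.frame: `taxon`, `stat`, `df`, `p`, and the fitted
#'   presence coefficient `log_fc` (natural-log scale).
#' @export
coculture_lrt <- function(x, taxon, pseudo = NULL, interaction = FALSE) {
  stopifnot(inherits(x, "taxon_table"))
  if (!taxon %in% rownames(x$counts)) stop_gutreg("unknown taxon: ", taxon)
  keep <- x$samples$time != "0h"
  meta <- x$samples[keep, , drop = FALSE]
  cnt <- x$counts[, keep, drop = FALSE]
  if (all(cnt[taxon, ] == 0)) stop_gutreg("taxon has all-zero counts: ", taxon)
  for (arm in c(TRUE, FALSE))
    if (length(unique(meta$time[meta$cocultured == arm])) < 2)
      stop_gutreg("need both arms observed at >= 2 time points")
  depth <- colSums(cnt)
  pseudo <- pseudo %||% (0.5 / median(depth))
  yv <- log(cnt[taxon, ] / depth + pseudo)
  tm <- factor(meta$time)
  cc <- meta$cocultured
  ## block on the source individual when several donors are present: donor
  ## communities differ by orders of magnitude and would otherwise swamp
  ## the residual
  if (length(unique(meta$individual)) > 1) {
    ind <- factor(meta$individual)
    full <- if (interaction) lm(yv ~ ind + tm * cc) else lm(yv ~ ind + tm + cc)
    red <- lm(yv ~ ind + tm)
  } else {
    full <- if (interaction) lm(yv ~ tm * cc) else lm(yv ~ tm + cc)
    red <- lm(yv ~ tm)
  }
  stat <- max(0, 2 * (as.numeric(logLik(full)) - as.numeric(logLik(red))))
  df <- length(coef(full)) - length(coef(red))
  rss1 <- sum(stats::residuals(full)^2)
  rss0 <- sum(stats::residuals(red)^2)
  df2 <- length(yv) - length(coef(full))
  ## degenerate case: the reduced model already fits exactly (e.g. identical
  ## abundances in both arms) - the test is by construction null
  if (rss0 < 1e-12 * length(yv)) {
    stat <- 0; pval <- 1
  } else {
    fstat <- ((rss0 - rss1) / df) / (rss1 / df2)
    pval <- stats::pf(fstat, df, df2, lower.tail = FALSE)
  }
  data.frame(taxon = taxon, stat = stat, df = df, p = pval,
             log_fc = unname(coef(full)[["ccTRUE"]]))
}

#' Coculture-effect LRT across all taxa
#'
#' Runs [coculture_lrt()] for every taxon with a nonzero count, BH-adjusts
#' across taxa, and flags responders at the given FDR.
#'
#' @inheritParams coculture_lrt
#' @param fdr FDR threshold for the `responsive` flag (default 0.10).
#' @return data.frame: `taxon`, `stat`, `df`, `p`, `padj`, `log_fc`,
#'   `responsive`.
#' @export
coculture_lrt_all <- function(x, pseudo = NULL, interaction = FALSE,
                              fdr = 0.10) {
  stopifnot(inherits(x, "taxon_table"))
  ok <- rownames(x$counts)[rowSums(x$counts[, x$samples$time != "0h",
                                            drop = FALSE]) > 0]
  res <- do.call(rbind, lapply(ok, function(t)
    coculture_lrt(x, t, pseudo, interaction)))
  res$padj <- bh_adjust(res$p)
  res$responsive <- !is.na(res$padj) & res$padj < fdr
  rownames(res) <- NULL
  res
}
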