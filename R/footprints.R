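## Fragment-length-stratified, two-condition transcription-factor footprint
## model. Candidate motif sites are scanned with a PWM; Tn5 insertion events
## around each site are binned by fragment length (39-99, 100-139, 140-179,
## 180-250 bp) and condition; a two-component mixture with a logistic prior
## on the PWM score is fitted by EM, with the positional footprint profile
## shared across conditions.

FRAGMENT_BINS <- cbind(lo = c(39L, 100L, 140L, 180L),
                       hi = c(99L, 139L, 179L, 250L))

#' Default ATAC fragment-length bins
#'
#' Four (min, max) bp pairs: 39-99, 100-139, 140-179 and 180-250, matching
#' sub-nucleosomal through di-nucleosomal fragment classes.
#' @return 4 x 2 integer matrix with columns `lo`, `hi`.
#' @export
fragment_bins <- function() FRAGMENT_BINS

#' Scan sequences for PWM matches
#'
#' Scores every position on both strands as the sum over motif columns of
#' `log2(p_motif(base) / p_background(base))` and reports sites whose score
#' reaches `threshold`, in forward coordinates with strand.
#'
#' @param genome Named character vector of sequences.
#' @param motif A `motif_model`.
#' @param threshold Minimum log-odds score (sites at `score >= threshold`).
#' @return data.frame of class `candidate_sites`: `site`, `chrom`, `start`
#'   (0-based), `strand`, `motif`, `score`.
#' @export
scan_pwm <- function(genome, motif, threshold) {
  stopifnot(inherits(motif, "motif_model"))
  W <- motif$width
  lo <- log2(pmax(motif$mat, 1e-12) / motif$background)
  lo_rc <- lo[4:1, W:1, drop = FALSE]  # reverse complement scan
  rownames(lo_rc) <- rownames(lo)
  out <- list()
  for (ch in names(genome)) {
    codes <- match(strsplit(genome[[ch]], "")[[1]], c("A", "C", "G", "T"))
    L <- length(codes)
    if (L < W) next
    n <- L - W + 1L
    sf <- sr <- numeric(n)
    for (j in seq_len(W)) {
      cj <- codes[j:(n + j - 1L)]
      colf <- lo[, j]; colr <- lo_rc[, j]
      sf <- sf + ifelse(is.na(cj), -Inf, colf[cj])
      sr <- sr + ifelse(is.na(cj), -Inf, colr[cj])
    }
    for (str in c("+", "-")) {
      sc <- if (str == "+") sf else sr
      hit <- which(sc >= threshold)
      if (length(hit))
        out[[paste0(ch, str)]] <- data.frame(
          chrom = ch, start = hit - 1L, strand = str, motif = motif$id,
          score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    res <- data.frame(chrom = character(0), start = integer(0),
                      strand = character(0), motif = character(0),
                      score = numeric(0))
  else res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  res <- data.frame(site = if (nrow(res)) sprintf("%s:%s:%d:%s", res$motif,
                                                  res$chrom, res$start,
                                                  res$strand) else character(0),
                    res, row.names = NULL, stringsAsFactors = FALSE)
  class(res) <- c("candidate_sites", "data.frame")
  res
}

#' Build per-bin, per-condition insertion-count matrices
#'
#' Fragments with lengths outside `[39, 250]` are discarded (with a message).
#' Every retained fragment contributes two Tn5 insertion events (+4 offset
#' from each 5' end); each event falling inside a site's oriented window
#' `[start - S, start + W + S)` increments the (relative position, event
#' strand) cell of the matrix for the fragment's length bin and the sample's
#' condition. Windows of minus-strand sites are coordinate-reversed (and
#' event strands flipped) so profiles are motif-oriented. Each matrix has one
#' row per site and `(2S + W) * 2` columns (plus-strand cells first).
#'
#' @param fragments A `fragment_set`.
#' @param sites `candidate_sites` for one motif (unique site ids).
#' @param S Half-window size in bp (default 150).
#' @param W Motif width in bp.
#' @param bins Fragment-length bins (default [fragment_bins()]).
#' @param conditions Condition labels (default: those present in fragments).
#' @return Object of class `insertion_matrix_set`: list with `motif`, `S`,
#'   `W`, `bins`, `conditions`, `sites`, `scores`, and `X`, a list indexed
#'   `[[bin]][[condition]]` of sparse site x (2(2S+W)) matrices.
#' @export
build_insertion_matrices <- function(fragments, sites, S = 150L, W,
                                     bins = fragment_bins(),
                                     conditions = NULL) {
  stopifnot(inherits(fragments, "fragment_set"))
  if (anyDuplicated(sites$site)) stop_gutreg("duplicate site ids")
  conditions <- conditions %||% sort(unique(fragments$condition))
  K <- 2L * S + W
  nb <- nrow(bins)
  ns <- nrow(sites)
  len <- fragments$end - fragments$start
  keep <- len >= min(bins[, "lo"]) & len <= max(bins[, "hi"])
  if (any(!keep))
    message(sum(!keep), " fragment(s) outside [", min(bins[, "lo"]), ", ",
            max(bins[, "hi"]), "] bp discarded")
  ev <- tn5_insertions(structure(fragments[keep, , drop = FALSE],
                                 class = c("fragment_set", "data.frame")))
  ev$bin <- rep(NA_integer_, nrow(ev))
  for (b in seq_len(nb))
    ev$bin[ev$length >= bins[b, "lo"] & ev$length <= bins[b, "hi"]] <- b
  ev <- ev[!is.na(ev$bin) & ev$condition %in% conditions, , drop = FALSE]
  X <- lapply(seq_len(nb), function(b) {
    lapply(setNames(conditions, conditions), function(cc)
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(ns, 2L * K),
                           dimnames = list(sites$site, NULL)))
  })
  if (nrow(ev) && ns) {
    win_start <- sites$start - S
    for (ch in unique(sites$chrom)) {
      si <- which(sites$chrom == ch)
      ei <- which(ev$chrom == ch)
      if (!length(si) || !length(ei)) next
      q <- IRanges::IRanges(start = ev$pos[ei] + 1L, width = 1L)
      s <- IRanges::IRanges(start = win_start[si] + 1L, width = K)
      hits <- as.matrix(IRanges::findOverlaps(q, s))
      if (!nrow(hits)) next
      e <- ei[hits[, 1]]; st <- si[hits[, 2]]
      rel <- ev$pos[e] - win_start[st]
      minus_site <- sites$strand[st] == "-"
      rel[minus_site] <- (K - 1L) - rel[minus_site]
      estr <- ev$strand[e]
      estr[minus_site] <- ifelse(estr[minus_site] == "+", "-", "+")
      colidx <- ifelse(estr == "+", rel + 1L, K + rel + 1L)
      for (b in seq_len(nb)) for (cc in conditions) {
        sel <- ev$bin[e] == b & ev$condition[e] == cc
        if (!any(sel)) next
        X[[b]][[cc]] <- X[[b]][[cc]] +
          Matrix::sparseMatrix(i = st[sel], j = colidx[sel], x = 1,
                               dims = c(ns, 2L * K),
                               dimnames = list(sites$site, NULL))
      }
    }
  }
  structure(list(motif = sites$motif[1] %||% NA_character_, S = S, W = W,
                 bins = bins, conditions = conditions, sites = sites$site,
                 scores = setNames(sites$score, sites$site), X = X),
            class = "insertion_matrix_set")
}

#' @export
print.insertion_matrix_set <- function(x, ...) {
  cat("insertion_matrix_set for motif", x$motif, "\n")
  cat(length(x$sites), "sites,", nrow(x$bins), "fragment bins,",
      length(x$conditions), "condition(s),", 2 * (2 * x$S + x$W),
      "columns per matrix\n")
  invisible(x)
}

## Weighted logistic regression (fractional responses) by Newton-Raphson.
## Returns coefficients, SEs from the Fisher information, and fitted probs.
wlogit <- function(y, x, maxit = 50L, tol = 1e-10) {
  X <- cbind(1, x)
  beta <- c(qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)), 0)
  for (it in seq_len(maxit)) {
    eta <- pmin(pmax(drop(X %*% beta), -30), 30)
    p <- plogis(eta)
    w <- pmax(p * (1 - p), 1e-10)
    g <- crossprod(X, y - p)
    H <- crossprod(X * w, X)
    step <- tryCatch(solve(H, g)[, 1], error = function(e) NULL)
    if (is.null(step)) break
    step <- pmin(pmax(step, -5), 5)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  eta <- pmin(pmax(drop(X %*% beta), -30), 30)
  p <- plogis(eta)
  H <- crossprod(X * pmax(p * (1 - p), 1e-10), X)
  se <- sqrt(diag(tryCatch(solve(H), error = function(e)
    matrix(NA_real_, 2, 2))))
  list(beta = unname(beta), se = unname(se), fitted = p)
}

## Weighted NB ML for a count vector: mean = weighted mean, size by 1-D
## profile optimization. Returns function(t) giving log density.
wnb_fit <- function(tt, w, dist) {
  sw <- sum(w)
  if (sw < 1e-8) return(list(mu = mean(tt) + 0.1, size = Inf))
  mu <- max(sum(w * tt) / sw, 1e-4)
  if (dist == "poisson") return(list(mu = mu, size = Inf))
  nll <- function(ls) -sum(w * dnbinom(tt, size = exp(ls), mu = mu,
                                       log = TRUE))
  opt <- optimize(nll, c(-6, 12))
  size <- exp(opt$minimum)
  if (-opt$objective < sum(w * dpois_safe(tt, mu))) {
    ## Poisson (size -> Inf) fits at least as well
    return(list(mu = mu, size = Inf))
  }
  list(mu = mu, size = size)
}

dpois_safe <- function(tt, mu) stats::dpois(tt, lambda = mu, log = TRUE)

dnb_safe <- function(tt, par) {
  if (is.infinite(par$size)) dpois_safe(tt, par$mu)
  else dnbinom(tt, size = par$size, mu = par$mu, log = TRUE)
}

#' Fit the fragment-length-aware footprint mixture model
#'
#' Two-component mixture per condition with shared structure: a latent bound
#' indicator per (site, condition); prior `logit P(bound) = b0 + b_pwm *
#' score` with coefficients shared across conditions; given bound, the per-bin
#' event total follows a negative binomial (Poisson optional) with a
#' bound-specific rate and positions follow a multinomial footprint profile
#' `pi_l` shared across conditions; given unbound, a lower rate and a uniform
#' positional distribution. Fitted by EM with a small Dirichlet prior on the
#' profiles (the penalized objective is non-decreasing across iterations).
#' The activity Z-score is `b_pwm / SE` from the converged weighted logistic
#' prior fit.
#'
#' @param matrices An `insertion_matrix_set`.
#' @param scores Optional named PWM scores (default: carried by `matrices`).
#' @param dist Event-total family: `"nb"` (default) or `"poisson"`.
#' @param shared_indicator If TRUE, one bound indicator per site shared
#'   across conditions (default: per site and condition).
#' @param pseudo Dirichlet pseudocount per profile cell (default 0.5).
#' @param tol EM convergence tolerance on the penalized log-posterior
#'   (default 1e-6).
#' @param maxit Maximum EM iterations (default 200).
#' @return Object of class `footprint_fit`: prior `coefficients` (`b0`,
#'   `b_pwm`) with `se` and `Z`; `pi` (per-bin profiles, shared across
#'   conditions); `rates` (per bin/condition/component); `posterior` (site x
#'   condition matrix); `logpost` trace; `converged`.
#' @export
fit_footprint_model <- function(matrices, scores = NULL,
                                dist = c("nb", "poisson"),
                                shared_indicator = FALSE, pseudo = 0.5,
                                tol = 1e-6, maxit = 200L) {
  stopifnot(inherits(matrices, "insertion_matrix_set"))
  dist <- match.arg(dist)
  scores <- scores %||% matrices$scores
  ns <- length(matrices$sites)
  if (ns < 50) stop_gutreg("at least 50 candidate sites are required")
  conds <- matrices$conditions
  nb <- nrow(matrices$bins)
  K2 <- 2L * (2L * matrices$S + matrices$W)
  if (any(vapply(matrices$X, function(l) any(vapply(l, ncol, 0L) != K2),
                 TRUE)))
    stop_gutreg("matrix column count does not equal (2S+W)*2")
  if (all(vapply(matrices$X, function(l)
    all(vapply(l, function(m) sum(m) == 0, TRUE)), TRUE)))
    stop_gutreg("all insertion matrices are empty")
  x <- scores[matrices$sites] - mean(scores[matrices$sites])
  Tm <- lapply(seq_len(nb), function(b) sapply(conds, function(cc)
    Matrix::rowSums(matrices$X[[b]][[cc]])))  # totals: site x condition
  ## initialize: bound = upper half by total events
  tot <- Reduce(`+`, lapply(Tm, rowSums))
  gamma <- matrix(pmin(pmax((rank(tot) / ns - 0.25) , 0.05), 0.95),
                  ns, length(conds), dimnames = list(NULL, conds))
  logpi <- vector("list", nb)
  prior <- list(beta = c(0, 0), se = c(NA, NA))
  lunif <- -log(K2)
  logpost <- numeric(0)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    ## ---- M-step ----
    rates <- vector("list", nb)
    for (b in seq_len(nb)) {
      wc <- Reduce(`+`, lapply(conds, function(cc)
        Matrix::colSums(matrices$X[[b]][[cc]] * gamma[, cc])))
      pi_b <- (wc + pseudo) / sum(wc + pseudo)
      logpi[[b]] <- log(pi_b)
      rates[[b]] <- lapply(setNames(conds, conds), function(cc) {
        tt <- Tm[[b]][, cc]
        list(bound = wnb_fit(tt, gamma[, cc], dist),
             unbound = wnb_fit(tt, 1 - gamma[, cc], dist))
      })
    }
    pfit <- wlogit(as.vector(gamma), rep(x, length(conds)))
    prior <- pfit
    eta0 <- pmin(pmax(pfit$beta[1] + pfit$beta[2] * x, -30), 30)
    ## ---- E-step + objective ----
    llb <- llu <- matrix(0, ns, length(conds), dimnames = list(NULL, conds))
    for (b in seq_len(nb)) for (ci in seq_along(conds)) {
      cc <- conds[ci]
      tt <- Tm[[b]][, cc]
      llb[, ci] <- llb[, ci] + dnb_safe(tt, rates[[b]][[cc]]$bound) +
        as.numeric(matrices$X[[b]][[cc]] %*% logpi[[b]])
      llu[, ci] <- llu[, ci] + dnb_safe(tt, rates[[b]][[cc]]$unbound) +
        tt * lunif
    }
    if (shared_indicator) {
      lb <- eta0 + rowSums(llb); lu <- rowSums(llu)
      mx <- pmax(lb, lu)
      lobj <- sum(mx + log1p(exp(pmin(lb, lu) - mx)) - log1p(exp(eta0)))
      g1 <- plogis(lb - lu)
      gamma <- matrix(g1, ns, length(conds), dimnames = list(NULL, conds))
    } else {
      lb <- eta0 + llb; lu <- llu
      mx <- pmax(lb, lu)
      lobj <- sum(mx + log1p(exp(pmin(lb, lu) - mx))) -
        length(conds) * sum(log1p(exp(eta0)))
      gamma <- plogis(lb - lu)
    }
    for (b in seq_len(nb)) lobj <- lobj + pseudo * sum(logpi[[b]])
    logpost <- c(logpost, lobj)
    if (it > 1 && abs(lobj - logpost[it - 1]) < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning("footprint EM did not converge in ", maxit, " iterations")
  Z <- if (is.na(prior$se[2]) || prior$se[2] <= 0) NA_real_
       else prior$beta[2] / prior$se[2]
  structure(list(motif = matrices$motif,
                 coefficients = c(b0 = prior$beta[1], b_pwm = prior$beta[2]),
                 se = c(b0 = prior$se[1], b_pwm = prior$se[2]), Z = Z,
                 pi = lapply(logpi, exp), rates = rates,
                 posterior = gamma, sites = matrices$sites,
                 scores = scores[matrices$sites], conditions = conds,
                 S = matrices$S, W = matrices$W, dist = dist,
                 shared_indicator = shared_indicator, pseudo = pseudo,
                 logpost = logpost, converged = converged),
            class = "footprint_fit")
}

#' @export
print.footprint_fit <- function(x, ...) {
  cat("footprint_fit for motif", x$motif, "(", length(x$sites), "sites,",
      length(x$conditions), "condition(s) )\n")
  cat(sprintf("prior: logit P(bound) = %.3f + %.3f * score   Z = %.2f%s\n",
              x$coefficients[1], x$coefficients[2],
              if (is.na(x$Z)) NA else x$Z,
              if (!x$converged) "  [NOT CONVERGED]" else ""))
  invisible(x)
}

#' @export
summary.footprint_fit <- function(object, ...) {
  post <- object$posterior
  cat("Fragment-length-stratified footprint model:", object$motif, "\n")
  print(object)
  cat("mean posterior P(bound) by condition:\n")
  print(round(colMeans(post), 4))
  cat("sites with posterior > 0.99 by condition:\n")
  print(colSums(post > 0.99))
  invisible(object)
}

#' @export
coef.footprint_fit <- function(object, ...) object$coefficients

#' @export
logLik.footprint_fit <- function(object, ...) {
  structure(object$logpost[length(object$logpost)],
            df = 2 + length(object$pi) * (length(object$pi[[1]]) - 1),
            class = "logLik")
}

#' @export
fitted.footprint_fit <- function(object, ...) object$posterior

#' @export
plot.footprint_fit <- function(x, bin = 1, ...) {
  K <- 2 * x$S + x$W
  pr <- x$pi[[bin]]
  plot(seq_len(K) - x$S, pr[1:K], type = "l", col = "firebrick",
       xlab = "position relative to motif start (bp)",
       ylab = "insertion probability",
       main = paste0(x$motif, ", fragment bin ", bin), ...)
  graphics::lines(seq_len(K) - x$S, pr[(K + 1):(2 * K)], col = "navy")
  graphics::legend("topright", legend = c("+ events", "- events"),
                   col = c("firebrick", "navy"), lty = 1, bty = "n")
  invisible(x)
}

#' Call active motifs and bound sites
#'
#' A motif is active when its prior PWM-score effect has `Z > z_threshold`
#' (strict). A site is bound in a condition when its posterior exceeds
#' `posterior_threshold` (strict). Non-converged fits are excluded with a
#' warning.
#'
#' @param fits Named list of `footprint_fit` objects.
#' @param z_threshold Activity threshold (default 5).
#' @return Character vector of active motif ids.
#' @export
call_active_motifs <- function(fits, z_threshold = 5) {
  if (inherits(fits, "footprint_fit")) fits <- list(fits)
  ok <- vapply(fits, function(f) f$converged, TRUE)
  if (any(!ok))
    warning("excluding non-converged fits: ",
            paste(vapply(fits[!ok], function(f) f$motif, ""), collapse = ", "))
  z <- vapply(fits[ok], function(f) f$Z %||% NA_real_, 0)
  vapply(fits[ok][!is.na(z) & z > z_threshold], function(f) f$motif, "")
}

#' @rdname call_active_motifs
#' @param fit A `footprint_fit`.
#' @param condition Condition label.
#' @param posterior_threshold Binding threshold (default 0.99).
#' @return For `call_bound_sites`: character vector of bound site ids.
#' @export
call_bound_sites <- function(fit, condition, posterior_threshold = 0.99) {
  stopifnot(inherits(fit, "footprint_fit"))
  if (!condition %in% fit$conditions)
    stop_gutreg("unknown condition: ", condition)
  fit$sites[fit$posterior[, condition] > posterior_threshold]
}

#' Logistic enrichment of footprint counts in DE genes
#'
#' Per motif, a logistic regression of the gene-level DE indicator on the
#' number of that motif's bound footprints within `distance` bp of the gene
#' TSS: `logit P(DE) = b0 + b1 * count`. BH across motifs. Motifs with no
#' footprint near any gene are skipped; complete-separation fits are flagged
#' and excluded from the family.
#'
#' @param gene_de data.frame with columns `gene`, `de` (logical), `chrom`,
#'   `tss`.
#' @param bound_sites Named list (by motif) of data.frames with `chrom` and
#'   `start` of bound footprints.
#' @param distance Window around the TSS in bp (default 50000).
#' @param fdr FDR threshold for the `significant` flag (default 0.10).
#' @return data.frame: `motif`, `b0`, `b1`, `se`, `z`, `p`, `padj`,
#'   `flagged`, `significant`.
#' @export
footprint_de_enrichment <- function(gene_de, bound_sites, distance = 50000L,
                                    fdr = 0.10) {
  stopifnot(all(c("gene", "de", "chrom", "tss") %in% names(gene_de)))
  rows <- lapply(names(bound_sites), function(m) {
    bs <- bound_sites[[m]]
    cnt <- integer(nrow(gene_de))
    if (!is.null(bs) && nrow(bs)) {
      for (ch in unique(gene_de$chrom)) {
        gi <- which(gene_de$chrom == ch)
        pos <- bs$start[bs$chrom == ch]
        if (!length(gi) || !length(pos)) next
        cnt[gi] <- vapply(gene_de$tss[gi], function(t)
          sum(abs(pos - t) <= distance), 0L)
      }
    }
    if (all(cnt == 0)) {
      message("motif ", m, " has no footprint near any gene; skipped")
      return(NULL)
    }
    fit <- suppressWarnings(glm(gene_de$de ~ cnt, family = binomial()))
    co <- summary(fit)$coefficients
    flagged <- !fit$converged || abs(co[2, 1]) > 10 || co[2, 2] > 50
    data.frame(motif = m, b0 = co[1, 1], b1 = co[2, 1], se = co[2, 2],
               z = co[2, 3], p = co[2, 4], flagged = flagged,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res))
    return(data.frame(motif = character(0), b0 = numeric(0), b1 = numeric(0),
                      se = numeric(0), z = numeric(0), p = numeric(0),
                      padj = numeric(0), flagged = logical(0),
                      significant = logical(0)))
  p_for_adj <- ifelse(res$flagged, NA_real_, res$p)
  res$padj <- bh_adjust(p_for_adj)
  res$significant <- !is.na(res$padj) & res$padj < fdr
  rownames(res) <- NULL
  res
}
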