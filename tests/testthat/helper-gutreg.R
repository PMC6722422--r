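# Shared fixtures and independent oracle implementations used across the
# suite. Oracles are deliberately naive (loops, enumeration, closed forms)
# and independent of the package's code paths.

small_config <- function(seed = 1L, ...) {
  args <- list(n_transcripts = 200L, n_taxa = 60L,
               rarefaction_depth = 20000L, genome_length = 300000L,
               n_motif_instances = 200L, bg_frag_per_window = 10,
               seed = seed)
  over <- list(...)
  args[names(over)] <- over
  do.call(sim_config, args)
}

## Brute-force median-of-ratios size factors (independent reimplementation).
oracle_size_factors <- function(m) {
  ref <- apply(m, 1, function(r) all(r > 0))
  geo <- exp(rowMeans(log(m[ref, , drop = FALSE])))
  sf <- vapply(seq_len(ncol(m)), function(j)
    median(m[ref, j] / geo), 0)
  sf / exp(mean(log(sf)))
}

## Hand step-up BH.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

## Two-sided Fisher exact p by full hypergeometric enumeration of tables
## with the observed margins.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  m <- a + b; n <- cc + d; k <- a + cc
  xs <- max(0, k - n):min(k, m)
  probs <- dhyper(xs, m, n, k)
  p_obs <- dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

## Naive single-bin, single-condition footprint EM (Poisson totals),
## written with explicit loops; must match the packaged fit.
oracle_footprint_em <- function(X, scores, pseudo = 0.5, maxit = 200,
                                tol = 1e-6) {
  X <- as.matrix(X)
  ns <- nrow(X); K2 <- ncol(X)
  tt <- rowSums(X)
  x <- scores - mean(scores)
  gamma <- pmin(pmax((rank(tt) / ns - 0.25), 0.05), 0.95)
  lunif <- -log(K2)
  wlog <- function(y, x) {
    B <- cbind(1, x); beta <- c(qlogis(min(max(mean(y), 1e-6), 1 - 1e-6)), 0)
    for (i in 1:50) {
      p <- plogis(pmin(pmax(B %*% beta, -30), 30))
      H <- t(B * as.vector(p * (1 - p))) %*% B
      st <- solve(H + diag(1e-10, 2), t(B) %*% (y - p))
      st <- pmin(pmax(st, -5), 5)
      beta <- beta + st
      if (max(abs(st)) < 1e-10) break
    }
    beta
  }
  prev <- -Inf
  for (it in seq_len(maxit)) {
    wc <- colSums(X * gamma)
    pi1 <- (wc + pseudo) / sum(wc + pseudo)
    mu_b <- max(sum(gamma * tt) / max(sum(gamma), 1e-8), 1e-4)
    mu_u <- max(sum((1 - gamma) * tt) / max(sum(1 - gamma), 1e-8), 1e-4)
    beta <- wlog(gamma, x)
    eta0 <- pmin(pmax(beta[1] + beta[2] * x, -30), 30)
    llb <- dpois(tt, mu_b, log = TRUE) + as.vector(X %*% log(pi1))
    llu <- dpois(tt, mu_u, log = TRUE) + tt * lunif
    lb <- eta0 + llb; lu <- llu
    mx <- pmax(lb, lu)
    obj <- sum(mx + log1p(exp(pmin(lb, lu) - mx))) - sum(log1p(exp(eta0))) +
      pseudo * sum(log(pi1))
    gamma <- as.vector(plogis(lb - lu))
    if (it > 1 && abs(obj - prev) < tol) break
    prev <- obj
  }
  list(posterior = gamma, pi = pi1, beta = as.vector(beta))
}

## Quadratic all-pairs region-TSS linking scan.
oracle_links <- function(regions, ann, distance) {
  out <- list()
  for (i in seq_len(nrow(regions))) for (j in seq_len(nrow(ann))) {
    if (regions$chrom[i] != ann$chrom[j]) next
    p <- ann$tss[j]; s <- regions$start[i]; e <- regions$end[i]
    d <- if (p >= s && p < e) 0 else min(abs(p - s), abs(p - (e - 1)))
    if (d <= distance)
      out[[length(out) + 1]] <- data.frame(
        region = sprintf("%s:%d-%d", regions$chrom[i], s, e),
        transcript = ann$transcript[j], distance = d)
  }
  do.call(rbind, out)
}

make_region_set <- function(counts, condition) {
  n <- nrow(counts)
  samp <- data.frame(sample = colnames(counts), condition = condition)
  regions <- data.frame(chrom = "chrT", start = (0:(n - 1)) * 300,
                        end = (1:n) * 300)
  rownames(counts) <- sprintf("chrT:%d-%d", regions$start, regions$end)
  structure(list(regions = regions, counts = counts, samples = samp,
                 lib_sizes = pmax(colSums(counts), 1)),
            class = "region_set")
}

make_taxon_table <- function(counts, time, cocultured, individual = "Ind1") {
  samples <- data.frame(sample = colnames(counts),
                        individual = individual, time = time,
                        cocultured = cocultured)
  taxon_table(counts, samples)
}
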