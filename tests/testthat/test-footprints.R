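pwm_fixed <- function() {
  mat <- cbind(c(0.85, 0.05, 0.05, 0.05),
               c(0.05, 0.85, 0.05, 0.05),
               c(0.05, 0.05, 0.85, 0.05),
               c(0.05, 0.05, 0.05, 0.85),
               c(0.85, 0.05, 0.05, 0.05))
  motif_model("MFIX", mat)
}

test_that("PWM scanning: hand-computed scores, background nullity, strand symmetry", {
  m <- pwm_fixed()
  genome <- c(chr1 = "TTACGTATT")
  hits <- scan_pwm(genome, m, threshold = -Inf)
  ## consensus ACGTA at 0-based position 2 on the forward strand
  best <- hits[hits$start == 2 & hits$strand == "+", ]
  expect_equal(best$score, 5 * log2(0.85 / 0.25), tolerance = 1e-12)

  ## background-equal PWM scores 0 everywhere
  flat <- motif_model("FLAT", matrix(0.25, 4, 5))
  h0 <- scan_pwm(c(c1 = "ACGTACGTAC"), flat, threshold = -1)
  expect_true(all(abs(h0$score) < 1e-12))

  ## reverse-complemented genome gives the same site set with strands flipped
  rc <- function(s) chartr("ACGT", "TGCA",
                           paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  g <- c(chr1 = "GGACGTATTCCA")
  h1 <- scan_pwm(g, m, threshold = 2)
  h2 <- scan_pwm(c(chr1 = rc(g[[1]])), m, threshold = 2)
  expect_equal(nrow(h1), nrow(h2))
  expect_setequal(round(h1$score, 9), round(h2$score, 9))
  L <- nchar(g[[1]])
  expect_setequal(h2$start, L - h1$start - m$width)
  expect_setequal(h2$strand, ifelse(h1$strand == "+", "-", "+"))

  ## sequence shorter than the motif yields no sites
  expect_equal(nrow(scan_pwm(c(s = "ACG"), m, -Inf)), 0)
})

test_that("insertion matrices: hand-traced +4 offset, shapes, and bin bounds", {
  sites <- data.frame(site = "s+", chrom = "chr1", start = 150L,
                      strand = "+", motif = "MFIX", score = 3,
                      stringsAsFactors = FALSE)
  ## site window: [0, 310) with S = 150, W = 10
  fr <- fragment_set("chr1", 100, 180, "sampA", "treatment")
  ims <- build_insertion_matrices(fr, sites, S = 150L, W = 10L,
                                  conditions = c("treatment", "control"))
  K <- 2 * 150 + 10
  expect_equal(ims$S, 150L)
  for (b in 1:4) for (cc in c("treatment", "control"))
    expect_equal(ncol(ims$X[[b]][[cc]]), 2 * K)
  ## length 80 -> bin 1; + event at 104 -> column 105; - event at 175 ->
  ## column K + 176
  X1 <- as.matrix(ims$X[[1]]$treatment)
  expect_equal(sum(X1), 2)
  expect_equal(unname(X1[1, 105]), 1)
  expect_equal(unname(X1[1, K + 176]), 1)
  expect_true(all(sapply(2:4, function(b) sum(ims$X[[b]]$treatment) == 0)))
  expect_equal(sum(ims$X[[1]]$control), 0)

  ## minus-strand site: coordinates are reversed and event strands flipped
  sites_m <- within(sites, {site <- "s-"; strand <- "-"})
  ims_m <- build_insertion_matrices(fr, sites_m, S = 150L, W = 10L,
                                    conditions = "treatment")
  Xm <- as.matrix(ims_m$X[[1]]$treatment)
  ## genome + event at 104 (rel 104) -> reversed rel (309 - 104) = 205,
  ## flipped to a minus event -> column K + 206
  expect_equal(unname(Xm[1, K + 206]), 1)
  expect_equal(unname(Xm[1, (309 - 175) + 1]), 1)

  ## fragment lengths 38 and 251 contribute nothing (bins 39-99 ... 180-250)
  fr_out <- fragment_set("chr1", c(100, 100, 100), c(138, 351, 139),
                         rep("sampA", 3), rep("treatment", 3))
  expect_message(ims_o <- build_insertion_matrices(fr_out, sites, S = 150L,
                                                   W = 10L,
                                                   conditions = "treatment"),
                 "2 fragment")
  expect_equal(sum(sapply(ims_o$X, function(l) sum(l$treatment))), 2)

  ## no fragments: all-zero matrices with the correct shape
  fr0 <- fragment_set(character(0), integer(0), integer(0), character(0),
                      character(0))
  ims0 <- build_insertion_matrices(fr0, sites, S = 150L, W = 10L,
                                   conditions = "treatment")
  expect_equal(dim(ims0$X[[1]]$treatment), c(1L, 2L * K))
  expect_equal(sum(sapply(ims0$X, function(l) sum(l$treatment))), 0)

  expect_error(build_insertion_matrices(fr, rbind(sites, sites), S = 150L,
                                        W = 10L), "duplicate")
})

test_that("events in matrices never exceed twice the retained fragments", {
  cfg <- small_config(seed = 31)
  at <- gen_atac_fragments(cfg)
  st <- at$sites[at$sites$motif == at$sites$motif[1], ]
  ims <- suppressMessages(
    build_insertion_matrices(at$fragments, st, S = cfg$S,
                             W = cfg$motif_width))
  len <- at$fragments$end - at$fragments$start
  retained <- sum(len >= 39 & len <= 250)
  total <- sum(sapply(ims$X, function(l) sum(sapply(l, sum))))
  expect_lte(total, 2 * retained)
})

test_that("single-bin single-condition fit matches a brute-force EM", {
  set.seed(32)
  ns <- 100; K2 <- 80
  scores <- rnorm(ns, 0, 2)
  bound <- runif(ns) < plogis(0.2 + 0.8 * scores)
  prof <- prop.table(c(rep(1, 30), rep(4, 20), rep(1, 30)))
  X <- t(sapply(seq_len(ns), function(i) {
    n <- rpois(1, if (bound[i]) 60 else 15)
    if (bound[i]) tabulate(sample.int(K2, n, TRUE, prob = prof), K2)
    else tabulate(sample.int(K2, n, TRUE), K2)
  }))
  rownames(X) <- paste0("site", seq_len(ns))
  names(scores) <- rownames(X)
  ims <- list(motif = "M", S = (K2 / 2 - 10) / 2, W = 10,
              bins = fragment_bins()[1, , drop = FALSE],
              conditions = "treatment", sites = rownames(X),
              scores = scores,
              X = list(list(treatment = Matrix::Matrix(X, sparse = TRUE))))
  ims$S <- (K2 / 2 - 10) / 2  # so that 2*(2S+W) = K2
  class(ims) <- "insertion_matrix_set"
  fit <- fit_footprint_model(ims, dist = "poisson")
  oracle <- oracle_footprint_em(X, scores)
  expect_lt(max(abs(fit$posterior[, 1] - oracle$posterior)), 1e-4)
  expect_lt(max(abs(fit$pi[[1]] - oracle$pi)), 1e-6)
  expect_equal(unname(coef(fit)), oracle$beta, tolerance = 1e-4)
  ## EM objective is non-decreasing
  expect_true(all(diff(fit$logpost) > -1e-6))
})

test_that("null PWM effect never reaches the Z > 5 activity call", {
  zs <- vapply(1:200, function(k) {
    set.seed(3300 + k)
    ns <- 120; K2 <- 60
    scores <- setNames(rnorm(ns, 0, 2), paste0("s", 1:ns))
    bound <- runif(ns) < 0.4          # binding unrelated to the score
    prof <- prop.table(c(rep(1, 20), rep(5, 20), rep(1, 20)))
    X <- t(sapply(seq_len(ns), function(i) {
      n <- rpois(1, if (bound[i]) 50 else 12)
      if (bound[i]) tabulate(sample.int(K2, n, TRUE, prob = prof), K2)
      else tabulate(sample.int(K2, n, TRUE), K2)
    }))
    rownames(X) <- names(scores)
    ims <- structure(list(motif = "M", S = (K2 / 2 - 10) / 2, W = 10,
                          bins = fragment_bins()[1, , drop = FALSE],
                          conditions = "c1", sites = names(scores),
                          scores = scores,
                          X = list(list(c1 = Matrix::Matrix(X,
                                                            sparse = TRUE)))),
                     class = "insertion_matrix_set")
    fit <- suppressWarnings(fit_footprint_model(ims, dist = "poisson"))
    fit$Z
  }, 0)
  expect_equal(sum(abs(zs) > 5, na.rm = TRUE), 0)
  expect_lt(abs(mean(zs, na.rm = TRUE)), 0.3)
})

test_that("parameter recovery: posteriors, profiles and condition exchangeability", {
  cfg <- sim_config(n_transcripts = 50L, n_motifs = 1L, n_active_motifs = 1L,
                    n_motif_instances = 2000L, genome_length = 700000L,
                    prior_b0 = -0.85, atac_prior_shift = 0,
                    bg_frag_per_window = 0, seed = 34)
  K <- 2L * cfg$S + cfg$motif_width
  prof <- rep(1, K)
  prof[(cfg$S + 1):(cfg$S + cfg$motif_width)] <- 0.05
  prof[(cfg$S - 14):cfg$S] <- 8
  prof[(cfg$S + cfg$motif_width + 1):(cfg$S + cfg$motif_width + 15)] <- 8
  prof <- prof / sum(prof)
  at <- gen_atac_fragments(cfg, profile = prof)
  ims <- build_insertion_matrices(at$fragments, at$sites, S = cfg$S,
                                  W = cfg$motif_width)
  fit <- fit_footprint_model(ims)
  expect_true(fit$converged)
  ## posterior > 0.5 classification AUC at least 0.95 against truth
  lab <- fit$sites %in% at$truth$bound_sites$treatment
  po <- fit$posterior[, "treatment"]
  auc <- (sum(rank(po)[lab]) - sum(lab) * (sum(lab) + 1) / 2) /
    (sum(lab) * sum(!lab))
  expect_gte(auc, 0.95)
  ## per-bin profile recovery r >= 0.95 against the effective truth
  for (b in 1:4)
    expect_gte(cor(fit$pi[[b]], at$truth$effective_profile[[b]]), 0.95)
  ## profiles are shared across conditions by construction (single pi set)
  expect_length(fit$pi, 4)
  ## with identical generative parameters in both conditions the
  ## per-condition posteriors agree
  agree <- lab == (fit$sites %in% at$truth$bound_sites$control)
  expect_lt(mean(abs(fit$posterior[agree, "treatment"] -
                       fit$posterior[agree, "control"])), 0.05)
})

test_that("activity and binding calls use strict thresholds", {
  fake <- structure(list(motif = "MK", Z = 5.0, converged = TRUE,
                         posterior = matrix(c(0.995, 0.99, 0.2),
                                            dimnames = list(NULL, "treatment")),
                         sites = c("a", "b", "c"),
                         conditions = "treatment"),
                    class = "footprint_fit")
  expect_length(call_active_motifs(list(fake)), 0)       # Z = 5 exactly
  fake$Z <- 5.0001
  expect_equal(call_active_motifs(list(fake)), "MK")
  fake$converged <- FALSE
  expect_warning(out <- call_active_motifs(list(fake)), "non-converged")
  expect_length(out, 0)

  fake$converged <- TRUE
  expect_equal(call_bound_sites(fake, "treatment"), "a")  # 0.99 not > 0.99
  fake$posterior[] <- 0
  expect_length(call_bound_sites(fake, "treatment"), 0)
  expect_error(call_bound_sites(fake, "nope"), "unknown condition")
})

test_that("footprint count logistic enrichment: recovery, null calibration, separation", {
  ## parameter recovery: planted slope 0.5 per footprint over 4000 genes
  est <- vapply(1:60, function(k) {
    set.seed(3500 + k)
    n <- 4000
    cnt <- rpois(n, 1.2)
    de <- runif(n) < plogis(-2 + 0.5 * cnt)
    gd <- data.frame(gene = paste0("g", 1:n), de = de, chrom = "c",
                     tss = seq_len(n) * 200000)
    bs <- data.frame(chrom = rep("c", sum(cnt)),
                     start = rep(gd$tss, cnt))
    footprint_de_enrichment(gd, list(M = bs))$b1
  }, 0)
  expect_lt(abs(mean(est) - 0.5), 0.1)

  ## complete separation is flagged, not reported as significant
  gd <- data.frame(gene = paste0("g", 1:200),
                   de = rep(c(TRUE, FALSE), each = 100), chrom = "c",
                   tss = seq_len(200) * 200000)
  bs <- data.frame(chrom = "c", start = gd$tss[gd$de])
  sep <- footprint_de_enrichment(gd, list(M = bs))
  expect_true(sep$flagged[1])
  expect_true(is.na(sep$padj[1]))

  ## motif with no footprint near any gene is skipped
  far <- data.frame(chrom = "other", start = 5)
  expect_message(out <- footprint_de_enrichment(gd, list(MX = far)),
                 "skipped")
  expect_equal(nrow(out), 0)
})
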