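test_that("unknown design names are rejected with the list of valid designs", {
  cfg <- small_config()
  expect_error(gen_rnaseq_counts(cfg, "bogus"), "time_replicate")
  expect_error(design_spec("bogus"), "spikein_dose")
})

test_that("generators are deterministic under a fixed seed", {
  cfg <- small_config(seed = 9)
  a <- gen_rnaseq_counts(cfg, "time_replicate")
  b <- gen_rnaseq_counts(cfg, "time_replicate")
  expect_identical(a$counts$counts, b$counts$counts)
  expect_identical(a$truth$de_features, b$truth$de_features)
  ta <- gen_taxon_table(cfg); tb <- gen_taxon_table(cfg)
  expect_identical(ta$taxa$counts, tb$taxa$counts)
  fa <- gen_atac_fragments(cfg); fb <- gen_atac_fragments(cfg)
  expect_identical(fa$fragments$start, fb$fragments$start)
  expect_identical(fa$genome, fb$genome)
  ## the caller's RNG stream is untouched
  set.seed(123); x1 <- runif(1)
  set.seed(123); invisible(gen_taxon_table(cfg)); x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("null expression config has empty truth and exchangeable counts", {
  cfg <- small_config(seed = 10, de_fraction = 0)
  sim <- gen_rnaseq_counts(cfg, "time_replicate")
  expect_length(sim$truth$de_features, 0)
  expect_true(all(sim$truth$effect_sizes == 0))
  ## treated and control group means agree within sampling error
  trt <- sim$counts$samples$condition == "treatment"
  sf <- size_factors(sim$counts$counts)
  norm <- sweep(sim$counts$counts, 2, sf, "/")
  ratio <- rowMeans(norm[, trt]) / rowMeans(norm[, !trt])
  expect_lt(abs(median(log2(ratio), na.rm = TRUE)), 0.1)
})

test_that("planted fold changes match an independent NB Monte-Carlo oracle", {
  cfg <- sim_config(n_transcripts = 2000L, de_fraction = 0.1,
                    effect_size = 1, seed = 12)
  sim <- gen_rnaseq_counts(cfg, "time_replicate")
  cm <- sim$counts
  sel <- cm$samples$time == "2h"
  sf <- size_factors(cm$counts[, sel])
  norm <- sweep(cm$counts[, sel], 2, sf, "/")
  trt <- cm$samples$condition[sel] == "treatment"
  up <- names(sim$truth$effect_sizes)[sim$truth$effect_sizes == 1]
  obs <- mean(rowMeans(norm[up, trt]) / rowMeans(norm[up, !trt]))
  ## oracle: direct NB sampling under the same parameters
  set.seed(99)
  oracle <- replicate(200, {
    mu <- rlnorm(1, cfg$baseline_meanlog, cfg$baseline_sdlog)
    mean(rnbinom(5, mu = 2 * mu, size = 10)) /
      mean(pmax(rnbinom(3, mu = mu, size = 10), 1))
  })
  expect_lt(abs(obs - mean(oracle)) / mean(oracle), 0.15)
  expect_gt(obs, 1.7); expect_lt(obs, 2.6)
})

test_that("taxon table: column sums, depth guard, null and planted shifts", {
  cfg <- small_config(seed = 13)
  tt <- gen_taxon_table(cfg)$taxa
  expect_true(all(colSums(tt$counts) == cfg$rarefaction_depth))
  expect_error(gen_taxon_table(small_config(rarefaction_depth = 10L)),
               "cannot represent")

  ## null: proportions independent of the coculture flag
  perm_rej <- vapply(1:60, function(k) {
    cfg0 <- small_config(seed = 1400 + k, n_responsive = 0L)
    t0 <- gen_taxon_table(cfg0)$taxa
    cult <- t0$samples$time != "0h"
    props <- sweep(t0$counts[, cult], 2, colSums(t0$counts[, cult]), "/")
    cc <- t0$samples$cocultured[cult]
    tax <- sample(rownames(props), 1)
    ## permutation test within donors on one random taxon
    obs <- mean(props[tax, cc]) - mean(props[tax, !cc])
    null <- replicate(120, {
      p <- sample(cc); mean(props[tax, p]) - mean(props[tax, !p])
    })
    mean(abs(null) >= abs(obs)) < 0.01
  }, TRUE)
  expect_lte(mean(perm_rej), 0.05)

  ## planted 4x coculture shift is recovered
  cfg4 <- small_config(seed = 15, n_responsive = 1L, responsive_fold = 4)
  sim4 <- gen_taxon_table(cfg4)
  tax <- sim4$truth$responsive_taxa
  fold <- sim4$truth$responsive_folds[[tax]]
  t4 <- sim4$taxa
  cult <- t4$samples$time != "0h"
  props <- sweep(t4$counts[, cult], 2, colSums(t4$counts[, cult]), "/")
  cc <- t4$samples$cocultured[cult]
  obs_ratio <- mean(props[tax, cc]) / mean(props[tax, !cc])
  ## oracle: direct simulation of the generative model (many replicates)
  expect_equal(log(obs_ratio), log(fold), tolerance = 0.35)
})

test_that("fragment conversion honours the +4 insertion convention (hand trace)", {
  fr <- fragment_set("chr1", 100, 180, "s1", "treatment")
  ev <- tn5_insertions(fr)
  expect_equal(sort(ev$pos), c(104, 175))
  expect_equal(ev$strand[order(ev$pos)], c("+", "-"))
})

test_that("planted uniform profile yields flat insertion histograms at bound sites", {
  mk <- function(k) small_config(seed = 1600 + k, n_motifs = 1L,
                                 n_active_motifs = 1L,
                                 n_motif_instances = 60L,
                                 bg_frag_per_window = 0,
                                 prior_b0 = 3, prior_b_pwm = 0,
                                 bound_rate = 40,
                                 atac_treat_bio = 3L, atac_control_bio = 1L)
  cfg <- mk(0)
  K <- 2L * cfg$S + cfg$motif_width
  unif <- rep(1 / K, K)
  rej <- vapply(1:40, function(k) {
    cfg <- mk(k)
    at <- gen_atac_fragments(cfg, profile = unif)
    ims <- build_insertion_matrices(at$fragments, at$sites, S = cfg$S,
                                    W = cfg$motif_width)
    ## plus-strand (drawn) events pooled over bound sites and bins
    counts <- Reduce(`+`, lapply(1:4, function(b)
      Matrix::colSums(ims$X[[b]]$treatment) +
        Matrix::colSums(ims$X[[b]]$control)))[1:K]
    suppressWarnings(stats::chisq.test(counts)$p.value) < 0.01
  }, TRUE)
  expect_lte(mean(rej), 0.05)
})

test_that("PWM generation: columns sum to 1; infinite concentration gives a consensus", {
  m <- gen_pwm(8, concentration = 5, seed = 2)
  expect_equal(colSums(m$mat), rep(1, 8), ignore_attr = TRUE)
  mc <- gen_pwm(6, concentration = Inf, seed = 3)
  expect_true(all(apply(mc$mat, 2, max) == 1))
  ## the consensus sequence scores strictly highest under scan_pwm
  cons <- paste(c("A", "C", "G", "T")[apply(mc$mat, 2, which.max)],
                collapse = "")
  genome <- c(chr = paste0("ACGTGA", cons, "TTGACA"))
  hits <- scan_pwm(genome, mc, threshold = -Inf)
  best <- hits[which.max(hits$score), ]
  expect_equal(best$start, 6L)
  expect_equal(best$strand, "+")
  expect_gt(best$score, max(hits$score[-which.max(hits$score)]))
  expect_error(gen_pwm(3), ">= 4")
})

test_that("trait catalog: planted fold is realized; incompatible folds rejected", {
  cfg <- sim_config(n_transcripts = 200L, trait_base_rate = 0.05, seed = 17)
  genes <- sprintf("g%04d", 1:4000)
  de <- sample(genes, 200)
  folds <- vapply(1:150, function(k) {
    sim <- gen_trait_catalog(cfg, de, genes, enrichment_fold = 3,
                             seed = 1700L + k)
    hits <- mean(de %in% sim$catalog$gene)
    hits / mean(genes %in% sim$catalog$gene)
  }, 0)
  expect_equal(mean(folds), 3, tolerance = 0.1)
  expect_error(gen_trait_catalog(cfg, de, genes, enrichment_fold = 25),
               "incompatible")

  ## fold 1: downstream Fisher OR centred at 1
  ors <- vapply(1:100, function(k) {
    sim <- gen_trait_catalog(cfg, de, genes, enrichment_fold = 1,
                             seed = 2700L + k)
    trait_enrichment(de, sim$catalog, genes)$or_sample
  }, 0)
  expect_equal(median(ors, na.rm = TRUE), 1, tolerance = 0.15)
})

test_that("annotation invariants: ids match the expression generator, blocks valid", {
  cfg <- small_config(seed = 18)
  ann <- gen_annotations(cfg)
  sim <- gen_rnaseq_counts(cfg, "time_replicate")
  expect_setequal(ann$transcript, rownames(sim$counts$counts))
  expect_identical(unname(sim$truth$genes[ann$transcript]), ann$gene)
  expect_true(all(ann$end > ann$start))
  expect_true(all(vapply(seq_len(nrow(ann)), function(i) {
    bs <- ann$block_starts[[i]]; bz <- ann$block_sizes[[i]]
    !is.unsorted(bs, strictly = TRUE) && all(bz > 0) &&
      max(bs + bz) <= ann$end[i] - ann$start[i]
  }, TRUE)))
})
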