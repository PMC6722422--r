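test_that("tiling counts insertions with the +4 offset and half-open tiles", {
  fr <- fragment_set("chrT", c(100, 297), c(180, 400), c("s1", "s1"),
                     c("treatment", "treatment"))
  rs <- tile_and_count(fr, genome_length = 900, window = 300)
  ## fragment [100,180): insertions 104 and 175, both in tile [0,300)
  expect_equal(unname(rs$counts[1, "s1"]), 2)
  ## fragment [297,400): insertions 301 and 395, both in tile [300,600)
  expect_equal(unname(rs$counts[2, "s1"]), 2)
  expect_equal(sum(rs$counts), 2 * nrow(fr))
  expect_equal(rownames(rs$counts)[1], "chrT:0-300")

  ## insertion at exactly 300 goes to tile [300,600)
  fr2 <- fragment_set("chrT", 296, 400, "s1", "treatment")
  rs2 <- tile_and_count(fr2, genome_length = 900, window = 300)
  expect_equal(unname(rs2$counts[, "s1"]), c(0, 2, 0))

  ## empty fragment set and out-of-bounds rejection
  fr0 <- fragment_set(character(0), integer(0), integer(0), character(0),
                      character(0))
  rs0 <- tile_and_count(fr0, genome_length = 600, window = 300,
                        chrom = "chrT")
  expect_true(all(rs0$counts == 0) || ncol(rs0$counts) == 0)
  frx <- fragment_set("chrT", 880, 920, "s1", "treatment")
  expect_error(tile_and_count(frx, genome_length = 900), "record 1")
})

test_that("tile totals equal twice the fragment count when in bounds", {
  cfg <- small_config(seed = 21)
  at <- gen_atac_fragments(cfg)
  rs <- tile_and_count(at$fragments, cfg$genome_length, cfg$window)
  expect_equal(sum(rs$counts), 2L * nrow(at$fragments))
})

test_that("RPM filter is strictly greater-than and matches direct arithmetic", {
  counts <- rbind(a = c(1, 1), b = c(2, 2), c = c(0, 0),
                  d = c(3997, 3997))
  colnames(counts) <- c("s1", "s2")
  rs <- make_region_set(counts, condition = c("treatment", "control"))
  ## lib size 4000 -> RPM of region a = 250; set threshold exactly there
  suppressMessages(kept <- filter_regions(rs, min_rpm = 250))
  expect_setequal(rownames(kept$counts), c("chrT:300-600", "chrT:900-1200"))
  suppressMessages(k0 <- filter_regions(rs, min_rpm = 0))
  expect_setequal(rownames(k0$counts),
                  setdiff(rownames(rs$counts), "chrT:600-900"))
  set.seed(81)
  rc <- matrix(rpois(200 * 4, 5), 200, 4,
               dimnames = list(NULL, paste0("s", 1:4)))
  rsr <- make_region_set(rc, condition = rep(c("treatment", "control"), 2))
  suppressMessages(kr <- filter_regions(rsr, min_rpm = 1200))
  manual <- rowMeans(sweep(rsr$counts, 2, rsr$lib_sizes / 1e6, "/")) > 1200
  expect_equal(nrow(kr$counts), sum(manual))
})

test_that("DA test: label swap negates effects; planted shifts recover sign", {
  set.seed(82)
  n <- 20
  counts <- t(sapply(1:150, function(i) rnbinom(n, mu = 80, size = 20)))
  lfc <- rep(0, 150); lfc[1:8] <- 0.9 * sample(c(-1, 1), 8, replace = TRUE)
  trt <- rep(c(TRUE, FALSE), each = n / 2)
  counts[, trt] <- t(sapply(1:150, function(i)
    rnbinom(n / 2, mu = 80 * 2^lfc[i], size = 20)))
  colnames(counts) <- paste0("s", 1:n)
  rs <- make_region_set(counts, condition = ifelse(trt, "treatment",
                                                   "control"))
  suppressMessages(da <- da_test(rs))
  rs_sw <- rs
  rs_sw$samples$condition <- ifelse(trt, "control", "treatment")
  suppressMessages(da_sw <- da_test(rs_sw))
  expect_equal(da$log2FC, -da_sw$log2FC, tolerance = 1e-6)

  called <- which(!is.na(da$padj) & da$padj < 0.2)
  tp <- intersect(called, which(lfc != 0))
  expect_gt(length(tp), 3)
  expect_true(all(sign(da$log2FC[tp]) == sign(lfc[tp])))

  rs1 <- make_region_set(counts[, trt], condition = rep("treatment", n / 2))
  expect_error(da_test(rs1), "both treatment and control")
})

test_that("region-TSS linking matches a quadratic scan and the boundary rule", {
  ann <- transcript_annotation(
    transcript = c("t1", "t2", "t3"), gene = c("g1", "g2", "g3"),
    chrom = "chrT", strand = c("+", "-", "+"),
    start = c(55295, 100, 70000), end = c(56295, 1100, 71000),
    block_starts = list(0L, 0L, 0L), block_sizes = list(1000L, 1000L, 1000L))
  regions <- data.frame(chrom = "chrT", start = 5000, end = 5300)
  ## t1 TSS at 55295: 55295 - 5299 = 49996 <= 50000 -> linked
  ## t2 TSS at 1099 (minus strand): distance 3901 -> linked
  ## t3 TSS at 70000: distance 64701 -> not linked
  links <- link_regions_to_tss(regions, ann, 50000)
  expect_setequal(links$transcript, c("t1", "t2"))
  expect_equal(links$distance[links$transcript == "t2"], 5000 - 1099)

  ## TSS at exactly 50,000 bp is linked (<= rule)
  ann2 <- transcript_annotation("tb", "gb", "chrT", "+", 55299, 56299,
                                list(0L), list(1000L))
  expect_equal(nrow(link_regions_to_tss(regions, ann2, 50000)), 1)
  ann3 <- transcript_annotation("tc", "gc", "chrT", "+", 55300, 56300,
                                list(0L), list(1000L))
  expect_equal(nrow(link_regions_to_tss(regions, ann3, 50000)), 0)

  ## random layout equals the brute-force all-pairs scan
  set.seed(83)
  rr <- data.frame(chrom = "chrT", start = sample(0:200, 40) * 300)
  rr$end <- rr$start + 300
  tssr <- sample(0:60000, 60)
  annr <- transcript_annotation(paste0("t", 1:60), paste0("g", 1:60), "chrT",
                                "+", tssr, tssr + 500,
                                replicate(60, 0L, simplify = FALSE),
                                replicate(60, 500L, simplify = FALSE))
  got <- link_regions_to_tss(rr, annr, 7000)
  want <- oracle_links(rr, annr, 7000)
  expect_equal(nrow(got), nrow(want))
  expect_setequal(paste(got$region, got$transcript),
                  paste(want$region, want$transcript))
  expect_equal(got$distance[order(got$region, got$transcript)],
               want$distance[order(want$region, want$transcript)])
})

test_that("DAR/DE enrichment: proportional rows are null; Fisher p matches enumeration", {
  ## table [[2,3],[4,6]] by construction
  universe <- paste0("g", 1:15)
  links <- data.frame(region = "r1", transcript = "x",
                      gene = paste0("g", 1:5))
  de <- paste0("g", c(1, 2, 6, 7, 8, 9))
  en <- dar_de_enrichment("r1", de, links, universe)
  expect_equal(unname(as.vector(en$table)), c(2, 4, 3, 6))
  expect_equal(en$or_sample, 1)
  expect_equal(en$p, 1)

  ## [[8,2],[2,8]] against full hypergeometric enumeration
  universe2 <- paste0("g", 1:20)
  links2 <- data.frame(region = "r1", transcript = "x",
                       gene = paste0("g", 1:10))
  de2 <- paste0("g", c(1:8, 11, 12))
  en2 <- dar_de_enrichment("r1", de2, links2, universe2)
  expect_equal(unname(as.vector(en2$table)), c(8, 2, 2, 8))
  expect_equal(en2$p, oracle_fisher_p(en2$table), tolerance = 1e-12)

  ## independence simulation: sample OR centred at 1
  set.seed(84)
  ors <- replicate(300, {
    near <- sample(universe2, 10)
    dex <- sample(universe2, 10)
    l <- data.frame(region = "r1", transcript = "x", gene = near)
    dar_de_enrichment("r1", dex, l, universe2)$or_sample
  })
  expect_equal(median(log(ors), na.rm = TRUE), 0, tolerance = 0.2)
})

test_that("concordance: exact closed form, perfect proportionality, null r2", {
  mk_res <- function(ids, lfc, padj = rep(0.01, length(ids)))
    data.frame(feature = ids, log2FC = lfc, padj = padj)
  links <- data.frame(region = paste0("r", 1:12),
                      transcript = paste0("t", 1:12),
                      gene = paste0("g", 1:12))
  set.seed(85)
  x <- rnorm(12)
  cc <- suppressWarnings(concordance(mk_res(paste0("r", 1:12), x),
                                     mk_res(paste0("t", 1:12), 2 * x),
                                     links))
  expect_equal(cc$r2, 1, tolerance = 1e-12)
  expect_equal(cc$slope, 2, tolerance = 1e-12)

  y <- 1.5 * x + rnorm(12, 0, 0.3)
  cc2 <- concordance(mk_res(paste0("r", 1:12), x),
                     mk_res(paste0("t", 1:12), y), links)
  fit <- lm(y ~ x)
  expect_equal(cc2$slope, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(cc2$r2, summary(fit)$r.squared, tolerance = 1e-10)

  ## independent effects: r2 stays small in most replicates (n = 36 pairs)
  links36 <- data.frame(region = paste0("r", 1:36),
                        transcript = paste0("t", 1:36),
                        gene = paste0("g", 1:36))
  r2s <- replicate(200, {
    concordance(mk_res(paste0("r", 1:36), rnorm(36)),
                mk_res(paste0("t", 1:36), rnorm(36)), links36)$r2
  })
  expect_gte(mean(r2s < 0.2), 0.95)

  expect_error(concordance(mk_res("r1", 1), mk_res("t1", 1),
                           links[1, ]), "fewer than 3")
})

test_that("stratified FDR: single stratum equals plain BH; unions dominate; all-1 input", {
  set.seed(86)
  p <- setNames(runif(50)^1.5, paste0("r", 1:50))
  map1 <- data.frame(region = names(p), motif = "m1")
  s1 <- stratified_fdr(p, map1, fdr = 0.10)
  expect_equal(s1$padj, unname(bh_adjust(p)))
  expect_equal(s1$called, unname(bh_adjust(p) < 0.10))

  ## signal concentrated in one motif's stratum beats unstratified BH
  p2 <- setNames(c(runif(30, 0, 0.02), runif(170)), paste0("r", 1:200))
  map2 <- rbind(data.frame(region = paste0("r", 1:35), motif = "mA"),
                data.frame(region = paste0("r", 36:200), motif = "mB"))
  s2 <- stratified_fdr(p2, map2, fdr = 0.10)
  plain <- sum(bh_adjust(p2) < 0.10)
  expect_gt(sum(s2$called), plain)
  ## calls are a superset of every per-stratum BH call set
  for (m in c("mA", "mB")) {
    ids <- map2$region[map2$motif == m]
    sub <- bh_adjust(p2[ids]) < 0.10
    expect_true(all(names(p2[ids])[sub] %in% s2$region[s2$called]))
  }

  ## all p = 1 -> zero calls; empty strata skipped with a message
  p3 <- setNames(rep(1, 10), paste0("r", 1:10))
  expect_message(s3 <- stratified_fdr(p3, data.frame(region = c("r1", "zz"),
                                                     motif = c("m1", "m2"))),
                 "skipped")
  expect_equal(sum(s3$called), 0)
})
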