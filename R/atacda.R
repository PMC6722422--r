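## Windowed differential chromatin accessibility: Tn5 insertion counting on
## fixed 300-bp tiles, RPM filtering, the NB-GLM treatment-vs-control test,
## region-to-TSS linking, enrichment near DE genes, accessibility/expression
## concordance, and motif-stratified FDR.

#' Tn5 insertion events of a fragment set
#'
#' Each fragment yields two insertion events, 4 bp interior to each 5' end in
#' its 5' to 3' direction: position `start + 4` on the plus strand and
#' `end - 5` on the minus strand (0-based).
#'
#' @param fragments A `fragment_set`.
#' @return data.frame: `chrom`, `pos`, `strand`, `sample`, `condition`,
#'   `fragment` (record index), `length`.
#' @export
tn5_insertions <- function(fragments) {
  stopifnot(inherits(fragments, "fragment_set"))
  n <- nrow(fragments)
  data.frame(
    chrom = rep(fragments$chrom, 2),
    pos = c(fragments$start + 4L, fragments$end - 5L),
    strand = rep(c("+", "-"), each = n),
    sample = rep(fragments$sample, 2),
    condition = rep(fragments$condition, 2),
    fragment = rep(seq_len(n), 2),
    length = rep(fragments$end - fragments$start, 2),
    stringsAsFactors = FALSE)
}

#' Tile the genome and count insertion events
#'
#' Non-overlapping windows of `window` bp starting at coordinate 0; each
#' fragment contributes its two Tn5 insertion events to the half-open tiles
#' containing them.
#'
#' @param fragments A `fragment_set` (single chromosome).
#' @param genome_length Chromosome length in bp.
#' @param window Tile width in bp (default 300).
#' @param chrom Chromosome name (default: from the fragments).
#' @return Object of class `region_set`: list with `regions` (chrom, start,
#'   end), `counts` (region x sample insertion counts), `samples` (sample,
#'   condition), `lib_sizes` (total insertion events per sample).
#' @export
tile_and_count <- function(fragments, genome_length, window = 300L,
                           chrom = NULL) {
  stopifnot(inherits(fragments, "fragment_set"))
  chrom <- chrom %||% (if (nrow(fragments)) fragments$chrom[1] else "chr1")
  ev <- tn5_insertions(fragments)
  bad <- which(ev$pos < 0 | ev$pos >= genome_length)
  if (length(bad))
    stop_gutreg("fragment beyond genome bounds at record ", ev$fragment[bad[1]])
  ntile <- as.integer(ceiling(genome_length / window))
  samp <- unique(fragments[, c("sample", "condition")])
  if (nrow(samp) == 0) samp <- data.frame(sample = character(0),
                                          condition = character(0))
  tile <- ev$pos %/% window
  cnt <- table(factor(tile, levels = 0:(ntile - 1)),
               factor(ev$sample, levels = samp$sample))
  counts <- matrix(as.integer(cnt), nrow = ntile,
                   dimnames = list(NULL, samp$sample))
  regions <- data.frame(chrom = chrom, start = (0:(ntile - 1)) * window,
                        end = pmin((1:ntile) * window, genome_length))
  rownames(counts) <- sprintf("%s:%d-%d", chrom, regions$start, regions$end)
  structure(list(regions = regions, counts = counts, samples = samp,
                 lib_sizes = colSums(counts)),
            class = "region_set")
}

#' @export
print.region_set <- function(x, ...) {
  cat("region_set:", nrow(x$counts), "regions x", ncol(x$counts), "samples\n")
  invisible(x)
}

#' Filter regions by reads per million
#'
#' Keeps regions whose RPM strictly exceeds `min_rpm`: by default the mean
#' RPM across samples; `"pooled"` uses total counts over total library size;
#' `"per_sample"` requires the threshold to be exceeded in at least one
#' sample.
#'
#' @param x A `region_set`.
#' @param min_rpm RPM threshold (strict `>`; default 0.25).
#' @param mode One of `"mean"`, `"pooled"`, `"per_sample"`.
#' @return Filtered `region_set` (library sizes are kept from the full
#'   tiling).
#' @export
filter_regions <- function(x, min_rpm = 0.25,
                           mode = c("mean", "pooled", "per_sample")) {
  stopifnot(inherits(x, "region_set"))
  mode <- match.arg(mode)
  if (any(x$lib_sizes <= 0)) stop_gutreg("sample with zero library size")
  rpm <- sweep(x$counts, 2, x$lib_sizes / 1e6, "/")
  keep <- switch(mode,
                 mean = rowMeans(rpm) > min_rpm,
                 pooled = rowSums(x$counts) / sum(x$lib_sizes) * 1e6 > min_rpm,
                 per_sample = apply(rpm > min_rpm, 1, any))
  message(sum(keep), " of ", nrow(x$counts), " regions above ", min_rpm,
          " RPM (", mode, ")")
  structure(list(regions = x$regions[keep, , drop = FALSE],
                 counts = x$counts[keep, , drop = FALSE],
                 samples = x$samples, lib_sizes = x$lib_sizes),
            class = "region_set")
}

#' Differential accessibility test
#'
#' Per-region NB GLM (shared engine with the expression designs) of insertion
#' counts on the treatment indicator, Wald test treatment vs control, BH
#' across regions. The conventional report threshold is FDR < 20%.
#'
#' @param x A `region_set` containing both conditions.
#' @param control Condition label to use as the reference (default
#'   `"control"`).
#' @return DE-result data.frame (one row per region).
#' @export
da_test <- function(x, control = "control") {
  stopifnot(inherits(x, "region_set"))
  cond <- unique(x$samples$condition)
  if (length(cond) < 2)
    stop_gutreg("both treatment and control samples are required")
  f <- factor(x$samples$condition,
              levels = c(control, setdiff(cond, control)))
  X <- model.matrix(~f)
  colnames(X) <- c("(Intercept)", paste0("cond", levels(f)[-1]))
  nb_de(x$counts, X, contrast = colnames(X)[2], design = "atac_da",
        contrast_label = paste0(levels(f)[2], "_vs_", control))
}

## Distance between a 0-based half-open interval and a point: 0 when the
## point lies inside, else the distance to the nearest contained base.
interval_point_dist <- function(start, end, pos) {
  ifelse(pos >= start & pos < end, 0L,
         pmin(abs(pos - start), abs(pos - (end - 1L))))
}

#' Link regions to transcription start sites
#'
#' Pairs every region with every transcript whose TSS lies within `distance`
#' bp (inclusive) of the region; distance is 0 when the TSS falls inside the
#' region. Strand is used only to locate the TSS. Candidate pairs are found
#' with an interval-overlap query and then filtered by exact distance.
#'
#' @param x A `region_set` (or data.frame with chrom/start/end).
#' @param annotation A `transcript_annotation`.
#' @param distance Maximum linking distance in bp (default 50000).
#' @return data.frame: `region`, `transcript`, `gene`, `distance`.
#' @export
link_regions_to_tss <- function(x, annotation, distance = 50000L) {
  regions <- if (inherits(x, "region_set")) x$regions else x
  region_id <- if (inherits(x, "region_set")) rownames(x$counts) else
    sprintf("%s:%d-%d", regions$chrom, regions$start, regions$end)
  out <- list()
  for (ch in unique(regions$chrom)) {
    ri <- which(regions$chrom == ch)
    ai <- which(annotation$chrom == ch)
    if (!length(ri) || !length(ai)) next
    q <- IRanges::IRanges(start = regions$start[ri] + 1L - distance,
                          end = regions$end[ri] + distance)
    s <- IRanges::IRanges(start = annotation$tss[ai] + 1L, width = 1L)
    hits <- as.matrix(IRanges::findOverlaps(q, s))
    if (!nrow(hits)) next
    i <- ri[hits[, 1]]
    j <- ai[hits[, 2]]
    d <- interval_point_dist(regions$start[i], regions$end[i],
                             annotation$tss[j])
    keep <- d <= distance
    out[[ch]] <- data.frame(region = region_id[i][keep],
                            transcript = annotation$transcript[j][keep],
                            gene = annotation$gene[j][keep],
                            distance = d[keep], stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(region = character(0), transcript = character(0),
                      gene = character(0), distance = integer(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Enrichment of differentially accessible regions near DE genes
#'
#' Two-by-two Fisher test over the gene universe: {within `distance` of a
#' called DAR} x {differentially expressed}. Reports the two-sided Fisher p,
#' the conditional-MLE odds ratio and the sample odds ratio.
#'
#' @param dar_regions Character vector of called DAR region ids.
#' @param de_genes Character vector of DE gene ids.
#' @param links Region-transcript links from [link_regions_to_tss()].
#' @param universe Character vector of all tested gene ids.
#' @return List: `table` (2x2), `or_mle`, `or_sample`, `p`.
#' @export
dar_de_enrichment <- function(dar_regions, de_genes, links, universe) {
  near <- universe %in% links$gene[links$region %in% dar_regions]
  de <- universe %in% de_genes
  tab <- table(near = factor(near, c(TRUE, FALSE)),
               de = factor(de, c(TRUE, FALSE)))
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  if (!is.finite(or_sample)) or_sample <- NA_real_
  ft <- tryCatch(fisher.test(tab), error = function(e) NULL)
  list(table = tab,
       or_mle = if (is.null(ft)) NA_real_ else unname(ft$estimate),
       or_sample = or_sample,
       p = if (is.null(ft)) NA_real_ else ft$p.value)
}

#' Concordance of accessibility and expression changes
#'
#' Least-squares regression of transcript log2 fold change on region log2
#' fold change over linked (region, gene) pairs, using the representative
#' (minimum padj) transcript per gene.
#'
#' @param da_res Region-level DE results (`feature`, `log2FC`, `padj`).
#' @param de_res Transcript-level DE results (`feature`, `log2FC`, `padj`).
#' @param links Links from [link_regions_to_tss()].
#' @param both_called If TRUE (default), restrict to pairs where both the
#'   region and the gene pass their padj thresholds.
#' @param da_fdr,de_fdr Calling thresholds (defaults 0.20 and 0.10).
#' @return List: `r2`, `slope`, `p`, `n_pairs`, `pairs` (data.frame).
#' @export
concordance <- function(da_res, de_res, links, both_called = TRUE,
                        da_fdr = 0.20, de_fdr = 0.10) {
  tx <- merge(links, de_res[, c("feature", "log2FC", "padj")],
              by.x = "transcript", by.y = "feature")
  ## representative transcript per (region, gene): minimum padj
  tx <- tx[order(tx$padj), ]
  tx <- tx[!duplicated(tx[, c("region", "gene")]), ]
  pr <- merge(tx, da_res[, c("feature", "log2FC", "padj")],
              by.x = "region", by.y = "feature",
              suffixes = c("_tx", "_region"))
  if (both_called)
    pr <- pr[!is.na(pr$padj_region) & pr$padj_region < da_fdr &
               !is.na(pr$padj_tx) & pr$padj_tx < de_fdr, ]
  pr <- pr[complete.cases(pr[, c("log2FC_tx", "log2FC_region")]), ]
  if (nrow(pr) < 3) stop_gutreg("fewer than 3 linked pairs with both effects")
  fit <- lm(log2FC_tx ~ log2FC_region, data = pr)
  sm <- summary(fit)
  list(r2 = sm$r.squared, slope = unname(coef(fit)[2]),
       p = sm$coefficients[2, 4], n_pairs = nrow(pr), pairs = pr)
}

#' Motif-stratified FDR for differential accessibility
#'
#' For each motif, BH-adjusts the accessibility p-values of the regions
#' carrying that motif's footprint; a region is called when its adjusted p
#' falls below `fdr` in any motif stratum. The union is reported with the
#' calling (minimum-padj) stratum. Empty strata are skipped with a message.
#'
#' @param p Named p-value vector (names = region ids).
#' @param region_motifs data.frame with columns `region`, `motif` (one row
#'   per footprint-in-region).
#' @param fdr Calling threshold (strict `<`; default 0.10).
#' @return data.frame: `region`, `padj` (minimum across strata containing the
#'   region), `motif` (calling stratum), `called`.
#' @export
stratified_fdr <- function(p, region_motifs, fdr = 0.10) {
  if (is.null(names(p))) stop_gutreg("p must be named by region id")
  best <- setNames(rep(NA_real_, length(p)), names(p))
  best_motif <- setNames(rep(NA_character_, length(p)), names(p))
  for (m in unique(region_motifs$motif)) {
    ids <- intersect(unique(region_motifs$region[region_motifs$motif == m]),
                     names(p))
    if (!length(ids)) {
      message("stratum ", m, " contains no tested regions; skipped")
      next
    }
    padj <- bh_adjust(p[ids])
    upd <- is.na(best[ids]) | (!is.na(padj) & padj < best[ids])
    best[ids][upd] <- padj[upd]
    best_motif[ids][upd] <- m
  }
  data.frame(region = names(p), padj = unname(best),
             motif = unname(best_motif),
             called = !is.na(best) & best < fdr,
             stringsAsFactors = FALSE)
}
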