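## Trait-catalog enrichment of gene sets and cross-experiment effect
## concordance (community abundance model vs single-species spike-in).

#' Trait-catalog enrichment of a gene set
#'
#' Any-trait mode: a single 2x2 Fisher test of {in set} x {has any trait}
#' over the background, plus the fold enrichment
#' `(hits / set size) / (catalog rate in background)`. Per-trait mode: one
#' Fisher table per trait with Bonferroni correction across traits.
#'
#' @param genes Character vector (the gene set; must lie in `background`).
#' @param catalog data.frame with `gene`, `trait` columns.
#' @param background Character vector of background genes (e.g. all
#'   expressed genes).
#' @return List: `fold`, `or` (conditional MLE), `or_sample`, `p`, `table`,
#'   and `per_trait` (data.frame trait/hits/or/p/p_bonferroni).
#' @export
trait_enrichment <- function(genes, catalog, background) {
  if (!length(genes)) stop_gutreg("empty gene set")
  if (!all(genes %in% background))
    stop_gutreg("gene set must be a subset of the background")
  background <- unique(background)
  genes <- unique(genes)
  in_set <- background %in% genes
  has_any <- background %in% catalog$gene
  tab <- table(set = factor(in_set, c(TRUE, FALSE)),
               trait = factor(has_any, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  rate_bg <- mean(has_any)
  fold <- mean(has_any[in_set]) / rate_bg
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  per_trait <- do.call(rbind, lapply(unique(catalog$trait), function(tr) {
    in_tr <- background %in% catalog$gene[catalog$trait == tr]
    t2 <- table(factor(in_set, c(TRUE, FALSE)), factor(in_tr, c(TRUE, FALSE)))
    f2 <- fisher.test(t2)
    data.frame(trait = tr, hits = t2[1, 1], or = unname(f2$estimate),
               p = f2$p.value, stringsAsFactors = FALSE)
  }))
  if (!is.null(per_trait)) {
    per_trait$p_bonferroni <- pmin(per_trait$p * nrow(per_trait), 1)
    rownames(per_trait) <- NULL
  }
  list(fold = fold, or = unname(ft$estimate),
       or_sample = if (is.finite(or_sample)) or_sample else NA_real_,
       p = ft$p.value, table = tab, per_trait = per_trait)
}

#' Select genes strongly associated with a taxon
#'
#' Genes with at least one transcript at `p < p_cut` (strict) for the
#' taxon's abundance covariate; the taxon is reported only when the set
#' reaches `min_genes`.
#'
#' @param assoc Taxon-covariate DE results (`feature`, `p`, `contrast` =
#'   taxon id).
#' @param taxon Taxon id.
#' @param gene_of Named vector mapping transcript id to gene id.
#' @param min_genes Minimum reportable set size (default 30).
#' @param p_cut Nominal p threshold (default 3.5e-5).
#' @return Character vector of gene ids (empty when below `min_genes`).
#' @export
gene_selection_for_taxon <- function(assoc, taxon, gene_of, min_genes = 30,
                                     p_cut = 3.5e-5) {
  sub <- assoc[assoc$contrast == taxon & !is.na(assoc$p) & assoc$p < p_cut, ]
  genes <- unique(unname(gene_of[sub$feature]))
  if (length(genes) < min_genes) character(0) else genes
}

#' Concordance of effects between two experiments
#'
#' Spearman rank correlation of standardized effects (log2FC / SE) between
#' experiments A and B over shared transcripts, the same correlation within
#' the transcripts DE only in experiment B, and the least-squares regression
#' p-value for the linear trend.
#'
#' @param pairs data.frame with columns `effect_a`, `effect_b` and logical
#'   `de_a`, `de_b` (at least 10 rows).
#' @return List: `rho`, `rho_b_only`, `p_regression`, `n`, `n_b_only`.
#' @export
effect_concordance <- function(pairs) {
  need <- c("effect_a", "effect_b", "de_a", "de_b")
  stopifnot(all(need %in% names(pairs)))
  pairs <- pairs[complete.cases(pairs[, c("effect_a", "effect_b")]), ]
  if (nrow(pairs) < 10) stop_gutreg("at least 10 effect pairs are required")
  sp <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
    cor(a, b, method = "spearman")
  }
  rho <- sp(pairs$effect_a, pairs$effect_b)
  bo <- pairs$de_b & !pairs$de_a
  rho_b <- if (sum(bo) >= 3) sp(pairs$effect_a[bo], pairs$effect_b[bo])
           else NA_real_
  fit <- lm(effect_b ~ effect_a, data = pairs)
  list(rho = rho, rho_b_only = rho_b,
       p_regression = summary(fit)$coefficients[2, 4],
       n = nrow(pairs), n_b_only = sum(bo))
}

#' Overlap of DE calls between two experiments
#'
#' Two-by-two Fisher test of membership in set A against membership in set
#' B over a shared gene universe.
#'
#' @param set_a,set_b Character vectors (subsets of `universe`).
#' @param universe Character vector of all eligible genes.
#' @return List: `overlap`, `p`, `or` (conditional MLE), `or_sample`,
#'   `table`.
#' @export
validation_overlap <- function(set_a, set_b, universe) {
  if (!length(universe)) stop_gutreg("empty universe")
  universe <- unique(universe)
  a <- universe %in% set_a
  b <- universe %in% set_b
  tab <- table(A = factor(a, c(TRUE, FALSE)), B = factor(b, c(TRUE, FALSE)))
  ft <- fisher.test(tab)
  or_sample <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(overlap = sum(a & b), p = ft$p.value, or = unname(ft$estimate),
       or_sample = if (is.finite(or_sample)) or_sample else NA_real_,
       table = tab)
}
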