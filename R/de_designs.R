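## The study's expression designs: per-time-point treated-vs-control with
## microbiomes as replicates, per-microbiome contrasts, the trajectory LRT
## (does the response depend on which donor the microbiome came from?), the
## taxon-baseline-abundance covariate scan, and the spike-in dose model.
## Plus the expression filter and transcript-to-gene collapsing.

#' Design specification
#'
#' @param name One of `time_replicate`, `per_microbiome`, `trajectory_lrt`,
#'   `taxon_covariate`, `spikein_dose`.
#' @param taxa Taxon ids for `taxon_covariate` (default: all taxa carried by
#'   the count matrix).
#' @param padj_threshold,lfc_threshold Calling thresholds (defaults 0.10 and
#'   0.25; calls require `padj < padj_threshold` and `|log2FC| >
#'   lfc_threshold`).
#' @param dose_offset Offset inside the `log10(percent + offset)` dose
#'   coding (default 0.001, admitting the 0% control).
#' @return Object of class `design_spec`.
#' @export
design_spec <- function(name, taxa = NULL, padj_threshold = 0.10,
                        lfc_threshold = 0.25, dose_offset = 0.001) {
  valid <- c("time_replicate", "per_microbiome", "trajectory_lrt",
             "taxon_covariate", "spikein_dose")
  if (!name %in% valid)
    stop_gutreg("unknown design '", name, "'; valid designs: ",
                paste(valid, collapse = ", "))
  if (padj_threshold <= 0 || lfc_threshold < 0)
    stop_gutreg("thresholds must be positive")
  structure(list(name = name, taxa = taxa,
                 padj_threshold = padj_threshold,
                 lfc_threshold = lfc_threshold, dose_offset = dose_offset),
            class = "design_spec")
}

#' Expression filter
#'
#' Keeps transcripts with at least `min_total` reads summed over all
#' samples (default 20).
#'
#' @param x A `count_matrix`.
#' @param min_total Minimum total count (kept when total `>= min_total`).
#' @return Filtered `count_matrix`.
#' @export
filter_transcripts <- function(x, min_total = 20) {
  stopifnot(inherits(x, "count_matrix"))
  keep <- rowSums(x$counts) >= min_total
  message(sum(keep), " of ", nrow(x$counts), " transcripts with >= ",
          min_total, " total reads retained")
  out <- x
  out$counts <- x$counts[keep, , drop = FALSE]
  out
}

need_cols <- function(x, cols, design) {
  miss <- setdiff(cols, names(x$samples))
  if (length(miss))
    stop_gutreg("design ", design, " requires sample metadata column(s): ",
                paste(miss, collapse = ", "))
  for (cc in cols)
    if (all(is.na(x$samples[[cc]])))
      stop_gutreg("design ", design, " requires non-missing values in: ", cc)
}

#' Run one expression design
#'
#' * `time_replicate`: per time point, the treated samples (all microbiomes
#'   as replicates) against the controls; Wald test; BH within each time
#'   point.
#' * `per_microbiome`: one treated-vs-control contrast per (microbiome, time
#'   point); BH within each contrast.
#' * `trajectory_lrt`: LRT of the full time-by-microbiome model against the
#'   shared-trajectory (time only) reduced model; BH across transcripts.
#' * `taxon_covariate`: per taxon, a Wald test on the mean-centered baseline
#'   relative abundance covariate across treated samples; BH jointly over
#'   the full transcript-by-taxon cross.
#' * `spikein_dose`: Wald test on the centered `log10(percent + offset)`
#'   dose covariate; BH across transcripts.
#'
#' @param x A `count_matrix` (for `taxon_covariate` it must carry the
#'   `taxon_baseline` per-microbiome abundance matrix).
#' @param spec A `design_spec` (or design name).
#' @return DE-result data.frame (one row per feature and contrast) with the
#'   `called` flag at the spec's thresholds.
#' @export
run_design <- function(x, spec) {
  stopifnot(inherits(x, "count_matrix"))
  if (is.character(spec)) spec <- design_spec(spec)
  meta <- x$samples
  res <- switch(spec$name,
    time_replicate = {
      need_cols(x, c("time", "condition"), spec$name)
      do.call(rbind, lapply(unique(meta$time), function(tp) {
        sel <- meta$time == tp
        sub <- x$counts[, sel, drop = FALSE]
        f <- factor(meta$condition[sel], levels = c("control", "treatment"))
        X <- model.matrix(~f)
        colnames(X) <- c("(Intercept)", "treatment")
        nb_de(sub, X, contrast = "treatment", design = spec$name,
              contrast_label = tp)
      }))
    },
    per_microbiome = {
      need_cols(x, c("time", "condition", "microbiome"), spec$name)
      mbs <- setdiff(unique(meta$microbiome), "control")
      do.call(rbind, do.call(c, lapply(unique(meta$time), function(tp)
        lapply(mbs, function(mb) {
          sel <- meta$time == tp &
            (meta$condition == "control" | meta$microbiome == mb)
          f <- factor(meta$condition[sel], levels = c("control", "treatment"))
          X <- model.matrix(~f)
          colnames(X) <- c("(Intercept)", "treatment")
          nb_de(x$counts[, sel, drop = FALSE], X, contrast = "treatment",
                design = spec$name, contrast_label = paste(mb, tp, sep = ":"))
        }))))
    },
    trajectory_lrt = {
      need_cols(x, c("time", "microbiome"), spec$name)
      tm <- factor(meta$time)
      mb <- factor(meta$microbiome)
      mb <- stats::relevel(mb, ref = "control")
      X_full <- model.matrix(~ tm * mb)
      X_red <- model.matrix(~ tm)
      nb_de(x$counts, X_full, X_reduced = X_red, design = spec$name,
            contrast_label = "trajectory")
    },
    taxon_covariate = {
      need_cols(x, c("condition", "microbiome"), spec$name)
      ab <- x$taxon_baseline
      if (is.null(ab))
        stop_gutreg("design taxon_covariate requires the taxon_baseline ",
                    "abundance matrix on the count_matrix")
      taxa <- spec$taxa %||% rownames(ab)
      sel <- meta$condition == "treatment"
      sub <- x$counts[, sel, drop = FALSE]
      sf <- size_factors(sub)
      out <- do.call(rbind, lapply(taxa, function(tax) {
        cov_raw <- ab[tax, meta$microbiome[sel]]
        if (sd(cov_raw) < 1e-12)
          stop_gutreg("degenerate (constant) abundance covariate for taxon ",
                      tax)
        xv <- cov_raw - mean(cov_raw)
        X <- cbind(`(Intercept)` = 1, abundance = xv)
        nb_de(sub, X, contrast = "abundance", size_factors = sf,
              design = spec$name, contrast_label = tax)
      }))
      out$padj <- bh_adjust(out$p)  # joint family over the full cross
      out
    },
    spikein_dose = {
      need_cols(x, "dose", spec$name)
      xv <- log10(meta$dose + spec$dose_offset)
      xv <- xv - mean(xv)
      X <- cbind(`(Intercept)` = 1, dose = xv)
      nb_de(x$counts, X, contrast = "dose", design = spec$name,
            contrast_label = "spikein")
    })
  res$called <- de_calls(res, spec$padj_threshold, spec$lfc_threshold)
  rownames(res) <- NULL
  res
}

#' Significance calls from a DE-result table
#'
#' A feature is called when `padj < padj_threshold` and `|log2FC| >
#' lfc_threshold` (both strict). Rows without an effect estimate (pure LRT)
#' are called on `padj` alone.
#'
#' @param res DE-result data.frame.
#' @param padj_threshold,lfc_threshold Thresholds (defaults 0.10, 0.25).
#' @return Logical vector.
#' @export
de_calls <- function(res, padj_threshold = 0.10, lfc_threshold = 0.25) {
  !is.na(res$padj) & res$padj < padj_threshold &
    (is.na(res$log2FC) | abs(res$log2FC) > lfc_threshold)
}

#' Collapse transcript-level results to gene-level calls
#'
#' A gene is called when at least one of its transcripts is called; the
#' representative transcript is the one with minimal adjusted p.
#'
#' @param res Transcript-level DE results (single contrast family) with a
#'   `called` column (use [de_calls()] if absent).
#' @param annotation A `transcript_annotation` (or data.frame with
#'   `transcript` and `gene`).
#' @param padj_threshold,lfc_threshold Thresholds used if `called` is
#'   absent.
#' @return data.frame: `gene`, `de`, `representative`, `padj`, `log2FC`,
#'   `n_transcripts`.
#' @export
collapse_to_genes <- function(res, annotation, padj_threshold = 0.10,
                              lfc_threshold = 0.25) {
  if (!"called" %in% names(res))
    res$called <- de_calls(res, padj_threshold, lfc_threshold)
  idx <- match(res$feature, annotation$transcript)
  if (anyNA(idx))
    stop_gutreg("transcripts missing from the annotation: ",
                paste(unique(res$feature[is.na(idx)]), collapse = ", "))
  res$gene <- annotation$gene[idx]
  ord <- order(res$gene, is.na(res$padj), res$padj)
  r <- res[ord, ]
  first <- !duplicated(r$gene)
  genes <- r$gene[first]
  calls <- vapply(split(r$called, r$gene), any, TRUE)
  ntx <- vapply(split(res$feature, res$gene), length, 0L)
  data.frame(gene = genes, de = as.logical(calls[genes]),
             representative = r$feature[first], padj = r$padj[first],
             log2FC = r$log2FC[first],
             n_transcripts = as.integer(ntx[genes]),
             stringsAsFactors = FALSE, row.names = NULL)
}
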