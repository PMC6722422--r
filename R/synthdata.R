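## Synthetic-data generators. Every input the pipeline consumes can be
## generated with planted ground truth: NB expression counts under each
## study design, compositional taxon tables, a synthetic chromosome with
## planted motif instances and footprint-structured ATAC fragments, BED12
## transcript models, and a gene-trait catalog with a planted enrichment.
## All generators are deterministic under `config$seed`.

#' Simulation configuration
#'
#' Defaults describe the emulated study: five donor microbiomes plus
#' controls sampled at 1/2/4 h, a titrated single-species spike-in
#' (0/0.01/0.1/1/10 percent in duplicate), genus-level taxon tables rarefied
#' to 141,000 reads, and ATAC libraries of 5 biological x 2 technical
#' treatment replicates against one duplicated control.
#'
#' @param n_transcripts Number of transcripts.
#' @param tx_per_gene_probs Probabilities of a gene having 1, 2, ... transcripts.
#' @param n_microbiomes Number of donor microbiomes.
#' @param n_controls Control wells per time point.
#' @param times Time points for the expression designs.
#' @param nb_dispersion NB dispersion of expression counts.
#' @param baseline_meanlog,baseline_sdlog Log-normal baseline mean parameters.
#' @param libsize_sdlog Log-normal spread of per-sample size factors.
#' @param de_fraction Fraction of transcripts with a planted effect.
#' @param effect_size Planted |log2FC| (sign random).
#' @param n_taxa Number of taxa in the community.
#' @param taxon_sdlog Log-normal spread of taxon abundances.
#' @param rarefaction_depth Reads per sample in the taxon table.
#' @param n_responsive Taxa with a planted coculture effect.
#' @param responsive_fold Multiplicative coculture shift of responsive taxa.
#' @param n_assoc_taxa Taxa carrying planted taxon-transcript associations.
#' @param links_per_taxon Planted transcript links per associated taxon.
#' @param link_coef Planted log2-expression change per unit of centered
#'   relative abundance.
#' @param spikein_doses Spike-in doses (percent of the community).
#' @param spikein_reps Replicates per dose.
#' @param genome_length Synthetic chromosome length (bp).
#' @param n_gene_clusters,cluster_width_frac Gene placement: clusters and
#'   their width as a fraction of the genome.
#' @param n_motifs,n_active_motifs Motifs scanned / with a true PWM effect.
#' @param motif_width,motif_concentration PWM shape parameters.
#' @param n_motif_instances Planted motif instances (total).
#' @param S Footprint half-window (bp).
#' @param fragment_bins Fragment-length bins (4 x 2 matrix).
#' @param bin_weights Event mass per fragment bin.
#' @param bound_rate,unbound_rate Expected events per (site, bin, sample).
#' @param prior_b0,prior_b_pwm True binding-prior coefficients (per unit of
#'   centered PWM score).
#' @param atac_treat_bio,atac_tech_reps,atac_control_bio ATAC layout.
#' @param bg_frag_per_window Background fragments per 300-bp window/sample.
#' @param dar_fraction,dar_log2fc Planted differentially accessible windows.
#' @param window Accessibility window size (bp).
#' @param trait_base_rate,n_traits,trait_enrichment_fold Trait catalog.
#' @param seed Integer seed controlling all generators.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_transcripts = 2000L,
                       tx_per_gene_probs = c(0.6, 0.25, 0.15),
                       n_microbiomes = 5L, n_controls = 3L,
                       times = c("1h", "2h", "4h"),
                       nb_dispersion = 0.1,
                       baseline_meanlog = log(100), baseline_sdlog = 1,
                       libsize_sdlog = 0.2,
                       de_fraction = 0.1, effect_size = 1,
                       n_taxa = 200L, taxon_sdlog = 1.5,
                       rarefaction_depth = 141000L,
                       n_responsive = 10L, responsive_fold = 2,
                       n_assoc_taxa = 3L, links_per_taxon = 40L,
                       link_coef = 1,
                       spikein_doses = c(0, 0.01, 0.1, 1, 10),
                       spikein_reps = 2L,
                       genome_length = 1200000L,
                       n_gene_clusters = 8L, cluster_width_frac = 0.12,
                       n_motifs = 4L, n_active_motifs = 2L,
                       motif_width = 10L, motif_concentration = 8,
                       n_motif_instances = 600L,
                       S = 150L, fragment_bins = NULL,
                       bin_weights = c(0.4, 0.25, 0.2, 0.15),
                       bound_rate = 6, unbound_rate = 1.5,
                       prior_b0 = 0, prior_b_pwm = 1,
                       atac_prior_shift = 0.5,
                       atac_treat_bio = 5L, atac_tech_reps = 2L,
                       atac_control_bio = 1L,
                       bg_frag_per_window = 40,
                       dar_fraction = 0.02, dar_log2fc = 0.8,
                       dar_near_frac = 0.5,
                       window = 300L,
                       trait_base_rate = 0.05, n_traits = 8L,
                       trait_enrichment_fold = 3,
                       seed = 1L) {
  cfg <- as.list(environment())
  cfg$fragment_bins <- cfg$fragment_bins %||% FRAGMENT_BINS
  with(cfg, {
    stopifnot(n_transcripts > 0, n_taxa >= 2, nb_dispersion > 0,
              rarefaction_depth > 0, genome_length > 0, motif_width >= 4,
              all(fragment_bins > 0), abs(sum(tx_per_gene_probs) - 1) < 1e-9)
  })
  if (!isTRUE(all.equal(unname(cfg$fragment_bins),
                        unname(fragment_bins()))) &&
      nrow(cfg$fragment_bins) != 4)
    stop_gutreg("fragment_bins must have four (lo, hi) rows")
  structure(cfg, class = "sim_config")
}

## Deterministic partition of features into genes and planted-truth layout,
## shared across all generators so that designs agree on planted identities.
truth_layout <- function(config) {
  with_seed(config$seed, {
    ntx <- config$n_transcripts
    tx <- sprintf("tx%05d", seq_len(ntx))
    ## assign transcripts to genes
    sizes <- integer(0)
    while (sum(sizes) < ntx)
      sizes <- c(sizes, sample(seq_along(config$tx_per_gene_probs), 100,
                               replace = TRUE,
                               prob = config$tx_per_gene_probs))
    sizes <- sizes[cumsum(sizes) <= ntx]
    if (sum(sizes) < ntx) sizes <- c(sizes, ntx - sum(sizes))
    gene <- rep(sprintf("g%04d", seq_along(sizes)), sizes)
    baseline <- rlnorm(ntx, config$baseline_meanlog, config$baseline_sdlog)
    ## planted DE effects (treatment response, shared across designs)
    n_de <- round(config$de_fraction * ntx)
    de_idx <- sample.int(ntx, n_de)
    eff <- setNames(numeric(ntx), tx)
    eff[de_idx] <- config$effect_size * sample(c(-1, 1), n_de, replace = TRUE)
    ## planted taxon-transcript links
    assoc_taxa <- sprintf("taxon%03d", seq_len(config$n_assoc_taxa))
    links <- do.call(rbind, lapply(assoc_taxa, function(tax)
      data.frame(taxon = tax,
                 transcript = tx[sample.int(ntx, config$links_per_taxon)],
                 coef = config$link_coef * sample(c(-1, 1),
                                                  config$links_per_taxon,
                                                  replace = TRUE),
                 stringsAsFactors = FALSE)))
    ## The spiked species is assoc taxon 1. Its full transcriptome-wide
    ## coefficient vector is a dense weak component plus the strong sparse
    ## links; the spike-in dose response is half that vector plus
    ## experiment-specific noise. This gives the two experiments correlated
    ## standardized effects genome-wide (strongly so among spike responders).
    sp_links <- links[links$taxon == assoc_taxa[1], ]
    tax1_coef <- rnorm(ntx, 0, 0.15)
    tax1_coef[match(sp_links$transcript, tx)] <- sp_links$coef
    sp_eff <- setNames(0.5 * tax1_coef + rnorm(ntx, 0, 0.05), tx)
    list(transcripts = tx, genes = gene, baseline = baseline,
         effect_sizes = eff, de_features = tx[de_idx],
         taxon_gene_links = links, spikein_taxon = assoc_taxa[1],
         spikein_dense_coef = setNames(tax1_coef, tx),
         spikein_effects = sp_eff)
  })
}

#' Generate RNA-seq counts under one study design
#'
#' Counts are drawn NB with mean `size_factor x baseline x 2^(design
#' effect)` and dispersion `config$nb_dispersion`. The planted truth
#' (DE features, effect sizes, taxon-transcript links) is derived
#' deterministically from `config$seed` and therefore shared across designs.
#'
#' Designs: `time_replicate` (5 microbiomes as replicates vs controls per
#' time point), `per_microbiome` (one planted effect per microbiome
#' treatment), `taxon_covariate` (expression responds linearly, on the log2
#' scale, to mean-centered baseline relative abundance of linked taxa) and
#' `spikein_dose` (response linear in the centered `log10(percent + 0.001)`
#' dose covariate).
#'
#' @param config A `sim_config`.
#' @param design Design name.
#' @return List: `counts` (a `count_matrix`; for `taxon_covariate` with a
#'   `taxon_baseline` element of per-microbiome relative abundances) and
#'   `truth` (planted-truth record).
#' @export
gen_rnaseq_counts <- function(config,
                              design = c("time_replicate", "per_microbiome",
                                         "taxon_covariate", "spikein_dose")) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.character(design) || !design[1] %in%
      c("time_replicate", "per_microbiome", "taxon_covariate",
        "spikein_dose"))
    stop_gutreg("unknown design '", design[1], "'; valid designs: ",
                "time_replicate, per_microbiome, taxon_covariate, ",
                "spikein_dose")
  design <- design[1]
  lay <- truth_layout(config)
  ntx <- config$n_transcripts
  with_seed(config$seed + match(design, c("time_replicate", "per_microbiome",
                                          "taxon_covariate",
                                          "spikein_dose")), {
    if (design %in% c("time_replicate", "per_microbiome", "taxon_covariate")) {
      mb <- sprintf("Ind%d", seq_len(config$n_microbiomes))
      meta <- rbind(
        expand.grid(time = config$times, microbiome = mb,
                    replicate = 1L, stringsAsFactors = FALSE),
        expand.grid(time = config$times, microbiome = "control",
                    replicate = seq_len(config$n_controls),
                    stringsAsFactors = FALSE))
      meta$condition <- ifelse(meta$microbiome == "control", "control",
                               "treatment")
      meta$dose <- NA_real_
      ## per-microbiome baseline relative abundances of the assoc taxa
      taxa <- unique(lay$taxon_gene_links$taxon)
      ## baseline relative abundances in percentage points (mean 2%)
      ab <- matrix(rlnorm(length(taxa) * length(mb), log(2), 0.8),
                   nrow = length(taxa), dimnames = list(taxa, mb))
      ab <- sweep(ab, 1, rowMeans(ab) / 2, "/")
      eff <- matrix(0, ntx, nrow(meta))
      treated <- meta$condition == "treatment"
      if (design %in% c("time_replicate", "per_microbiome"))
        eff[, treated] <- lay$effect_sizes
      if (design == "taxon_covariate") {
        cent <- ab - rowMeans(ab)
        for (k in seq_len(nrow(lay$taxon_gene_links))) {
          lk <- lay$taxon_gene_links[k, ]
          if (lk$taxon == lay$spikein_taxon) next  # dense vector used below
          i <- match(lk$transcript, lay$transcripts)
          eff[i, treated] <- eff[i, treated] +
            lk$coef * cent[lk$taxon, meta$microbiome[treated]]
        }
        eff[, treated] <- eff[, treated] +
          outer(lay$spikein_dense_coef,
                cent[lay$spikein_taxon, meta$microbiome[treated]])
      }
    } else {
      meta <- expand.grid(dose = config$spikein_doses,
                          replicate = seq_len(config$spikein_reps),
                          stringsAsFactors = FALSE)
      meta$time <- "2h"
      meta$microbiome <- "Ind4"
      meta$condition <- "treatment"
      x <- log10(meta$dose + 0.001)
      x <- x - mean(x)
      eff <- outer(lay$spikein_effects, x)
    }
    meta$sample <- sprintf("s%02d", seq_len(nrow(meta)))
    sf <- exp(rnorm(nrow(meta), 0, config$libsize_sdlog))
    mu <- (lay$baseline * 2^eff) %*% diag(sf)
    counts <- matrix(rnbinom(length(mu), mu = mu,
                             size = 1 / config$nb_dispersion),
                     nrow = ntx,
                     dimnames = list(lay$transcripts, meta$sample))
    cm <- count_matrix(counts,
                       meta[, c("sample", "time", "microbiome", "condition",
                                "dose", "replicate")])
    if (design == "taxon_covariate") cm$taxon_baseline <- ab
    truth <- list(design = design, de_features = lay$de_features,
                  effect_sizes = lay$effect_sizes,
                  taxon_gene_links = lay$taxon_gene_links,
                  spikein_taxon = lay$spikein_taxon,
                  spikein_effects = lay$spikein_effects,
                  genes = setNames(lay$genes, lay$transcripts))
    list(counts = cm, truth = truth)
  })
}

#' Generate a compositional taxon table
#'
#' Per-donor log-normal community profiles sampled multinomially to
#' `rarefaction_depth` reads. Samples cover the uncultured baseline (0h) and
#' cultured communities at 1/2/4 h with and without colonocytes; responsive
#' taxa receive a multiplicative abundance shift when cocultured.
#'
#' @param config A `sim_config`.
#' @return List: `taxa` (a `taxon_table`) and `truth` (with
#'   `responsive_taxa` and their fold changes).
#' @export
gen_taxon_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$rarefaction_depth < config$n_taxa)
    stop_gutreg("depth ", config$rarefaction_depth,
                " cannot represent all ", config$n_taxa, " taxa")
  with_seed(config$seed + 11L, {
    taxa <- sprintf("taxon%03d", seq_len(config$n_taxa))
    inds <- sprintf("Ind%d", seq_len(config$n_microbiomes))
    base <- matrix(rlnorm(config$n_taxa * length(inds), 0,
                          config$taxon_sdlog),
                   nrow = config$n_taxa, dimnames = list(taxa, inds))
    n_resp <- min(config$n_responsive, config$n_taxa)
    resp_idx <- sample.int(config$n_taxa, n_resp)
    folds <- setNames(config$responsive_fold ^
                        sample(c(-1, 1), n_resp, replace = TRUE),
                      taxa[resp_idx])
    meta <- rbind(
      data.frame(individual = inds, time = "0h", cocultured = FALSE),
      expand.grid(individual = inds, time = config$times,
                  cocultured = c(FALSE, TRUE), stringsAsFactors = FALSE))
    meta$sample <- sprintf("m%02d", seq_len(nrow(meta)))
    counts <- matrix(0L, config$n_taxa, nrow(meta),
                     dimnames = list(taxa, meta$sample))
    for (j in seq_len(nrow(meta))) {
      w <- base[, meta$individual[j]] *
        exp(rnorm(config$n_taxa, 0, 0.1))  # small culture noise
      if (meta$cocultured[j]) w[resp_idx] <- w[resp_idx] * folds
      counts[, j] <- rmultinom(1, config$rarefaction_depth, w / sum(w))[, 1]
    }
    tt <- taxon_table(counts, meta[, c("sample", "individual", "time",
                                       "cocultured")])
    list(taxa = tt,
         truth = list(responsive_taxa = taxa[resp_idx],
                      responsive_folds = folds))
  })
}

#' Generate a PWM
#'
#' Columns are Dirichlet draws with one favored base per position;
#' `concentration = Inf` yields a deterministic one-hot consensus PWM.
#'
#' @param width Motif width (>= 4).
#' @param concentration Dirichlet concentration of the favored base.
#' @param seed RNG seed.
#' @param id Motif id.
#' @return A `motif_model`.
#' @export
gen_pwm <- function(width, concentration = 8, seed = NULL, id = "M1") {
  if (width < 4) stop_gutreg("motif width must be >= 4")
  with_seed(seed, {
    mat <- sapply(seq_len(width), function(j) {
      fav <- sample.int(4, 1)
      if (is.infinite(concentration)) {
        col <- numeric(4); col[fav] <- 1
      } else {
        a <- rep(1, 4); a[fav] <- concentration
        g <- stats::rgamma(4, shape = a)
        col <- g / sum(g)
      }
      col
    })
    motif_model(id, mat)
  })
}

## Induced minus-strand insertion profile: the fragment's second end lands
## L - 9 bp right of the drawn plus insertion, with L uniform over the bin;
## contributions outside the window are dropped.
induced_minus_profile <- function(pi_plus, lo, hi) {
  K <- length(pi_plus)
  out <- numeric(K)
  lens <- lo:hi
  for (r in which(pi_plus > 0)) {
    tgt <- r + lens - 9L
    ok <- tgt >= 1 & tgt <= K
    if (any(ok))
      out[tgt[ok]] <- out[tgt[ok]] + pi_plus[r] / length(lens)
  }
  out
}

## Default plus-strand footprint shape: flat flanks, a depleted motif core,
## and elevated shoulders just outside the core.
default_profile <- function(S, W) {
  K <- 2L * S + W
  prof <- rep(1, K)
  prof[(S + 1):(S + W)] <- 0.15
  sh <- 15L
  prof[(S - sh + 1):S] <- 4
  prof[(S + W + 1):(S + W + sh)] <- 4
  prof / sum(prof)
}

#' Generate a synthetic chromosome with planted footprints and fragments
#'
#' Plants motif instances on a random chromosome, assigns each (site,
#' condition) a latent bound state from a logistic prior on the centered PWM
#' score (only active motifs have a nonzero score effect), and emits ATAC
#' fragments. For bound sites the plus-strand Tn5 insertion of each fragment
#' is drawn from the planted footprint profile and converted to a fragment
#' such that the +4 offset recovers the drawn position; unbound sites draw
#' uniform positions at a lower rate. Background fragments tile the whole
#' chromosome, with planted differentially accessible windows whose
#' treatment intensity is shifted by `dar_log2fc`.
#'
#' @param config A `sim_config`.
#' @param annotation Optional `transcript_annotation`; with `de_genes` it
#'   couples planted DAR placement to DE-gene TSSs.
#' @param de_genes Optional data.frame with `gene` and `log2FC` columns
#'   (planted DE genes): a fraction `config$dar_near_frac` of DAR windows is
#'   placed within 50 kb of these genes' TSSs with a matching effect sign.
#' @param profile Optional plus-strand footprint profile of length
#'   `2S + W` summing to 1 (default: a flank-shoulder/core-depletion shape).
#' @return List: `fragments` (a `fragment_set`), `sites` (candidate sites),
#'   `motifs` (list of `motif_model`), `genome` (named character vector),
#'   `samples` (sample sheet) and `truth` (bound sites per condition, active
#'   motifs, DAR window ids, effective per-bin profiles).
#' @export
gen_atac_fragments <- function(config, annotation = NULL, de_genes = NULL,
                               profile = NULL) {
  stopifnot(inherits(config, "sim_config"))
  S <- config$S; W <- config$motif_width
  K <- 2L * S + W
  if (config$genome_length <= 2 * (S + W))
    stop_gutreg("genome_length must exceed 2*(S + motif width)")
  profile <- profile %||% default_profile(S, W)
  if (length(profile) != K)
    stop_gutreg("profile length ", length(profile), " != 2S+W = ", K)
  if (abs(sum(profile) - 1) > 1e-9) stop_gutreg("profile must sum to 1")
  bins <- config$fragment_bins
  with_seed(config$seed + 23L, {
    chrom <- "chrSim"
    genome_v <- sample(c("A", "C", "G", "T"), config$genome_length,
                       replace = TRUE)
    motifs <- lapply(seq_len(config$n_motifs), function(k)
      gen_pwm(W, config$motif_concentration, id = sprintf("motif%02d", k)))
    names(motifs) <- vapply(motifs, function(m) m$id, "")
    active <- names(motifs)[seq_len(min(config$n_active_motifs,
                                        config$n_motifs))]
    ## non-overlapping windows on a grid
    n_sites <- config$n_motif_instances
    grid <- seq(S + 1L, config$genome_length - S - W - 1L, by = K + 10L)
    if (length(grid) < n_sites)
      stop_gutreg("genome too short for ", n_sites, " non-overlapping sites")
    starts0 <- sort(sample(grid, n_sites))  # 0-based motif starts
    site_motif <- sample(names(motifs), n_sites, replace = TRUE)
    site_strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    ## embed a PWM draw at each instance (reverse-complemented on -)
    for (i in seq_len(n_sites)) {
      m <- motifs[[site_motif[i]]]
      bases <- vapply(seq_len(W), function(j)
        sample(c("A", "C", "G", "T"), 1, prob = m$mat[, j]), "")
      if (site_strand[i] == "-")
        bases <- rev(chartr("ACGT", "TGCA", bases))
      genome_v[(starts0[i] + 1):(starts0[i] + W)] <- bases
    }
    genome <- setNames(paste(genome_v, collapse = ""), chrom)
    ## score the planted instances
    score1 <- function(i) {
      m <- motifs[[site_motif[i]]]
      seqb <- genome_v[(starts0[i] + 1):(starts0[i] + W)]
      if (site_strand[i] == "-")
        seqb <- rev(chartr("ACGT", "TGCA", seqb))
      sum(log2(pmax(m$mat[cbind(match(seqb, c("A", "C", "G", "T")),
                                seq_len(W))], 1e-12) / 0.25))
    }
    scores <- vapply(seq_len(n_sites), score1, 0)
    sites <- data.frame(
      site = sprintf("%s:%s:%d:%s", site_motif, chrom, starts0, site_strand),
      chrom = chrom, start = starts0, strand = site_strand,
      motif = site_motif, score = scores, stringsAsFactors = FALSE)
    class(sites) <- c("candidate_sites", "data.frame")
    ## sample sheet
    treat <- expand.grid(bio = seq_len(config$atac_treat_bio),
                         tech = seq_len(config$atac_tech_reps))
    ctrl <- expand.grid(bio = seq_len(config$atac_control_bio),
                        tech = seq_len(config$atac_tech_reps))
    samples <- rbind(
      data.frame(sample = sprintf("trt_b%d_r%d", treat$bio, treat$tech),
                 condition = "treatment"),
      data.frame(sample = sprintf("ctl_b%d_r%d", ctrl$bio, ctrl$tech),
                 condition = "control"))
    conds <- c("treatment", "control")
    ## latent bound states; the treatment condition may carry a shifted
    ## binding prior (microbiome-induced TF activity)
    cs <- scores - mean(scores)
    bound <- sapply(conds, function(cc) {
      shift <- if (cc == "treatment") config$atac_prior_shift else 0
      pr <- plogis(config$prior_b0 + shift +
                     ifelse(site_motif %in% active,
                            config$prior_b_pwm, 0) * cs)
      runif(n_sites) < pr
    })
    ## Effective per-bin profiles at bound sites: the drawn plus-strand
    ## events follow `profile`, each fragment's second end follows the
    ## induced minus profile (truncated at the window), and uniform
    ## background fragments contribute at a rate computable from the
    ## config. The mixture of the three is what insertion counts at bound
    ## sites actually follow.
    bg_len_range <- 250L - 39L + 1L
    eff_prof <- lapply(seq_len(nrow(bins)), function(b) {
      minus <- induced_minus_profile(profile, bins[b, "lo"], bins[b, "hi"])
      fp <- config$bound_rate * config$bin_weights[b] * c(profile, minus)
      binfrac <- (bins[b, "hi"] - bins[b, "lo"] + 1L) / bg_len_range
      bg_rate <- 2 * (config$bg_frag_per_window / config$window) * K * binfrac
      p <- fp + bg_rate / (2 * K)
      p / sum(p)
    })
    ## site fragments
    frag <- list()
    for (j in seq_len(nrow(samples))) {
      cc <- samples$condition[j]
      for (b in seq_len(nrow(bins))) {
        rate <- ifelse(bound[, cc], config$bound_rate,
                       config$unbound_rate) * config$bin_weights[b]
        nev <- rpois(n_sites, rate)
        tot <- sum(nev)
        if (!tot) next
        site_i <- rep.int(seq_len(n_sites), nev)
        isb <- bound[site_i, cc]
        rel <- integer(tot)
        if (any(isb))
          rel[isb] <- sample.int(K, sum(isb), replace = TRUE, prob = profile)
        if (any(!isb))
          rel[!isb] <- sample.int(K, sum(!isb), replace = TRUE)
        ## map motif-oriented relative position to genome coordinates
        win0 <- starts0[site_i] - S
        minus_site <- site_strand[site_i] == "-"
        gpos <- ifelse(minus_site, win0 + (K - rel), win0 + rel - 1L)
        estr <- ifelse(minus_site, "-", "+")
        L <- bins[b, "lo"] + sample.int(bins[b, "hi"] - bins[b, "lo"] + 1L,
                                        tot, replace = TRUE) - 1L
        fs <- ifelse(estr == "+", gpos - 4L, gpos + 5L - L)
        frag[[length(frag) + 1L]] <-
          data.frame(start = fs, end = fs + L, sample = samples$sample[j],
                     stringsAsFactors = FALSE)
      }
    }
    ## background fragments with planted DAR windows; optionally a fraction
    ## of DARs is placed near DE-gene TSSs with the gene's effect sign
    nwin <- as.integer(config$genome_length %/% config$window)
    n_dar <- max(1, round(config$dar_fraction * nwin))
    dar_idx <- integer(0); dar_dir <- numeric(0)
    if (!is.null(de_genes) && !is.null(annotation) && nrow(de_genes)) {
      n_near <- round(config$dar_near_frac * n_dar)
      gt <- annotation[!duplicated(annotation$gene), c("gene", "tss")]
      hit <- merge(de_genes, gt, by = "gene")
      if (nrow(hit) && n_near > 0) {
        ## promoter-proximal placement at the DE gene's TSS
        pick <- hit[sample.int(nrow(hit), n_near, replace = TRUE), ]
        w <- (pmin(pmax(pick$tss + round(runif(n_near, -1500, 1500)), 0),
                   config$genome_length - 1L)) %/% config$window + 1L
        keep <- !duplicated(w)
        dar_idx <- w[keep]
        dar_dir <- sign(pick$log2FC[keep])
        dar_dir[dar_dir == 0] <- 1
      }
    }
    remaining <- setdiff(seq_len(nwin), dar_idx)
    extra <- sample(remaining, n_dar - length(dar_idx))
    dar_idx <- c(dar_idx, extra)
    dar_dir <- c(dar_dir, sample(c(-1, 1), length(extra), replace = TRUE))
    lam <- rep(config$bg_frag_per_window, nwin)
    for (j in seq_len(nrow(samples))) {
      lj <- lam
      if (samples$condition[j] == "treatment")
        lj[dar_idx] <- lj[dar_idx] * 2^(config$dar_log2fc * dar_dir)
      nv <- rpois(nwin, lj)
      tot <- sum(nv)
      if (!tot) next
      win_i <- rep.int(seq_len(nwin) - 1L, nv)
      L <- sample(39:250, tot, replace = TRUE)
      fs <- win_i * config$window +
        sample.int(config$window, tot, replace = TRUE) - 1L
      frag[[length(frag) + 1L]] <-
        data.frame(start = fs, end = fs + L, sample = samples$sample[j],
                   stringsAsFactors = FALSE)
    }
    fr <- do.call(rbind, frag)
    ## clip to genome bounds (keep insertions in range)
    ok <- fr$start >= 5 & fr$end <= config$genome_length - 5
    fr <- fr[ok, ]
    cond_of <- setNames(samples$condition, samples$sample)
    fragments <- fragment_set(chrom, fr$start, fr$end, fr$sample,
                              unname(cond_of[fr$sample]))
    dar_ids <- sprintf("%s:%d-%d", chrom, (dar_idx - 1L) * config$window,
                       pmin(dar_idx * config$window, config$genome_length))
    truth <- list(
      active_motifs = active,
      bound_sites = lapply(setNames(conds, conds),
                           function(cc) sites$site[bound[, cc]]),
      dar_windows = dar_ids,
      dar_log2fc = setNames(config$dar_log2fc * dar_dir, dar_ids),
      effective_profile = eff_prof,
      prior = c(b0 = config$prior_b0, b_pwm = config$prior_b_pwm))
    list(fragments = fragments, sites = sites, motifs = motifs,
         genome = genome, samples = samples, truth = truth)
  })
}

#' Generate transcript models on the synthetic chromosome
#'
#' Genes are placed in a small number of clusters (so that TSS-proximity
#' questions have both near and far cases); transcripts of a gene share the
#' TSS and differ in exon structure.
#'
#' @param config A `sim_config`.
#' @return A `transcript_annotation` whose transcript/gene ids match the
#'   expression generators.
#' @export
gen_annotations <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  lay <- truth_layout(config)
  with_seed(config$seed + 31L, {
    genes <- unique(lay$genes)
    ng <- length(genes)
    cw <- max(config$cluster_width_frac * config$genome_length, 10000)
    anchors <- sort(runif(config$n_gene_clusters, 0.05, 0.95)) *
      config$genome_length
    gcl <- sample(seq_len(config$n_gene_clusters), ng, replace = TRUE)
    tss <- pmin(pmax(round(anchors[gcl] + runif(ng, -cw / 2, cw / 2)), 1000),
                config$genome_length - 6000)
    strand <- sample(c("+", "-"), ng, replace = TRUE)
    tx_gene <- lay$genes
    tx_i <- match(tx_gene, genes)
    n <- length(lay$transcripts)
    width <- sample(1000:5000, n, replace = TRUE)
    start <- ifelse(strand[tx_i] == "+", tss[tx_i],
                    tss[tx_i] - width + 1L)
    start <- pmax(start, 0L)
    end <- start + width
    block_starts <- vector("list", n)
    block_sizes <- vector("list", n)
    for (i in seq_len(n)) {
      nex <- sample(1:3, 1)
      cuts <- sort(sample(seq(50, width[i] - 50, by = 10), 2 * (nex - 1)))
      bs <- as.integer(c(0, cuts[seq_len(nex - 1) * 2]))
      be <- as.integer(c(cuts[seq_len(nex - 1) * 2 - 1], width[i]))
      block_starts[[i]] <- bs
      block_sizes[[i]] <- be - bs
    }
    transcript_annotation(lay$transcripts, tx_gene, "chrSim", strand[tx_i],
                          as.integer(start), as.integer(end),
                          block_starts, block_sizes)
  })
}

#' Generate a gene-trait catalog with planted enrichment
#'
#' Trait membership probabilities are chosen so that the overall catalog
#' rate equals `base_rate` while the planted gene set is enriched
#' `enrichment_fold`-fold in expectation relative to the whole background.
#'
#' @param config A `sim_config` (supplies `trait_base_rate`, `n_traits` and
#'   the default fold).
#' @param de_set Character vector of planted genes.
#' @param genes Background gene universe.
#' @param enrichment_fold Expected fold enrichment of `de_set` (>= 1).
#' @param seed RNG seed (default `config$seed + 41`).
#' @return List: `catalog` (data.frame gene/trait) and `truth`.
#' @export
gen_trait_catalog <- function(config, de_set, genes,
                              enrichment_fold = config$trait_enrichment_fold,
                              seed = config$seed + 41L) {
  stopifnot(inherits(config, "sim_config"))
  if (enrichment_fold < 1) stop_gutreg("enrichment_fold must be >= 1")
  q <- config$trait_base_rate
  N <- length(genes); m <- length(de_set)
  if (!all(de_set %in% genes)) stop_gutreg("de_set must be within the universe")
  p_de <- enrichment_fold * q
  if (p_de > 1)
    stop_gutreg("enrichment_fold ", enrichment_fold,
                " incompatible with base rate ", q,
                ": expected hits exceed the set size")
  p_bg <- q * (N - enrichment_fold * m) / (N - m)
  if (p_bg < 0)
    stop_gutreg("enrichment_fold incompatible with set sizes")
  with_seed(seed, {
    p <- ifelse(genes %in% de_set, p_de, p_bg)
    has <- runif(N) < p
    catalog <- data.frame(
      gene = genes[has],
      trait = sample(sprintf("trait%02d", seq_len(config$n_traits)),
                     sum(has), replace = TRUE),
      stringsAsFactors = FALSE)
    list(catalog = catalog,
         truth = list(enrichment_fold = enrichment_fold, base_rate = q))
  })
}
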