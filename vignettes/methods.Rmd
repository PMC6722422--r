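---
title: "Models and methods in gutreg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in gutreg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`gutreg` analyses an *in vitro* host–microbiome system: colonocytes
exposed to complex gut communities, read out by RNA-seq, ATAC-seq and
taxon count tables. This vignette explains the models, their
assumptions, the tunable parameters, the synthetic-data generator, and
the numerical and design choices — in enough detail that a maintainer
could re-derive every estimator.

## The count model

All sequencing counts (transcript RNA-seq counts, per-window Tn5
insertion counts) share one engine. Feature *i* in sample *j* is

$$y_{ij} \sim \mathrm{NB}(\mu_{ij}, \alpha_i), \qquad
\log \mu_{ij} = x_j^\top \beta_i + \log s_j,$$

with variance $\mu + \alpha\mu^2$. Assumptions: counts are independent
across features given the design; library composition is stable enough
for median-of-ratios normalization (a majority of features unchanged);
dispersion is feature-specific but exchangeable around a mean-dispersion
trend.

**Size factors.** $s_j$ is the median over reference features (positive
in every sample) of $y_{ij}/(\prod_j y_{ij})^{1/n}$, rescaled to
geometric mean 1. If no feature is positive everywhere the engine falls
back to total-count scaling with a warning.

**Dispersion.** Per feature, $\alpha_i$ maximizes the Cox–Reid adjusted
profile likelihood (the $-\tfrac12\log\det X^\top W X$ term removes the
leading bias from estimating $\beta$), searched on
$\log\alpha \in [\log 10^{-8}, \log 30]$ with fitted means re-estimated
once at the optimum. With at least 20 usable features the estimates are
then moderated: a normal prior on $\log\alpha$ centred on a lowess
mean–dispersion trend, with prior variance estimated as the MAD$^2$ of
the residuals minus the approximate sampling variance
$\psi_1((n-p)/2)$, floored at $0.0625$. Features more than two prior
standard deviations *above* the trend keep their raw estimate
(dispersion outliers must not be shrunk down, or their tests become
anticonservative). All-zero features are flagged and excluded.

**Wald test with moderated degrees of freedom.** The statistic is
$\hat\beta/\widehat{SE}$; the reference is $t$ with
$df = r + r\,\psi_1(r/2)/\sigma^2_{prior}$ where $r = n - p$. The two
limits are the right ones: with no shrinkage the reference is $t_r$,
with infinitely strong shrinkage (dispersion effectively known) it is
normal. This choice is what keeps the test calibrated at this study's
replicate numbers (five treated wells against three controls); the plain
normal reference is several-fold anticonservative below $p = 0.005$ at
that size, which matters because BH works with the far tail.

**LRT.** Twice the log-likelihood difference of nested fits (same
$\alpha_i$, estimated under the full design), $\chi^2$ with the rank
difference as df. Nesting is verified by projecting the reduced design
onto the full column space; a non-nested reduction is an error naming
the offending columns. Identical designs give statistic 0 and $p = 1$.

**BH.** Step-up with monotonicity, NAs excluded and propagated.
Family scopes: within each (design, contrast) for the per-time and
per-microbiome designs and the spike-in; jointly across the entire
transcript-by-taxon cross for the abundance scan (mirroring a single
global test family for that analysis); across regions for
accessibility; across motifs for footprint enrichment.

## Expression designs

* `time_replicate` — per time point, treated (all donor communities as
  biological replicates) vs control wells, Wald on the condition term.
* `per_microbiome` — one contrast per (donor, time) against that time
  point's controls.
* `trajectory_lrt` — full model `~ time * microbiome` (controls the
  reference level), reduced `~ time`: does the response trajectory
  depend on which donor the community came from?
* `taxon_covariate` — across treated samples only, a Wald test on the
  mean-centered baseline relative abundance of a taxon, one run per
  taxon. Abundance is expressed in percentage points, so the
  coefficient is log2 expression change per percentage point of the
  taxon in the inoculum; a constant covariate is a collinearity error,
  never fitted.
* `spikein_dose` — dose covariate $\log_{10}(\mathrm{percent} + 0.001)$,
  centered; the offset admits the 0% control and makes the five doses
  (0, 0.01, 0.1, 1, 10%) near-equally spaced. Coding the 0% control
  this way is a modelling choice, not a measurement; any monotone
  transform spanning four orders of magnitude behaves similarly.

Calls require padj < 0.10 *and* |log2FC| > 0.25, both strict. A gene is
called when any of its transcripts is called; the representative
transcript is the minimum-padj one (ties broken by order).

## Taxon dynamics

Rarefaction subsamples to exact depth without replacement (multivariate
hypergeometric); samples below depth are dropped with a warning.
Diversity is Gini–Simpson $1-\sum p_i^2$ — the only Simpson variant
consistent with values of 0.94–0.98 for diverse stool communities.
The coculture test compares Gaussian linear models on
$\log(\text{relative abundance} + 0.5/\text{depth})$: full
`~ donor + time + cocultured`, reduced `~ donor + time`. Two deliberate
choices: (i) the donor blocking term appears in both models because
donor communities differ by orders of magnitude — without it the test
has essentially no power at this design size; (ii) the p-value uses the
exact F reference for the (monotone-equivalent) LRT statistic, since
the $\chi^2$ approximation is anticonservative at 18 cultured samples.
Presence is a main effect (df = 1); an interaction version is available
behind a flag. The pseudo-abundance $0.5/\text{depth}$ handles
post-rarefaction zeros and is configurable.

## Windowed accessibility

Each fragment contributes two Tn5 insertion events, 4 bp interior to
each 5' end in its 5'→3' direction: positions $start+4$ and $end-5$ in
0-based coordinates. Non-overlapping 300-bp tiles from coordinate 0
count events by half-open membership. Regions pass at RPM strictly
greater than 0.25 — by default the mean RPM across samples; pooled and
per-sample modes are provided because the choice is not determined by
the method description. The accessibility test is the NB engine on the
treatment indicator, BH across regions, reported at FDR < 20%.

Region–TSS links pair a region with every transcript whose TSS is
within 50 kb (inclusive; distance 0 inside the region; strand used only
to place the TSS). Enrichment near DE genes is a two-sided Fisher test
on {near a called DAR} × {DE} over the gene universe, reporting both
the conditional-MLE and sample odds ratios. Concordance regresses the
representative transcript's log2FC on the region's log2FC over linked
pairs in which both members are called. The stratified FDR adjusts
region p-values separately within each motif's footprint-bearing
stratum and calls the union (a region is called if any stratum adjusts
it below 10%); with a single stratum this reduces exactly to plain BH.
The union carries a multiplicity caveat — no further correction is
applied across strata, which is logged rather than hidden.

## The footprint mixture model

For a motif of width $W$, candidate sites come from a log-odds PWM scan
($\sum_k \log_2 p_k(b)/q(b)$, both strands, threshold on that scale).
Around each site a ±150 bp window ($S = 150$) collects insertion
events into matrices with $(2S+W)\times 2$ columns (position × event
strand), one matrix per fragment-length bin (39–99, 100–139, 140–179,
180–250 bp) per condition; minus-strand site windows are
coordinate-reversed and event strands flipped so profiles are
motif-oriented.

The model: site $i$, condition $c$ carries a latent bound indicator
$Z_{ic}$ with prior $\mathrm{logit}\,P(Z=1) = \beta_0 +
\beta_{pwm}\,\mathrm{score}_i$ (coefficients shared across conditions);
given bound, the bin-$l$ event total is NB with a bound rate and
positions are multinomial with profile $\pi_l$ *shared across
conditions*; given unbound, a lower rate and uniform positions. EM:
posteriors in the E-step; in the M-step the profiles are
pseudocount-smoothed weighted count sums (Dirichlet 0.5 per cell — the
smoothing enters the objective, keeping the penalized log-posterior
provably non-decreasing, which the tests assert per iteration), rates
are exact weighted NB maximum-likelihood (weighted mean plus a 1-D size
optimization; Poisson is both a config option and the automatic limit
when it fits at least as well), and the prior is a weighted logistic
Newton fit with step clamping. Convergence: absolute change in the
penalized log-posterior below 1e-6 or 200 iterations (non-convergence
flags the fit; posteriors are still returned). $Z =
\hat\beta_{pwm}/SE$ from the converged logistic information. Activity
requires $Z > 5$ strictly; binding requires posterior > 0.99 strictly
in the named condition.

Two open points were decided as follows: the latent indicator is per
(site, condition) by default — the stated purpose of joint fitting is a
shared *shape*, not a shared state — with a shared-indicator flag; and
condition-specific priors sit behind a flag while the default shares
$\beta$ across conditions. The per-motif enrichment model is a logistic
regression of the gene-level DE indicator on the count of bound
footprints within 50 kb of the TSS; complete separation is detected
(|slope| > 10 or SE > 50) and flagged rather than reported.

## The synthetic-data generator

The generator's defaults describe the emulated study: 5 donor
microbiomes plus 3 control wells at 1/2/4 h; 2,000 transcripts with NB
dispersion 0.1, log-normal baselines (meanlog log 100, sdlog 1),
log-normal size factors (sdlog 0.2), 10% of transcripts planted at
|log2FC| = 1; a 200-taxon community with log-normal abundances
(sdlog 1.5, giving baseline Gini–Simpson in the mid-0.9s), rarefied to
141,000 reads, 10 taxa with a 2-fold coculture response; a spike-in at
0/0.01/0.1/1/10% in duplicate whose transcriptome-wide effect vector is
half the spiked taxon's (dense weak + sparse strong) abundance
coefficient vector plus noise — which is what makes the two experiments'
standardized effects genuinely concordant; and a 1.2-Mb synthetic
chromosome with 600 planted motif instances of 4 motifs (2 truly
score-responsive), ATAC layout 5 biological × 2 technical treatment
replicates vs 1 × 2 controls, 40 background fragments per 300-bp window
per sample (roughly 25-fold below study-scale coverage, the desk-scale
compromise that still powers the window test), 2% of windows planted as
differentially accessible at |log2FC| 0.8, and a treatment shift of
+0.5 on the binding-prior logit.

Two generator subtleties are worth recording. First, bound-site
fragments are generated by drawing the plus-strand insertion from the
planted profile and back-computing the fragment so the +4 rule recovers
it; the fragment's second end then lands $L-9$ bp downstream, so the
truth record stores the *effective* profile — drawn plus half, induced
minus half (exact convolution with the bin's length distribution,
truncated at the window), plus the computable uniform background
contribution. Recovery tests compare against that effective profile,
because it is what the data actually follow. Second, planted
accessibility signal leaks into the next window through second ends
(about 47% of a window's events originate in the previous window's
fragments), so the observed window-level fold change is roughly 0.6 of
the planted value; the planted 0.8 therefore appears as ≈0.5 — the
scale of reported single-region effects — and the pipeline's
false-discovery accounting treats immediate right-neighbour windows of
true DARs as leakage, not false positives.

What the generator does *not* emulate: read-level errors, mappability
and GC structure, genuine biological replicate correlation beyond
size-factor noise, OTU-level phylogenetic structure, chromatin domains,
or motif co-occurrence. Passing tests therefore demonstrate that the
estimators recover what they model, not that the model captures
everything in real data.

On the miniaturized chromosome every gene lies within 50 kb of some
region, so the end-to-end pipeline evaluates its proximity *metrics*
(DAR-near-DE enrichment, accessibility/expression concordance) at a
desk-scale distance (genome length / 500, at least 2.5 kb, capped at
50 kb); the 50-kb convention itself is unchanged in the API and is
asserted at its boundary in the tests.

## Problem sizes used in validation

Null calibrations use balanced designs of moderate size — 1,500 null
features or regions at 10 vs 10 samples, 600 coculture replicates, 800
logistic-enrichment replicates — chosen so the asymptotic regimes the
tests rely on actually hold and each block runs in minutes on one CPU.
Parameter-recovery runs use the study-condition generator defaults at
the 1,500–2,000-feature scale, and the footprint recovery uses 2,000
sites with a strong planted profile on model-generated data (no
background fragments), the appropriate regime for checking an
estimator against its own generative model. The end-to-end pipeline
runs the full defaults.

## Known limitations

* Dispersion moderation uses a single global prior width; no
  independent filtering or outlier count replacement is performed.
* The footprint model attributes all events at a bound site to the
  footprint component; genome background at sites is absorbed into the
  profile rather than modelled as a third component.
* The Gaussian coculture model treats time as a factor and assumes
  homoscedastic log-abundances; taxa at very low counts are dominated
  by the pseudo-abundance.
* Fisher enrichment on the synthetic chromosome is geometry-limited;
  odds ratios there are reported, not asserted.
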