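---
title: "Verifying sample identities with sex, ancestry and kinship evidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Verifying sample identities with sex, ancestry and kinship evidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Public sequencing archives attach metadata — individual name, studbook or
registry number, sex, species — to each deposited genome.  When samples are
switched before or during sequencing, every downstream study that relies on
*which animal* a genome came from inherits the error.  `trifold` implements
a verification procedure built from three independent molecular evidence
channels, each compared against archival expectations:

1. **Genetic sex** from the ratio of reads mapped to the X and Y
   chromosomes;
2. **Species / population of origin** by supervised admixture against a
   labelled conspecific reference panel;
3. **Kinship** between each query genome and genotyped known relatives,
   compared with the coefficients expected from recorded pedigrees.

A sample keeps the registry identities compatible with its inferred sex and
species (exclusion), gains a confirmed identity when an observed kinship
coefficient resembles a recorded relationship, and is finally assigned under
a global uniqueness constraint.  Identity is only trusted where the
available channels concord; everything else is flagged rather than forced.

## Sex from X:Y read ratios

For a sample with per-chromosome mapped-read counts, the statistic is the
length-normalized coverage ratio

$$ R = \frac{m_X / L_X}{m_Y / L_Y}. $$

An XY male carries one copy of each, so $R \approx 1$ under this
normalization; an XX female has no Y and her $m_Y$ is mismapping noise, so
$R$ is one to two orders of magnitude larger.  Because published ratios in
the wild vary with the reference build, the Y assembly and the mapping
pipeline, `trifold` never hard-codes bands: `calibrate_thresholds()` takes
known-sex individuals and widens the observed male maximum and female
minimum by a multiplicative margin (default 0.25), leaving an explicit
*undetermined* zone between the widened bands.  Ties at a threshold resolve
toward the labelled side.  A zero Y count returns an infinite ratio with a
flag, interpreted as strongly female.

## Supervised admixture

Genotypes are modelled binomially: dosage $g_m \sim \mathrm{Bin}(2, p_m)$
with $p_m = \sum_k q_k f_{km}$, where $q$ is the sample's ancestry vector
over $K$ source populations and $F = (f_{km})$ the population allele
frequencies.  `supervised_q()` maximizes this likelihood over the simplex
with $F$ held fixed, by the classical EM update — monotone in the
log-likelihood, which the tests assert at every iteration.

Two practical points matter with a small panel (9 diploids per population
in the default design):

* **Plug-in panel frequencies attenuate.**  Holding $F$ at panel estimates
  makes the MLE of a truly pure sample's major component level off around
  0.83 — errors-in-variables shrinkage, since mixing populations averages
  away the panel noise.  `supervised_admixture()` therefore implements the
  proper supervised mode: panel samples' $q$ are pinned to their labels
  while $F$ is re-estimated from *all* samples by block EM.  Pure samples
  then recover $q > 0.95$ routinely.
* **Pseudocounts.**  Panel frequencies use $(c + 0.5)/(2n + 1)$ and are
  clamped to $[10^{-6}, 1-10^{-6}]$ so monomorphic panels never produce a
  degenerate likelihood.

A sample is called to a population when its majority component reaches
`major_min` (default 0.85), otherwise *admixed* — which matches no registry
candidate and is flagged.

The number of source populations is checked by `cv_error()`: genotype
*cells* are masked in random folds, the unsupervised model is refitted on
the remainder (EM updates simply skip masked cells), and masked dosages are
scored by squared error against $2\sum_k q_k f_{km}$; the whole procedure is
repeated over re-randomized fold assignments and reported as mean ± SD.
Masking cells rather than whole samples keeps every sample in every fit,
mirroring how held-out deviance is normally computed for this model; the
squared-error score is a deliberate simplification of the binomial deviance
and is documented as such.

## Ancestry-adjusted kinship

With individual-specific frequencies $\mu_{im} = \sum_k q_{ik} f_{km}$, the
kinship coefficient of samples $i, j$ is the moment estimator

$$ \hat\Phi_{ij} = \frac{\sum_m (g_{im} - 2\mu_{im})(g_{jm} - 2\mu_{jm})}
   {4 \sum_m \sqrt{\mu_{im}(1-\mu_{im})\,\mu_{jm}(1-\mu_{jm})}}, $$

which conditions out population structure: unrelated individuals from the
same (or different) populations centre at zero, parent–offspring pairs at
0.25, and a sample against itself at $(1 + F_i)/2 \approx 0.5$.

**Finite-panel correction.**  When both $\mu_i$ and $\mu_j$ are built from
the *same* small panel, the shared estimation error of $\hat f_{km}$
inflates the numerator by $4\sum_m \sum_k q_{ik} q_{jk}
\mathrm{Var}(\hat f_{km})$ — about $1/(2n_k)$ on the kinship scale, i.e.
$\approx 0.056$ for a 9-diploid panel, far above the 0.02 confirmation
floor.  `panel_bias_correction()` evaluates this term by plug-in and
`kinship_pairs()` subtracts it when panel sizes are supplied.  For the same
reason the kinship stage uses the *plug-in* panel frequencies (whose
sampling variance is known in closed form) together with the jointly
estimated ancestry vectors, rather than the jointly re-estimated $F$, whose
errors are correlated with the query genotypes in a way that has no clean
correction.

IBD-state proportions $(\delta_0, \delta_1, \delta_2)$ are estimated from
the observed 3×3 joint-genotype table: expected tables under 0, 1 or 2
shared alleles are computed per SNP (the shared allele drawn at the
pair-averaged frequency $\bar\mu_m$ — a documented approximation), and the
simplex-constrained least-squares weights are found exactly by enumerating
the seven active sets of a three-variable quadratic program.

**Pedigree expectations** come from two independent routes: the recursive
kinship algorithm ($\phi(a,a) = \tfrac12(1+\phi(s_a,d_a))$,
$\phi(a,b) = \tfrac12(\phi(s_a,b)+\phi(d_a,b))$, founders unrelated and
non-inbred) and exact inheritance-vector enumeration for the IBD-state
probabilities (one bit per parent–child transmission, up to 20 bits, with a
seeded Monte Carlo fallback beyond that).  The identity
$\Phi = \delta_1/4 + \delta_2/2$ ties the two together and is asserted
exactly in the tests.  Inbred pairs are rejected — condensed identity
coefficients are out of scope.

## Resolution rules

* **Exclusion**: candidates must match inferred sex (undetermined matches
  both) and inferred species (admixed matches none).
* **Confirmation**: candidate $c$ is confirmed for sample $s$ if some known
  relative $r$ of $c$ shows $\hat\Phi_{sr} > \texttt{floor}$ (default 0.02)
  and $|\hat\Phi_{sr} - \Phi_{\exp}(c,r)| \le \tau$ (default 0.1).  The
  tolerance is deliberately wide: in the worked example shipped with the
  package, a genuine grandmother–granddaughter link shows 0.036 against an
  expected 0.125, a deviation of 0.089 — real relationships can attenuate
  substantially, while the next degree of relationship is far enough away
  that $\tau = 0.1$ does not cross it.  If passing hits support more than
  one candidate, none is confirmed.
* **Uniqueness**: singleton candidate sets are assigned first
  (iteratively, lexicographic order for determinism); the remainder go
  through maximum bipartite matching restricted to their candidate sets,
  and a match is accepted only when it is *forced* (removing the edge
  shrinks the maximum matching).  Samples with disagreeing channels are
  flagged `conflict`, ambiguous ones `unresolved`; nothing is ever
  force-assigned, and no individual is assigned twice.

An optional archival-records channel (a per-sample candidate from
biomaterial or LIMS records) joins the intersection when present; its
absence weakens the confidence flag but never blocks assignment.  Archival
lab-id validation enters only the discrepancy summary, where a reported
lab id that the records cannot verify counts as a relabel without a
misattribution.

## The synthetic-data generator

`make_scenario()` builds complete study scenarios so the whole pipeline is
testable without external data.  What it emulates, and the default values:

| Feature | Default | Why |
|---|---|---|
| Populations | 3, Balding–Nichols, $F_{st} = 0.1$ per population | three diverged lineages; 0.1 gives clean $K=3$ separation at $10^4$ SNPs |
| Ancestral SNP frequencies | $U[0.05, 0.95]$, $1.4 \times 10^4$ raw SNPs | $\ge 10^4$ survive the MAF $\ge 0.05$ complete-case filter |
| Reference panel | 27 individuals, 9 per population | matches the conspecific panel size of the motivating study |
| Queries | 10 (5/4/1 across populations), mixed sexes | matches the re-sequenced cohort |
| Relatives | 8 genotyped, covering 7 queries; degrees 1,1,1,1,2,2,2,3 with one relative child of two queries and one family of three relatives | same degree multiset as the motivating genogram |
| Planted permutation | single random cycle over 9 of 10 queries | the "nine of ten switched" design |
| Read counts | Poisson; autosomes 2 copies, X 2/1, Y 1 or mismap leak; depth 1–5×, mismap 0.01 | separates male ratios (~1) from female (~100) |
| Chromosomes | 22 autosomes 227–47 Mb, X 140 Mb, Y 26 Mb | great-ape-like magnitudes; configurable, not constants |

All randomness flows from one base seed through named substreams
(`substream_seed()`), so every stage is independently reproducible and a
scenario is byte-identical under the same seed.

What the generator does **not** emulate — and hence what passing tests do
not show about real data: linkage (SNPs are unlinked by construction; LD
pruning is exercised on a dedicated option that duplicates SNPs with copy
noise), genotyping error and missingness, sequencing-error models,
reference bias, admixed or inbred founders (founders are purebred unless
configured otherwise), and sex-chromosome aneuploidy.

**Why the default pipeline does not LD-prune the scenario.**  With a
45-sample cohort, the sampling noise of $r^2$ between truly independent
markers has mean $\approx 1/(n-1) \approx 0.023$ and a long tail above the
0.1 pruning ceiling, so pruning would discard a large fraction of
mostly-independent — and preferentially ancestry-informative — SNPs.
Since the generator produces unlinked SNPs, the default scenario skips the
pruning step (`prune = FALSE`); the pruning algorithm itself (PLINK-style
sliding window, composite-LD $r^2$ on mean-centred dosages, lower-MAF
member removed, later coordinate on ties) is exercised and re-scanned on
deliberately correlated blocks.

## Numerical choices

* Allele frequencies are clamped to $[10^{-6}, 1-10^{-6}]$ everywhere.
* EM stops when the log-likelihood improves by less than `tol`; the
  scenario pipeline uses `tol = 0.05` (log-likelihood units) with a
  400-iteration cap — ancestry estimates stabilise well before the
  likelihood tail flattens, and the species call only needs the majority
  component to clear 0.85.
* MAF filtering is inclusive ($\ge$) and computed from allele counts, so a
  frequency of exactly 0.05 survives a 0.05 threshold.
* The simplex least-squares for $(\delta_0,\delta_1,\delta_2)$ rejects
  degenerate designs (near-collinear expected tables, e.g. all frequencies
  at a bound) by condition-number check.
* Bipartite matching tie-breaks are lexicographic so re-runs are identical.

## Problem sizes used by the checks

The packaged studies run at desk scale, chosen to keep each check's
sampling error well inside its tolerance: kinship calibration uses 20
replicates of $10^4$ SNPs (estimator SD $\approx 0.008$ per replicate,
i.e. $\approx 0.002$ on the mean, against tolerances of 0.02); supervised
recovery uses 5 seeds at $10^4$ SNPs against a 0.05 tolerance;
cross-validation over $K$ uses 30 samples × 2000 SNPs with 5 folds × 10
fold re-randomizations; end-to-end recovery runs the full default scenario
over 20 seeds.

## Known limitations

* The kinship confirmation rule requires only one passing hit (plus no
  passing hit for a different candidate); how to weigh one failing hit
  against several passing ones for the same candidate is a judgement call,
  and this package's rule is one documented choice.
* IBD-state estimation assumes non-inbred, outbred pairs; the 9-state
  condensed coefficients are not implemented.
* The records channel is an abstract per-sample candidate; digitizing
  archival documents is out of scope.
* Unsupervised admixture labels are unidentifiable (any population
  permutation is an equivalent optimum); only supervised runs carry
  population names.
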