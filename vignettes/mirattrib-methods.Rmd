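---
title: "Methods: attributing mutant-ER expression programs to microRNAs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: attributing mutant-ER expression programs to microRNAs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirattrib)
```

## Scope and model

`mirattrib` chains five statistical steps that together quantify how much of
the gene expression program specific to ER-mutant (Y537S/D538G) breast
cancer cells can be attributed to differentially expressed miRNAs. Each step
is an ordinary, well-understood procedure; the package's contribution is the
integrated, direction-aware accounting and a generator that makes the whole
chain testable against planted truth.

### Panel miRNA normalization

Raw panel counts $c_{ij}$ (feature $i$, sample $j$) are normalized by a
per-sample factor derived from a reference feature set $R$:

$$g_j = \Big(\prod_{i \in R}(c_{ij}+1)\Big)^{1/|R|}, \qquad
  f_j = \bar g / g_j, \qquad
  x_{ij} = c_{ij} f_j, \qquad
  y_{ij} = \log_2(x_{ij}+1).$$

Two choices of $R$ are supported: the 100 endogenous features with the
highest mean raw count across **all** samples (one global set, so every
sample is scaled against the same reference), or the spike-in controls.
Using $\bar g$ (the arithmetic mean of the $g_j$) as the reference value
preserves the overall count magnitude; any other positive constant would
only shift all log values. After scaling, the pseudocounted geometric mean
of $R$ is equal across samples by construction ($g_j f_j = \bar g$); this
identity is the package's core normalization invariant and is tested to
$10^{-9}$. Note that the normalized *values* are equivariant, not invariant,
under a global rescaling of the raw counts — only the ratios
$x_{ij}/\bar g$ are scale-free.

The +1 pseudocount (inside the geometric means and before the log) is the
smallest integer shift that keeps zero counts finite; panel data contain
many zeros near the detection floor. Background thresholding and
housekeeping-content normalization are deliberately out of scope.

### Differential miRNA calling

Per miRNA and contrast, a two-sided two-sample $t$ test on $y$ (pooled
variance by default; Welch behind `var_equal = FALSE`) or a paired $t$ test
on within-pair differences for knock-down designs, where pairs are
clone-matched samples and the pairing absorbs clone-level baseline shifts.
Calls use the raw $p < \alpha$ (default 0.05) with **no multiple-testing
correction**, reflecting the hypothesis-generating character of the step;
BH $q$ values are always reported alongside. A miRNA is differentially
expressed if it is significant under *either* normalization scheme; a miRNA
significant under both schemes with conflicting directions is dropped and
logged. Degenerate zero-variance rows follow a deterministic convention:
zero difference gives $t = 0, p = 1$; nonzero difference gives
$t = \pm\infty, p = 0$ with a `degenerate` flag.

Whether the $t$ tests run on $\log_2$ or natural-log values is immaterial
for $p$; $\log_2$ is used so fold changes read in doublings.

### Direction-aware target enrichment

miRNAs repress their targets, so the biologically coherent test opposes
directions: targets of an up-regulated miRNA against *down*-regulated
mutant-specific genes, and vice versa. Each test is an upper-tail
hypergeometric probability $P(X \ge k)$ (computed by `stats::phyper`, which
works in log space; verified against exhaustive enumeration for all
parameter combinations with $N \le 12$). Concordant pairings are available
as negative controls. The universe is the set of genes tested in the DEG
analysis (all genes, not just significant ones), intersected upstream with
the target database's gene space if desired; it is always an explicit
argument and is echoed in every report, because enrichment $p$ values are
meaningless without it. Candidates are miRNAs significant in at least one
genotype, annotated `both` / genotype-specific.

Two properties of this funnel are worth stating plainly. First, the exact
test is discretely conservative: at realistic set sizes (target sets of
60–150 genes, 500 DEGs per direction in a 15000-gene universe) its realized
null rejection rate is ≈ 0.032 rather than 0.05. Second, with ~69
non-enriched differential miRNAs entering the funnel at raw
$\alpha = 0.05$, about 2–3 chance candidates are expected per run alongside
~15 true ones, i.e. roughly 13–17% of selections are impostors. That is the
price of the no-correction design; the reported BH $q$ values let a user
apply a stricter rule.

### Perturbation integration and the explained fraction

A mimic restores a mutant-down miRNA (its responsive targets go down); an
inhibitor suppresses a mutant-up miRNA (targets go up). The perturbation
DEG set and the mutant-specific DEG set are partitioned into the four
direction combinations; each is tested with the hypergeometric overlap
test, and the direction-opposed combination expected for the perturbation
type (mimic: perturbation-down × mutant-up; inhibitor: perturbation-up ×
mutant-down) defines the *miRNA-altered mutant-specific genes*. Genes
tested in only one experiment are excluded from both the overlap and its
universe. Within the opposed shared set, the fraction that are predicted
direct targets is reported with its own enrichment $p$.

The attribution summary pools the opposed shared genes across perturbed
miRNAs per genotype (matched-genotype pooling) and computes

$$E \;=\; \frac{|\text{unexplained} \cap \text{pooled miRNA-altered}|}
              {|\text{unexplained}|},$$

where "unexplained" is the mechanism flag for mutant-specific genes not
attributed to constitutive ER activity, differential ER binding, or
accessibility changes. $E$ is a set-union count, hence monotone
non-decreasing as miRNAs join the pool, and is reported as missing (never
0/0) when no gene carries the flag.

### Regulatory context

Windows are anchored at the pri-miRNA TSS point, symmetric $\pm d$
(defaults 10 kb and 100 kb), half-open; any overlap of a site interval with
the window counts. TSS positions are an input annotation, not inferred.
Nearest distances use the IRanges gap convention (bases strictly between
TSS and site; 0 when covering or abutting). A miRNA is intronic only under
strict containment within a single intron — touching an exon boundary
disqualifies — and host concordance requires, by default, same-strand
containment (the co-transcription mechanism is strand-dependent) plus
significant differential expression of both members in the same genotype
with the same sign; opposite-strand containment is reported but excluded.
All interval logic runs through GenomicRanges and is tested for equality
with a naive $O(nm)$ scan; internal coordinates are 0-based half-open
everywhere, with GFF3 converted at the boundary.

### Growth kinetics

Per well, confluence is normalized to the earliest measured point and
$\log_2$-transformed, so exponential growth becomes a line whose slope is
the rate in doublings/hour. Two conditions are compared in one Gaussian
linear model `y ~ time * condition` over the pooled well-level
observations; the slope difference is the interaction coefficient and the
Wald statistic $z = \Delta\beta / \mathrm{SE}$ is referred to the standard
normal (a $t$ reference and a well-clustered robust SE are available behind
flags). Wells enter as independent observations, mirroring the plain
linear-model design; with 4 wells × 25 time points the normal and $t$
references are indistinguishable.

One subtlety: when measurement noise also affects the $t_0$ reference used
for normalization, the per-well reference error propagates into every
residual of that well. It cancels exactly out of the slope estimate
(balanced design), but inflates the residual variance estimate, so the
nominal Wald test becomes conservative (empirical size ≈ 0.017 at
$\sigma = 0.05$). Under iid deviations on the log scale the test is
calibrated (size ≈ 0.05, verified by simulation). Users comparing very
subtle rate differences should know the test errs on the safe side for
IncuCyte-style normalized data.

## The synthetic-data generator

`simulation_config()` defines the study conditions; `simulate_all()` draws
every pipeline input plus the ground truth. Defaults describe the
study-shaped scenario and were fixed once, by design-stage power
reasoning, before any end-to-end checks were run:

| parameter | default | rationale |
|---|---|---|
| panel | 800 miRNAs + 5 spike-ins | human panel-assay scale |
| baseline design | 2 genotypes × (2 clones × 3 reps) vs WT | 6 vs 6 per contrast |
| NB means | $2^{U(3,11)}$ | panel dynamic range ~8–2000 counts |
| NB dispersion | 0.1 | typical panel overdispersion |
| size factors | lognormal, sdlog 0.2 | makes normalization consequential |
| planted DE | 84 miRNAs, $\lvert\log_2\mathrm{FC}\rvert = 2$, split 12 both / 44 Y537S / 28 D538G | ~10% of panel, allele-specific |
| coupled subset | 15 (2 both / 8 / 5), odds 5 | targets enriched in opposed DEGs |
| targets per miRNA | 60–150 | validated-database scale after expression filtering |
| mutant DEGs | 500 per genotype × direction of 15000 genes | thousands in total across genotypes |
| mechanism flags | 45/15/10/30% constitutive / ER-binding / accessibility / unexplained | two-thirds explained a priori |
| knock-down arm | 4 pairs per genotype, pair sdlog 0.4, 50% of planted miRNAs revert by 60% | clonal variability motivates the paired test |
| genome | loci 1 Mb apart; ERBS within 10 kb w.p. 12/15, 100 kb-only 1/15, differential 4/13, ATAC 6/15; 30/84 intronic, 4/30 host-concordant | study-shaped placement probabilities |
| growth | 0–48 h at 2 h, 4 wells, $C_0 = 15\%$, ceiling 100%, $\sigma = 0.05$; mutant ~0.03 doublings/h halved-to-abolished by mimic | live-cell-imaging design |

Spike-ins share one mean across samples *before* size-factor scaling, so
spike-in normalization removes size factors in expectation — this is what
makes the two schemes genuinely different estimators of the same factors.
Baseline-arm counts are iid within a group (no clone random effect), so the
null calibration of the unpaired $t$ test is a meaningful property;
clone-level heterogeneity is modeled only in the knock-down arm as
pair-level lognormal offsets, which is precisely the situation the paired
test addresses. Coupling is implemented by weighted sampling of targets
(weight = odds for direction-opposed DEGs), which makes the enrichment's
power analytically approximable; `coupling_odds = Inf` draws targets
exclusively from the opposed set and errors if it cannot.

Each generator stage draws from its own seeded stream (config seed + fixed
stage offset), so stages are individually reproducible and reordering one
does not perturb another. Identical config + seed produces byte-identical
outputs, including the final JSON report.

What the generator does **not** emulate: read-level sequencing data,
background thresholding of panel counts, batch effects, protein-level
measurements (RNA–protein discordance cannot arise here), correlated
multi-miRNA targeting of the same gene, or saturation kinetics beyond a
hard confluence ceiling. Passing recovery tests therefore demonstrates that
the statistical machinery is correct and calibrated under the stated
generative model — not that the model captures every failure mode of real
panel or imaging data.

## Numerical and design choices

- **Coordinates.** 0-based half-open internally; GFF3 (1-based closed)
  converted at the boundary; the conversion is self-inverse and round-trip
  tested.
- **Raw counts are immutable.** Normalized values live in a separate
  object; count files always contain integers.
- **Hypergeometric tail.** Delegated to `phyper(k-1, K, N-K, n,
  lower.tail = FALSE)`; $k = 0$ returns exactly 1; parameter violations are
  hard errors, not clamped.
- **Union rule.** Significant under either scheme; conflicting directions
  drop the miRNA (logged); the reported statistics come from the
  smaller-$p$ significant scheme.
- **Candidate labels.** Sorted by miRNA so selection is invariant to input
  order.
- **Ties and degeneracy.** Zero-variance $t$ tests and empty shared sets
  follow fixed conventions (above) so pathological synthetic inputs are
  deterministic.
- **No stage caching.** The pipeline is deterministic and runs in seconds
  at study scale; a cold rerun *is* the cache, and removing cache keys
  removes a whole class of staleness bugs.
- **Reports.** One TSV per stage plus a JSON summary written at full
  precision with unboxed scalars; every JSON number is recomputable from
  the TSVs, and the tests do recompute them.

## Problem sizes used by the test suite

The suite favors a few deep, parameterised checks over many shallow ones.
Monte-Carlo sizes were chosen so each check resolves the property it tests:
hypergeometric enumeration sweeps every parameter set with $N \le 12$;
normalization invariants use 50 random matrices; null calibration of the
differential calls pools 32 000 tests over 20 seeded simulations;
planted-recovery pools 10 genotype contrasts over 5 seeds; the candidate
funnel pools 20 seeds; interval queries are checked on 100 random genomes;
the growth Wald test uses 2000 null replicates and 100 power replicates.
Where a Monte-Carlo estimate is compared against a fixed band, the
comparison allows for the estimate's own sampling error.

## Known limitations

- The no-correction candidate funnel admits ~$\alpha \times$ (number of
  non-enriched DE miRNAs) chance candidates by construction; use the
  reported $q$ values for a purified list.
- The explained fraction attributes by set overlap, not causality; a gene
  counted as "explained by miRNAs" may also respond through secondary
  transcription-factor effects.
- Host-gene concordance uses the strictest reading (both members
  significant, same genotype, same sign); moderate but sub-threshold
  coordination is not counted.
- The growth model ignores well-level random effects beyond the optional
  clustered SE, and the Wald test is conservative under reference-point
  noise (see above).
- PDX-style cohorts are supported by the data structures (`cohort` column,
  `set_overlap_test()` for cross-cohort DE-miRNA overlap) but the generator
  does not emulate xenograft-specific variability.
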