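# mirattrib

Attribution of mutant estrogen receptor (ER) gene expression programs to
microRNAs.

## The problem

Activating mutations in the ligand-binding domain of ER&alpha; (most commonly
Y537S and D538G) arise in a large fraction of hormone-therapy-resistant
ER-positive breast cancers. These mutants are constitutively active and
dysregulate thousands of genes ("mutant-specific genes"); constitutive ER
activity, altered ER genomic binding and chromatin accessibility account for
most of those changes, but a sizeable remainder is mechanistically
unexplained. Because miRNAs are Pol II transcripts that ER can regulate, and
because each miRNA represses a battery of target mRNAs, differential miRNA
expression is a natural candidate mechanism for the unexplained remainder.

`mirattrib` implements the full quantitative chain of that argument as a
reusable, tested R pipeline, for computational biologists who want to run
the analysis on their own panel-miRNA / RNA-seq / live-cell-imaging data or
to study its statistical behavior on simulated data:

1. **Panel miRNA quantification** — geometric-mean normalization of raw
   counts under two schemes (reference set = top-100 expressed miRNAs, or
   the spike-in controls): for sample *j*,
   *g<sub>j</sub>* = geomean(c<sub>ij</sub>+1) over the reference set,
   *f<sub>j</sub>* = mean(*g*)/*g<sub>j</sub>*, then
   *y<sub>ij</sub>* = log&#8322;(c<sub>ij</sub>·f<sub>j</sub>+1).
   Per-contrast two-sided t tests (Student by default; paired for knock-down
   designs with clone-matched pairs) call differential miRNAs at raw
   *p* &lt; &alpha;, and calls are unioned over the two schemes
   (direction conflicts dropped).
2. **Direction-aware target enrichment** — since miRNAs repress their
   targets, the target set of an up-regulated miRNA is tested against
   *down*-regulated mutant-specific genes and vice versa, with the
   upper-tail hypergeometric probability
   P(X &ge; k) = &Sigma;<sub>i&ge;k</sub> C(K,i)C(N&minus;K,n&minus;i)/C(N,n);
   miRNAs significant in at least one genotype become candidates.
3. **Perturbation integration** — mimic/inhibitor RNA-seq DEG tables are
   overlapped with mutant-specific genes in all four direction
   combinations; the direction-opposed overlaps (the "miRNA-altered
   mutant-specific genes") are scored for predicted direct targets and
   pooled into an explained fraction
   E = |unexplained &cap; miRNA-altered| / |unexplained|.
4. **Regulatory context** — ER-binding sites and differential
   accessible-chromatin peaks are counted in &plusmn;10 kb / &plusmn;100 kb
   windows around each pri-miRNA TSS, and intronic miRNAs are checked for
   expression concordance with their host genes.
5. **Growth kinetics** — confluence time courses are normalized to each
   well's initial value, log&#8322;-transformed, and condition slopes
   (doublings/hour) are compared with a Wald test on the interaction term
   of a joint Gaussian linear model.

A first-class synthetic-data generator emulates every input — negative
binomial counts with lognormal size factors and planted differential
miRNAs, a planted miRNA&rarr;target repression structure coupled to DEG
directions, a synthetic genome with planted TSS-proximal binding sites and
intronic host genes, and exponential growth curves with planted rates — and
returns the ground truth, so every stage can be tested for calibration and
recovery.

## Worked example

```r
library(mirattrib)

cfg <- run_config(sim = simulation_config(seed = 1))
run <- run_pipeline(cfg)

run$summary$n_de_mirnas_total
#> [1] 180
head(run$candidates, 4)
#>      mirna genotypes n_genotypes        min_p
#> 1 miR-0022     D538G           1 6.966597e-05
#> 2 miR-0040      both           2 4.118798e-08
#> 3 miR-0104     D538G           1 2.063952e-02
#> 4 miR-0176     Y537S           1 6.099397e-07
run$attribution[, c("genotype", "n_unexplained", "n_pooled_unexplained",
                    "explained_fraction")]
#>   genotype n_unexplained n_pooled_unexplained explained_fraction
#> 1    Y537S           287                   32         0.11149826
#> 2    D538G           303                   22         0.07260726
run$slopes[1, ]
#>   condition_1   condition_2 delta_slope           se         z             p
#> 1 Y537S_mimic Y537S_negctrl -0.03072779 0.0009556922 -32.15239 8.178863e-227
```

Reading the output: 180 of 800 panel miRNAs are called differentially
expressed in at least one ER-mutant line (84 planted plus raw-&alpha;
chance calls from the union over two normalization schemes, mirroring the
hypothesis-generating design); 21 candidates survive the direction-aware
enrichment funnel, including 14 of the 15 truly coupled miRNAs; pooling the
direction-opposed perturbation overlaps explains 11.1% / 7.3% of the
unexplained mutant-specific genes in Y537S / D538G under the default
response settings; and the mimic that reverts a down-regulated miRNA wipes
out the mutant line's growth advantage (slope change &minus;0.031
doublings/h, Wald z = &minus;32).

`write_report(run, "out/")` writes one TSV per stage plus a `report.json`
whose every number is recomputable from the TSVs.
`write_simulation(simulate_all(cfg$sim), "inputs/")` materializes all input
files (counts TSV, sample sheet, GMT target sets, BED6/GFF3 annotations,
DEG tables, growth TSV) plus `truth.json`, and the readers
(`read_count_matrix()`, `read_gmt()`, `read_bed6()`, `read_gff3()`,
`read_deg_table()`, `read_growth_table()`) load the same formats from any
other source. `read_run_config()` builds a run from a YAML file.

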