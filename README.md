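# shellform

Where are mollusk shell matrix protein (SMP) genes transcribed, and which
genes respond when the shell is damaged? `shellform` implements the
inference chain for answering both questions from *unreplicated* bulk
RNA-seq — one library per organ, one pooled library per treatment group —
the design under which most early invertebrate transcriptome studies were
run and where ordinary replicate-based differential expression does not
apply.

The package is aimed at analysts working with single-library count tables
(historic datasets, pooled designs, pilot experiments) who need the classic
exact-test + persistence machinery in tested, scriptable form.

## What it computes

**Organ-of-origin classification.** Counts are normalized to RPKM,
`10^9 * c / (L * N)` (count `c`, gene length `L` bp, library size `N`). A
gene is *expressed* in an organ when RPKM > 5 (strict). An SMP gene is
*non-mantle* when its mantle RPKM is below 5 while another organ exceeds 5
at ≥ 2× the mantle value; the *non-mantle, non-hemolymph* subclass also
requires hemolymph RPKM < 5, excluding circulating hemocytes as the source
of the signal.

**Exact two-library tests.** Treated vs control counts are compared by the
Audic–Claverie conditional test: given control count `x`, the treated count
follows `P(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))` — a
negative binomial with size `x+1` and prob `N1/(N1+N2)` — with a two-sided
p doubling the smaller tail. Calls use strict `p < 1e-3` and
depth-normalized rate direction.

**Recurrence against a random-recurrence null.** For each gene, `k` counts
the dates (of 7) on which it is called upregulated on the damaged side.
Genes with `k >= 6` form the shell-formation candidate set. The "would this
happen by chance?" question is answered against a Poisson-binomial null
(closed form) and a date-wise permutation null (preserves per-date call
counts), with an excess histogram and a Monte-Carlo tail p-value.

**Enrichment.** Hypergeometric over-representation of any gene set with
Benjamini–Hochberg FDR, over a user-supplied gene→term table (GO terms,
KEGG pathways, anything).

**Simulation.** Negative-binomial/Poisson count generators for both
experiments with known ground truth (planted non-mantle SMP genes, planted
persistent and transient damage responders), used throughout the test
suite for parameter-recovery checks.

## Worked example

```r
library(shellform)

cfg <- run_config(seed = 7,
                  atlas      = atlas_scenario(n_genes = 2000),
                  timecourse = timecourse_scenario(n_genes = 2000),
                  n_permutations = 200)
res <- run_full_pipeline(cfg, "shellform_results")
res$recurrence$left_up
```

```
recurrence_test (permutation null), side=left, direction=up
               0      1    2     3     4 5 6  7
observed 1916.00   19.0 25.0  0.00  0.00 0 0 40
expected 1675.91  300.1 23.1  0.88  0.02 0 0  0
excess    240.09 -281.1  1.9 -0.88 -0.02 0 0 40
tail k >= 6 : observed 40 expected 0  one-sided p = 0.00498
```

The simulated damaged-side mantle shows 40 genes upregulated on all 7
dates where the permutation null expects essentially none — these are
exactly the 40 planted persistent responders (2% of 2000 genes), and
`res$selected` recovers them. The null expectation decays steeply in `k`
(the "gradual random decay" shape); the observed pile-up at `k = 7` is the
damage signature. The tail p of 0.005 is at the resolution limit of 200
permutations.

The origin classifier output carries the evidence per gene:

```r
subset(res$origin, is_non_mantle)[, c("class", "mantle_rpkm",
                                      "best_other_organ", "best_other_rpkm")]
```

```
                             class mantle_rpkm best_other_organ best_other_rpkm
gene00001 non_mantle_non_hemolymph   0.6362136              Gil         19.8002
gene00002               non_mantle   0.7950142              Amu         21.8887
```

Both planted non-mantle genes (floor(0.01 × 200 SMP genes) = 2) are found:
silent in the mantle (RPKM ≪ 5), strongly expressed elsewhere.

For real data, point `run_config(paths = list(...))` at count-table,
manifest, SMP-list and annotation TSVs — formats are documented in
`?read_count_matrix`, `?read_samples_manifest` and `?read_annotation_map` —
or call the stages directly (`compute_rpkm`,
`classify_shell_protein_origin`, `call_de`, `count_recurrence`,
`null_recurrence`, `excess_statistic`, `select_persistent_genes`,
`hypergeom_enrich`). A thin subcommand CLI over the same functions ships in
`inst/cli/shellform.R`.

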