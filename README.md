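# avoidr

Scoring and inference for *Caenorhabditis elegans* chemosensory
avoidance experiments — the behavioral paradigm in which worms detect and
escape repellent bacterial secretions (e.g. *Streptomyces*-produced
dodecanoic acid) through their head (amphid) and tail (phasmid)
chemosensory neurons — together with the two supporting measurement
pipelines such studies rely on: GCaMP calcium imaging of sensory neurons,
and extracted-ion-chromatogram (EIC) quantification of secreted fatty
acids by LC-MS. A synthetic-data generator emulates every input modality,
so the whole analysis is testable end to end without any external data.

It is intended for researchers quantifying nematode avoidance behavior who
want the standard scoring conventions and the accompanying statistics in
one reproducible, pipe-friendly toolkit.

## What it computes

**Behavioral scoring.** Tail (phasmid) dry-drop assays record the time *T*
an animal backs into a dried repellent drop before halting. The wild-type
relative response index normalizes to the same-day 0.6 mM SDS positive
control:

    RI_wt = 100 · mean(T_treatment) / mean(T_SDS)

so SDS itself scores 100% and faster halting gives a lower index. For
mutants whose baseline backing differs from wild type, the double-ratio
form is used:

    RI_mut = 100 · [mean(T_treatment,mut) / mean(T_buffer,mut)] /
                   [mean(T_SDS,wt) / mean(T_buffer,wt)]

Head (amphid) assays score a binary halt/no-halt response, summarized as a
proportion; chemotaxis plates are scored as
CI = (#experimental − #control) / #total ∈ [−1, 1].

**Inference.** Pooled two-proportion z-tests (head assays), one-way ANOVA
with Tukey HSD or pooled t-tests with Hochberg step-up adjustment (tail
assays), Cohen's d and arcsine-h effect sizes, and power-based sample-size
calculations (noncentral-t for means; the arcsine normal approximation for
proportions). `run_figure_analysis()` executes a declarative plan of
comparison families and assigns `***`/`**`/`*`/`ns` codes at
0.001/0.01/0.05 from the family-adjusted p-values.

**Calcium imaging.** ΔF/F₀ percent change against the intensity at the
15 s pre-stimulus timepoint, pointwise subtraction of the mean
buffer-control time series, trapezoidal area under the curve over the
15–75 s stimulus window per worm, group mean ± SEM traces, and a
two-sample t-test on AUC between genotypes.

**Mass spectrometry.** Monoisotopic m/z from elemental formulas (electron
mass included for ions), EIC extraction from centroided runs within a
±100 ppm window (closed bounds, one point per scan), trapezoidal peak
integration over an explicit retention-time window with optional linear
baseline, and sample/control relative abundance with a detection floor.

## Worked example

```r
library(avoidr)

# power calculations used when planning assay group sizes
sample_size_t(d = 0.8, alpha = 0.05, power = 0.8)
#>   n_per_group power_achieved     d alpha power_target sides
#> 1          26          0.807   0.8  0.05          0.8     2
sample_size_two_prop(0.3, 0.8)
#>       h n_per_group   p1    p2 alpha power_target
#> 1  1.06          14  0.3   0.8  0.05          0.8

# fully simulated study: behavior + calcium + LC-MS, analyzed end to end
res <- run_demo("demo_out", seed = 42)
res$response_indices[, c("group", "index_percent")]
#>   group                  index_percent
#> 1 wildtype S.avermitilis          105.
#> 2 wildtype dodecanoate            130.
#> 3 srb-6 dodecanoate               409.
```

The indices say: wild-type worms halt into *S. avermitilis* supernatant
about as fast as into the SDS positive control (≈105%), while the
chemoreceptor-null *srb-6* mutant backs ~4× longer into dodecanoate
(409%) — a strong avoidance defect. The planned test families agree:

```r
res$figure_analysis[, c("family", "comparison", "statistic", "p_adjusted", "signif")]
#>   family        comparison                                statistic p_adjusted signif
#> 1 head_srb6     srb-6:dodecanoate vs wildtype:dodecanoate     -3.62   2.96e- 4 ***
#> 2 head_wildtype wildtype:S.avermitilis vs wildtype:buffer      6.04   3.10e- 9 ***
#> ...
res$auc_test          # wild-type vs srb-6 stimulus-window calcium AUC: t = 36.4, p < 1e-24
res$ms_abundance      # dodecanoate [M+H]+ peak ~200x above the control run
```

Every table is also written as CSV under `demo_out/`, and the same seed
reproduces the run byte for byte. A thin command-line wrapper is installed
as `exec/avoidr` (`avoidr demo --out DIR --seed N`, plus `behavior`,
`calcium`, and `eic` subcommands over CSV/YAML/JSON-lines inputs).

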