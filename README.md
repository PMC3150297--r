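# camba

Coverage-aware Bayesian calling of rare induced point mutations — and the
wells that carry them — from deep-sequenced, bi-dimensionally overlapping
DNA pools, as produced by TILLING-by-sequencing reverse-genetics screens.

## The problem

A mutagenized population (EMS or Az-MNU) of 768 individuals is arrayed on a
96-well plate, 8 individuals per well, and pooled twice: 8 row pools and 12
column pools, so each individual's DNA is present in exactly two sequencing
libraries. A real induced mutation elevates the frequency of one base change
in exactly one row pool *and* one column pool, which identifies both the
position and the carrier well. But a single heterozygous mutant is 1 allele
in 192, barely above the sequencing error floor, and coverage varies widely
across libraries — so frequency-only outlier detection breaks down exactly
where deep sequencing is supposed to help.

## The model

At each position with reference base *r*, the caller scores every
*configuration* — the null, or one mutant individual in well *w* with change
*r → m* and zygosity *z* — by Bayes' theorem:

- **Likelihood**: each non-reference count is
  *k*<sub>lm′</sub> ~ Binomial(*n*<sub>l</sub>, *r*<sub>lm′c</sub>) with
  *r*<sub>lm′c</sub> = (1 − *m*<sub>lc</sub>) *e*<sub>m′c</sub> + *m*<sub>lc</sub>,
  where *m*<sub>lc</sub> is the mutant allele fraction (1/(2*i*<sub>l</sub>)
  het, 1/*i*<sub>l</sub> hom, 0 in non-carrier libraries) and
  *e*<sub>m′c</sub> is the error rate pooled over the libraries that cannot
  carry the mutation. Coverage enters the score directly — the model's
  defining feature.
- **Prior**: per-well binomial over *i*<sub>well</sub> individuals at the
  mutagen's per-change rate (*p*<sub>c</sub> for canonical G→A / C→T,
  *p*<sub>nc</sub> otherwise), times the zygosity fraction
  (*t*<sub>het</sub> = 2/3).
- Posteriors are zygosity-collapsed per (well, change), and calls are
  ranked by the log-odds score *F*(*t*) = ln(*t*/(1 − *t*)).

Around the model sit the published preprocessing filters (per-library
quality cutoff, a 10,000 expected-coverage gate, Fisher-exact
strand-orientation vetoes, mutant-exceeds-reference vetoes), the
expected-mutation × 1.55 prediction budget and split-pool empirical FP
procedure, a z-score Outlier comparator, scaled confusion-matrix
evaluation, and a full synthetic pooled-experiment simulator. See the
methods vignette (`vignettes/camba-methods.Rmd`) for the details and the
design decisions.

## Worked example

Simulate a rice-like screen with 4 planted mutations, call, and check
recovery:

```r
library(camba)
set.seed(11)
design <- build_design(8, 12, 8)
params <- experiment_params(p_c = 5.6e-6, p_nc = 4.93e-7)
refs   <- setNames(random_reference(300, gc = 0.44), "gene1")
spec   <- simulation_spec(design, refs, params, error_rate = 1e-3, coverage = 100)
truth  <- plant_mutations(spec, n_fixed = 4)
pos    <- generate_counts(spec, truth)
res    <- camba_call(pos, design, params, n_predictions = 4)
res$calls
#>   seqid pos ref alt row_library column_library    well t   F rank
#> 1 gene1  44   G   A          R8             C8 (R8,C8) 1 700    1
#> 2 gene1 194   C   T          R5             C2 (R5,C2) 1 700    2
#> 3 gene1 282   C   T          R1             C9 (R1,C9) 1 700    3
#> 4 gene1 299   G   A          R7             C7 (R7,C7) 1 700    4
match_calls(res$calls, truth)
#> [1] 4
```

All four planted mutations are recovered with their carrier wells; the
posterior *t* saturates at 1 at this coverage (100× per individual), so
*F*(*t*) sits at its clamp of 700.

The evaluation arithmetic converts a prediction list plus a confirmed
subset into the scaled confusion matrix; for the wheat screen's 107
predictions with 36 of 39 confirmed mutations recovered over 4,670
positions:

```r
scaled_confusion(107, 36, 39, 107, 4670)
#> $TP 99  $FP 8  $FN 8  $sensitivity 92.52  $specificity 99.82
```

i.e. estimated sensitivity 92.52% and specificity 99.82%.

A command-line front end wrapping the same functions is installed as
`inst/scripts/camba.R`, with subcommands `simulate`, `call`, `outlier`,
`threshold` and `evaluate`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/camba.R", package = "camba"))')" \
    simulate --config config.json --out-dir sim --seed 7
```

## Acceptance script

`scripts/acceptance.R` runs the complete pipeline from scratch — builds the
8 × 12 × 8 design, simulates a rice-like experiment with planted mutations,
runs preprocessing, the Bayesian caller and call selection, and matches the
calls against the simulated truth — then writes a JSON summary:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

All randomness derives from `--seed`; the run log reports positions,
planted and recovered mutation counts.
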