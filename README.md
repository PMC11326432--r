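# toothpos

Comparative phylogenetic analysis of **tooth morphological complexity** and
the **anteroposterior position of the dentition** in the cranium, built for
fossil taxa on non-ultrametric, time-scaled trees. The motivating question is
whether more complex (multicuspid) teeth are associated with a more posterior
tooth-eruption position in the upper jaw — as morphogenetic field theory
predicts — across the amniote lineages on the stem of mammals.

The package provides every stage of that analysis as tested, reusable
functions:

- **Tree handling** (`parse_trees`, `consensus_with_lengths`, `prune_tree`,
  `graft_tip`): rooted Newick/NEXUS I/O, majority-rule consensus *with branch
  lengths* (each retained clade's edge length is the mean over the trees
  containing it), distance-preserving pruning, and age-based grafting of a
  tip onto an edge.
- **Landmark geometry** (`read_tps`, `project_to_midline`, `compute_lengths`):
  ten 2-D cranial landmarks per specimen are projected perpendicularly onto
  the midline (anterior end of the premaxilla → basion); paired left/right
  positions are averaged, calibrated to mm (digitized scale, or published
  skull length as a proxy), and natural-logged into five lengths: to the
  posterior end of the dentition, the anterior and posterior ends of the
  palatine, the posterior end of the maxilla, and the cranial length.
- **Complexity scoring** (`classify_tooth`, `score_taxon`): a deterministic
  five-level ordinal rubric — 1: one cusp; 2: two or three cusps in a
  mesio-distal row; 3: more than three cusps in a row; 4: more than two cusps
  with one deviated from the row by more than a cusp width (triangular
  arrangement); 5: cusp rows on both lingual and buccal sides. Lateral-only
  views are capped at level 3; a taxon scores the maximum over its teeth.
- **PGLS with Pagel's λ** (`fit_lambda_ml`, `position_residuals`,
  `correlation_model`): generalized least squares with error covariance
  σ²·C(λ), where C holds shared root-to-tip path lengths and λ ∈ [0, 1]
  multiplies its off-diagonal entries (well defined for fossil tips); λ is
  estimated by maximum likelihood. Dentition position is quantified as the
  residual of `ln(length to post-dentition) ~ ln(reference length)`, and the
  complexity–position test fits
  `ln(post-dentition) ~ complexity + ln(reference)` for each of the four
  reference lengths.
- **Parsimony ancestral states** (`sankoff_ordered`, `enumerate_mprs`,
  `count_acquisitions`, `squared_change_asr`): ordered-character Sankoff
  reconstruction with step cost |i − j|, exhaustive enumeration of
  most-parsimonious reconstructions, per-branch classification of
  unambiguous/possible gains and losses of each level, and (weighted)
  squared-change parsimony for the continuous position characters.
- **Synthetic data** (`synthesize_study`, `simulate_tree`, `simulate_bm`,
  `simulate_ordered_walk`, `emit_landmarks`): generates fossil trees,
  λ-structured log-length variables, an ordered five-state complexity
  character, and landmark sheets, so every stage is exercisable without the
  original study's raw data.
- **Pipeline** (`run_study`): consensus → prune/graft → residuals → ASR →
  the four correlation models, written out as a regression table (blocks
  (a)–(d)), residual tables, annotated trees and a JSON manifest.

## Worked example

```r
library(toothpos)

study <- synthesize_study(study_config(n_taxa = 60, seed = 42))
fit <- correlation_model(study$records, "cranial", study$tree)
print(fit)
#> Phylogenetic GLS fit (n = 60 )
#>   Pagel's lambda (ML): 0.5867
#>   sigma2 (ML): 0.007482   logLik: 74.9195
#>
#>         term estimate      se      t         p
#>  (Intercept) -1.14136 0.31829 -3.586 6.975e-04
#>   complexity  0.06496 0.01178  5.514 8.869e-07
#>  len_cranial  1.04462 0.06593 15.844 1.521e-22
```

The `complexity` row is the quantity of interest: here each extra complexity
level is associated with a 0.065 increase in log length to post-dentition
(≈ 6.7% more posterior dentition) after controlling for cranial length and
phylogeny — close to the generating effect of 0.07 — with λ̂ ≈ 0.59
indicating substantial but incomplete phylogenetic signal in the residuals.

```r
asr <- sankoff_ordered(study$tree,
                       setNames(study$records$complexity, study$records$taxon))
print(asr)
#> Ordered-parsimony ancestral-state reconstruction
#>   states: 1..5   tips: 60
#>   minimum total cost: 18 steps
#>   branches with ambiguous change: 4
count_acquisitions(asr, level = 4)
#> $unambiguous_count
#> [1] 3
#> $possible_count
#> [1] 6
#> $loss_unambiguous
#> [1] 0
#> $loss_possible
#> [1] 1
```

So triangular-or-better teeth (level ≥ 4) arise unambiguously three times on
this simulated tree (up to six times in some equally parsimonious
reconstruction), with at most one loss.

## Acceptance script

`scripts/acceptance.R` regenerates a full synthetic study from the given
seed, runs the entire pipeline (consensus handling, residual quantification
for all four references, ordered and continuous ancestral-state
reconstruction, and the four PGLS correlation models) against the installed
package, prints the per-model λ̂ and parsimony cost, and writes its JSON
report:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

## Documentation

The methods vignette (`vignettes/tooth-complexity-dentition-position.Rmd`)
describes the model and its assumptions, the synthetic world the generator
emulates, numerical choices, and known limitations.
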