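---
title: "Tooth complexity and dentition position: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tooth complexity and dentition position: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(toothpos)
```

## The scientific problem

Mammalian molars are complex, multicuspid teeth; the extinct amniote
lineages on the mammalian stem span everything from single-cusped pegs to
molar-like crowns. Developmental work links tooth form to morphogen
gradients (e.g. BMP4 anteriorly, FGF8 posteriorly) laid out along the
anteroposterior axis of the jaw, which suggests a simple macroevolutionary
prediction: lineages whose tooth row sits further back relative to those
morphogenetic fields should evolve more complex teeth, and lineages whose
dentition shifts forward should simplify. Testing this on fossils requires
four ingredients, each of which is a module here:

1. a **quantification of dentition position** from published cranium
   illustrations (landmark geometry),
2. an **ordinal scale of tooth complexity** applicable to any cusp
   arrangement (the five-level rubric),
3. a **phylogenetic regression** that respects shared ancestry on a
   time-scaled fossil tree (PGLS with Pagel's λ), and
4. **ancestral-state reconstruction** to read the history of gains and
   losses off the tree (ordered parsimony for the discrete character,
   squared-change parsimony for the continuous positions).

## Measurement model

Ten 2-D landmarks are digitized on a ventral-view cranium: (1) the anterior
end of the premaxilla and (2) the basion define the **midline**; pairs
(3,4), (5,6), (7,8), (9,10) mark the posterior end of the dentition and the
anterior palatine, posterior palatine and posterior maxilla ends on the two
sides of the skull. Each landmark's axial position is the foot of its
perpendicular on the midline, as a signed distance from landmark 1; this is
computed as the scalar projection of $L_k - L_1$ onto the unit vector
$\widehat{L_2 - L_1}$, which is algebraically identical to intersecting the
perpendicular with the midline (the test suite checks both routes agree to
$10^{-9}$ and that the positions are invariant under rigid motions).

Paired positions are averaged across sides, converted to mm, and
natural-logged. When an illustration carries no scale bar, the taxon's
published skull length is used as a proxy: mm-per-unit = skull length ÷
illustration-unit distance $|L_1 L_2|$. Averaging before or after scaling is
mathematically indistinguishable under a shared scale factor; we average
axial positions first, for deterministic rounding. Two choices were
genuinely open and are resolved as follows:

* **"Posterior end of the cranium"** is taken to be the basion (landmark 2),
  the only posterior midline landmark in the scheme.
* **Negative pre-log lengths** (a landmark projecting anterior to landmark
  1) are rejected as digitization errors rather than clamped.

The posterior end of the maxilla cannot be located in some published
illustrations, so pair (9,10) may be absent; the post-maxilla length is then
an explicit `NA`, and only post-maxilla models drop those taxa (listwise).

## The complexity rubric

Five ordered levels, from cusp count and arrangement: one cusp (1); two or
three cusps in a mesio-distal row (2); more than three cusps in a row,
including along a cingulum (3); more than two cusps with at least one
deviated from the cusp row (triangular arrangement, 4); cusp rows on both
the lingual and the buccal side (5). Two operational decisions:

* "Deviated **beyond** the cusp width" is a strict inequality: a deviation
  of exactly one cusp width reads as still in the row. Level 4 also requires
  *more than two* cusps, so a deviated two-cusp tooth scores 2.
* Teeth known only from **lateral view** cannot show deviation or a second
  cusp row, so they are assumed linear and capped at level 3.

A taxon's level is the maximum over its scored teeth. Treating the five
levels as equally spaced — both as the numeric covariate in the regressions
and as the |i − j| step cost in parsimony — is the model's central ordinal
assumption; it is an assumption, not an estimate.

## Consensus trees with branch lengths

Published time-scaled topologies come as a set of trees. The rooted
majority-rule consensus retains every clade whose frequency strictly
exceeds the threshold (default 0.5); a retained edge's length is the
arithmetic mean of that edge's length **over the trees containing the
clade** (not over all trees), and unsupported edges collapse into
polytomies. Averaging over supporting trees matches the documented behavior
of the consensus-edges approach used in this literature; averaging over all
trees is the main alternative and would shrink weakly supported edges
toward zero. Any two retained clades co-occur in at least one input tree
(each is in more than half), so the retained set is always compatible and
the consensus is well defined.

Tips can be grafted onto the consensus at a stated divergence age: the
attachment edge is split at that age (time before present, with the present
defined by the deepest tip) and the new tip hangs from the split at its own
age, leaving all pre-existing node ages untouched.

## PGLS with Pagel's λ

For response $y$ (log length to post-dentition) and design $X$ the model is
$y = X\beta + \varepsilon$, $\varepsilon \sim N(0, \sigma^2 C(\lambda))$,
where $C_{ij}$ is the depth of the MRCA of taxa $i,j$ from the root and
$C(\lambda)$ multiplies the **off-diagonal** entries by λ, leaving the
diagonal (root-to-tip depths) untouched. On ultrametric trees this is the
classical λ transform; on fossil trees, where branch-rescaling variants
disagree, the covariance form stays well defined — which is why it is the
package's choice. Estimation details:

* **ML, not REML**, for both λ and σ², matching the default of the software
  this style of analysis is usually run in. Exact third-decimal agreement
  with published tables can hinge on this choice and on the λ-transform
  variant, so both are recorded in the run manifest.
* Standard errors scale $(X'C^{-1}X)^{-1}$ by $\hat\sigma^2\, n/(n-p)$, the
  small-sample correction that makes the identity-covariance case reproduce
  textbook OLS output exactly; p values are two-sided from $t_{n-p}$.
* λ is profiled over $[0,1]$ with bounded scalar optimization (tolerance
  $10^{-6}$); both endpoints are evaluated explicitly and ties are broken
  toward the interior. The tests check the returned λ̂ dominates a dense
  101-point grid.
* Zero-length internal edges are collapsed into polytomies before analysis,
  so $C$ stays positive definite; a singular $C$ or a collinear design is a
  hard error naming the cause.

Dentition position for the ancestral-state maps is the **response residual**
$y - X\hat\beta$ of the position-on-reference regression (larger = more
posterior). For the hypothesis test itself, complexity enters as a covariate
alongside the reference length — controlling by multiple regression rather
than regressing residuals on complexity, which is the statistically sound
version of the same comparison.

## Parsimony ancestral states

**Ordered (Sankoff) reconstruction.** Bottom-up dynamic programming with
cost |i − j| per step over states 1..5, polytomies treated as hard
(simultaneous divergence). The top-down pass computes each node's **MPR
set** — the states it takes in at least one most-parsimonious
reconstruction. Because the cost decomposes over children given a parent
state, the feasible parent/child state pairs of a branch are exactly the
pairs realized in some MPR; gains of a level ("state crosses the threshold
upward on this branch") are counted as *unambiguous* (in every MPR) or
*possible* (in some MPR) from those pairs, mirroring the
closed-circle/open-triangle distinction used when such histories are drawn.
Exhaustive MPR enumeration (deterministic depth-first order, default cap
10,000) backs this up and is cross-checked against the pair analysis and
against brute-force enumeration over all internal assignments in the tests.

**Continuous characters.** Squared-change parsimony minimizes
$\sum_e (x_{parent(e)} - x_{child(e)})^2 / w_e$; the default weights
$w_e$ = branch length make the optimum identical to Brownian-motion ML
ancestral states (checked to $10^{-8}$ against an independent GLS-based
computation), while `weighted = FALSE` gives the unweighted variant offered
by desktop parsimony programs. The choice is surfaced in the output
metadata because the original desktop implementations differ and published
node values may depend on it. The optimum solves the sparse
first-order-optimality system in which every internal value is the
weighted mean of its neighbours.

## The synthetic world

`synthesize_study()` generates the world the estimators assume, with
defaults stating the study-scale conditions rather than tunable knobs:

| parameter | default | why |
|---|---|---|
| `n_taxa` | 60 | the study's sample size |
| tree | pure-birth, fossil-truncated tips, unit height | non-ultrametric like a fossil supertree |
| `lambda_true` | 0.8 | mid-range of the reported per-model λ̂ (0.53–0.92) |
| `sigma2_true` | 0.01 | residual sd 0.1 on the natural-log scale, the scale at which reported coefficient SEs (~0.03) arise at n = 60 |
| `beta_complexity` | 0.07 | the reported complexity effect (log-mm per level) |
| `slope_reference` | 1.0 | isometry of jaw lengths on cranial length |
| `intercept` | −0.9 | post-dentition ≈ 40% of cranial length |
| `complexity_step_rate` | 3 /unit height | a handful of state changes per root-to-tip path, giving levels 1–5 coverage |
| `fraction_missing_post_maxilla` | 2/60 | the study's two taxa with unidentifiable post-maxilla |

Cranial length is Brownian (root ln 150 mm, rate 0.05); the three jaw
references are anatomical offsets from it (ln 0.4, 0.7, 0.8 of cranial)
plus small Brownian noise; complexity is a reflected ±1 random walk on 1..5
(root state 1, Poisson events along branches); and the response follows the
fitted model family exactly, with λ-attenuated Brownian residuals drawn
through the Cholesky square root of $\sigma^2 C(\lambda)$. Generator and
estimator share the likelihood family deliberately: parameter-recovery and
type-I-error tests are then fair tests of the estimator, not of model
misspecification. What the generator does **not** emulate — and what a
green test therefore does not establish — includes fossilized-birth-death
sampling, correlated digitization error across landmarks, morphological
integration among the length variables, state-dependent diversification,
and any real-data violation of the equal-spacing assumption on complexity
levels.

An inverse emitter (`emit_landmarks()`) places landmark sheets consistent
with a measurement table (plus arbitrary rigid motion and illustration
scale), so the geometry stage can be exercised end-to-end from synthetic
data too.

## Numerical and interface choices

* Tree text is written with 17 significant digits and measurement CSVs with
  full (`%.17g`) precision, so write → read round trips are exact and
  re-running a stage from its intermediate files is byte-identical.
* In the unanimous-consensus case, mean edge lengths short-circuit to the
  common value, avoiding the one-ulp drift of `sum/n`.
* The λ optimizer's non-convergence is not observed in practice (the
  profile is smooth on [0,1]); the grid-domination test guards the
  optimizer.
* This package is used from R; the exported functions plus `run_study()`
  are the interface, and `scripts/acceptance.R` is the only shell entry
  point.

## Limitations

* The rubric consumes structured cusp descriptors; identifying cusps in
  published figures remains expert work upstream of the package.
* Ordinal complexity as an equally spaced numeric covariate is a modeling
  convention inherited from the analysis being reproduced; a
  threshold/latent-liability model would be the principled alternative.
* ML λ̂ at n ≈ 60 is usable but noisy (the recovery tests bound only the
  mean across replicates within ±0.1); per-dataset λ̂ should be read with
  that in mind.
* No measurement-error model: digitization noise is absorbed into the
  residual term.
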