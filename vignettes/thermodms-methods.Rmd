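---
title: "Thermodynamic models for combinatorial deep mutational scanning: methods and design choices"
author: "thermodms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Thermodynamic models for combinatorial DMS: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermodms)
```

## The biophysical model

`thermodms` treats a variant fitness measurement as a noisy, affinely
scaled readout of a Boltzmann state probability. Protein folding is a
two-state equilibrium between unfolded (u) and folded (f) states; ligand
binding adds a folded-and-bound (fb) state (the unfolded-and-bound state
is assumed to have negligible occupancy):

$$p_f = \frac{K_f}{1 + K_f}, \qquad
  p_{fb} = \frac{K_f K_b c}{1 + K_f + K_f K_b c},$$

with $K_f = e^{-\Delta G_f / RT}$, $K_b = e^{-\Delta G_b / RT}$,
$T = 303\,\mathrm{K}$ and $R = 0.001987$ kcal K$^{-1}$ mol$^{-1}$
($RT \approx 0.602$ kcal/mol). The ligand concentration $c$ is
dimensionless, fixed to 1 by default, and therefore absorbed into
$\Delta G_b$; it is exposed as a model constant for completeness.

Free energies are additive over a variant's substitutions. For the binary
genotype $x \in \{0,1\}^K$ over a library's $K$ substitutions,

$$\Delta G = \Delta G_{wt} + \sum_i x_i\,\Delta\Delta G_i
           + \sum_{i<j} x_i x_j\,\Delta\Delta\Delta G_{ij},$$

where the second-order terms (pairwise energetic couplings) are present
only in `maxInteractionOrder = 2` models. Third-order energy terms are
deliberately not implemented; third-order interactions exist only in the
linear baseline (`fitLinearBaseline`), where they quantify how much
complexity a phenotype-additive model needs to imitate the thermodynamic
nonlinearity. Each phenotype — `abundance` reading out $p_f$, `binding`
reading out $p_{fb}$ — has a two-parameter affine transform
$\hat y = a + b\,p$ mapping the probability to assay fitness units.

Internally all energies are dimensionless parameters $\theta$ with
$\Delta G = \theta RT$; reported models are always in kcal/mol.

## Fitting protocol

The loss is a precision-weighted, lightly regularized mean absolute
error,

$$\mathcal{L} = \frac{1}{N}\sum_n \frac{|y_n - \hat y_n|}{\sigma_n}
  + \lambda_2 \lVert\theta\rVert^2,$$

with $\lambda_2 = 10^{-6}$, so poorly measured variants are down-weighted
and very large energies are mildly discouraged. Optimization uses Adam
(initial learning rate 0.05 by default; 0.005 is the conservative choice
for very large libraries) for at most 1000 epochs over mini-batches of the
training variants. The protocol around it:

* **Splits.** A random 30% of variants is held out — 20% validation, 10%
  test — with the wild type always kept in training. Validation data
  drive hyperparameter selection and the learning-rate schedule; test
  data are used exactly once, for the reported held-out $R^2$.
* **Batch size** is the tuned hyperparameter: each candidate in
  `batchSizeGrid` (default 512/1024/2048) is trained for 100 epochs from
  the same initialization and the smallest validation loss wins. A
  length-one grid skips tuning.
* **Measurement-error propagation.** Training fitness values are replaced
  by one random draw from each variant's error distribution, taken as
  Gaussian with the variant's standard error (the error distribution's
  family is an assumption; only location and scale are reported
  upstream). Validation and test data are never perturbed.
* **Learning-rate decay.** When the mean validation loss over the most
  recent ten epochs fails to improve on the preceding ten, the rate is
  multiplied by $\gamma = 0.98$.
* **Early stopping.** Training ends once the wild-type free energies are
  stable — standard deviation at most $10^{-3}$ kcal/mol over the last
  ten epochs.

Two choices the protocol leaves open are made as follows and matter in
practice:

* **Initialization** is a two-stage warm start. First, the affine
  transform is anchored at the 1%/99% training-fitness quantiles and
  per-variant energies are obtained by inverting the logistic link
  ($\theta \approx -\mathrm{logit}\,\hat p$) and regressing on the
  genotype matrix, weighting each variant by $p(1-p)$ and excluding
  plateau variants whose inverted energy is censored rather than
  measured. Second, a deterministic BFGS minimization of the
  precision-weighted squared error polishes this start. Without the warm
  start, stochastic optimization of the non-convex landscape reliably
  finds a local optimum in which the affine slope inflates and the
  wild-type energy shallows while couplings absorb the residual warp —
  predictions are almost as good, parameters are not.
* **Parameter readout.** The returned estimate is the average of the
  parameter vector over the final ten epochs — the same window the
  stopping rule monitors — which removes the jitter a sign-based
  (absolute-error) gradient leaves around the optimum.

### Gauge fixing

The two-state logistic has an exact discrete symmetry: negating all
folding energies while mapping $(a, b) \mapsto (a + b, -b)$ leaves every
prediction unchanged. No constraint is imposed during optimization;
reported abundance-only models are canonicalized afterwards so that
$b > 0$ (more folded = fitter), making recovered parameters comparable to
a simulator's ground truth without gauge drift. The three-state
likelihood breaks the symmetry, so joint abundance+binding fits are
returned as estimated. Whether this matches the sign convention of any
particular prior analysis is documented, not asserted.

### Uncertainty

`monteCarloUncertainty()` refits the model ten times (configurable), each
refit drawing an independent train/validation/test split and an
independent resample of the training fitness values. Per coefficient it
reports the across-refit mean, standard deviation and 2.5/97.5 percentile
interval; couplings with intervals narrower than 1 kcal/mol are flagged
`confident`. Failed refits are tolerated up to two; beyond that the
estimate is refused rather than silently degraded.

## The synthetic-data generator

`truthSpec()`/`generateTruth()`/`simulateMeasurements()` generate data
with the statistical structure the analysis assumes: first-order folding
effects drawn from a destabilization-biased normal distribution (default
$\mathcal{N}(+1, 1)$ kcal/mol), pairwise couplings zero-centred and sparse
(default $\mathcal{N}(0, 0.25)$, 25% of pairs nonzero), binding effects
milder ($\mathcal{N}(+0.5, 0.5)$), wild type at $\Delta G_{f,wt} = -2$ and
$\Delta G_{b,wt} = -1$ kcal/mol, and identity affine transforms. These
defaults are calibrated to the qualitative picture of real single-domain
stability data — single-substitution effects strong and biased towards
destabilization, couplings an order of magnitude milder and centred on
zero — not to any particular fitted values.

Replicate noise is i.i.d. Gaussian per measurement with
$\sigma_v = \sigma_0 + \sigma_1(0.5 - |p - 0.5|)$: a floor plus an
optional heteroscedastic bump mid-range, where a bounded growth assay is
least certain. The shape is an assumption; $\sigma_1 = 0$ gives the
constant-noise mode used by oracle tests. Aggregate fitness is the
replicate mean with standard error $\sigma_v / \sqrt{R}$.

Two deliberate regimes are used in the package's own experiments:

* **Random-mutagenesis decay** (`foldedFractionByOrder`) uses the default
  $\mathcal{N}(+1,1)$ effects: summing five random such substitutions
  onto a $-2$ kcal/mol wild type leaves only a few percent of variants
  folded, and essentially none at ten — the regime that makes random
  combinatorial sampling uninformative.
* **Library-like recovery experiments** use mild effects
  ($\mathcal{N}(+0.4, 0.4)$, or $\mathcal{N}(+1, 0.5)$ where a strongly
  asymmetric nonlinearity is wanted). This mirrors how real combinatorial
  libraries are designed: substitutions are chosen mild so that
  high-order variants remain in the measurable transition region. The
  distinction is not cosmetic. A coupling between two strongly
  destabilizing substitutions is present only in variants that are
  already fully unfolded, where the readout carries no gradient — the
  coefficient is unidentifiable from the data, and no optimizer can
  recover it. Parameter-recovery claims are therefore made in the regime
  where the experiment design itself guarantees identifiability.

When a measurement budget exceeds the size of the genotype space (e.g.
20,000 measurements over a $2^{10}$ space), `sampleGenotypeLibrary(...,
replace = TRUE)` draws a multiset and `simulateMeasurements` collapses
duplicates: a genotype drawn $m$ times receives $mR$ replicate draws and a
$\sqrt{m}$-smaller standard error. Genotype bits are drawn directly
(each bit uniform) rather than by indexing the space with one random
number, which would exceed the RNG's integer resolution for $K > 31$ and
bias the low bits.

What the simulations do *not* emulate: read counting and sequencing
error, selection dynamics, replicate-specific scale differences,
non-Gaussian error tails, and any correlation between a substitution's
effect and its measurement error. Passing recovery tests on simulated
data therefore demonstrates correctness of the inference machinery under
the stated model, not robustness to real-data pathologies upstream of the
fitness table.

## Greedy library design

Candidates are first filtered to substitutions with confident energies
(95% CI < 1 kcal/mol on every trait in use), measured in at least 20
genetic backgrounds, and reachable by a single-nucleotide change in the
wild-type coding sequence. From each possible starting substitution the
algorithm iteratively adds, among candidates at not-yet-mutated
positions, the one maximizing the objective of the cumulative mutant: the
geometric mean of predicted growth rates over the declared phenotypes
(a single phenotype reduces to that growth rate). Growth rates are
clamped at $10^{-6}$ before the geometric mean — they are non-negative by
construction, and the clamp only guards exact zeros. Ties break
deterministically: lowest position, then alphabetical mutant amino acid.

Candidate libraries are scored by simulating the median predicted growth
rates of 10,000 uniformly sampled members (exhaustive below that size); a
library is *viable* when the geometric mean of its median growth rates is
at least 70% of the maximal value. "Maximal value" is interpreted as the
wild-type (size-0) geometric mean; the alternative reading — the maximum
over candidate libraries — is available via `maximal = "max"`. The
selected design is the largest viable size over all starts. Greedy search
carries no optimality guarantee; on instances small enough for exhaustive
subset search the gap to the true optimum is measured in the test suite
and is small but real.

The window-constrained design style is supported as a filter
(`windowDesignFilter`): positions with mild effects (within a fitness
band of the wild type), nucleotide-reachable, and outside the binding
interface (ligand distance < 5 Å) are counted in sliding windows of 20,
21 and 22 residues. Surface-saturation designs are supported only through
the contact-map and RSASA filters; automated clustering of the contact
map is out of scope.

## Structural analysis of couplings

Inter-residue distance is the minimal side-chain heavy-atom distance;
glycine has no side-chain heavy atoms and falls back to its C$\alpha$,
flagged in the output. Structures are read with `bio3d`; residue
numbering is mapped to domain-local 1-based positions via an explicit
offset, never guessed. Contacts use an 8 Å threshold; "long-range" means
backbone separation $|i-j| > 5$ residues (index difference, not inclusive
counting).

The 12-feature linear model of coupling strength $|\Delta\Delta\Delta
G_f|$ uses five pair-geometry features (backbone distance, 3D side-chain
distance, counts of core residues with RSASA < 0.25, of binding-interface
residues with ligand distance < 5 Å, and of beta-strand residues) and
seven chemical-bond counts consumed from a GetContacts-style table
(backbone–backbone, side chain–backbone and side chain–side chain
hydrogen bonds; pi–cation; pi-stacking; salt bridges; van der Waals).
Bond counts are taken literally from the table — a contact listed twice
counts twice — and unknown interaction labels are dropped with a warning.
Features are z-scored before ordinary least squares, because the model's
purpose is ranking features by significance, which must not depend on
units; per-coefficient two-sided t-test p-values are reported uncorrected.
Evaluation on held-out couplings refuses any train/test pair overlap.
Spearman statistics are unweighted (confidence weighting of couplings is
a possible refinement, not implemented). RSASA and secondary structure
are inputs; computing them is out of scope.

## Problem sizes and numerical choices

The package's experiments and checks run at these scales, chosen so the
full cycle is convenient on a single core:

* Parameter recovery: $K = 10$, a 20,000-measurement multiset over the
  1024-genotype space, order-2 truth with 25% nonzero couplings,
  replicate noise 0.1 fitness units.
* Model-family comparison: $K = 14$, 10,000 distinct variants, order-1
  truth; residual-versus-order correlations are evaluated on the held-out
  30% because OLS training residuals are orthogonal to mutant order by
  construction.
* Uncertainty behaviour: $K = 6$ exhaustive, ten refits at three noise
  levels.
* Calibration: 200 null regressions of 100 pairs each.

Degenerate inputs are rejected rather than repaired: non-positive
measurement errors, duplicate genotype rows, identity substitutions,
binding data without abundance data (the three-state model is a joint
fit), more parameters than variants, fewer than ten variants to split,
and classification requires an identifiable wild-type row. Probability
computations use saturation-safe forms (log-sum-exp style) so extreme
energies saturate instead of overflowing. Ties at a classification
threshold of 0.5 classify negative (strict inequality). All randomness
flows through stage seeds derived deterministically from one global seed,
and every fit is bit-reproducible given its configuration.

## Known limitations

Energy models are limited to pairwise couplings; genuinely higher-order
energetic interactions would be absorbed into pairwise terms or
residuals. The affine transform is shared across replicates of a
phenotype (per-replicate transforms would need replicate-resolved input).
The unfolded-and-bound state is assumed unpopulated, which fails for
ligands that bind unfolded chains. Identifiability degrades at the
plateaus: wild-type energies of very stable proteins and couplings
between strongly destabilizing substitutions carry wide intervals, which
the Monte Carlo machinery reports rather than hides.
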