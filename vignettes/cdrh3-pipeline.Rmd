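---
title: "Methods: CDR-H3 repertoire analysis, tight-binding kinetics, and synthetic ground truth"
author: "cdrh3kit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CDR-H3 repertoire analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdrh3kit)
```

This vignette is the package's own account of the methods it
implements: the models and their assumptions, the parameters that
matter, what the synthetic-data generator does and does not emulate,
and the numerical choices made where the design was genuinely open.

## 1. The analysis problem

Directed-evolution campaigns against metalloproteinases select scFv
antibodies from yeast-displayed libraries by FACS, producing a
*positive* (binder) and a *negative* (expressed non-binder) population.
Amplicon NGS of the heavy-chain variable gene then asks two questions:
which CDR-H3 loop lengths and which residues distinguish binders from
non-binders? Separately, a purified candidate is characterized in a
fluorogenic inhibition assay to measure its equilibrium inhibition
constant $K_i$. The package implements both analyses plus a simulator
that generates inputs with planted, recoverable truths.

## 2. CDR-H3 extraction

Reads are translated in all six frames (standard genetic code, trailing
partial codons dropped, `N`-containing codons to `X`, stops to `*`) and
scanned for the two framework anchors that bound the loop in this
library design: `DTAVYYCAR` upstream and `FDYWGQGTLVTVSS` downstream.
The loop is the substring strictly between the final `R` of the
upstream anchor and the initial `F` of the downstream anchor, the
convention that exactly reproduces the published loops of the isolated
SynAb variants (`synab_variants()`).

Design choices, with rationale:

* **Hamming-only anchor matching, leftmost wins.** The anchors are
  framework-invariant, so alignment is unnecessary; mismatch budgets of
  0 (9-mer) and 1 (14-mer) tolerate a single sequencing error on the
  long anchor without admitting spurious matches. Indels are not
  tolerated: an indel inside an amplicon of a protein-coding gene
  breaks the reading frame anyway.
* **Frame ambiguity is fatal, never guessed.** A read is `extracted`
  only if exactly one frame yields a valid loop. A silently wrong-frame
  loop would contaminate enrichment statistics with plausible-looking
  garbage; discarding and logging (`ambiguous_frame`) is cheap at
  amplicon depths. In practice ambiguity is vanishingly rare because a
  second frame would need both anchors by chance.
* **Loop length bounds [1, 25].** The library design varies loop length
  over a much narrower range; 25 is a safety ceiling, not a biological
  claim. Failures are reported as statuses (`no_frame`,
  `internal_stop`, `loop_out_of_bounds`), never silently dropped, so
  stage counts always reconcile.
* **A note on the downstream anchor.** The library's constant
  downstream context is described in places as 12 residues, but the
  literal motif `FDYWGQGTLVTVSS` has 14; the package uses the literal
  string.

Deduplication happens after translation, on amino-acid loops: clones
are unique loop sequences with read counts, sorted by descending count
with lexicographic tie-break so the ordering is total and reproducible.

## 3. Quality filtering

The upstream sequencing step only promises "high-quality reads", so
thresholds are a design choice: mean Phred ≥ 20, no `N` bases, and
length within [72, 600] nt (72 nt = both anchors plus a one-residue
loop; 600 ≈ twice a generous amplicon). All are configurable via
`filter_policy()`. The filter is deliberately mild — the anchor match
downstream is the real specificity filter — and is idempotent, with a
report that partitions every input read by its first failing criterion.

## 4. Repertoire statistics

For a fixed loop length $L$, the positional frequency is

$$F_{AA,p} = \frac{c_{AA,p} + \alpha}{\sum_{AA'} c_{AA',p} + 20\alpha},
\qquad p = 1, \dots, L$$

with $c$ the (count-weighted) residue tally and $\alpha$ a pseudocount
defaulting to 0, which makes $F$ the plain frequency. Enrichment is the
cell-wise ratio $E_{AA,p} = F^{+}_{AA,p} / F^{-}_{AA,p}$; pooled mode
first collapses positions (weighted by their tallies) or whole
libraries into composition vectors. Choices:

* **Count weighting is the default** (`read_weighted`): a clone seen
  1,000 times is 1,000 observations of selection, and downstream
  classifier weighting is also count-based. `unique_clone` mode is
  provided for sensitivity analysis; which convention published
  repertoire figures use is often unstated, so both are first-class.
* **Pseudocount 0 with explicit undefined cells.** Fidelity to the
  ratio definition; cells with $F^{-} = 0$ become `NA` rather than
  `Inf`, and class summaries exclude and count them. $\alpha = 0.5$ is
  available for plotting-friendly matrices.
* **Positions are numbered 1..L from the residue after the upstream
  anchor**, and length-7 loops are the conventional slice for
  positional heatmaps since they dominate binder repertoires here.
* **Mode ties break toward the shorter length**, making the reported
  mode deterministic.

No significance testing is attached to enrichment ratios: at these
depths the multinomial error on common residues is small, and the
biological signal of interest (ratios near 3, or near 0.5) is far
outside it. The tests instead verify recovery of planted ratios within
3-sigma multinomial bands.

## 5. Morrison tight-binding kinetics

For tight binders, free inhibitor differs from total inhibitor, and the
classical $v = v_0/(1 + I/K_i^{app})$ is biased. The package uses
Morrison's closed form

$$v = v_0\left(1 - \frac{(E + I + K_i^{app}) -
\sqrt{(E + I + K_i^{app})^2 - 4EI}}{2E}\right),
\qquad K_i^{app} = K_i\left(1 + \frac{S}{K_m}\right)$$

* **Units.** Inputs carry natural units (nM enzyme/inhibitor, µM
  substrate and $K_m$); everything is converted to pM before the
  quadratic is evaluated. Mixing nM and µM naively puts ~9 orders of
  magnitude inside the discriminant and loses precision exactly where
  tight binding lives (sub-nM).
* **Fitting.** Levenberg–Marquardt (`minpack.lm::nlsLM`) over
  $(K_i, v_0)$ with $K_m$ fixed, box constraints $K_i \in (0, 10^9]$ pM.
  $v_0$ is fitted jointly by default because fixing it is an extra
  assumption the data can test; a `fix_v0` option exists. Starting
  values are deterministic (interpolated IC50 corrected by $E/2$ and
  the substrate factor; $v_0$ from the lowest-inhibitor point), so the
  same data always give the same fit. An estimate at the cap or a
  solver failure is reported as `converged = FALSE` with a warning,
  never as a silent number.
* **Initial velocities.** The default policy fits a least-squares slope
  over the first 10 points of a trace. The alternative `best_linear`
  policy (longest prefix with $R^2 \ge 0.99$) is implemented, but it is
  *not* the default for a numerical reason worth recording: $R^2$
  barely penalizes smooth curvature. On a noiseless
  exponential-approach trace at 20% substrate conversion, the full
  121-point prefix still has $R^2 = 0.9992$ while its slope
  underestimates the initial rate by 10%. A short early window bounds
  the curvature bias instead (≈0.4% at the simulator's defaults);
  `best_linear` remains useful on noisy traces where averaging matters
  more than bias.
* **Accuracy budget.** On the direct velocity route
  (`morrison_velocity` → `fit_ki`) recovery of a planted $K_i$ is exact
  to machine precision. Through simulated progress curves, the
  straight-line initial-rate step leaves a residual curvature bias that
  differs across inhibitor concentrations, so curve-route recovery is
  at the percent level (~0.6% at defaults); the unit tests assert 1%
  there and 0.1% on the velocity route. Under 2% multiplicative noise,
  100 seeded replicates at the standard design recover $K_i$ with a
  median relative error under 10% (observed ≈3%).

## 6. The synthetic-data generator

The generator's defaults encode the study conditions the analysis
targets, and its manifest records everything needed to predict the
downstream statistics:

* **Length profiles.** Negative libraries peak at 6 residues and decay;
  positive libraries are broader with a peak at 7. Only the modes are
  dictated by the target repertoires; the surrounding shape
  (`5:12` support, see `NEGATIVE_LENGTH_PMF`/`POSITIVE_LENGTH_PMF`
  internals) is a realistic unimodal choice made once.
* **Composition bias with an exact plant.** The positive library
  multiplies a uniform composition by class: K/R/H ×3, D/E ×0.5, G/S/P
  ×1, and the remaining 12 residues ×7/12. The 7/12 factor makes the
  multipliers average to exactly 1 over 20 residues, so renormalization
  is a no-op and the *realized* enrichment against the uniform negative
  library equals the multiplier exactly — the planted K enrichment is
  3, not "3 before normalization". The mild hydrophobic depletion this
  implies matches the qualitative behaviour of sorted binder
  repertoires. Residues are i.i.d. per position: no positional
  structure is planted by default because no positional generative
  model is available to copy; a per-position override is the natural
  extension.
* **Reads.** Loops are reverse-translated with uniform synonymous
  codons (codon usage is irrelevant downstream of translation),
  embedded in the SynAb-A2 heavy-chain context around the anchors,
  flipped to the reverse strand with probability 0.5, and offset by 0–2
  leading random bases so all six frames occur. Substitution errors
  (default 0.001/base), Gaussian-rounded Phred qualities (mean 35,
  sd 3, clamped to [2, 41]) and a default 1% of anchor-free junk reads
  emulate a well-behaved Illumina amplicon run.
* **Assay curves.** Product fluorescence approaches the
  substrate-depletion plateau as
  $F(t) = F_\infty(1 - e^{-v_I t / F_\infty})$, whose initial slope is
  exactly the Morrison velocity; $F_\infty$ is set so the uninhibited
  reaction converts 10% of substrate over the 120-minute watch, a
  conventional initial-rate regime. The curve shape only matters
  through the initial-rate extraction, so this single-exponential
  choice is cosmetic by design.
* **Determinism.** Every generator takes an explicit seed, produces
  bit-identical output under it, and restores the caller's RNG state.

What the generator does **not** emulate — and therefore what passing
tests do and do not show: there is no FACS sorting dynamics, no
expression/display variation, no clonal phylogeny or PCR amplification
bias, no positional epistasis, and no sequence-specific binding
thermodynamics. Recovery tests demonstrate that the *pipeline* is
correct and unbiased on data whose generating process is known; they
say nothing about whether a real library satisfies that process.

## 7. Binder classification scaffold

The classification module reproduces the *shape* of a
protein-language-model pipeline at desk scale: featurize → PCA keeping
95% variance → count-weighted linear classifier → binder-class F1 on a
held-out 20% split. Choices:

* Built-in featurizers (padded one-hot with a 21st blank channel;
  overlapping k-mer counts) are deliberately simple and deterministic;
  an `external_embedding_file` hook accepts precomputed embeddings
  (e.g. from a large protein language model run elsewhere) keyed by
  sequence, so the identical evaluation harness applies to both.
  GPU-scale embedding models and their fine-tuning are out of scope
  here, and the published F1 values obtained with them are not
  reproduction targets: they depend on undeposited sequencing data and
  model weights.
* The PCA is fitted on training rows only and applied to test rows
  (verified by a leakage test); components kept = the smallest count
  reaching the variance target.
* "Linear classifier" is pinned down as ridge-penalized logistic
  regression (`glmnet`, $\alpha = 0$, small fixed $\lambda$): convex,
  deterministic, weight-aware. Binder weights are clone counts over
  total positive counts, so training emphasis follows observation
  depth; duplicating a row is exactly equivalent to adding its weight.
* The split is stratified by label under an explicit seed, and
  evaluation is invariant to input row order.

## 8. Problem sizes and runtime

The test-suite and acceptance runs use libraries of $10^4$ reads
(scaled from the real campaign's ~0.8–1×$10^4$ unique fragments per
sort), 100-replicate noise studies for the kinetics, and a
10,000-read brute-force oracle comparison for the extractor. These
sizes put all multinomial error bars well inside the asserted
tolerances while keeping a full run in minutes on a single core.

## 9. Known limitations

* Anchor matching assumes the framework context is intact; heavily
  truncated amplicons that cut into an anchor are reported `no_frame`
  rather than rescued.
* Enrichment ratios carry no uncertainty estimates; for rare residues
  at low depth, users should consult the pseudocount option and the
  undefined-cell flags rather than trust point ratios.
* The kinetics module fits a single-site tight-binding model;
  mechanism discrimination, $K_m$ estimation, and IC50-only analyses
  are out of scope.
* The classifier's built-in featurizers cannot represent long-range
  sequence context; they are evaluation plumbing for the scaffold, not
  a claim about optimal binder prediction.
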