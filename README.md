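# cdrh3kit

Analysis toolkit for FACS-sorted single-chain antibody (scFv) libraries
sequenced by amplicon NGS, aimed at protein engineers running directed
evolution against protease targets such as the ADAM-17 catalytic domain.
The package covers the full desk-side arc of such a campaign:

1. **Sequence processing** — FASTQ reading and quality filtering,
   six-frame translation, and localization of the hypervariable CDR-H3
   loop between the conserved heavy-chain framework anchors
   `DTAVYYCAR` (upstream) and `FDYWGQGTLVTVSS` (downstream), followed by
   aggregation of unique loops into frequency-sorted clone tables.
2. **Repertoire statistics** — loop-length distributions, positional
   amino-acid frequency matrices, and enrichment ratios between sorted
   libraries, with residue-class summaries.
3. **Inhibition kinetics** — initial-velocity extraction from
   fluorogenic progress curves and nonlinear fitting of the equilibrium
   inhibition constant K<sub>i</sub> for tight-binding inhibitors.
4. **Binder classification** — a desk-scale scaffold (featurization,
   variance-capped PCA, count-weighted linear classifier, binder-class
   F1) that also accepts precomputed protein-language-model embeddings.
5. **Synthetic data** — generators for paired positive/negative
   libraries, framework-embedded FASTQ reads with a quality/error model,
   and inhibition assay curves, each with a planted-truth manifest so
   every statistic the pipeline computes can be checked against a known
   answer.

## The statistics and models at the core

**Positional frequencies and enrichment.** For clones of a fixed loop
length, the frequency of amino acid *AA* at loop position *p* is

    F(AA, p) = count(AA at p) / total count at p

and the enrichment of the positive (binder) library over a reference
library is the ratio

    E(AA, p) = F_pos(AA, p) / F_neg(AA, p)

computed cell-wise (positional mode) or after collapsing positions and
lengths into whole-library compositions (pooled mode). `E > 1` marks
preference in binders, `E < 1` depletion; cells with a zero denominator
are flagged undefined rather than infinite.

**Tight-binding kinetics.** When inhibitor and enzyme concentrations
are comparable, free and total inhibitor differ, and velocities follow
Morrison's equation

    v = v0 * (1 - ((E + I + Ki_app) - sqrt((E + I + Ki_app)^2 - 4 E I)) / (2 E))

with `Ki_app = Ki (1 + S/Km)`. `fit_ki()` minimizes squared residuals
over (K<sub>i</sub>, v<sub>0</sub>) with `Km` fixed, converting all
concentrations to pM internally to keep the quadratic well conditioned.

## Worked example

Simulate a positive library, sequence it, extract loops, and compare it
against a negative partner:

```r
library(cdrh3kit)

sim_pos <- sample_loops(positive_library_spec(n_reads = 5000, seed = 1))
reads   <- embed_and_sequence(sim_pos$clones, read_model(), seed = 2)
kept    <- quality_filter(reads)$kept
log     <- extract_from_reads(kept)$log
table(log$status)
#>     extracted internal_stop      no_frame
#>          4880             7           156

clones <- aggregate_clones(log, "positive")
length_distribution(clones)$mode
#> [1] 7

sim_neg <- sample_loops(negative_library_spec(n_reads = 5000, seed = 3))
e <- enrichment(pooled_frequencies(clones),
                pooled_frequencies(sim_neg$clones), mode = "pooled")
round(e[c("K", "R", "H", "D", "E", "G", "S")], 2)
#>    K    R    H    D    E    G    S
#> 3.05 3.05 3.05 0.51 0.51 1.04 1.03
```

The extracted repertoire reproduces the generator's plant: loop lengths
peak at 7 residues, lysine/arginine/histidine come back ~3-fold
enriched, aspartate/glutamate ~2-fold depleted, and glycine/serine
neutral. The 156 `no_frame` reads are the planted anchor-free junk plus
reads whose anchors were destroyed by simulated sequencing errors.

Fitting K<sub>i</sub> from noisy simulated progress curves:

```r
cond <- assay_condition(E_total_nM = 8, S_total_uM = 20, Km_uM = 7.76, v0 = 40)
asy  <- simulate_assay(cond, Ki_pM = 435.5, noise_sd = 0.02, seed = 4)
vel  <- data.frame(I_nM = sapply(asy$curves, attr, "inhibitor_nM"),
                   v    = sapply(asy$curves, initial_velocity))
fit_ki(vel, cond)
#> Morrison tight-binding fit: Ki = 430.9 pM (SE 43), v0 = 39.91, converged (n = 8)
```

Extracting the loop from a published heavy-chain sequence:

```r
v <- synab_variants()
locate_cdrh3(v$heavy_chain[v$variant == "A2"])$loop
#> [1] "SYYEYVG"
```

A command-line wrapper over the same functions lives at
`inst/cli/cdrh3kit.R` (subcommands `simulate-library`, `extract`,
`stats`, `enrich`, `simulate-assay`, `fit-ki`, `classify`), driven by a
YAML config; every run writes a JSON manifest of its resolved
configuration and stage counts.

## Limitations

The synthetic generator emulates the statistical structure of sorted
repertoires (length modes, composition biases, sequencing error), not
the biophysics of binding; see the methods vignette
(`vignettes/cdrh3-pipeline.Rmd`) for the generative model, parameter
rationale, and numerical design choices.
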