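---
title: "Methods and design of museomics"
author: "museomics authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of museomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`museomics` re-creates, as tested and reusable functions, the analysis
chain used to take degraded, barcoded, target-captured sequencing reads
from museum specimens to mitochondrial consensus genomes, and to run the
macroevolutionary analyses such mitogenomes feed: diversification-rate
model selection on chronograms, a gridded range-overlap test of
allopatric speciation, and likelihood-based comparison of competing
trees. Every stage can be exercised on synthetic data with known ground
truth, so the pipeline's error behaviour is measurable without access to
any museum dataset.

This vignette explains the models and conventions behind each module,
the parameters that matter, the choices made where the design was
genuinely open, and what the synthetic benchmarks do and do not
demonstrate about real data.

## The synthetic library generator

`library_sim_config()` / `simulate_library()` emulate a capture library
from old tissue:

* **Fragment lengths** are log-normal, parameterised by their median
  (default 58 nt, well below the 76-nt read length, as is typical for
  historical specimens) and a log-scale shape (default `sdlog = 0.3`).
  Only the median is anchored by published summaries of such libraries;
  the dispersion is a package choice of a standard ancient-DNA
  fragmentation model. Draws below 20 nt are resampled, and a configured
  median below 20 nt is rejected outright — fragments that short cannot
  be mapped meaningfully at this read length.
* **Circularity.** Endogenous fragments are sampled from the doubled
  reference sequence, so inserts may span the origin of the circular
  mitogenome; their truth coordinates are recorded on the unrolled axis
  and interpreted modulo the reference length.
* **Read layout.** The sample barcode is attached at the fragment 3'
  end, so mate 1 reads insert → reverse-complemented barcode → adapter,
  and mate 2 reads barcode → reverse-complemented insert → adapter.
  Reads shorter than the insert construct are padded by adapter
  read-through from two fixed synthetic 30-mers; this is what makes
  merge-time adapter trimming testable. The demultiplexer therefore
  reads the barcode from the start of mate 2 (configurable).
* **Errors and qualities.** Substitution errors are uniform per base
  (default 0.002) and independent of the reported quality; per-cycle
  Phred means decay linearly (38 at cycle 1 to 28 at cycle 76, sd 3).
  Post-mortem deamination damage is deliberately *not* simulated — the
  consensus pipeline being tested does not model damage either, so
  adding it would measure a property the pipeline never claims.
* **Sources.** Contaminant ("human-like") and numt-like fragments are
  drawn from user-supplied homologous sequences at configured
  proportions. In the packaged benchmarks the contaminant is the
  endogenous reference mutated at 15% of sites, a divergence in the
  range separating human mtDNA from Old-World-monkey mtDNA closely
  enough for competitive classification to be a genuine test.
* **Duplicates.** An optional `frac_duplicate` makes some fragments
  exact positional copies of earlier ones (fresh errors and qualities),
  populating the truth table's `duplicate_of` column so the duplicate
  collapsing stage can be validated.

What passing tests on these libraries shows: the pipeline's arithmetic,
coordinate handling, filtering rules and estimators are correct under
the stated generative model. What it does not show: robustness to
damage patterns, indels, quality miscalibration, or reference bias from
deeply diverged references — all explicitly out of scope.

## Barcode design and demultiplexing

Barcodes are fixed-length DNA words with a guaranteed minimum pairwise
Hamming distance (defaults: 7 nt, distance 3), so fewer than three
substitutions can never convert one barcode into another.
`design_barcodes()` uses a seeded greedy pass over a random permutation
of all words; homopolymers are always excluded, and for lengths of 6 nt
and up words with fewer than 2 or more than length − 2 G/C bases are
excluded as well (synthesis and sequencing behave poorly at composition
extremes). For very short words the composition filter is suppressed,
because in a 4-letter space of length 4 it would dominate the
combinatorics. Every designed set is checkable with
`verify_barcode_set()`, an independent O(n²·L) pairwise verifier kept
deliberately separate from the construction code.

Demultiplexing is by exact match only — the defensible rule when
barcodes are distance-3 separated and reads are error-filtered — and
conserves reads: assigned plus unassigned equals input.

## Quality filtering and mate merging

A read is discarded when more than 5 of its bases fall below Phred 15;
a pair is discarded when either mate fails. Merging then searches all
ungapped relative shifts between mate 1 and the reverse complement of
mate 2, scoring matches minus mismatches, and accepts the best shift if
the overlap is at least 11 nt and at most 10% mismatched. The 11-nt
minimum is the anchored parameter; the 10% cap and the score function
are package choices that make the acceptance rule explicit. A tie
between two distinct best shifts leaves the pair unmerged
(conservative), as does any failure — only merged fragments continue
down the pipeline.

Consensus qualities in the overlap follow a deterministic combination
of the two published conventions: agreeing bases get the *sum* of their
qualities, capped at 60; disagreeing bases get the *higher-quality*
base with quality equal to the absolute difference (mate 1 wins an
exact tie). The cap reflects the usual practice of not reporting
confidences beyond 1 in 10⁶. The merged fragment spans from the start
of mate 1 to the end of reverse-complemented mate 2; bases outside that
span on either read are adapter read-through and are removed.

## Iterative reference-guided assembly

`map_fragments()` is a seed-and-extend mapper: exact 13-mer seeds at
four evenly spaced positions anchor candidate diagonals on the doubled
reference (so origin-spanning fragments map contiguously; coordinates
are 0-based half-open, reduced modulo the length), and candidates are
scored by full-length ungapped extension at match +5 / mismatch −4. A
fragment is accepted at 0.8 of its maximal score — about 11% mismatches
for typical fragments — and left unmapped when two distinct loci tie.
The substitution-only extension matches the generator (and the
non-goal of indel-rich mapping); a gapped rescue path using
`Biostrings::pairwiseAlignment` (gap open −8, extend −2) exists for
fragments with no seed at all and is used by the contamination
classifier, where diverged reads are the point.

Duplicate removal groups alignments by orientation and start and
single-linkage-chains their end coordinates with a ±2-nt tolerance;
each cluster keeps its highest-summed-quality member. The tolerance
interprets "compatible end coordinates" — the original tool's exact
rule is unpublished — and the chaining is idempotent by construction.

Consensus calling requires at least 2-fold *unique* coverage, a
majority base supported by at least 2 fragments, and a majority
fraction of at least 2/3; positions at 0–1× are `low_coverage_N`,
covered positions without a qualifying majority are `ambiguous_N`. The
2/3 threshold operationalises "ambiguous"; anything weaker would call
sites where a third of unique fragments disagree.

Iteration repeats map → dedup → consensus with the previous round's
consensus as the next mapping reference, N positions back-filled from
the current reference *for mapping only*. Convergence is declared when
the back-filled reference stops changing — equivalent to every called
base agreeing with the mapping reference, which makes a clean library
converge in a single iteration. A period-2 cycle stops the loop with an
`oscillated` flag; the cap is 10 iterations.

## Contamination and numt error models

Competitive classification maps each merged fragment against the
ingroup references alone (pass 1, defining the mapped set) and then
competitively against ingroup plus contaminant. Strictly higher ingroup
score → endogenous; strictly higher contaminant score → contaminant;
tie → noninformative. Classification keeps the assembly scoring but
drops the acceptance threshold to 0.5 of maximal score: the signal is
the score *difference*, and a strict threshold would censor diverged
contaminant reads out of pass 1 and bias the estimate downward.
`p_cont` uses the informative denominator
(contaminant / (contaminant + endogenous)); the all-mapped denominator
is also reported as `p_cont_mapped`. Uncertainty is an exact
Clopper–Pearson interval.

Because consensus calling demands 2 independent fragments, a site is
corrupted by contamination only when *all* supporting fragments are
contaminant, so the per-site error is `p_cont^2` — at a 2.3% read-level
contamination rate, 5.3 × 10⁻⁴ per position. The numt model follows the
same logic from genomic constants: mean numt length = total numt
content / numt count; expected lineage-private numt content = private
count × mean length; per-fragment probability = nuclear-to-mito
fragment ratio × private content / genome size; error rate = that
probability squared. All quantities are computed from unrounded
intermediates and reported at 2 significant figures, which keeps the
chain self-consistent regardless of how intermediate values are rounded
for display.

## Diversification-rate model selection

`fit_bdl()` fits six models to the branching times of an ultrametric
tree: pure birth and constant birth–death (rate-constant), logistic and
exponential density dependence (DDL: r₀(1 − k/K); DDX: r₀·k⁻ˣ), and
two- and three-regime piecewise-constant pure birth (yule2rate,
yule3rate). The likelihood is the waiting-time form conditioned on the
root: with k lineages, an inter-event interval of length w contributes
ln(k·r_k) − k·r_k·w, and the censored terminal interval contributes
−n·r_n·w. The constant birth–death model uses the classical
extinction-adjusted survival form with net rate r and extinction
fraction a; its a = 0 limit coincides exactly (constant included) with
the pure-birth form, and the package's birth–death log-likelihoods
agree with `ape::birthdeath` to numerical precision. Because all six
models share one additive constant, AIC differences are directly
comparable, and the nestings pureBirth ≤ yule2rate ≤ yule3rate and
pureBirth = DDX(x = 0) hold exactly — both are asserted in the test
suite.

Numerical strategy: the multirate models are maximised *exactly* by a
grid search over shift times restricted to observed branching times
(sufficient for piecewise-constant rates) with closed-form
events/lineage-time rate estimates per segment; DDX and DDL profile
their initial rate out analytically and optimise the single remaining
shape parameter by bounded 1-D search; birth–death uses bounded
quasi-Newton from five spread starting points on a log/logit scale.
Rates are bounded in [10⁻⁸, 10³]; a DDL carrying capacity at or below
the tip count would imply non-positive rates and is excluded from the
search region rather than crashed on. A taxon-sampling-fraction hook
exists but defaults to complete sampling; the incomplete-sampling
correction itself is out of scope.

`model_select()` reports ΔAIC_RC = AIC(best rate-constant) − AIC(best
rate-variable); `shift_significance()` calibrates it by parametric
bootstrap, simulating trees of the observed tip count under the best
rate-constant model's MLE and refitting everything. The tree simulator
(`simulate_yule_shift_tree`) specifies rate shifts in forward time from
the root, because the total depth of a tree conditioned on its tip
count is random, so shift *ages* cannot be fixed in advance; the
realised shift ages are returned as an attribute. The simulator closes
each tree with one additional censored waiting interval, matching the
fitted likelihood's terminal term.

The packaged calibration experiment uses 200 null Yule trees of 100
tips against a 200-replicate bootstrap critical value, and the power
experiment 100 two-shift trees of 150 tips with a 5-fold rate increase
and decrease (rates 0.4 → 2 → 0.4); both sizes were chosen to give
stable Monte-Carlo estimates at desk scale. Headline analyses of real
chronograms (specific shift ages, observed ΔAIC_RC values) require the
original data deposits and are context, not package claims.

## Range overlap and the allopatry test

Ranges are sets of occupied equal-area grid cells (nominally 25 km²
each; the package treats the grid as already equal-area — projection is
out of scope). Clade ranges are unions over descendant tips, one
representative per taxon. Overlap degree is |A ∩ B| / min(|A|, |B|),
the standard convention that reads 1 when one range nests inside the
other. `range_overlap_points()` produces an overlap-versus-node-age
point per internal node (daughter-clade unions; a sisters-only mode
restricts to cherries), and `arc_regression()` fits overlap on age by
OLS with t-tests of both coefficients. Under allopatric speciation with
post-speciation range movement, young nodes have near-zero overlap
(intercept statistically indistinguishable from 0) and overlap grows
with age (positive slope); sympatric speciation predicts a positive
intercept. When the fit is numerically exact (zero residual variance)
the p-values are defined by convention: 1 for a zero estimate, 0
otherwise.

The range generator splits a parent range into two disjoint halves
along its longer axis at each cladogenesis (allopatric mode; sympatric
mode copies it) and then lets each range drift by random cell swaps —
vacate a random occupied cell, colonise a random unoccupied neighbour —
at an expected `drift` swaps per occupied cell per unit time (default
0.25, i.e. roughly full range turnover over a typical root-to-tip span
of ~4 time units; swaps apply in batches of at most a tenth of the
range for efficiency). The default grid is 64 × 64 with a root block
covering 75% of each axis, deep enough that repeated halving rarely
reaches single cells; a single-cell parent places its second daughter
on an adjacent cell so daughters stay disjoint. These defaults were set
once, from the turnover argument above, as the regime in which overlap
accrues roughly linearly without saturating inside the tree depth.

## Tree likelihoods and the SH test

`site_loglik()` is a Felsenstein pruning engine for JC69, HKY85 and
GTR with optional discrete-gamma rate variation (4 categories, median
method — note other implementations commonly use category means, so
gamma likelihoods are comparable only within one convention). Rate
matrices are scaled to one expected substitution per unit branch
length; transition probabilities come from the symmetrised eigen
decomposition, numerically stable for any reversible model. Gaps and
ambiguity codes are missing data (all-ones partials). Branch lengths
are taken as given — the test's use case is fixed, published trees —
and no optimisation is performed.

`sh_test()` implements the Shimodaira–Hasegawa test with RELL
resampling: multinomial site weights, per-tree centering of resampled
totals, and a one-sided p for each tree against the centered maximum
advantage, 10,000 replicates by default. Under this convention the
best tree always has p = 1 (implementations that split ties report 0.5
for self-comparison; the conventions are documented, not reconciled).
The suite's calibration experiment simulates data on a four-taxon tree
whose internal branch is zero, evaluates the two conflicting
resolutions, and checks that twice the worse tree's p — which should be
U(0, 0.5) for two exchangeable trees — passes a Kolmogorov–Smirnov
uniformity test across 200 replicates.

## Pipeline orchestration

`run_pipeline()` wires simulate (optional) → demultiplex → filter →
merge → assemble → classify, with defaults fixed at the anchored values
(Q15/5-base filter, 11-nt overlap, 2-fold coverage, 7-nt distance-3
barcodes), writes every stage output plus the resolved configuration
next to the results, and emits a JSON run report whose counts are
monotone non-increasing through the read-processing stages. Reruns
with the same configuration and seed are bit-identical; this is
asserted by checksum in the tests. Thin Rscript wrappers under
`inst/scripts/` expose the simulator and the pipeline to shell users;
the R functions are the primary interface.

## Known limitations

* No damage model, no indel errors, no quality recalibration; the
  generator and mapper are substitution-only by design.
* The mapper is not a general-purpose aligner: beyond roughly 15%
  divergence seeds vanish and only the (slower) rescue path can place
  fragments.
* Diversification likelihoods condition on the root and complete
  sampling; absolute log-likelihoods are comparable only within this
  package's convention, though model *rankings* are not affected.
* The SH engine evaluates fixed trees; it does not search or re-fit
  branch lengths, and partitioned models are not supported.
* Range analysis assumes the grid is already equal-area and ranges
  arrive as cell presences; no projection, rasterisation or occurrence
  cleaning is provided.
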