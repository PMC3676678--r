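# museomics

Reconstructing mitochondrial genomes from museum-specimen sequencing
libraries, and testing the macroevolutionary hypotheses those genomes
support.

DNA from century-old study skins is short (median fragment sizes near
58 nt), contaminated (human handling, environmental microbes) and only
accessible through target capture and deep multiplexing. `museomics`
implements the full analysis chain for such data as tested R functions:

* **Synthetic ground truth** (`simulate_library`,
  `simulate_yule_shift_tree`, `simulate_clade_ranges`) — barcoded
  paired-end reads from a circular reference with contaminant and
  numt-like spikes, ultrametric trees under multi-rate Yule processes,
  and gridded clade ranges under allopatric or sympatric scenarios, all
  with per-read/per-node truth tables.
* **Barcodes** (`design_barcodes`, `demultiplex`) — greedy design of
  barcode sets with a guaranteed minimum pairwise Hamming distance
  (default 7-mers at distance ≥ 3) and exact-match demultiplexing.
* **Read processing** (`quality_filter`, `merge_pairs`) — the
  more-than-5-bases-below-Q15 filter, and overlap merging of mate pairs
  (≥ 11 nt overlap) with consensus qualities and adapter removal.
* **Assembly** (`map_fragments`, `dedup`, `call_consensus`,
  `iterate_assembly`) — iterative reference-guided consensus on a
  circular mitogenome: seed-and-extend mapping, duplicate collapsing by
  orientation/start/compatible ends, and ≥ 2-fold-unique-coverage
  majority calling with Ns elsewhere.
* **Contamination** (`classify_fragments`, `binomial_ci`,
  `per_site_error`, `numt_error_model`) — competitive-alignment
  classification into endogenous / noninformative / contaminant with
  exact binomial confidence intervals, and the closed-form error models:
  per-site error `p_cont^2` at 2-fold coverage, and the numt model
  (mean numt length → expected private numt content → per-fragment
  probability → squared error rate).
* **Diversification** (`fit_bdl`, `model_select`,
  `shift_significance`) — six birth–death-likelihood models (pure
  birth, birth–death, DDL, DDX, yule2rate, yule3rate) on branching
  times; ΔAIC_RC = AIC(best rate-constant) − AIC(best rate-variable);
  parametric-bootstrap significance for rate shifts.
* **Range overlap** (`overlap_degree`, `range_overlap_points`,
  `arc_regression`) — |A∩B|/min(|A|,|B|) on equal-area grids, node age
  versus overlap regression: allopatric speciation predicts an
  intercept near 0 and a positive slope.
* **Tree comparison** (`site_loglik`, `sh_test`) — Felsenstein-pruning
  per-site log-likelihoods (JC69/HKY85/GTR, optional discrete gamma)
  and the Shimodaira–Hasegawa test with RELL resampling.
* **Orchestration** (`run_pipeline`) — simulate → demultiplex → filter
  → merge → assemble → classify from one YAML/list configuration, with
  a machine-readable, seed-reproducible run report.

## Worked example

Simulate a contaminated capture library, assemble the mitogenome, and
quantify contamination:

```r
library(museomics)

set.seed(1)
ref <- paste(sample(c("A","C","G","T"), 8000, TRUE), collapse = "")
contaminant <- simulate_homolog(ref, 0.15)   # 15%-diverged homolog

cfg <- library_sim_config(ref, contaminant_ref = contaminant,
                          n_fragments = 4000, frac_contaminant = 0.02,
                          per_base_error = 0.002, seed = 7)
sim    <- simulate_library(cfg)
dmx    <- demultiplex(sim$pairs, c(sample1 = cfg$barcode))
flt    <- filter_read_pairs(dmx$samples$sample1)
merged <- merge_pairs(flt$kept)
merged
#> merged_fragments: 3929 merged, 7 unmerged

asm <- iterate_assembly(merged, ref)
asm$consensus
#> consensus_genome: 8000 positions, 8000 called, 0 low-coverage N, 0 ambiguous N

classify_fragments(merged, list(ref), contaminant)
#> contamination report
#>   endogenous:     3838
#>   contaminant:    87
#>   noninformative: 2
#>   unmapped:       2
#>   p_cont = 0.0222  (95% CI 0.0178-0.0273)
```

The merged fragments (3,929 of 3,936 filtered pairs) assemble back to a
fully called consensus; the estimated contaminant fraction (2.2%, exact
95% CI 1.8–2.7%) brackets the simulated 2% spike. The implied per-site
consensus error at 2-fold coverage is `p_cont^2 ≈ 4.9e-4`. The numt
misincorporation model from its default genomic constants:

```r
numt_error_model()
#> numt misincorporation model
#>   mean numt length:        602.8 bp
#>   expected private total:  60.9 kb
#>   per-fragment probability: 0.00406
#>   error rate at 2-fold:    1.6e-05
```

Diversification-rate model selection on a simulated chronogram with a
3-fold rate shift:

```r
tr  <- simulate_yule_shift_tree(c(1, 3), shift_times = 3, n_tips = 150,
                                seed = 11)
model_select(branching_times(tr))
#>       model     logL n_params       AIC      dAIC
#>   pureBirth 564.1731        1 -1126.346 37.136590
#>  birthDeath 576.2667        2 -1148.533 14.949461
#>         DDL 564.1729        2 -1124.346 39.137057
#>         DDX 576.6380        2 -1149.276 14.206865
#>   yule2rate 584.7414        3 -1163.483  0.000000
#>   yule3rate 585.8805        5 -1161.761  1.721902
#> best model: yule2rate;  delta AIC_RC = 14.949
```

The single-shift model wins with a large rate-constant-versus-variable
AIC gap, as it should for data generated with one shift;
`shift_significance()` attaches a parametric-bootstrap p-value to that
gap.

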