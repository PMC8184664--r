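# isletcon

Functional-connectivity analysis of pancreatic islet β cells from Ca²⁺
imaging, plus pre-ranked gene-set enrichment for scoring
epithelial/mesenchymal expression programmes.

Within an islet, glucose-stimulated β cells oscillate in partial synchrony;
how strongly and how widely cells co-oscillate is a readout of islet
coordination and, ultimately, of insulin-secretory competence. `isletcon`
quantifies this from the standard imaging readout — one mean-fluorescence
time series per segmented cell (ROI) — and is aimed at imaging labs that
record isolated islets loaded with a Ca²⁺ dye (e.g. fluo-8) at ~0.5 Hz with
~50 ROIs per islet.

## The method

For each islet recording:

1. **Preprocessing.** Each trace is smoothed with a retrospective (trailing)
   moving average over the previous 10 samples and normalised to its baseline
   fluorescence F₀ (the mean of the pre-stimulus frames), giving F/F₀.
2. **Pairwise correlation.** The Pearson coefficient R is computed for every
   unordered cell pair (autocorrelations excluded).
3. **Bootstrap significance.** For each pair, frames are resampled with
   replacement (identically for both cells) and R recomputed per replicate;
   the one-sided significance is
   p = (1 + #{replicate R ≤ 0}) / (n_boot + 1),
   i.e. the bootstrap confidence interval for R must exclude zero. Moving-block
   and permutation variants are provided for serially correlated traces.
4. **Edge rule.** Cells are connected iff **R > 0.25 and p < 0.001**. Edges
   are binned by strength — green (0.25–0.5), yellow (0.5–0.75), red
   (0.75–1.0) — and drawn as straight lines between the cells' Cartesian
   ROI coordinates; the full R matrix is exported as a heatmap fixed to
   [−1, 1].

A coupled-oscillator simulator (`simulate_islet()`) generates recordings with
a planted coupled subpopulation and a closed-form expected pairwise
correlation R = a²v / (a²v + σ²), which makes recovery, calibration and
type-I-error claims testable without external data.

For transcriptomics, `gsea_preranked()` scores gene sets against a
differential-statistic-ranked gene list with the running-sum enrichment
score, a gene-label permutation null (exact enumeration when feasible) and
Benjamini–Hochberg adjustment across sets.

## Worked example

```r
library(isletcon)

# a 20-cell islet, 10 cells sharing a glucose-driven oscillation
spec <- islet_sim_spec(n_cells = 20, coupled_mask = rep(c(TRUE, FALSE), 10),
                       seed = 42)
sim <- simulate_islet(spec)

fit <- islet_connectivity(sim$traces, sim$coords, smooth_window = 1,
                          n_boot = 2000, seed = 42)
fit
#> Islet functional connectivity fit
#>   20 cells, 300 frames; pairs_bootstrap with 2000 replicates (seed 42)
#>   edges (R > 0.25, p < 0.001): 45 of 190 pairs (23.68%)
summary(fit)
#> 20 cells, 45 edges: 23.68% of pairs connected; mean R over edges 0.580
head(fit$graph$edges, 3)
#>   cell_a cell_b         r            p    bin
#> 1 cell_1 cell_3 0.6148380 0.0004997501 yellow
#> 2 cell_1 cell_5 0.6004519 0.0004997501 yellow
#> 3 cell_1 cell_7 0.5151293 0.0004997501 yellow
```

The 45 recovered edges are exactly the C(10,2) = 45 pairs of planted coupled
cells: 23.68% of all pairs, with mean edge strength 0.58 (the simulator's
default noise puts the expected coupled-pair R near 0.58). `plot(fit)` draws
the connectivity line map over the ROI positions and
`plot(fit, type = "heatmap")` the [−1, 1] Pearson matrix.

Enrichment of a planted 20-gene set in a 500-gene ranked list:

```r
sim2 <- simulate_ranked_list(n_genes = 500, set_size = 20, shift = 1.5, seed = 7)
gsea_preranked(sim2$ranked,
               list(sim2$gene_set,
                    gene_set("random20", sample(sim2$ranked$gene, 20))),
               n_perm = 1000, seed = 7)
#> Pre-ranked enrichment: 2 set(s)
#>          set size      es    nes           p           q
#>  planted_set   20  0.6895  2.085 0.001692047 0.003384095
#>     random20   20 -0.3654 -1.178 0.206650831 0.206650831
```

The planted set scores ES = 0.69 (NES 2.1, q ≈ 0.003); the random set is
null, as it should be.

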