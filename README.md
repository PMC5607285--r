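# atacmix

Cell-type deconvolution and sensitivity analysis for ATAC-seq cell
mixtures.

Bulk chromatin-accessibility profiles of heterogeneous tissues — pancreatic
islets with their alpha/beta-cell mixture being the motivating case —
superimpose the open-chromatin landscapes of every constituent cell type.
`atacmix` is for epigenomics analysts who have peak count profiles of pure
cell populations (e.g. αTC1/βTC6-like lines) and want to (i) define
cell-type **signature peaks**, (ii) estimate the **cellular composition** of
mixed samples, and (iii) know how detection of cell-specific peaks degrades
with cell proportion and sequencing depth.

## The model

Counts over a consensus peak set are normalized by effective library size
(reads in peaks) and TMM factors to linear-scale CPM. From pure replicates,
per-type one-vs-rest Welch tests on log2(CPM + 0.5) with BH adjustment
select signature candidates (q < 0.3, ranked by fold change); for each
candidate size *g* the matrix **S** of per-type replicate medians is built
and the *g* minimizing its 2-norm condition number κ is kept. A mixture's
profile **m** over the signature peaks is modeled as the
proportion-weighted sum of the pure profiles,

```
f̂ = argmin‖S f − m‖₂  subject to  f ≥ 0,   then rescaled so Σ f̂ = 1
```

solved by non-negative least squares. Detection sensitivity uses a
count-level Poisson background test (λ = library size × peak length /
effective genome; BH q < 0.01) and binomial thinning to lower depths. A
negative binomial simulator of titrated mixtures (0–100% in 10% steps)
makes the whole pipeline runnable and testable with no external data;
differential peaks use the conventional FDR < 5%, |log2 FC| > 2 thresholds.

## Worked example

```r
library(atacmix)

exp  <- simulate_mixture_experiment(sim_params(n_peaks = 5000, depth = 1e6, seed = 1))
norm <- normalize_cpm(cbind_counts(exp$pure, exp$mixtures))
sig  <- select_signature_matrix(norm, exp$groups)
sig
#> Signature matrix: 100 peaks x 2 cell types (g = 50 per type, condition number 1.04)
#>   per-type signature peaks: A=50, B=50

fit <- deconvolve(sig, norm, samples = rownames(exp$design), truth = exp$design)
fit
#> Cell-type deconvolution (nnls): 11 samples, 2 cell types, 100 signature peaks
#>             A     B
#> mix_000 0.010 0.990
#> mix_010 0.113 0.887
#> mix_020 0.193 0.807
#> ...
#> mix_100 0.989 0.011
#> Recovery vs truth: R = 0.9881, RMSE = 0.0487
```

The coefficient matrix (`coef(fit)`) holds one estimated composition per
mixture sample; `mix_020` — truly 20% type A — is estimated at 19.3% A.
The pooled Pearson correlation between estimated and true proportions over
all samples and types is 0.988 with RMSE 0.049 at this reduced scale
(5,000 peaks, 10⁶ reads; the full benchmark runs 20,000 peaks at 5×10⁶).
Detection rates of A's signature peaks rise with the A proportion:

```r
rates <- detection_rates(exp$mixtures, sig$peaks_by_type)
subset(rates$rates, cell_type == "A" &
       sample %in% c("mix_000", "mix_020", "mix_050", "mix_100"))$detection_rate
#> [1] 0.44 0.92 1.00 1.00
```

i.e. 92% of A signature peaks are already detected when only 20% of the
cells are type A. `depth_titration()` repeats deconvolution and detection
after binomial thinning to lower sequencing depths, and
`annotate_tss_distance()` / `assign_peak_to_gene()` /
`fold_change_concordance()` relate peaks to genes and expression fold
changes. A thin command line lives in `inst/cli/atacmix.R`
(`simulate`, `normalize`, `signatures`, `deconvolve`, `sensitivity`,
`run-all`, with `--config`/`--seed`/`--outdir`).

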