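# mbimpute

Identification and imputation of non-biological zeros in microbiome
sample-by-taxon count matrices.

## The problem

Microbiome count matrices (OTU/ASV tables from 16S sequencing, species
tables from shotgun metagenomics) are dominated by zeros. Some are
biological — the taxon is absent — but many are technical: a low-abundance
taxon missed because of limited sequencing depth or library-preparation
artifacts. Imputing *all* zeros destroys real absences; imputing none
biases differential-abundance tests, ordinations, and network estimates.
This package is for microbiome researchers who want the middle road: decide
per entry whether a value is likely a non-biological zero, and impute only
those.

## The method

Counts are normalized per sample to a total of 10^6 and transformed to
`Y = log10(count + 1.01)`. Then, in two steps:

**Step 1 — identification.** Each taxon *j* is modeled as a Gamma-normal
mixture

    Y_ij ~ p_j Gamma(alpha_j, beta_j) + (1 - p_j) N(X_i' gamma_j, sigma_j^2)

whose Gamma component (mean near zero) captures non-biological zeros and
falsely low counts, and whose normal mean is linear in the sample
covariates X (intercept, log10 library size, optional metadata). The
mixture is fit by EM and screened against a plain normal model with a
likelihood-ratio test on chi-square(3). For taxa where the mixture wins,
entries with posterior probability of the Gamma component >= 0.5 are
flagged; everything else forms the training set Omega.

**Step 2 — imputation.** One joint penalized linear model is trained on
Omega:

    Y_ij = Y_i.' kappa_j + Y_.j' tau_i + X_i.' zeta_j + eps_ij

borrowing from each taxon's k phylogenetically nearest taxa, from the other
samples, and from the covariates, with the weighted-L1 penalty

    lambda * ( sum_{j != j'} D_jj'^psi |kappa_jj'| + sum_{i != i'} |tau_ii'| )

where `D` holds branch-count distances from the phylogeny (all 1 without a
tree), so distant taxa are shrunk harder. `(psi, lambda)` are chosen by
cross-validation; the solver is a warm-started coordinate descent in C++.
Flagged entries are replaced by their fitted values; unflagged entries are
never altered.

The package also ships a synthetic-data generator (covariate-, sample-, and
taxon-encoded signal with injected zero inflation), a proportional
downsampling experiment, and evaluation metrics (MSE, per-taxon Pearson
correlation, Wasserstein distance of mean/SD ratios, detection
sensitivity/specificity).

## Worked example

```r
library(mbimpute)

sim <- simulate_dataset(n = 30, m = 25, seed = 3)   # synthetic ground truth
fit <- mbimpute(sim$counts, covariates = sim$covariates, tree = sim$newick,
                normalize = FALSE, seed = 1)
fit
#> mbimpute fit: 30 samples x 25 taxa
#> mb_mask: 236 of 750 entries flagged for imputation (31.5%), d_thre = 0.5
#>   25 of 25 taxa screened into the mixture model
#> mb_model: k = 5 neighbor taxa, selected psi = 0.5, lambda = 35.42
#>   nonzero coefficients: 0 taxon-taxon, 46 sample-sample
```

31.5% of entries were judged non-biological (the generator injected ~30%),
and the cross-validated model here leans on similar samples and covariates.
Per-taxon diagnostics and the imputed table come back as tibbles:

```r
tidy(fit)   # one row per taxon: LRT statistic/p-value, p_hat, flag counts
#> # A tibble: 25 x 9
#>   taxon  lrt_stat lrt_pvalue p_hat n_flagged ...
#> 1 taxon1     45.5   7.19e-10 0.299         9
#> 2 taxon2     67.9   1.20e-14 0.496        15

imputed_counts(fit, scale = "log")   # samples x taxa tibble
autoplot(fit)                        # posterior-probability histogram
```

Because the generator keeps the complete matrix, recovery is measurable:

```r
detection_scores(fit$mask, sim$truth_mask)
#> sensitivity 0.991, specificity 0.983
mse(sim$Y_complete, sim$Y_observed, sim$truth_mask)   # 12.12 before
mse(sim$Y_complete, fit$Y_imputed,  sim$truth_mask)   #  1.57 after
```

Real data enter the same way: `mbimpute("counts.tsv", covariates =
"meta.tsv", tree = "tree.nwk")` reads delimited text and newick directly,
and `imputed_counts(fit, "original")` returns counts on the input library
sizes. A thin command-line front end with `run` / `simulate` / `evaluate`
subcommands is installed at `system.file("cli/mbimpute.R", package =
"mbimpute")`.

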