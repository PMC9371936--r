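# spotgist

Image-guided Bayesian cell-type decomposition for spatial
transcriptomics.

Sequencing-based spatial transcriptomics measures genome-wide expression
at spatially barcoded mRNA-capture spots, but each spot mixes transcripts
from several cells. Estimating the proportion of each cell type at each
spot ("decomposition") is the step almost every downstream analysis
depends on, and it fails exactly where it matters: transcriptionally
similar cell types are statistically near-collinear, and poorly captured
slide regions carry little expression signal. Most slides, however, come
with a paired tissue image -- an immunofluorescence stain for a
cell-type-specific marker, or an H&E stain that a deep-learning model can
annotate (e.g. for tumor-infiltrating lymphocytes). `spotgist` is for
analysts who want that image to *inform* the decomposition rather than
sit beside it.

## The model

For normalized spot expression $Y$ ($m$ genes $\times$ $n$ spots) and a
signature matrix $W$ ($m \times p$, per-type mean reference expression),
each spot $j$ is modelled as

$$y_{ij} \sim t\left(\nu_j,\ \beta_{0j} + W_i H^{(j)},\ \sigma_j\right),
\qquad h_{kj} > 0,\ \textstyle\sum_k h_{kj} = 1,$$

with a flat Dirichlet prior on the proportion column $H^{(j)}$,
$\nu_j = 3 + \mathrm{Gamma}(2, 0.1)$, flat $\beta_{0j}$, half-Cauchy
$\sigma_j$. That is the **base model**: robust per-spot simplex
regression, fitted by MCMC, posterior means as estimates. The
**image-guided model** adds one factor: a per-spot Beta prior on the
proportion of the image-informed cell type $a$,

$$\pi(h_{aj}) \sim \mathrm{Beta}(\tau_j\lambda,\ (1-\tau_j)\lambda),$$

whose mean $\tau_j$ comes from the image (capped/aggregated intensities
or patch probabilities, quantile-mapped onto a first prior-free fit) and
whose total count $\lambda$ sets the image's weight against the
transcriptome: $\lambda \to 0$ recovers the base model, large $\lambda$
pins $h_{aj}$ at $\tau_j$. A sweep utility locates the largest safe
$\lambda$ by watching when a held-out cell type's agreement with
independent reference values starts a sustained decline (operating
default: $\lambda = 50$). Grouped targets (one prior on the *sum* of
several types, e.g. total lymphocyte content) are supported.

## Worked example

Simulate a benchmark dataset (6 cell types, negative-binomial counts,
flat-Dirichlet ground truth), fit the base model, then add a synthetic
image prior of fidelity 0.9 on cell type `ct1`:

```r
library(spotgist)

cfg <- sim_config(seed = 1, n_genes = 400, n_spots = 40, cells_per_type = 50)
ref <- simulate_reference(cfg)
mix <- simulate_mixtures(ref$truth$W_true, cfg)

hvgs <- select_shared_hvgs(mix$counts, ref$reference, top_n = 250)
Y <- expression_matrix(normalize_counts(mix$counts)$values[hvgs, ],
                       layer = "normalized")
W <- signature_matrix(build_signature(ref$reference)$values[hvgs, ])

base  <- fit_base_model(Y, W, mcmc_config(1000, 500, seed = 1))
H_base <- posterior_proportions(base)
H_base
#> <proportions_matrix> 6 cell types x 40 spots

truth <- mix$truth$H_true
mean_absolute_error(H_base, truth)
#> [1] 0.0898

# image channel tracking ct1's true proportions, mapped onto the base fit
image_vals <- simulate_image_prior(truth$values["ct1", ], fidelity = 0.9,
                                   seed = 7)
tau    <- quantile_map(image_vals, H_base$values["ct1", ])
prior  <- make_prior(tau, "ct1", lam = 50)
guided <- fit_gist_model(Y, W, prior, mcmc_config(1000, 500, seed = 1))
H_gist <- posterior_proportions(guided)

mean_absolute_error(H_gist, truth)
#> [1] 0.0888
rank_agreement(H_base$values["ct1", ], truth$values["ct1", ])
#> [1] 0.695
rank_agreement(H_gist$values["ct1", ], truth$values["ct1", ])
#> [1] 0.918
```

The guided fit leaves the five uninformed cell types essentially
untouched (overall MAE 0.090 → 0.089) while the informed type's rank
agreement with ground truth jumps from 0.70 to 0.92 -- the image
"suggestion" sharpens exactly the parameter it speaks about, and the
expression data retain the rest.

Agreement with a binary annotation (e.g. pathologist-labelled
immune-infiltrated spots) is quantified by the ratio statistic
$Q = \mathrm{median}(h_{\text{annotated}}) /
\mathrm{median}(h_{\text{other}})$, the improvement
$\Delta = Q_{\text{guided}} - Q_{\text{base}}$, and a permutation test
that reshuffles annotations at fixed count:

```r
mask <- spot_annotation(colnames(Y$values), truth$values["ct1", ] > 0.25)
permutation_test(H_gist$values["ct1", ], H_base$values["ct1", ], mask,
                 n_perm = 10000, seed = 1)
#> <permutation_result> Delta = 0.03819, p = 0.107 (greater, 10000 permutations)
```

A thin command-line front end over the same functions ships at
`inst/cli/spotgist.R` (subcommands `simulate`, `preprocess`,
`make-prior`, `fit-base`, `fit-gist`, `evaluate`).

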