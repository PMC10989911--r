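# pandec — strain-level decomposition of pangenome coverage profiles

Coexisting strains of a bacterial species differ chiefly in their accessory
gene content, and that variation — nutrient utilization, pathogenicity,
antibiotic resistance — is what makes strain identity matter. `pandec`
reconstructs, from multi-sample metagenomic data, both the **composition**
of coexisting strains and the **gene content** of each strain, directly and
simultaneously.

The input is a pangenome coverage profile: a nonnegative matrix *D* (gene
families × samples, RPKM units) produced by mapping each sample's reads
against a species pangenome (the package does not perform read mapping).
`pandec` fits the model

```
D ≈ P · S
```

where *P* (families × K strains) is **binary** — gene family *i* present in
strain *j* or not — and *S* (K strains × samples) holds relative abundances
with columns summing to 1. Estimation proceeds by:

1. **Preprocessing** — trim entries below 10 RPKM, drop empty families,
   drop samples detecting fewer than 0.9 × *g*<sub>min</sub> families
   (*g*<sub>min</sub> = minimum per-reference-genome family count).
2. **Sparse NMF** — alternating exact nonnegative least squares on the
   penalized objective ‖D − P′S′‖²<sub>F</sub> + η‖P′‖²<sub>F</sub> +
   β Σ<sub>j</sub>‖S′<sub>·j</sub>‖²₁ (C++ block-principal-pivoting NNLS
   core; seeded restarts; objective provably non-increasing).
3. **Binarization with confidence** — per strain, a kernel density over the
   raw weights; the density peak whose induced threshold
   θ = 0.5 × p<sub>max</sub> calls closest to the expected per-genome
   family count is selected; calls carry the confidence score
   C = 1 if p′ ≥ θ, else (θ − p′)/θ.
4. **Composition re-estimation** — NNLS of *D* on the binarized *P*,
   column-normalized.
5. **Rank selection** — K scanned over 1–12; a solution is plausible only
   if every strain has mean abundance > τ₂ = 0.1, gene count >
   τ₃ × g<sub>min</sub> = 0.5 × g<sub>min</sub>, and pairwise profile
   Jaccard distance > τ₁ = 0.1; the largest plausible K is kept.

A benchmarking layer (Jensen–Shannon divergence on sorted compositions,
MCC, Jaccard-nearest-reference annotation, confidence-ranked
precision–recall curves with a random-profile baseline, Hungarian strain
matching) and a matrix-level synthetic mixture generator (Dirichlet
compositions with a 5% minimum frequency ≙ one depth unit, 20 units per
sample, core/accessory pangenomes, Poisson or lognormal-Poisson count
noise, background contamination) complete the toolkit. See the vignette
`vignettes/strain-decomposition.Rmd` for the full methods account.

## Worked example

```r
library(pandec)

# simulate a 3-strain mixture over 600 gene families and 12 samples
cfg <- sim_config(n_families = 600, n_strains = 3, n_samples = 12,
                  noise_model = "poisson", seed = 42)
sim <- simulate_dataset(cfg)

# pangenome statistics from the reference gene-content table
stats <- pangenome_stats(sim$truth$true_content)
print(stats)
#> pangenome_stats: 600 gene families, 3 reference genomes (g_min = 427, g_expected = 430.7)

# preprocess and decompose with automatic strain-number selection
pre <- trim_and_filter(sim$D, stats)
fit <- pan_decompose(pre$matrix, stats,
                     factorize_params(rank = 1, seed = 1),
                     rank_select_config(rank_max = 6))
print(fit)
#> pandec_fit: 3 strains over 564 gene families x 12 samples
#>   relative reconstruction error: 0.0204
#>   mean strain relative abundances: 0.528, 0.276, 0.196
#>   gene families per strain: 427, 430, 435

# benchmark against the simulation ground truth
ev <- evaluate_decomposition(fit, sim$truth)
ev$per_strain[, c("pred_strain", "true_strain", "precision", "recall", "auprc")]
#>   pred_strain true_strain precision recall auprc
#> 1     strain1      truth1         1      1     1
#> 2     strain2      truth2         1      1     1
#> 3     strain3      truth3         1      1     1
summary(ev$per_sample$jsd)
#>      Min.   1st Qu.    Median      Mean   3rd Qu.      Max.
#> 4.561e-07 1.550e-06 3.676e-06 5.072e-06 6.533e-06 2.034e-05
```

The three strains are recovered at the correct rank with their gene-content
profiles called perfectly (precision, recall, AUPRC all 1) and per-sample
compositions matching the ground truth to JSD ≈ 10⁻⁶–10⁻⁵.
`tidy(fit)` / `glance(fit)` give tabular views; `plot_composition(fit)`,
`plot_weight_density(fit)` and `autoplot()` on a PR curve give the standard
figures. `write_decomposition(fit, dir)` serializes `P.tsv`,
`P_weights.tsv`, `confidence.tsv`, `S.tsv` and `diagnostics.json`.

A command-line wrapper with `simulate` / `decompose` / `evaluate`
subcommands is installed at `inst/cli/pandec`:

```sh
Rscript inst/cli/pandec simulate --out sim/ --seed 1
Rscript inst/cli/pandec decompose --matrix sim/D.tsv \
    --pangenome sim/membership.tsv --out fit/ --seed 1
Rscript inst/cli/pandec evaluate --result fit/ --truth sim/ --out report/
```

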