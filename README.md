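# mbdiet

Downstream analysis of dietary DNA metabarcoding for comparing the diets of
co-occurring insectivorous predators — written for the common two-marker
(COI + 16S) fecal-sample design used to study sympatric bats, but applicable
to any predator pair whose prey are identified from taxonomically assigned
amplicon hit tables.

Ecologists ask how two morphologically similar, sympatric species partition
food: how diverse is each diet, how much do the diets overlap, how completely
has sampling covered the true prey richness, and do the species differ in
*how* they catch prey (aerial hawking versus gleaning from surfaces)?
`mbdiet` takes the output of standard amplicon bioinformatics (ZOTU tables
with best taxonomic hits) and carries it through the whole downstream
analysis with tested, reproducible code.

## What it computes

Starting from per-marker hit tables (sample × ZOTU × best hit, with read
counts, percent identity, alignment length, E-value and rank-resolved
taxonomy), the pipeline:

1. **Filters** assignments with rank demotion: COI hits keep their species
   name at ≥ 98 % identity, fall back to the family in \[96, 98) and to the
   order in \[90, 96); 16S hits need identity ≥ 90 %, alignment ≥ 100 bp and
   E-value < 10⁻⁷. A detection needs ≥ 10 reads for its final taxon, summed
   over ZOTUs. Samples with < 1000 reads, or with no retained prey, are
   excluded with a reasoned report.
2. **Merges markers** into a binary samples × taxa incidence matrix, counting
   a prey item once even when both markers detect it.
3. **Profiles diets** as percentages of occurrence (POO),
   `p_i = (occurrences of taxon i) / (all prey occurrences)`, and computes
   Hill numbers `^qD = (Σ p_i^q)^{1/(1-q)}` for q = 0, 1, 2, Shannon
   `H' = −Σ p_i ln p_i`, Simpson `1 − Σ p_i²`, Levins breadth
   `B = 1/Σ p_i²` with its \[0, 1] normalisation, and Pianka overlap
   `O_jk = Σ p_ij p_ik / √(Σ p_ij² Σ p_ik²)` on the total and the "core"
   diet (prey consumed more than once), plus per-rank overlap counts and a
   family-level partition table.
4. **Estimates richness coverage** with sample-based accumulation curves,
   the incidence-based ICE estimator at species level and the
   abundance-style ACE estimator on rank-aggregated counts, reporting
   coverage `S_obs / S_est` per taxonomic level.
5. **Infers foraging mode**: prey are classified as likely caught by
   gleaning (non-volant, or volant but diurnal) or aerial hawking (volant
   and nocturnal), and the per-sample proportion of gleaned prey is
   modelled as `y_s ~ Binomial(n_s, π_s)`,
   `logit π_s = β₀ + β₁·species + u_s`, `u_s ~ N(0, σ_u²)` — a binomial
   GLMM with an observation-level random intercept, fitted by adaptive
   Gauss–Hermite quadrature and tested by a parametric-bootstrap
   likelihood-ratio test, with Wald χ², marginal probabilities and the
   species odds ratio.
6. **Simulates** complete two-predator datasets with known ground truth
   (prey preferences, true overlap, true gleanable diet fractions), so
   every stage above is testable without any external data.

## Worked example

```r
library(mbdiet)

cfg <- synth_config(seed = 7)          # two predators, 53 + 45 samples
ds  <- generate_dataset(cfg)

det <- filter_hits(rbind(ds$hits$COI, ds$hits$S16), filter_config())
qc  <- qc_samples(ds$samples, det)
mat <- merge_markers(det, qc$samples)
mat
#> <detection_matrix> 98 samples x 290 prey taxa
#>   predators: Murina ussuriensis (n=53), Myotis ikonnikovi (n=45)
#>   taxon ranks: family 37, order 12, species 241

p_mus <- poo(mat, "Murina ussuriensis")
p_mik <- poo(mat, "Myotis ikonnikovi")
diversity_profile(p_mik)
#>   q       qD
#> 1 0 206.0000
#> 2 1 157.1183
#> 3 2 126.7201

pianka_overlap(p_mus, p_mik)$O_jk
#> [1] 0.3009553

fit <- fit_binomial_glmm(tally_modes(mat, ds$traits))
marginal_probs(fit)$probs
#>             predator      prob         se
#> 1  Myotis ikonnikovi 0.2369825 0.01801941
#> 2 Murina ussuriensis 0.3482410 0.02693032
```

The matrix holds 98 QC-passed samples by 290 rank-qualified prey taxa
(species-level identifications coexist with family- and order-level
demotions). The q-profile reads: 206 prey taxa were observed (q = 0),
the diet behaves like ~157 equally common taxa (q = 1) and ~127 when
dominant prey are emphasised (q = 2). The Pianka value 0.30 indicates
modest overlap between the two diets, and the capture-mode model estimates
that gleanable prey make up 34.8 % of one predator's diet versus 23.7 % of
the other's.

The same analysis runs from a YAML configuration through a single call —
`run_pipeline("config.yaml")` — or from a shell via the thin wrapper in
`inst/scripts/mbdiet`; each stage writes tab-separated outputs plus a
`manifest.json` so a rerun with the same seeds is byte-identical.

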