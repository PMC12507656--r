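# etibdiv

Model-based analysis of multidecadal biodiversity change from metabarcoding
time series — OTU-by-sample read-count tables collected at a few sites over
decades, such as those recovered from archived natural-sampler organisms
(tree leaves, mussels, macroalgae) in environmental specimen banks.

Communities change constantly even without disturbance: OTUs immigrate from
a regional pool, go locally extinct, and are imperfectly detected by
metabarcoding. `etibdiv` decides whether observed diversity trends exceed
that baseline. It implements:

* **Dataset filtering and occurrence conversion** — sites sampled ≥5 years,
  years covered by ≥50% of sites, isolated years (>2 years from any
  neighbour) removed, low-coverage samples (<50% of the median reads)
  removed; an OTU is present at ≥0.01% of a sample's reads.
* **Diversity indices** — per-cell richness (α), full Jaccard dissimilarity
  and its Baselga turnover component for temporal and spatial pairs (β),
  bootstrap extrapolated regional richness (γ), and ACE.
* **A dynamic occupancy model** derived from the equilibrium theory of
  island biogeography: per year, an absent OTU immigrates with probability
  m and a present one goes extinct with probability e, so local richness
  equilibrates at s = mS/(m+e) for a metacommunity of S OTUs. Per-OTU rates
  are Beta(α, α(1−m)/m)-distributed around the community mean with rate
  ranks conserved across sites (large α = neutral); present OTUs are
  detected with probability ρ.
* **Sequential inference** — ρ from ACE; (m, e) by maximum likelihood of a
  two-state hidden Markov model (gap-aware forward algorithm, detection
  held fixed); (S, log α) by simulation-based inference with a 132-64-32
  ELU network (dropout 0.5) trained on simulated diversity summaries.
* **Trend tests** — AR(1) linear mixed-model slopes per index, compared
  with a null ensemble of re-simulated equilibrium communities
  (significant = outside the central 95%), the Δα/Δγ
  homogenization–differentiation classification, and binomial GLMM
  occurrence trends per OTU with BH correction.
* **A synthetic-data generator** with known ground truth (equilibrium,
  regional turnover with widespread invaders, site-specific
  differentiation, α decline) whose detection arises from read subsampling
  calibrated to ρ, so the whole inference chain can be validated without
  any external data.

## Worked example

Generate a synthetic homogenization scenario and run the full pipeline at
desk scale:

```r
library(etibdiv)

cfg <- run_config(
  scenario = scenario_config("regional_turnover", seed = 7),
  desk_scale = TRUE,          # 2,000 SBI simulations, 200-replicate null
  seed = 7, outdir = "demo_run")
out <- run_pipeline(cfg)
res <- attr(out, "results")

res$rates
#>    site      m_hat     e_hat       rho    loglik converged n_otus_fit
#> 1 site1 0.04923904 0.2345263 0.8749674 -2653.400      TRUE        340
#> 2 site2 0.05093642 0.2093018 0.8800044 -2747.812      TRUE        340
#> 3 site3 0.05473382 0.2330943 0.8771872 -2832.440      TRUE        355
#> 4 site4 0.04769198 0.2129943 0.8656020 -2691.327      TRUE        339
#> 5 site5 0.06406584 0.2367291 0.8898752 -2919.906      TRUE        351
#> (true generating values: m = 0.05, e = 0.20, detection = 0.8)

res$sbi$S_hat        # 574   (true metacommunity size 500)
res$sbi$log_alpha_hat # 3.82 (true log-concentration 3)

res$tests
#>           index        slope     slope_se        phi n_obs p_high p_low significant
#> 1         alpha  0.267867043 0.1864908480  0.5888835   100  0.135 0.865       FALSE
#> 2 temporal_beta  0.021732772 0.0024364288  0.9299039    95  0.920 0.080       FALSE
#> 3  spatial_beta -0.003180199 0.0003711694 -0.0451028    20  1.000 0.000        TRUE
#> 4         gamma -0.773638966 0.4522009646  0.2682575    20  0.800 0.200       FALSE

res$blowes
#> blowes_point: delta_alpha 0.0035007, delta_gamma -0.0022751 -> homogenization
```

Reading: local richness (α) and temporal turnover move as an equilibrium
community would, but spatial β-diversity declines more steeply than every
one of the 200 null replicates (p_high = 1, p_low = 0): the sites are
homogenizing, exactly the disturbance this scenario encodes. The Δα/Δγ
classification of the same dataset agrees (Δα > Δγ, spatial
homogenization), and `demo_run/` holds every stage artifact (occurrence
tensor, diversity tables, rate and SBI estimates, trend tests, per-OTU
trends, manifest).

A thin CLI over the same functions ships in `inst/cli/etibdiv`
(subcommands `simulate`, `filter`, `diversity`, `rates`, `sbi`, `nulltest`,
`blowes`, `otutrends`, `all`; YAML config).

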