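# soilage

Bacterial age and generation-time distributions in soil pore networks.

## What this package is for

Most bacteria on Earth live in soil, and most of them divide rarely — yet
almost everything we know about bacterial generation times comes from
well-mixed cultures growing near their maximal rate.  `soilage` is for
microbial ecologists and modellers who want to ask: *what distribution of
cell ages and interdivision times should we actually expect in soil, and
why is it so broad?*

The package has three connected parts:

1. **An individual-based hotspot simulator.**  A two-dimensional disk of
   angular pore channels (triangular cross-sections, lognormal inscribed
   radii) whose water films, water/air partitioning and effective
   diffusivities follow from a prescribed matric potential ψ via
   Young–Laplace corner capillarity.  Carbon diffuses from a central source
   (0.1 mM) and is lost to the carbon-poor bulk at the rim; oxygen enters
   from the rim (0.27 mM, Henry-partitioned gas + aqueous pathways).
   Obligate-aerobic cells grow by dual-Monod kinetics
   μ = μ_max · C/(K_C+C) · O/(K_O+O) with maintenance, divide symmetrically
   at twice the birth biomass, swim by run-and-tumble chemotaxis when films
   are thicker than the capillary-pinning threshold, and carry inherited
   lineage barcodes.  Every division is logged with the parent's age — its
   generation time.

2. **Demographic post-processing.**  Generation-time ECDFs with
   extrapolation for cells that have not yet divided
   (τ̂ = age + ln(m_div/m)/(μ−m_maint)), per-lineage reproductive success,
   dominant/rare classification by Li's minimum cross-entropy threshold,
   cell-age histograms with a bimodality screen, and maximum-likelihood
   fitting and AIC ranking of heavy-tailed candidate distributions (power
   law, exponentially truncated power law, exponential, gamma, lognormal).

3. **A closed-form steady-state age model.**  For one population,
   u(a) = 2k·e^(−ka)·S(a) with k = ln2/τ and S the survival function of a
   Gamma generation-time distribution (shape 1/CV², scale τ·CV²); its
   CV→0 limit truncates at τ; and community mixtures over growth rates from
   one division per year to one per 30 minutes, which for uniformly present
   rates collapse to the power law ū(a) = 2/a².

## A worked example

```r
library(soilage)

net <- build_pore_network(2, seed = 1, n_hetero_regions = 2)  # 2 mm disk
cfg <- sim_config(psi = -3, n_inoculum = 200, t_end_s = 8 * 3600, seed = 1)
sim <- simulate_hotspot(cfg, net)
summary(sim)
#> final cells: 15320  divisions: 15120  biomass: 3.256e+06 fg
#> generation time (h): mean 1.23, median 1.15; max generation 11

fin <- sim$snapshots[[length(sim$snapshots)]]
lt  <- lineage_table(sim$events, fin, sim$inoculum_lineages)
cl  <- classify_dominant_rare(lt)
cl$fraction_dominant        # 0.56  -- slightly over half the inoculum
cl$rare_biomass_fraction    # 0.012 -- rare lineages hold ~1.2% of biomass
```

At −3 kPa roughly half of the 200 founder lineages dominate the final
biomass while 38 lineages never divide at all (they landed in carbon-poor,
capillary-pinned positions); the rare class holds about 1% of final
biomass.  Repeating the run at ψ = 0 and −7 kPa shows the characteristic
non-monotone response: the population peaks at intermediate hydration
(a saturated hotspot loses most of its carbon to the bulk and, at full
scale, suffocates its own center), while drier soil slows and fragments
growth, lengthening generation times and concentrating success in the few
lineages near the source.

The analytic model reproduces its own closed forms:

```r
p <- age_model_params(200, 0.1)       # tau = 200 d, CV = 0.1
age_density_single(0, p) / p$k        # 2 (newborn excess of binary fission)
age_density_mass(p)                   # 0.9976059
w <- lognormal_weights(make_k_grid(), "homogeneous")
a <- 10^seq(1, 2.8, length.out = 100)
loglog_slope(a, community_age_density(a, w, CV = 0), 10, 600)  # ~ -2.00
```

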