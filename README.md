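# flocrrt

Resource-ratio competition and community-diversity analytics for
nitrifying activated-sludge flocs.

## The problem

Ammonia-oxidizing bacteria (AOB) in activated sludge compete for two
essential resources, ammonia and oxygen. Resource-ratio theory (RRT)
predicts that the number of coexisting taxa depends on how much of the
resources is supplied and how heterogeneous the supply is: richness
first rises with enrichment, then falls — the *paradox of enrichment*.
Inside a sludge floc, diffusion and consumption create exactly the kind
of micro-scale resource heterogeneity the theory needs. `flocrrt`
implements that chain of reasoning end to end for engineers and
microbial ecologists who want to explore whether RRT can describe AOB
diversity in bioreactors, together with the community-profile
statistics used to analyse such reactors (DGGE-style fingerprints and
16S clone libraries).

## The model

Each taxon *i* grows on ammonia (N) and oxygen (O) with Monod kinetics
combined by Liebig's law of the minimum,

    mu_i(R_N, R_O) = mu_max,i * min( R_N / (K_N,i + R_N), R_O / (K_O,i + R_O) ),

and persists at loss rate *m* only where both concentrations exceed its
break-even values `R*_j = K_j m / (mu_max − m)` — the corner of its
right-angled zero-net-growth isocline (ZNGI). At a supply point
`(S_N, S_O)` the equilibrium community follows from the classical
graphical construction: the winner among single residents is the taxon
whose equilibrium is uninvadable, and two taxa with crossing ZNGIs
coexist where the supply falls inside the cone spanned by their
consumption vectors. `chemostat_outcome()` verifies any such outcome by
integrating the chemostat ODEs to steady state.

Floc geometry enters through a spherical reaction–diffusion balance
(`solve_floc_profile()`): its volume-weighted, bulk-normalized
concentration standard deviation σ (`nondim_variation()`) sets the size
of a *microhabitat* — the disk of radius 2.58 σ around a mean supply
point, the 0.99 probability contour of a circular bivariate normal.
Richness of a microhabitat is the union of survivor sets over supply
points sampled inside that disk, and `richness_curve()` sweeps this
across an enrichment gradient (50 replicate microhabitats of 100 points
each per position, by default).

The analytics side provides Raup–Crick null-model similarity
(Monte-Carlo and exact hypergeometric mid-P forms), single-linkage
clustering with Newick export, moving-window drift analysis, band-count
richness, and Chao1 / ACE / rarefaction estimators for clone-library
counts, plus free-ammonia / free-nitrous-acid equilibrium chemistry.
Synthetic generators (`gen_species_pool()`, `gen_band_matrix()`,
`gen_otu_counts()`) produce every input with the statistical structure
the analyses assume, so the whole pipeline runs without external data.

## Worked example

```r
library(flocrrt)

pool     <- gen_species_pool(pool_spec(seed = 1))      # 23 AOB taxa
gradient <- build_gradient(c(0.05, 0.025), c(6, 3), 20)
curve    <- richness_curve(gradient, pool, sigma_mode = "diffusion",
                           n_replicates = 50, n_points = 100,
                           D = 0.2, seed = 1)
which.max(curve$mean_richness)   # 3
max(curve$mean_richness)         # 5.98
curve$mean_richness[c(1, 20)]    # 0.00 1.00
```

The curve is humped: essentially no taxon tolerates the lowest
supplies, a peak of about six coexisting taxa appears at low-to-
intermediate enrichment where one microhabitat straddles many
coexistence wedges, and rich supplies collapse the community toward a
single winner. The replicate standard deviation is largest on the
rising limb (0.5 species at its peak vs 0.0 at the top of the
gradient): diversity is intrinsically hardest to predict where
resources are scarce.

The floc chemistry behind the microhabitat size
(`analysis/02_floc_profiles.R`):

| case              | radius (µm) | C_bulk (mg/L) | C_centre | σ       |
|-------------------|------------:|--------------:|---------:|--------:|
| O2, high aeration |         100 |          3.60 |    3.41  | 0.0141  |
| O2, low aeration  |         100 |          0.22 |    0.16  | 0.0701  |
| NH4, low feed     |         100 |         24.20 |   24.18  | 0.00025 |
| O2, default floc  |         200 |          3.60 |    2.84  | 0.0556  |

Oxygen varies measurably through a floc while ammonia stays flat, so
oxygen heterogeneity alone sizes the resource microhabitats.

The numbered scripts under `analysis/` run each stage as a narrative:
pool construction, floc profiles, the richness gradient, fingerprint
dynamics (late samples cluster purely by reactor), clone-library
richness (mean observed 8.5 taxa vs Chao1 9.5 and ACE 10.1 — the
libraries are undersampled), and free-NH3/HNO2 speciation. Outputs land
in `results/`.

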