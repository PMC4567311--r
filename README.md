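# chestnutgall

Associational-resistance analysis of Asian chestnut gall wasp damage on
sweet chestnut.

## The problem

The Asian chestnut gall wasp (*Dryocosmus kuriphilus*), an invasive
cynipid, induces galls on buds, leaves and shoots of sweet chestnut
(*Castanea sativa*), reducing leaf area and nut yield. The associational
resistance hypothesis predicts that host trees growing among
heterospecific neighbors suffer less herbivore damage — because the host
resource is diluted (resource concentration), because natural enemies are
favoured in diverse stands (natural enemies), or because focal hosts
hidden below taller neighbors are harder to find (plant apparency).

This package implements the full analysis chain used to test these
hypotheses on mature chestnut stands sampled along a tree-species
richness gradient (monocultures to four-species mixtures, 30 m × 30 m
mapped plots), for ecologists analysing class-coded crown-condition
surveys together with stand maps.

## What it computes

**Crown damage.** Field crews score five crown variables into seven
percentage classes (0, 0.5–1, 1.5–12, 12.5–25, 25.5–50, 50.5–75, >75 %)
from at least two viewing sides: the crown fraction in sunlight (P_CL),
dead branches in the sunlit and shaded parts (P_DBL, P_DBS), and
defoliation of the living crown in each part (P_DL, P_DS). Class codes
resolve to class midpoints, sides are averaged, and the damage indices
follow:

    T_DBL = P_CL · P_DBL
    P_ACL = P_CL(1−P_DBL) / [P_CL(1−P_DBL) + (1−P_CL)(1−P_DBS)]
    T_D   = P_ACL · P_DL + (1−P_ACL) · P_DS
    T_DC  = P_DL · P_CL(1−P_DBL) + P_DS(1−P_CL)(1−P_DBS) + T_DBL

with T_D (total defoliation) the response of all models and T_DC (total
damaged crown) satisfying the identity `T_DC = T_D·L + T_DBL`, where L is
the living fraction of the crown.

**Stand geometry.** Crowns are circles of equivalent projected area; two
trees are neighbors when their crown circles come within 3 m edge to
edge. Coppice clumps collapse to single trees; focal trees whose crown
plus the 3 m gap reaches past the plot boundary are excluded from
neighborhood analyses. Tree apparency is
`ΔH = mean(H_focal − H_neighbor_i)`.

**Diversity covariates.** Species richness, Shannon index and the
proportion of *C. sativa* on relative stem basal area, abundance-weighted
taxonomic diversity Δ (mean Linnaean path length between individuals),
and the percentage of oak leaves bearing cynipid galls — each at the plot
and the neighborhood level.

**Outlier screen.** 1,000 Gaussian samples simulated at the observed n,
mean and SD; raw points outside the pooled 95% envelope are flagged, and
all analyses can be redone with outliers kept.

**Inference.** Linear mixed models of log total defoliation with a plot
random intercept (lme4), compared by AICc with Akaike weights; the
minimum adequate model is the lowest-K model within 2 AICc units of the
best. Six candidate models at the plot level, fifteen at the
neighborhood level, plus a sequential variance decomposition separating
the unique and shared contributions of apparency and diversity, and a
Pearson correlation battery.

**Synthetic stands.** A generator reproduces the sampling design (15
plots, richness 2/3/5/5 per class, 70 focal chestnuts scored in classes
on two sides) with log defoliation driven by a negative richness effect
and a positive apparency effect at the published magnitudes, so the whole
pipeline runs without field data.

## Worked example

```r
library(chestnutgall)

study <- simulate_study(seed = 1)   # 15 plots, 70 focal chestnuts
res   <- run_study(study, seed = 1)

print(res$plot$screen)
#> Parametric-simulation outlier screen (pooled envelope)
#>   n = 70, mean = 0.1292, sd = 0.09848, 1000 simulated samples
#>   95% envelope: [-0.06514, 0.323]
#>   5 point(s) flagged

print(res$plot$comparison)
#> AICc model comparison, n = 65 (MAM: prop_castanea)
#>          model K    AICc delta weight estimate    se      t     p ...
#>  prop_castanea 4 120.919 0.000  0.382    0.892 0.268  3.331 0.001
#>        shannon 4 121.728 0.809  0.255   -0.461 0.144 -3.191 0.002
#>       richness 4 122.248 1.329  0.197   -0.197 0.064 -3.098 0.003
#>      oak_galls 4 122.761 1.842  0.152   -0.018 0.006 -3.005 0.004
#>           null 3 128.197 7.278  0.010       NA    NA     NA    NA
#>        tax_div 4 130.270 9.350  0.004   -0.002 0.005 -0.420 0.676
```

Five of 70 trees fall outside the simulation envelope and are screened
out. Every diversity covariate beats the intercept-only model by more
than 2 AICc units (Δ(null) = 7.3): defoliation declines along the
diversity gradient. The richness slope −0.197 means each added tree
species multiplies expected defoliation by exp(−0.197) ≈ 0.82. Which of
the five strongly intercorrelated covariates ranks first in a single
15-plot realization is stochastic — here the host-proportion model, with
shannon and richness within 2 units. The correlation battery
(`res$plot$correlations`) shows T_D and T_DC nearly collinear (r = 0.96)
and leaf-level gall incidence echoing crown defoliation (r = 0.79,
n = 46). At the neighborhood level (`res$neighborhood`), the apparency
model carries a positive slope — taller, more apparent chestnuts are hit
harder — and the sequential decomposition tests apparency before and
after the plot-level Shannon index.

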