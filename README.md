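# xelim

Deterministic evolutionary dynamics of the transition from **digenic**
(XX/X0) to **monogenic** sex determination by maternal imprinting and
zygotic elimination of the paternal X chromosome.

In many insects with monogenic reproduction (sciarid fungus gnats, gall
midges, springtails) every zygote starts with the same chromosome
constitution and the sex-determining X/autosome signal is *re-created in the
embryo* by eliminating X chromosomes of paternal origin.  Two female classes
coexist: **gynogenic** females whose broods are all daughters and
**androgenic** females whose broods are all sons.  `xelim` is for population
geneticists who want to simulate, and dissect, how such a system can evolve
from an ordinary XX/X0 ancestor through the sequential appearance of four
modifier genes:

| gene | function when active |
|------|----------------------|
| *e*  | maternal inhibitor: the oocyte stores a dose of product [e] equal to the mother's count of *e* alleles; 1[e] inactivates 1[r] (the enhanced allele *e\** inactivates 2[r] per dose) |
| *s*  | AB spermatogenesis: the maternally and paternally derived complements segregate intact, so sperm carry a whole parental complement and never a recombinant |
| *r*  | zygotic elimination factor: a functional zygote holds 2[r], and every active dose removes one unprotected X |
| *g*  | maternal imprinting: the egg-borne X (and, in sons, the whole maternal complement at spermatogenesis) is protected from elimination |

## The model

An infinite panmictic population with discrete, non-overlapping generations.
Each generation the per-sex genotype frequencies `f` (females) and `m`
(males) map through

1. **gametogenesis** — eggs pool over mothers (Mendelian, unlinked loci; each
   egg carries the mother's cytoplasmic dose and imprint mark), sperm pool
   over fathers under one of three regimes (Mendelian X/0; maternal
   complement only for imprinted AB males — the meiotic drive; both
   complements at 1/2 without imprinting);
2. **zygote resolution** — active doses `max(0, 2·[r functional] − [e] −
   2·[e*])` (two-factor) or `[e]` (one-factor) each remove one unprotected
   X; survivors with two X are females, with one are males, with none die;
3. **viability selection** `w = Π (1 or 1−µ)` on adults of both sexes
   (µ = 0.1), then the sex ratio SR = male/female mass is recorded and each
   sex renormalises.

Everything is deterministic — "random" elimination targets are mass splits —
so every run is bit-reproducible.

## Worked example

Introduce the spermatogenesis gene *s* at frequency 0.05 into the ancestral
imprinting-fixed population, with a recessive viability advantage
(µ = 0.1), and iterate to equilibrium:

```r
library(xelim)
cfg <- model_config()                      # two-factor model, loci e s r g
pop <- ancestral_population(cfg) |>
  introduce_allele(cfg, "s", freq = 0.05)
tr  <- run_to_equilibrium(pop, cfg, selection_regime("s", "recessive"))
glance(tr)
#>   generations converged    delta sex_ratio n_female_classes n_male_classes
#> 1         530 TRUE      9.57e-11     0.624                3              4
tr$final
#> <xelim_population> generation 530, SR = 0.6244
#>   sex    genotype          frequency
#> 1 female XX EE ss RR gg        0.378
#> 2 female XX EE Ss RR gg        0.464
#> 3 female XX EE SS RR gg        0.158
#> 4 male   g(X0 EE ss RR gg)     0.224
#> 5 male   g(X0 EE sS RR gg)     0.395
#> 6 male   g(X0 EE Ss RR gg)     0.129
#> 7 male   g(X0 EE SS RR gg)     0.252
```

The balance is between meiotic drive (imprinted `ss` fathers make only
X-bearing sperm, hence only daughters — note the female-biased SR of 0.62)
and the recessive viability advantage of `ss`.  Females settle at
SS/Ss/ss = 0.158/0.464/0.378.

Single-pair crosses print in the standard layout; a gynogenic female of the
monogenic state yields only androgenic daughters:

```r
cross("XX ee ss rr gg", "g(X0 EE ss rr gg)", cfg)
#>   egg       cytoplasm sperm     offspring      sex     mass
#> 1 X e s r g 2[e]      X E s r g XX Ee ss rr gg female     1
```

The built-in catalogue covers every emergence order under every dominance
regime, the non-imprinting and imprinting-acquisition grids, the enhanced
inhibitor *e\**, the one-factor variant and the sciarid presets
(X-linked *e*, double-X sperm, triple-X zygotes):

```r
grid <- run_grid()        # ~3 minutes, 41 scenarios
tidy(grid)                # outcome class + per-stage allele fates
```

`tidy()`, `glance()` and `autoplot()` methods are provided for
trajectories, scenario results and grids; `inst/cli/xelim.R` is a small
command-line front end (`run`, `grid`, `cross`, `classify`).

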