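# wsbsim

An agent-based simulator of how group-level social context shapes
construction workers' adoption of safety behaviors.

## The problem

Construction work groups in many countries are organized around informal
ties — kinship, townsman networks, an informal foreman — and three
group-level properties of that context are widely held to shape whether
front-line workers comply with and participate in safety practice:

- **IGII** — intra-group informal interaction: informal verbal, behavioral,
  and emotional exchange among group members;
- **GKS** — group knowledge sharing: exchange of experience, technology,
  and safety information;
- **GI** — group identification: members' recognition and acceptance of
  their group.

`wsbsim` models a construction site as a toroidal lattice of context
patches, each carrying fixed IGII/GKS/GI levels on a 0–10 scale, and a
population of workers who random-walk over it. The package is for
researchers in occupational-safety and health-behavior modelling who want
a tested, seeded, fully replicable version of this class of threshold
diffusion model: scenario suites, onset/plateau metrics, and calibration
are first-class, scriptable operations instead of a GUI experiment.

## The model

Each worker *i* carries a safety-behavior cost `c_i ~ N(45, 1)` and a
baseline willingness from other factors `b_i ~ N(20, 1)` (0–100 scale,
clamped). Patch fields are `N(m, 1)` around the site means `m`
(defaults 2; clamped to 0–10). Per tick, each worker:

1. moves to a uniformly chosen Moore neighbor (torus wrap);
2. accumulates cultivated willingness from its new patch,
   `Δw = g · (w₁·igii + w₂·gks + w₃·gi)` with weights summing to 1 and
   gain `g` bridging the 0–10 field scale to the 0–100 willingness scale;
3. is *willing* when net willingness `b_i + w_i(t) − c_i > 0`;
4. if willing, exhibits safety behavior this tick with probability
   `p = 0.8` (re-drawn every tick, so the adopter count fluctuates
   binomially around `n·p` once the population saturates).

Cultivated willingness only accumulates, so the willing count is monotone
in time; the first tick with any exhibitor is the **onset**, and the first
tick at which the willing count reaches 95% of its final value is the
**plateau tick**. The default gain `g = 0.7074` is derived by the
package's own bisection calibration so that the all-defaults baseline has
a median onset of tick 15 over 100 replicates.

## Worked example

```r
library(wsbsim)

cfg <- validate_config(list(seed = 1))
r <- run_sim(cfg)
r
#> <wsb_run> seed 1; 50 workers; 50 ticks; onset 15; final exhibiting 37
c(onset = onset_tick(r), plateau = plateau_tick(r), level = plateau_level(r))
#>   onset plateau   level
#>      15      22      41
```

With the default (calibrated) gain, the first worker adopts safety
behavior at tick 15; by tick 22 the willing count has reached 95% of its
final value; and the adopter count then fluctuates around 41 of 50
workers — the binomial plateau `n·p = 50 × 0.8 = 40`.

The experiment suites reproduce the low-vs-high contrasts under a shared
(coupled) seed schedule:

```r
single_variable_suite(replicates = 100)[, c("scenario", "onset_median", "plateau_fraction")]
#>   scenario onset_median plateau_fraction
#>   igii_low           15          0.79948
#>  igii_high            8          0.79948
#>    gks_low           15          0.79948
#>   gks_high            8          0.79948
#>     gi_low           15          0.79948
#>    gi_high            8          0.79948
```

Raising any one context factor from 2 to 8 brings the median onset
forward from tick 15 to tick 8. (With the default equal cultivation
weights the three factors are exchangeable, and under the shared seed
schedule their high scenarios are draw-for-draw identical — hence the
identical rows.) Raising all three compounds the effect:

```r
multi_variable_suite(replicates = 100)[, c("scenario", "onset_median")]
#>        scenario onset_median
#>  igii2_gi2_gks2           15
#>  igii8_gi2_gks2            8
#>  igii8_gi8_gks2            6
#>  igii8_gi8_gks8            4
```

From a shell, the same operations are available through the CLI:

```sh
Rscript exec/wsbsim run --seed 7 --replicates 10 --out out/
Rscript exec/wsbsim suite --which multi --replicates 100
Rscript exec/wsbsim calibrate --target-onset 15 --replicates 100
```

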