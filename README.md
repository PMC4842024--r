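# pedpower

**Is my pedigree good enough to identify maternal effects?**

`pedpower` answers that question for quantitative geneticists working
with wild pedigreed populations.  Given a pedigree (yours, or a
synthetic stand-in emulating an insular passerine metapopulation), it
runs a fully simulation-based protocol: simulate traits under nested
Bayesian animal models, fit the competing models, and calibrate a
DIC-difference test by Monte Carlo — yielding the critical value, the
power curve along a grid of maternal-effect sizes, and the bias,
coverage and omitted-effect consequences of the variance estimators.

## The model

For phenotyped individuals *i* in a pedigree of *n<sub>p</sub>*
individuals:

> y<sub>i</sub> = β₀ + a<sub>i</sub> + m<sub>m(i)</sub> + p<sub>m(i)</sub> + ε<sub>i</sub>

with a | A,σ²ₐ ~ N(0, σ²ₐ**A**) the direct additive genetic effect
(**A** the pedigree relationship matrix), m | A,σ²ₘ ~ N(0, σ²ₘ**A**)
the maternal genetic effect of individual *i*'s mother *m(i)*,
p ~ N(0, σ²ₚ**I**) a per-mother individual (environmental) effect, and
ε ~ N(0, σ²<sub>ε</sub>**I**) the residual.  The nested sub-models are
**M1** (*a* only), **M2** (*a+m*), **M3** (*a+p*), **M4** (all).
Variances carry InvGamma(0.5, 0.5) priors, the intercept a flat prior,
and *a* and *m* sum-to-zero constraints.  Fitting is by a conjugate
blocked Gibbs sampler (compiled sweep loop, exact constraint handling);
model choice uses the conditional deviance information criterion, with
ΔDIC = DIC(H₀) − DIC(H₁) and a critical value C taken as the 95%
empirical quantile of ΔDIC under data simulated from H₀ — so the test
holds its nominal level by construction, whatever DIC's penalties do.

## Worked example

A desk-scale study of the maternal *individual* effect (pair S2:
M1 vs M3) on a ~800-individual synthetic pedigree, 40 replicates per
grid point:

```r
library(pedpower)
cfg <- desk_config(pair = "S2", seed = 1, S = 40)
res <- run_study(cfg, progress = FALSE)
print(res)
#> simulation study S2 : S = 40 per grid point, np = 820 , nd = 238
#> critical value C = 50.62 (alpha = 0.050, 30 null replicates)
#> power along the maternal-variance grid:
#>   grid maternal_true  power     se  n
#> 1    1           0.0 0.0333 0.0328 30
#> 2    2           0.2 0.5806 0.0886 31
#> 3    3           0.3 0.8182 0.0671 33
#> 4    4           0.4 0.9688 0.0308 32
#> non-converged replicates excluded: 34
```

Reading this: the null ΔDIC distribution on *this* pedigree has 95%
quantile C ≈ 51 (conditional DIC lets the extra maternal block absorb
noise, so the null distribution sits at positive values — exactly why
the threshold must be calibrated rather than fixed by convention).
Against that threshold the test holds its level at the null point
(power ≈ 0.03 ≈ α), and a maternal individual variance of 0.3 of a
unit phenotypic variance is detected with power ≈ 0.8.  Replicates
whose chains fail the convergence gate are excluded and counted, never
re-run.  `res$misspecification` tabulates what M1's variance estimates
absorb when the maternal effect is real; `res$diagnostics` the bias and
coverage of M3's estimators.

The same protocol at full scale — `study_config(pair = "S1", S = 1000)`
on a ~3600-individual system — is a cluster-sized job; the desk preset
exists so the whole pipeline runs on a laptop in minutes.

## Command line

```sh
Rscript inst/cli/pedpower.R simulate-pedigree --preset desk --seed 1 --out ped.csv
Rscript inst/cli/pedpower.R relationship --pedigree ped.csv --out-prefix rel
Rscript inst/cli/pedpower.R study --pair S2 --preset desk --seed 1 --out-prefix s2
```

Every run writes a `*_manifest.json` (config echo + seed + version)
next to its results; logs go to stderr.

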