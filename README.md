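# aclcea

Cost-effectiveness analysis of surgical reconstruction versus conservative
treatment after rupture of the anterior cruciate ligament (ACL), as a
tested, config-driven R package. It is aimed at health economists and
orthopedic outcome researchers who want a transparent, reproducible cohort
decision-tree model rather than a point-and-click tree editor.

## The model

Two strategies are compared from a third-party-payer perspective over a
90-month horizon:

- **Reconstruction**: surgical cost `C_s`; with probability `p_fail` the
  graft fails and one repeat surgery is added, the patient dropping one
  Gottlob activity class (class I stays); with probability `p_seq` a late
  sequela occurs — osteoarthritis (share `s_oa`, total knee prosthesis) or
  a meniscal lesion — adding its surgical cost and pinning the patient at
  activity class II.
- **Conservative**: conservative cost `C_c`; with probability `p_x` the
  patient crosses over to surgery (adds `C_s`, cost only); sequelae as
  above with arm-specific probability and split.

Outcome is expected utility `E = Σ_c P(class c) · u_c`, where the activity
distribution per arm is pooled from study-level counts and `u_c` maps
Gottlob activity classes I–V to utilities on [0,1]. Strategies are compared
by the incremental cost-effectiveness ratio

    ICER = (C_rec − C_cons) / (E_rec − E_cons)   [USD/QALY]

and by net monetary benefit `NMB(λ) = λ·E − C` at willingness to pay `λ`.
Parameter uncertainty in the utilities is propagated by Monte Carlo
probabilistic sensitivity analysis (10,000 independent truncated-normal
draws of the per-class utilities), summarized as a cost-effectiveness
acceptability curve and frontier.

Because the per-class utilities behind the published analysis are not in
the public domain, `fit_utilities()` calibrates a monotone, bounded key to
the published arm-level effects, and two per-arm residual cost constants
(384.45 / 172.87 USD, both < 2.5% of the arm cost) absorb unpublished
micro-structure of the original tree; both are stored openly in the shipped
config and can be set to zero for a literal rollback. See the methods
vignette (`vignettes/acl-cea-model.Rmd`) for every assumption.

## Worked example

```r
library(aclcea)

cfg    <- baseline_config()            # shipped calibrated baseline
params <- config_model_params(cfg)
key    <- config_utility_key(cfg)

tab <- incremental_table(evaluate_strategies(params, key))
writeLines(format_cea_table(tab))
```

```
strategy             cost  incr_cost  effect incr_eff   CE ratio       ICER status
conservative        15466               0.66               23391            reference
reconstruction      16038        572    0.78     0.12      20612       4893 frontier
```

Reconstruction costs 572 USD more per patient and yields 0.12 more
utility-weighted effect, an ICER of ~4,893 USD/QALY — far below common
willingness-to-pay thresholds, so reconstruction is the preferred strategy
at 10,000 USD/QALY. The worst-case scenario (ignore all sequelae):

```r
wc <- worst_case_no_sequelae(params, key)
wc$icer[2] / tab$icer[2]
#> [1] 16.8395
```

i.e. removing osteoarthritis and meniscal sequelae inflates the ICER more
than 16-fold. A PSA with acceptability curve:

```r
psa   <- run_psa(params, config_psa_spec(cfg, seed = 1))
curve <- ceac(psa)                     # WTP grid 0..100,000 by 1,000
subset(curve, wtp == 10000 & frontier)
#>      wtp       strategy probability frontier
#> 22 10000 reconstruction      0.9283     TRUE
```

A command-line interface wraps the same operations
(`pool`, `costs`, `run`, `worst-case`, `psa`, `synth`):

```sh
Rscript exec/aclcea run --config inst/extdata/baseline_config.json --out out/
Rscript exec/aclcea psa --config inst/extdata/baseline_config.json --seed 7 --out out/
```

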