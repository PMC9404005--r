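# logdqsrr

Apparent n-octanol/water distribution coefficients (log D) of weakly and
strongly ionized compounds, estimated from reversed-phase liquid
chromatography retention data via cascaded QSRR models.

## The problem

log D at a given pH is the workhorse lipophilicity descriptor in drug design
and environmental risk assessment. RPLC estimates it cheaply by regressing
log D of trusted model compounds on their retention — specifically on
log k<sub>w</sub>, the log retention factor extrapolated to a 100 % aqueous
mobile phase through the linear solvent strength relation
log k = log k<sub>w</sub> − S·φ. But strongly ionized solutes (sulfonic and
polycarboxylic acids) do not retain under ion-suppression conditions at all,
and almost none of them has an experimental log D, so they have no model
compounds of their own type. This package implements a two-stage bridge on
descriptor space:

1. **Stage 1 (IS-RPLC).** On 46 compounds with reference log D (26 neutrals,
   20 weak acids), fit

   log D₇.₀ = c₀ + c₁·log k<sub>w-IS</sub> + c₂·n<sub>e</sub> + c₃·A + c₄·B

   where n<sub>e</sub> is the solute's net static charge at pH 7.0 and A, B
   its hydrogen-bond acidity/basicity. Use it to label 19 ionized compounds
   that retain in IS mode but lack literature values.

2. **Stage 2 (IP-RPLC).** Add a tetrabutylammonium ion-pair reagent so the
   strong acids retain; train the analogous model on log k<sub>w-IP</sub>
   over the 62-compound mixed model group (neutrals + weak acids +
   stage-1-labeled compounds) and predict the 8 strongly ionized compounds
   measurable only in IP mode.

Around the cascade the package provides the retention factor
k = (t_R − t₀)/t₀, double-point retention-time recalibration, per-solute LSS
extrapolation (`fit_lss()`), the monoprotic-acid ionization correction
log D = log P − log₁₀(1 + 10^(pH − pKa)) (`logd_at_ph()`), external
validation with a leakage guard, a synthetic-data generator for
parameter-recovery testing, and the packaged 73-compound reference table.

## Worked example

```r
library(logdqsrr)

tbl <- compound_table() # packaged 73-compound reference table
cas <- run_cascade(tbl)
cas$stage1
#> QSRR model: stage 1 (ion suppression)
#>   log_d_ref = +1.110(±0.079)·log_kw_is +1.647(±0.297)·n_e +0.603(±0.507)·a -1.244(±0.454)·b +0.025(±0.341)
#>   N = 46, R² = 0.9611, sigma = 0.453
cas$stage2
#> QSRR model: stage 2 (ion pair, mixed model group)
#>   log_d_ref = +1.090(±0.079)·log_kw_ip +2.373(±0.167)·n_e +0.197(±0.248)·a -1.566(±0.324)·b +0.080(±0.317)
#>   N = 62, R² = 0.9453, sigma = 0.543
```

The positive retention coefficient near 1 is the Collander-type
hydrophobicity link; the large positive coefficient on the (non-positive)
net charge says that each unit of anionic charge costs roughly 2.4 log units
of apparent lipophilicity at fixed retention; the negative basicity
coefficient captures hydrogen-bond interactions with the partly dissociated
silanols. Stage 2 then prices the strongly ionized unknowns:

```r
dplyr::mutate(cas$stage2_predictions, predicted = round(predicted, 2))
#>   id    name                               predicted
#> 1 W21   1,4-benzenedicarboxylic acid           -4.26
#> 2 W27   4-aminobenzoic acid                    -2.81
#> 3 W33   3,5-dihydroxybenzoic acid              -2.34
#> 4 S2    1,5-naphthalenedisulfonic acid         -4.71
#> 5 S6    2-amino-1,4-benzenedisulfonic acid     -5.57
#> 6 S10   4-sulfobenzoic acid                    -4.71
#> 7 S13   4-hydroxybenzenesulfonic acid          -2.70
#> 8 S14   3-sulfobenzoic acid                    -4.37
```

External validation on three held-out ionized compounds (the leakage guard
verifies none of them trained stage 2):

```r
external_validation(cas, tbl)
#>   id   name                 reference source                predicted  error
#> 1 W20  pentachlorophenol         2.80 literature (SFM/SSM)       3.22   0.42  <- flagged discrepant
#> 2 W1   benzoic acid             -0.93 literature (SFM/SSM)      -0.97  -0.04
#> 3 S12  3,5-dicarbomethoxy...    -1.55 stage-1 model             -1.50   0.06
```

Benzoic acid and the sulfonic acid land within the 10 % relative-error
bound; pentachlorophenol exceeds it and is flagged rather than hidden.
`reproduce_paper()` runs the whole analysis in one call and can write the
report bundle (models, predictions, validation, discrepancy log) as
deterministic text files.

## Data notes

The packaged table stores the source values exactly as printed, including a
flagged transposition of the N5/N6 log k_w pair that `compound_table()`
repairs by default (set `repair_transposition = FALSE` for the verbatim
table). See the vignette `vignettes/logd-from-retention.Rmd` for the audit
behind the repair, the model assumptions, and known limitations.
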