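# mirkinetics

Chemical-kinetics validation of repressive miRNA–mRNA interactions from
time-course expression data.

## The problem

Sequence-based target prediction (TargetScan, miRanda) assigns hundreds of
candidate mRNA targets to every miRNA — far too many to test. Given
expression time courses recorded in **two** experimental conditions
(wild-type and a GCNF knock-out, in which one transcriptional repressor is
forced to zero), `mirkinetics` keeps a candidate pair (M, G) only if a
small kinetic network embedding the pair can *predict* the downstream
expression profile in **both** conditions with a single parameter set. The
package is for systems-biology analysts who have (a) a long-format table of
expression recordings (miRNAs, mRNAs, actin-normalized Western-blot
proteins on their respective day grids) and (b) a miRNA→target table, and
who want a short, mechanistically annotated list of repressive pairs.

## The models

Every profile is averaged over replicates and interpolated onto a common
19-point grid (t = 0, 1/3, …, 6 days) by monotone PCHIP. Regulators act
through Hill impacts a(x) = (γx)^c; repressor/activator impacts sum to
REP(t), ACT(t), and the committed transcription fraction is
F = ACT/((1+ACT)(1+REP)) (or 1/(1+REP) without activators). Two
ordinary-differential-equation models cover the two silencing modes:

* **Transcription–degradation** (the miRNA degrades the mRNA G directly):
  `dG/dt = k_transcr·F(t) − k_react·G·M(t) − k_deg·G`
* **Translation–inhibition** (miRNAs block translation of protein P):
  `dP/dt = k_transl·G(t)/(1 + REP_mir(t)) − k_degP·P`
  with `k_degP` pre-estimated from the protein's own declining segment.

Parameters are fitted per network by a deterministic multi-scale grid
search over the Hill parameters (binding sites c ≤ 4, saturating factors on
a 0.1–0.9 grid, refined once at 0.01 resolution) combined with nonnegative
least squares for the rate constants, pooling the discretized residuals of
both conditions (38 equations on the 19-point grid). Fit quality is the
**smoothed relative error of prediction**, `|pred − obs| / max(obs, mean
obs)` averaged over the grid, in percent; a network is validated when this
ErrPred is strictly below 10% in every scored condition, and a pair is
validated when at least one embedding network is. Validated networks are
ranked by ErrPred with parameter-parsimony tie-breaks.

## Worked example

The built-in synthetic campaign plants one interaction of each mode (with
known kinetic parameters, 5% multiplicative replicate noise, GCNF zeroed in
the KO condition) alongside three decoy pairs whose downstream profiles no
model of the class can reproduce:

```r
library(mirkinetics)
fx  <- recovery_fixture(seed = 1, noise_sigma = 0.05)
res <- run_campaign(fx$recordings, fx$target_table, fx$tf_config, fx$ti_spec)
res$fit_table[, c("arch_id", "n_params", "errpred_WT", "errpred_KO", "validated")]
#>                            arch_id n_params errpred_WT errpred_KO validated
#> 1    TD:GeneA:mirHL1|rep=GCNF|act=        5       2.59       1.73      TRUE
#> 2 TD:GeneC:mirHL3|rep=|act=ProtAct        5      32.12      33.43     FALSE
#> 3 TD:GeneC:mirLH1|rep=|act=ProtAct        5      32.12      33.43     FALSE
#> 4            TI:GeneB>ProtB:mirLH3        3       1.09       2.29      TRUE
#> 5            TI:GeneD>ProtD:mirLH2        3      34.44      35.32     FALSE
res$verdicts[, c("mirna_id", "gene_id", "validated", "mode", "best_errpred")]
#>   mirna_id gene_id validated          mode best_errpred
#> 1   mirHL1   GeneA      TRUE Transcr.Degr.         2.59
#> 2   mirLH3   GeneB      TRUE Transl.Inhib.         2.29
#> 3   mirHL3   GeneC     FALSE          none           NA
#> 4   mirLH1   GeneC     FALSE          none           NA
#> 5   mirLH2   GeneD     FALSE          none           NA
```

Both planted pairs are recovered (worst-condition prediction errors of
2.6% and 2.3%, below the 10% rule) and each is assigned its true silencing
mode; all three decoys are rejected with errors above 30%. The same
pipeline runs from the shell via
`Rscript inst/scripts/mirkinetics-cli.R simulate|fit|report …`, reading
and writing delimited-text tables and a YAML transcription-factor
configuration.

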