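# allonmr

Mapping dynamic allosteric networks in large proteins from methyl-TROSY NMR
mutant panels — combined chemical-shift perturbation analysis with robust
(MAD) significance filtering, chemical shift covariance (CHESCA) clustering,
side-chain dynamics from ¹H triple-quantum build-up, biochemical fits, and
correlation of shift trajectories with activity.

## The problem

ABC-type ATPases such as the Rad50 nucleotide-binding domain couple ATP
binding to functional changes ~50 Å away. The connecting intermediates are
sparsely populated and invisible to crystallography, but every ILVM
side-chain methyl in a methyl-TROSY spectrum is a local reporter: when point
mutations (e.g. hinge mutants V156M/V160M or the basic-switch mutant R805E)
shift a two-state equilibrium that is fast on the chemical-shift timescale,
each responding peak moves linearly with the excited-state population, and
peaks responding to the *same* equilibrium move in correlated ways.

`allonmr` turns a panel of assigned peak lists (wild type + mutants) into:

- **δ_Methyl = δ_C/w_C + δ_H/w_H** per methyl, with BMRB-derived weights
  w_C = (1.65, 1.60, 1.40, 1.54), w_H = (0.29, 0.28, 0.27, 0.41) for
  Ileδ1/Leuδ/Valγ/Metε;
- a **signed MAD modified Z-score** on the per-methyl shift spread,
  z = 0.6745 (s − median s)/MAD, gate z > 0.25;
- **CHESCA clusters** from correlation distances d_ij = 1 − r_ij under
  complete linkage, dendrogram cut 1.5, minimum cluster size 3;
- **η rates** from |I_forbid/I_allow| = C η tanh(√(η²+δ²) T) /
  (√(η²+δ²) − δ tanh(√(η²+δ²) T)), C = 0.75, delays 2–42 ms, and order
  parameters S²_axis = η/(k τ_c);
- **dynamics classes** (correlated/uncorrelated × flexible/rigid) from the
  0.13 ppm range gate, |R_P| > 0.7, and |η_WT − mean η_mut| > 8 s⁻¹;
- **biochemical constants** from the quadratic tight-binding isotherm, the
  exact ternary competitive equilibrium, Hill–Michaelis–Menten kinetics,
  SEC box-sum dimer fractions and background-corrected nuclease signals;
- **shift-activity correlations** with the |mean R_P| > 0.65 gate and
  per-cluster sign summaries.

A synthetic-data module (`two_state_model()`, `gen_*()`) generates every
input with known ground truth, so the whole chain is verifiable end to end.

## Worked example

The `analysis/` directory is a numbered workflow over the package. Running

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_csp_chesca.R
Rscript analysis/03_relaxation.R
Rscript analysis/04_biochem.R
Rscript analysis/05_correlate.R
```

simulates a full experimental campaign (a 143-methyl, 4-variant panel with three
planted responder groups of 25/10/8 methyls, plus build-up curves,
titrations, kinetics and chromatograms) and then analyses it from the files
alone. Stage 2 prints:

```
62 of 143 methyls pass the modified Z-score gate (z > 0.25)
CHESCA clustering: 62 methyls, cutoff 1.5; 4 cluster(s) of size >= 3, 0 unclustered
variant trajectory order: WT -> V156M -> V160M -> R805E
adjusted Rand index vs planted responder groups: 1
```

— the MAD gate keeps all 43 planted responders (plus the expected share of
noise methyls; see the vignette on why that share is irreducible), complete
linkage at 1.5 reassembles the three planted groups exactly (ARI = 1), and
the variant ordering recovers the planted population order. Stages 3–5 print

```
eta recovery: median relative error 1.24%
K_D,ATP (WT) = 16.3 +/- 0.7 uM
K_I,ADP (WT) = 2.37 +/- 0.24 uM
dimer %: WT=35, V156M=64, V160M=57, R805E=79
cluster 1: 27 of 31 methyls meaningfully correlated (|mean R_P| > 0.65), 100% positive
```

i.e. build-up fits recover the planted η to ~1%, the binding and
competition fits recover their generating constants (16.9 µM and 2.3 µM)
within noise, box-sum integration returns the planted dimer percentages,
and the cluster following the main trajectory correlates coherently — and
with one sign — with hydrolysis, dimerization and nuclease activity.

Tables land under `results/`; every number above is produced by the code at
run time.

## Layout

```
R/                 implementation (peak I/O, CSP, CHESCA, relaxation,
                   biochemistry, correlations, synthetic data, pipeline)
analysis/          numbered workflow drivers (simulate -> correlate)
scripts/           acceptance.R
tests/testthat/    unit, property and acceptance tests with independent
                   brute-force oracles
vignettes/         methods vignette (models, assumptions, defaults,
                   numerical choices, limitations)
```
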