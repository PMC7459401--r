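---
title: "Label-free quantification and treatment-specific protein selection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Label-free quantification and treatment-specific protein selection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

`tardiquant` implements a peak-area based label-free quantification and
candidate-selection workflow for three-group proteomics designs — an
untreated control, a solvent (vehicle) control, and a chemical treatment —
of the kind used to ask which proteins a pre-treatment changes in the
anhydrobiotic tardigrade *Hypsibius exemplaris*. It covers five stages:

1. reading and validating peptide evidence tables, FASTA databases,
   sample manifests and survival count tables (`read_evidence()`,
   `read_fasta_db()`, `read_manifest()`, `read_survival()`);
2. quantification: run normalization, peptide relative expression, and a
   median roll-up over unique peptides (`normalize_runs()`,
   `peptide_relative_expression()`, `protein_rollup()`);
3. the differential cascade with vehicle control and strict criteria
   (`triplicate_filter()`, `classify_differential()`,
   `apply_strict_criteria()`);
4. survival-assay statistics, including a Tukey–Kramer test built on the
   studentized-range distribution (`recovery_summary()`, `tukey_kramer()`,
   `studentized_range_sf()`);
5. a spike-in simulator with ground truth that makes every stage testable
   without any experimental download (`simulate_proteome()`,
   `simulate_survival()`, `recovery_report()`).

Everything upstream of the evidence table — acquisition, peptide/protein
identification and FDR control — is out of scope; the evidence table with
one peak area per (peptide, run) is the entry point.

# The quantification model

Let $A_{p,r} > 0$ be the integrated peak area of peptide $p$ in LC–MS run
$r$; absence of a value means the peptide was not detected in that run
(zeros in input files are treated as absences, because a zero intensity
cell in peptide tables is a sentinel, not a measurement).

**Run normalization.** Peak areas are made comparable between runs using
all identified peptides. With run totals $T_r = \sum_p A_{p,r}$ and grand
mean $\bar T$, every area is scaled by $s_r = \bar T / T_r$, so all runs
carry the same total signal afterwards. This total-sum reading is the
minimal interpretation of normalizing "with the peak areas of all
identified peptides"; a median-based scale (`statistic = "median"`) is
available for data whose totals are dominated by a few peptides. Note that
any normalization anchored on a per-run summary statistic estimates scale
factors only up to one common constant — that constant cancels in the next
step.

**Peptide relative expression.** For each peptide,
$E_{p,r} = \tilde A_{p,r} / \operatorname{mean}_{r' \in D_p} \tilde A_{p,r'}$,
where $\tilde A = A \cdot s_r$ and $D_p$ is the set of runs in which $p$
was detected. The mean is taken over *detected* runs only: a mean over all
runs would have to invent values for runs with no measurement. By
construction the detected-run mean of $E$ is exactly 1 for every peptide,
which the test suite asserts to $10^{-9}$.

**Protein roll-up.** The protein-level relative expression is
$L_{q,r} = \operatorname{median}\{ E_{p,r} : p \text{ unique to } q,\,
p \in D_r \}$. Only peptides matching exactly one database protein
contribute; shared (including razor-style) peptides never do. The median
is computed per run, giving a protein-by-run matrix, because the
downstream t-tests need per-replicate values. Even-count medians are the
arithmetic mean of the two central values. A cell is defined iff at least
one unique peptide was detected; undefined cells stay masked (`NA`) and
are never imputed. Peptide-to-protein matching is contiguous substring
search against the database with isoleucine and leucine collapsed
(`il_equivalent = TRUE`), since the two residues are mass-identical for
the instrument class this models; the equivalence can be switched off.
How the original analysis derived uniqueness from its search output is not
recorded; substring matching against the same database is this package's
explicit reconstruction.

The combination is scale-invariant end to end: multiplying every raw area
of any single run by any $c > 0$ leaves $L$ unchanged to $10^{-9}$
(normalized areas themselves change by one common, irrelevant factor —
exact cell-wise invariance of the normalized table is impossible for any
data-anchored scale).

# The selection cascade

Proteins move through four nested states:
*detected* (quantified somewhere) → *tested* → *differentially regulated*
→ *significant (up/down)*.

**Triplicate filter.** Only proteins quantified in every replicate of
every group are tested. This is the strictest reading of requiring
detection "as biological triplicates", and the one under which both
t-tests and both fold changes are always computable; a
`triplicate_rule = "compared_groups"` option relaxes it for designs with
extra groups.

**Tests.** Each tested protein's $L$ values in the treatment group and in
the vehicle group are compared against the untreated group with the
classical equal-variance two-sample Student's t-test
($df = n_a + n_b - 2$, two-sided), the test the reproduced analysis names;
Welch's variant is available by flag. Degenerate inputs are pinned down:
zero pooled variance with equal means gives $t = 0, p = 1$; with unequal
means, $p = 0$ plus a `degenerate` flag. Tests run on $L$ on the linear
scale by default (the scale on which group means and SDs are reported);
`log_transform = TRUE` switches to $\log L$.

**Differential call.** A protein is *differentially regulated* iff
$p_\text{treatment} < \alpha$ **and** $p_\text{vehicle} \ge \alpha$
(default $\alpha = 0.05$) — a significant change only in the treated
group, so solvent-driven changes are screened out. No multiple-testing
correction is applied: the workflow's reliability control is the pair of
strict criteria below, and a Benjamini–Hochberg column is emitted for
information only.

**Strict criteria.** Among differentially regulated proteins, a protein is
*significant* iff (a) the treatment/untreated fold change (ratio of
arithmetic group means, matching mean-and-SD bar reporting; geometric
option by flag) shows more than two-fold change — strictly $> 2$ or
$< 0.5$ — and (b) the vehicle/untreated fold change lies in the closed
band $[0.8, 1.2]$. Both thresholds are configurable
(`selection_config()`). Whether the original band compared means or
medians is unstated; means are used, consistently with the fold-change
statistic. `normalize_to_untreated()` re-expresses group means and SDs
relative to the untreated mean for figure-style reporting.

Tightening either criterion can only remove calls, and the four states are
nested on every input — both are enforced by property tests.

# Survival statistics

Recovery rates are $r_i = \text{recovered}_i / \text{total}_i$ per
replicate; summaries are means and sample SDs ($n-1$). Rates are analysed
untransformed, as assay figures report raw percentages; an
arcsine-square-root flag exists for variance stabilization. Two
conditions are compared with the Student's t-test; three or more with the
Tukey–Kramer test (`survival_test(test = "auto")`).

The Tukey–Kramer test is implemented from first principles because the
test itself is part of the reproduced analysis: pooled one-way-ANOVA MSE,
pairwise statistics
$q_{ij} = |\bar y_i - \bar y_j| / \sqrt{(MSE/2)(1/n_i + 1/n_j)}$ (the
Kramer adjustment for unequal $n$), and p-values
$P(Q_{k,\nu} \ge q)$ from the studentized-range distribution computed by
direct double numerical integration: the inner integral gives the CDF of
the range of $k$ standard normals,
$k \int \phi(z)\,[\Phi(z+w) - \Phi(z)]^{k-1}\,dz$, and the outer integral
mixes it over the pooled scale $s = \sqrt{\chi^2_\nu / \nu}$. Inner and
outer tolerances ($10^{-7}$ and $10^{-6}$ relative) keep the result
accurate to better than $10^{-4}$, ample for significance testing. The
implementation is cross-checked in the tests against three independent
routes: the exact $k = 2$ reduction to the two-sided t, R's `ptukey()`,
and a $10^6$-draw Monte-Carlo oracle.

# The simulator and what it does (not) emulate

`simulate_proteome()` generates evidence as
$A_{p,r} = \text{base}_q \cdot \text{ion}_p \cdot
\text{effect}(g_r, q) \cdot \text{scale}_r \cdot \varepsilon$ with
log-normal $\varepsilon$, then applies detection dropout. Defaults follow
the emulated study design where it is stated — 3 groups × 3 biological
replicates, ~1500 proteins with 1–10 peptides each, survival assays of 15
animals × 3 replicates — and otherwise use values chosen once as
field-realistic:

| parameter | default | rationale |
|---|---|---|
| `median_area` | $10^7$ | typical integrated-area magnitude; arbitrary units, cancels in $E$ |
| `sdlog_protein` | 1 | ~3 orders of magnitude of protein abundance across a proteome |
| `sdlog_peptide` | 0.7 | wide ionization-efficiency spread between peptides of one protein |
| `cv_biological` | 0.10 | replicate-to-replicate CV of a peptide's area ($\sigma = \sqrt{\log(1+CV^2)}$) |
| `scale_range` | 0.5–2 | log-uniform per-run loading/instrument drift |
| `dropout` | 0.05 | missingness per (peptide, run); intensity-dependent logistic option |
| `fraction_shared` | 0.1 | peptides embedded in a second protein, hence non-unique |
| spike fractions | 0.01 / 0.01 / 0.01 | treatment-up / treatment-down / confounded; see below |
| `fold_treatment`, `fold_confounded` | 4 | clearly detectable at CV 10%, n = 3 |
| `survival_p` | vehicle 0.35, treatment 0.75 | magnitude of the emulated assay's improvement |

**Spike design.** Spiked proteins are 3% of the proteome, with the
vehicle-confounded class alternating up/down so the spiked mass is
directionally balanced. This is a deliberate benchmark-design choice made
at the initial power check: total-sum normalization anchors on run totals,
so a directionally unbalanced spike set biases the scale factors of the
affected groups, shifting *every* null protein's apparent level in those
runs and contaminating the measurement of calling power with a
normalization artifact. Keeping the spiked mass small and balanced makes
the benchmark measure the cascade itself. The effect is real, not an
artifact of the simulator — heavy asymmetric regulation genuinely biases
total-sum normalization, which is a documented limitation below. The
`dropout_exempt_spiked` flag excludes spiked proteins from dropout so
power can be measured separately from missingness.

**Sequence construction.** Protein "sequences" are concatenations of
designed tryptic peptides (bodies free of K/R and of isoleucine, a K/R
terminus). Because cleavage residues occur only at peptide ends and no
peptide is a suffix of another (enforced during generation), substring
matching recovers the designed unique/shared flags exactly. No realism
beyond this correctness is attempted: amino-acid composition, peptide
length distributions, missed cleavages and modifications are not modelled.

Other simplifications worth keeping in mind when interpreting green
tests: biological noise is peptide-level and independent (no correlated
protein-level variation, so many-peptide proteins are more precise than
real ones), dropout is independent of intensity by default (left-censoring
is the realistic mechanism and is available as an option), there are no
interference or co-elution effects, and identification errors do not
exist. Passing tests therefore demonstrate the correctness and calibration
of the *computation*, not performance on real LC–MS data.

# Numerical and degenerate-input conventions

- Masked values propagate as `NA`; nothing is imputed anywhere.
- Median ties / even counts: mean of the two central values, no
  interpolation alternatives.
- Zero pooled variance in the t-test: see above; the flag distinguishes a
  genuine null from a degenerate separation.
- A run with non-positive total, a group with fewer than 3 replicates, a
  sample of size < 2, and configs violating their invariants all error
  before computation, naming the offender.
- Proteins with no unique peptide are excluded from the matrix and
  reported, not silently dropped.
- Report tables are written with 17 significant digits so that writing and
  re-reading is lossless; the run-log contains no timestamps, making
  pipeline outputs byte-identical across re-runs on the same inputs.
- All randomness in the simulator flows from one integer seed.

# Problem sizes used by the test and acceptance runs

Unit tests run on 40–120-protein simulations; the calibration and
spike-recovery studies use the full default design (1500 proteins, 9
runs), with 20 simulation seeds pooled for the power study and a
$10^6$-draw Monte-Carlo oracle for the studentized range — sizes chosen so
the whole suite completes in a few minutes while leaving Monte-Carlo error
well below the margins being tested.

# Known limitations

- Total-sum normalization is biased when regulation is heavy and
  asymmetric; the median-ratio option mitigates but the package
  deliberately mirrors the reproduced workflow's normalization by default.
- Strictly-unique-peptide roll-up discards shared-peptide information and
  can lose proteins entirely (they are reported as excluded).
- The cascade's vehicle criterion uses non-significance of the vehicle
  contrast, which rewards noisy vehicle measurements; the strict vehicle
  band exists to counteract exactly this, but both depend on $n = 3$
  group sizes being honest.
- No multiple-testing correction is applied by design; the emitted BH
  column should be consulted when the strict criteria are loosened.
- The studentized-range integration targets $10^{-4}$ accuracy; p-values
  far into the tail (say below $10^{-6}$) are reported as computed but
  their relative error is not controlled at that depth.
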