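---
title: "Methods: histomolecular risk classification of endometrial carcinoma"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: histomolecular risk classification of endometrial carcinoma}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(endorisk)
```

# Scope and data model

`endorisk` models one patient as an 18-column record (`cohort_columns()`):
clinicopathologic profile (histotype, two-tier grade with FIGO G1–G2 mapped
to *low* and G3 to *high*, myometrial invasion in three tiers *none/<50%/≥50%*,
three-tier LVSI *absent/focal/substantial*, nodal status, FIGO stage IA–IVB,
residual disease), marker panel (p53 IHC pattern, four MMR proteins, POLE
status or raw variant calls), and disease-free survival follow-up. Missing
values are always explicit sentinels (`unknown`, `not_done`, `not_tested`);
nothing is imputed. Stage is stored as recorded and invasion is an
independent field used only by rules that need it; the one cross-field
invariant enforced at validation is that residual disease requires stage
III–IVB. Coarse stage input `IV` resolves to `IVA` unless the residual/
distant-disease flag marks `IVB`, so that coarsely reported data load while
the 2020 rules can still distinguish III–IVA (± residual) from IVB.

# Molecular classification

The four TCGA-surrogate subgroups are assigned by the fixed diagnostic
hierarchy POLEmut ≻ MMRd ≻ p53abn ≻ NSMP. The marker interpretations are:

* **p53**: overexpression, null pattern and cytoplasmic staining are all
  mutant-like (*abnormal*); only the wild-type pattern is normal.
* **MMR**: loss of any one of MLH1/PMS2/MSH2/MSH6 is *deficient*. An
  untested protein with no loss elsewhere leaves the status undetermined —
  the classifier then refuses rather than guesses (`assign_subgroup()` raises
  "insufficient markers").
* **POLE**: calls are first filtered for analytic validity — VAF ≥ `vaf_min`
  (default 0.05, the "at least 5%" criterion read inclusively) and alt reads
  on both strands — then a tumor is POLEmut if any retained call is a
  whitelisted exonuclease-domain hotspot in a covered exon (default 9–14).

The default whitelist holds the eleven canonical hotspots
(P286R, V411L, S297F, S459F, F367S, L424I, M295R, P436R, M444K, D368Y,
A456P). This is a deliberate simplification of full pathogenicity scoring
schemes (which also weigh recurrence counts and tumor mutational burden):
membership in the whitelist is the whole criterion. Laboratories using
extended curation can override the whitelist via
`pole_ruleset()`/`read_pole_ruleset()`; with the default list, rare
non-hotspot pathogenic variants will be under-called.

Multiple-classifier tumors (≥ 2 positive markers) are resolved by the
hierarchy but keep their complete `classifier_profile`, so downstream audits
(for example of the triage blind spot, below) remain possible.

# Risk stratification engines

Both systems are ordered rule lists over the same five classes
(low, intermediate, high-intermediate, high, advanced/metastatic), evaluated
advanced → … → low with first-match-wins. This precedence convention makes
overlap resolution explicit and testable: the test suite enumerates the full
clinicopathologic grid (6 histotypes × 2 grades × 6 stages × 3 invasion
levels × 3 LVSI tiers × 2 residual states, plus the 4 subgroups in known
mode) and checks totality and uniqueness. Rule ids are stable and mirrored
with prose conditions in the versioned resource
`inst/rules/risk_rules.yaml`; `fired_rule` in every assignment refers to
those ids. The YAML file is the inspectable reference; the executable
predicates live in the package code under the same ids.

Key semantic differences encoded:

* **LVSI**: 2016 binarizes (focal = positive); 2020 counts only substantial
  LVSI. Hence a low-grade stage IA tumor with focal LVSI is
  high-intermediate under 2016 but low under 2020 — one of the main drivers
  of downward migration.
* **2020 molecular overrides** (stage I–II only): POLEmut → low risk,
  including high-grade and stage II tumors; p53abn with myometrial invasion
  → high risk, p53abn stage IA without invasion → intermediate. MMRd and
  NSMP follow the clinicopathologic rules. Stage III/IV disease is high risk
  or advanced/metastatic regardless of subgroup, which is also why the
  triage algorithm need not sequence it.
* **Stage II MMRd/NSMP** classifies high-intermediate. Published summaries
  are ambiguous between intermediate and high-intermediate for these tumors;
  the cross-tabulation evidence (seven 2016-high patients appearing in the
  2020 high-intermediate column) supports high-intermediate, and that is
  what the engine does.

**Grid closure.** Two covariate combinations are clinically degenerate but
must still classify for the engines to be total: non-endometrioid stage
IB–II with recorded invasion *none* (stage IB is defined by deep invasion),
and analogously p53abn stage IB–II without invasion. Both classify *high*,
the class they would occupy with the invasion their stage implies. Real
records never hit these cells; enumeration tests do.

# POLE-sequencing triage

MMR and p53 IHC are universal. The triage exempts (i) stage III/IV —
class independent of subgroup — and (ii) clinicopathologic low-risk patients
(2020 rules without molecular data), whom POLE cannot down-stage further.
All remaining patients are tested; each satisfies at least one of
*non-endometrioid histotype, high grade, substantial LVSI, stage IB–II*, and
the decision record lists every satisfied criterion.

For the concordance audit, an unsequenced POLE is *assumed wild-type* (and
recorded as assumed): `evaluate_triage()` compares each patient's 2020
known-mode class under full testing with the class under triaged testing.
Exhaustive enumeration over the grid × all 8 marker combinations shows
discordance is confined to clinicopathologic low-risk tumors carrying p53abn
together with a hidden pathogenic POLE mutation — and among those, only the
MMR-proficient ones, because a concomitant MMR loss masks p53abn in the
triaged call and both routes then agree on a low-risk class. The audit
quantifies this blind spot; whether such stage IA low-grade p53abn cases
should be sequenced anyway is a clinical policy question the package does
not decide.

# Cohort statistics

* **Migration**: 5×5 cross-tabulations in fixed class order; "down" means
  the column-system class is strictly lower on the scale than the
  row-system class (direction convention matches the reallocation diagrams
  of the development study).
* **Association tests**: Pearson χ² for categorical covariates, switching to
  Fisher's exact test when any expected cell is below 5 (the threshold is a
  `fisher_threshold` argument); Kruskal–Wallis for numeric covariates;
  two-sided p-values. Which exact/asymptotic choice a given published table
  used is typically unstated, so tests against published p-values assert
  order of magnitude, not equality.
* **Survival**: disease-free survival only (any recurrence is an event;
  overall survival is out of scope). Kaplan–Meier product-limit curves and
  the k-group log-rank test are computed through the `survival` package with
  the standard hypergeometric variance for ties and no continuity
  correction. The test suite cross-checks the log-rank p-value against a
  10,000-shuffle permutation null and the KM estimator against empirical
  survival on uncensored samples.

# The synthetic-cohort generator

`cohort_spec()`/`generate_cohort()` emulate the 211-patient consecutive
development cohort whose summary tables ship in
`reference_cohort_tables()`:

* subgroup prevalences 7.6 / 32.2 / 20.9 / 39.3% (POLE/MMRd/p53abn/NSMP);
* per-subgroup conditional distributions of histotype, grade, depth, LVSI,
  nodal status and stage equal to the published conditional frequencies
  (e.g. P(serous | p53abn) = 19/44, P(high grade | p53abn) = 43/44);
* multiple-classifier rates 1, 4, 9 and 2 per 211 (POLE∩MMRd, POLE∩p53abn,
  MMRd∩p53abn, triple), injected so that generated marker panels re-classify
  exactly to the drawn subgroup under the hierarchy;
* recurrence: exponential times with a monthly hazard per 2020 known-mode
  risk class, default (0.001, 0.003, 0.006, 0.009, 0.030)/month — strictly
  increasing by construction and calibrated to give roughly 13% recurrence
  at a median follow-up near 22 months under the default censoring (monthly
  exponential with median 22 months, capped at 120 months).

Free parameters the published tables do not pin down, chosen once: the
focal:substantial split of LVSI-positive tumors defaults to the cohort-wide
66:75 ratio; the fraction of <50%-invasion tumors with no invasion at all is
0.2 (a realistic share of endometrium-confined disease); stage III/IVA
tumors carry residual disease with probability 7/50 so that about 7/211
patients land in the advanced/metastatic class; coarse stage IV resolves to
IVA. Depth of invasion is kept coherent with stage I definitions (IA < 50%,
IB ≥ 50%).

**What the generator does not emulate.** Covariates are drawn independently
within subgroup, because only subgroup-conditional marginals are published;
real cohorts correlate stage, grade, LVSI and histotype positively. One
visible consequence: the expected clinicopathologic low-risk mass under
independence is ≈ 28% of patients rather than the 39% observed in the
development cohort, so the expected synthetic POLE-triage reduction is
≈ 52–54% rather than the 62.6% obtained from the published counts
(`triage_accounting()` reproduces the latter deterministically). Passing
tests on synthetic cohorts therefore demonstrate the correctness and
internal consistency of the pipeline — closed-loop marker/subgroup
consistency, accounting identities, monotone hazard recovery — not
distributional fidelity of joint covariate structure. Copula-style
dependence modelling is deliberately out of scope.

**Published-table reconciliation.** The development cohort's printed
2016-vs-2020-known cross-tabulation is internally inconsistent by one
patient (cells sum to 212; the intermediate column to 19 against a printed
marginal of 18). The five off-diagonal cells are attested three times over
(the itemized reallocation narrative and its stated totals of 69 changed,
61 down, 8 up), so `reference_cohort_tables()` keeps them as reported and
reduces the high-intermediate diagonal from 14 to 13, making the grid sum
to n = 211. The companion unknown-vs-known cross-tabulation is consistent
as published and is stored verbatim.

# Numerical and engineering choices

* VAF threshold boundary is inclusive (≥ 0.05); whitelist matching is
  case-insensitive and tolerates a `p.` prefix.
* All rule evaluation is vectorized over the cohort, so exhaustive-grid
  tests (5,184 known-mode cells) and large simulations run in seconds.
* Determinism: `generate_cohort()` is a pure function of its spec and seed;
  the CLI writes the resolved configuration (including the rule-table
  version) next to every output.
* Problem sizes in the test suite are chosen to keep the full run near
  twenty seconds while leaving no property under-powered: exhaustive grids
  wherever the domain is finite; n = 50,000 for prevalence recovery
  (±0.01 against the configured probabilities); n = 1,000 for the low-vs-high
  log-rank separation (p < 10⁻⁴); 10,000 permutations for the log-rank
  calibration check.

# Known limitations

* Whitelist-only POLE pathogenicity (no recurrence/TMB scoring, no variant
  database lookup).
* No MLH1 promoter methylation, MSI molecular testing, or Lynch-syndrome
  workflow; no PTEN/Ki67, no adjuvant-therapy recommendation output; no
  Cox regression or competing risks; no FIGO 2023 restaging.
* The risk engines implement the two European systems as reconstructed rule
  tables validated against published reclassification patterns; sites with
  local deviations should review `risk_rule_table()` before relying on
  `fired_rule` semantics.
* Synthetic cohorts are structurally faithful but covariate-independent
  within subgroup (see above); do not use them to estimate joint-structure
  quantities such as realistic triage reduction rates.
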