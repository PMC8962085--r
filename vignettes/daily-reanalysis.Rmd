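---
title: "Methods: variant triage and daily knowledge-base reanalysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant triage and daily knowledge-base reanalysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(varitriage)
```

## The problem

A third to a half of patients with neurodevelopmental delay who undergo
proband-only exome sequencing receive a molecular diagnosis at first
analysis. Much of the remainder is not undiagnosable in principle: the
causal variant is sitting in the data, waiting for the field to describe
the gene-disease relationship, reclassify the variant, or for the
clinician to submit the phenotype term that makes the match obvious.
varitriage models the machinery that closes this gap *prospectively*:
instead of scheduling a manual reanalysis every year or two, the whole
undiagnosed cohort is re-evaluated every day against whatever changed in
the knowledge base the previous day.

The package implements four interlocking components: an ACMG/AMP
evidence engine, a phenotype-similarity scorer over the Human Phenotype
Ontology (HPO), a report-triage rule set, and the daily diff-driven
reanalysis loop, plus a synthetic cohort generator that makes the loop
testable end to end without access to OMIM, ClinVar or patient data.

## Evidence engine

`evaluate_criteria()` maps structured evidence onto criterion
assignments at *applied* strengths, and `combine_criteria()` folds the
assignments into the five-tier classification (P, LP, VUS, LB, B) with
the standard combining table. Two deliberate simplifications:

* **PVS1** uses a condensed three-way switch: very strong when the
  transcript is predicted (or not known to escape) nonsense-mediated
  decay, moderate when it escapes. The full loss-of-function decision
  tree is out of scope; the switch is the seam where it would plug in.
* **PM2** is applied at *supporting* strength by default, following
  current Sequence Variant Interpretation practice, with
  `acmg_config(pm2_strength = "moderate")` restoring the original
  guideline weighting. The frequency ceilings are 1e-5 for dominant and
  X-linked conditions and 1e-4 for recessive ones; BA1 fires above 5%
  and short-circuits everything else, BS1 above a configurable maximum
  credible frequency (default 1%). All thresholds live in one
  `acmg_config()` object.

Reputable-source codes (PP5/BP6) are disabled by default — database
assertions instead feed PS1 (same change asserted pathogenic).
The combining table reads counts as "at least", never inspects the
criterion code except the stand-alone benign code, and resolves
simultaneous pathogenic- and benign-side qualification — or neither —
to VUS. The test suite checks the implementation against an independent
rule-list evaluator over every multiset with up to three criteria per
strength level, and checks monotonicity: adding pathogenic evidence
never moves a call toward benign (with the conflict state pinned at
VUS), and vice versa.

## Symptom similarity

The similarity between a patient's HPO term set and a disease's
annotation profile is an asymmetric best-match average of Lin
similarities, scaled to 0-10:

$$\mathrm{score}(P, D) = \frac{10}{|P|}\sum_{a \in P}\max_{b \in D}
  \frac{2\,IC(\mathrm{MICA}(a,b))}{IC(a) + IC(b)}$$

with information content $IC(t) = -\ln\big((n_t + 1)/(N + 1)\big)$,
where $n_t$ counts the diseases annotated to $t$ or a descendant and
$N$ is the corpus size. Add-one smoothing keeps leaf ICs finite on tiny
corpora; the root has IC 0 and contributes nothing. A score of 10 means
every patient term has an exact informative counterpart; terms in
disjoint branches contribute 0. The operating threshold — a disease
"fits the phenotype" when the score is at least 5 — corresponds to a
mean term-level similarity of 0.5.

The exact formula used by the production system this package models is
unpublished; the asymmetric patient-to-disease direction (how much of
the *patient's* presentation the disease explains) and the 0-10 scale
were chosen so that the published flagging threshold of 5 keeps its
meaning on a bounded scale. This is the largest fidelity gap in the
package and the scorer is deliberately pluggable behind
`similarity_score()`.

## Report triage

`triage_case()` evaluates each gene-disease entry implicated by a
patient's classified variants and takes the most conclusive outcome:

* **positive** — in a fitting, OMIM-registered entry: one het/hemi P or
  LP variant (dominant, X-linked, or digenic entries); for recessive
  entries a homozygous P/LP, two P/LP potential compound heterozygotes,
  or a P/LP with a VUS carrying **two or more** moderate pathogenic
  criteria;
* **inconclusive** — a single het/hemi VUS in a fitting dominant or
  X-linked entry; recessive P/LP + VUS with at most one moderate
  criterion; multiple recessive VUS; any P/LP in a
  literature-candidate (not yet OMIM-registered) gene; or a P/LP whose
  phenotype fit is below threshold, pending additional phenotyping;
* **negative** — otherwise.

Design choices where the published rules were open:

* The source rules leave a VUS with exactly one moderate criterion
  unassigned ("two criteria" qualifies as positive, "less than one" as
  inconclusive); a count of one routes to inconclusive, the
  conservative reading.
* Phenotype fit is nowhere quantified for P/LP variants; the package
  reuses the same threshold of 5, overridable via
  `acmg_config(fit_threshold=)`, so there is exactly one tunable
  notion of fit. When no score is computable (no phenotype data), the
  fit requirement is assumed satisfied rather than blocking a report.
* Entries flagged *digenic* (parsed from the diagnosis name in the
  packaged fixture) accept a single heterozygous P/LP like a dominant
  entry. This is required by the one digenic condition in the packaged
  cohort, where a single heterozygous pathogenic variant was reported
  as diagnostic despite the entry's recessive label.
* Dominant-and/or-recessive entries are tested under both rule sets and
  the more conclusive category wins. Dual diagnoses are supported: all
  qualifying entries are reported.
* X-linked entries accept heterozygous females and hemizygous males
  alike; dominant/recessive subtypes of X-linked inheritance are not
  distinguished beyond the entry's tag.

Secondary findings (`flag_secondary_findings()`) annotate P/LP variants
in a configured gene list; they never change the report category.

## The daily loop

`diff_snapshots()` compares consecutive dated knowledge-base snapshots
on three channels: gene-disease entries (keyed on gene + disease id; any
field change counts), variant assertions (keyed on the normalised
`GENE|TRANSCRIPT|c.` key), and allele frequencies. Frequency updates are
recorded in the delta but only mark a gene as *affected* when they cross
a criterion threshold bin (the PM2/BS1/BA1 boundaries) — a frequency
drifting inside one bin cannot change any criterion call, and ignoring
such churn keeps the daily queue meaningful.

`daily_run()` re-evaluates the variants of eligible (undiagnosed) cases
in affected genes and emits a `ReclassificationEvent` when a variant
newly reaches P or LP, or when a VUS scores at or above the similarity
threshold and has not been flagged before under the same evidence state.
Review decisions (`record_review()`) feed a ledger: an *excluded*
variant is suppressed exactly while its evidence fingerprint — a
canonical string over its assertions, its gene's entry fields, its
frequency bin and the patient's term set — is unchanged, and re-surfaces
as soon as any component changes. Confirmed decisions (or every event,
in simulation mode) refresh the case report; once positive, a case
leaves the loop permanently. Phenotype updates submitted later rescore
similarity and can flag a VUS with trigger `phenotype_update`.

Re-evaluation is scoped to delta-touched genes for efficiency; a
`full_scan` mode re-evaluates everything and the test suite uses it to
prove the scoping loses no events. Reruns of the same day with the same
delta and ledger emit nothing (idempotence).

`cohort_metrics()` summarises a run: newly reclassified variants and
distinct patients per day (over days with at least one event), the
cumulative diagnosed curve, and the interval from each case's first
report to its confirming event in years (365.25 days per year).

## Synthetic cohorts

The generator (`simulation_config()`, `generate_cohort()`,
`generate_kb_timeline()`, `replay()`) emulates the study conditions at
desk scale:

* gene-disease discoveries arrive as a Poisson process at 250/year and
  variant assertions at 9200/year, the field's reported pace; the
  causal entries of planted-but-undiscovered patients are assigned to
  discovery events so each appears in the knowledge base exactly on its
  discovery date (discovery is a property of the disease entry, shared
  by all its carrier patients);
* phenotype sizes target 8.6 ± 4.6 HPO terms, the cohort-typical load;
  plantable patients draw their terms from their disease profile, with
  configurable dropped-term and added-noise rates (defaults: drop 0,
  add Poisson(2) unrelated terms — enough to keep scores informative
  without pushing planted cases below the flagging threshold);
* the ontology is a deterministic balanced four-level tree of 199
  synthetic terms with a 50-disease corpus; it reproduces the *graph
  shape* the scorer needs, not the real ontology's depth or annotation
  skew;
* inheritance modes are sampled at field-typical proportions (70%
  dominant, 19% recessive, 9% X-linked, 2% both), with recessive
  causal variants planted homozygous and truncating so the evidence
  engine can call them without parental data;
* one random stream per concern (cohort, timeline, noise), derived from
  the single mandatory seed, so changing one knob does not reshuffle
  the others.

What passing replays show: the loop recovers every planted diagnosis on
exactly its discovery day (recall 1.0, zero anticipation, checked at
200 patients over a two-year timeline), and patients enrolled after the
discovery wave are diagnosed at initial triage, reproducing the
shorter-interval-for-later-enrolment effect qualitatively. What they do
not show: real-data messiness — phenotype vocabularies drifting across
clinics, frequency spectra, genes with conflicting assertions, or the
cohort-scale diagnostic yields and daily-event averages of the
motivating study, which depend on its non-public patient data and are
deliberately out of scope.

## Numerical and degenerate-input choices

* HGVS parsing strips all whitespace first (published tables typeset
  spaces around ">"); unparseable strings are kept with consequence
  `other`, never dropped. Coordinates are 1-based coding positions; no
  3'-shifting or genomic normalisation is attempted, and the c. string
  is byte-preserved inside variant keys. Insertions of unknown length
  are `other`; delins net change is inserted minus deleted length.
* An intron offset of 0 is invalid; offsets of magnitude one or two are
  canonical splice, anything else splice region.
* Ontology construction rejects cycles, multiple roots and annotations
  to unknown terms; unknown patient terms are dropped with a warning
  (clinical inputs are messy), and an empty patient set after dropping
  is an error.
* Disease ranking breaks score ties by disease id ascending, and triage
  sorts variants by gene and key before rule evaluation, so results are
  invariant to input order.
* A calendar day with no snapshot is a no-op; deltas must end on the
  run date, and out-of-order snapshots are an error.

## Problem sizes

The shipped tests run the combining-table enumeration over 8192
multisets, property loops of 20-300 random cases per invariant, and
synthetic replays at 12 patients/120 days (unit level) and 200
patients/730 days (acceptance level). These sizes were chosen so the
properties are exercised well past their edge cases while the whole
suite stays comfortably interactive.

## Known limitations

* The evidence engine automates what the modelled production system
  resolved with a final manual review by medical geneticists; manual
  overrides are representable only as ledger decisions.
* PS3/BS4-style functional and segregation evidence beyond a single
  cosegregation flag, Bayesian point-based combining, CNV and
  mitochondrial analysis, and trio logic are out of scope.
* The similarity scorer is a reasoned reconstruction, not the original
  formula (see above).
* Eligibility for the daily loop treats candidate-gene P/LP
  inconclusive reports as "no clinically significant variant", since
  such cases demonstrably were diagnosed by later registration; a
  stricter reading would exclude them.
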