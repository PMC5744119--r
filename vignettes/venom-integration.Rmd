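---
title: "Integrating a venom gland transcriptome with an intact-mass venom proteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Integrating a venom gland transcriptome with an intact-mass venom proteome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(venomics)
```

## The problem

Scorpion venoms are mixtures of hundreds of peptides and proteins: ion
channel toxins constrained by disulfide bonds (DBPs), non-disulfide-bound
host-defense peptides (NDBPs and relatives), enzymes, protease inhibitors
and families of unknown function. Characterizing a venom from a species that
is hard to collect proceeds along two largely independent measurements — an
assembled and annotated venom gland transcriptome, and a whole-venom LC-MS
intact-mass fingerprint — that must then be reconciled. `venomics`
implements that reconciliation as a set of small, testable stages:

1. **Triage**: decide which annotated transcripts plausibly code for venom
   components.
2. **Classification and nomenclature**: place candidates in a family/subtype
   taxonomy and assign reproducible systematic names.
3. **Theoretical mass**: compute the expected mass of each predicted mature
   peptide.
4. **Fingerprint curation**: strip adduct/modification satellites from the
   deconvolved intact-mass list.
5. **Mass matching**: pair theoretical and experimental masses.
6. **Digestion and coverage**: validate identifications from bottom-up
   (tryptic) LC-MS/MS by sequence coverage.
7. **Physicochemical profiling**: helical-wheel descriptors for the
   host-defense peptides.

## Triage and classification

A transcript is a venom-component candidate if any of three evidence classes
supports it: similarity to a previously reported EST from the same species,
one of a configurable list of venom-associated protein domains
(`default_venom_domains()`), or similarity to a curated animal-toxin database
entry. The only threshold that matters at this stage is the e-value cutoff
of the upstream similarity searches, 1e-4 by default (`triage_thresholds()`);
triage is deliberately monotone — more evidence can never un-flag a
transcript.

Classification applies an *ordered* keyword rulebook
(`default_rulebook()`) to the best annotation descriptor; the first matching
rule wins, which makes the outcome deterministic and the rulebook auditable
as plain data. Anything unmatched falls through to the catch-all class
(Oth/Und). The systematic name is species code + family code + subtype code
+ two-digit serial (e.g. `TatNaTAlp01`). Serials are assigned in ascending
`transcript_id` order — the one ordering that is reproducible without
expression data — and sequences that exactly match a registry of published
names keep the original name, so database duplications are avoided. The
two-digit serial is a hard limit by design; widening it is an explicit
configuration decision, not a silent format change.

Family tallies roll NaT, KTx and CaT up into a single DBP group and report
the Oth subtypes (La1, CRI, Und) individually, the convention used when
summarizing venom gland transcriptomes.

## Theoretical masses

`peptide_mass()` sums residue masses plus one water, on both the
monoisotopic and the average scale. The default — average mass, free
cysteines, free C-terminus — reproduces what ProtParam reports for a mature
sequence, which is the convention under which published theoretical masses
of predicted venom peptides are produced. C-terminal amidation
(−0.98402 Da mono) and disulfide bonds (−2.01565 Da mono per bond) are
opt-in corrections, because published tables are generally uncorrected; the
calcin example in the packaged data (theoretical 3788.48 Da vs experimental
3787.85 Da) is consistent with uncorrected output, so uncorrected is the
default and the corrections are flags.

Amidation is predicted from the precursor itself: NDBP-type precursors end
the mature peptide at a glycine-led motif (G, GK, GR, GKR, GRR) opening the
C-terminal propeptide. `detect_amidation()` accepts both range conventions
(donor glycine inside or outside the mature range) and reports which one it
applied.

Percent identity between pre-aligned sequences is truncated — not rounded —
to one decimal. Truncation never overstates identity and is the only
one-decimal convention under which "reports 100.0 exactly when identical"
holds; it also reproduces the published 96.5% for 2 substitutions in 58
residues.

## Fingerprint curation

The deconvolved intact-mass list mixes real components with satellites:
sodium/potassium/ammonium adducts, oxidations and deamidations (heavier than
their parent), dehydrations and CO losses (lighter). `artifact_filter()`
removes, for every matching pair, the peak on the *derived* side of the rule
and logs the removal; a derived peak may itself parent further satellites,
so double-adduct chains collapse onto the true component. Three numerical
choices matter:

* **Mass-kind boundary.** Deconvolution reports isotope-resolved
  (monoisotopic) masses only below 3000 Da; at and above 3000 Da masses are
  average. The boundary value 3000.00 itself is assigned to *average*,
  since the stated rule is "below 3000 Da is monoisotopic".
* **Tolerances.** 0.02 Da for mono-kind pairs and 0.5 Da for average-kind
  pairs by default, reflecting the different precision of the two mass
  scales; both configurable, as no single value suits all instruments.
* **Bin locality.** Satellites co-elute with their parent, so only peaks in
  the same retention-time bin are compared by default
  (`same_bin_only = TRUE`).

The fixed-point iteration is capped at 10 passes with a loud warning — a
guard against pathological chains, never hit on realistic data.

## Mass matching

`match_masses()` compares each theoretical entry against fingerprint peaks
of the same mass kind only (a monoisotopic value must not be compared to an
average one), takes the nearest peak within tolerance, and breaks ties
toward the smaller absolute delta, then the lower peak mass. The default
tolerance is 1.0 Da: the largest delta among the five published
transcriptome–proteome matches in the packaged data is 0.90 Da, so 1.0 Da
reproduces the published table exactly while remaining a sensible width for
average-mass deconvolution. One theoretical entry yields at most one match,
but a peak may serve several entries — isobaric peptides exist and the
published tables make no exclusivity claim.

## Digestion, PSM filtering and coverage

`tryptic_digest()` cleaves after K/R with the classic proline suppression
(toggleable) and enumerates all unions of up to `max_missed + 1` adjacent
fragments (two missed cleavages by default, matching common search-engine
settings). PSM acceptance is strict-greater-than on score (> 25) and
inclusive on fragment support (>= 2); scores are engine-specific and are
treated as dimensionless pass-through values. FDR strata (strict 0.01 /
relaxed 0.05) are consumed as labels — decoy-based FDR estimation belongs to
the search engine. Coverage is the union of all exact occurrences of the
accepted peptides in the parent, as a percentage of parent residues;
peptides that do not occur are logged, not errors. Fixed
carbamidomethyl-cysteine and variable Met-oxidation/amidation mass variants
(at most 3 variable sites per peptide) are available through
`peptide_mass_variants()`.

## Physicochemical descriptors

`physchem_profile()` reports length, mean hydrophobicity on the
Fauchère–Pliska scale (the HeliQuest default; alternative scales are a
plain named vector away), the Eisenberg hydrophobic moment at 100° per
residue (configurable for other helix geometries), and net side-chain
charge counting R/K as +1 and D/E as −1 with histidine and the termini
neutral. The no-termini charge convention is recorded on the output because
published tables rarely state it. Published descriptor tables for these
peptides cannot be regression-tested — the mature sequences are not printed —
so this module is validated against closed forms (single residue,
homopolymer geometric sum, phase-shift invariance, the |c|-scaling law)
rather than against table values, and the table layout is reproduced
format-level only.

## Synthetic data: what it does and does not show

The generators in `make_transcript_fixture()`, `make_fingerprint_fixture()`
and `make_psm_fixture()` are pure functions of a `fixture_spec()` and its
seed. The default transcript composition is the study condition the package
models: 160 venom transcripts (41 DBP, 17 HDP, 55 enzymes, 7 La1-like,
24 protease inhibitors, 8 CRISPs, 8 undefined) among 40 background
transcripts; DBP subtypes follow the published subfamily proportions
(13 NaTx, 21 KTx, 7 CaTx). Residue composition is biased per class
(cysteine-rich DBPs, cationic/hydrophobic NDBPs) for realism only —
correctness never depends on it. Every fixture ships its ground truth
(which transcripts must be flagged, which fingerprint peaks are planted
satellites, what coverage each parent must show), so the tests assert exact
recovery rather than plausibility.

What passing these tests shows: the bookkeeping — triage logic,
classification determinism, satellite-removal direction, digest
combinatorics, coverage arithmetic — is correct under controlled inputs.
What they do not show: robustness to real annotation noise (conflicting
descriptors, chimeric assemblies), to deconvolution errors beyond the
modeled jitter, or to search-engine score pathologies. The fingerprint
generator plants at most one satellite per base peak and spaces bases at
least 100 Da apart; real fingerprints can contain genuinely ambiguous
near-isobaric components, which the filter will then resolve by its
deterministic tie rules rather than by chemistry.

Problem sizes in the test suite (200-residue digests against an exhaustive
interval oracle, 99–200-peak fingerprints, 20 generator seeds for
satellite-recovery, 1000 random peptides for the mass laws) were chosen so
that the brute-force oracles stay exact and enumerable.

## Known limitations

* The triage stage consumes upstream similarity/domain evidence; it does
  not run BLAST, Pfam, SignalP or ProP, and cannot rescue transcripts those
  tools missed.
* The artifact filter models mass relationships only; it has no access to
  isotope envelopes or charge states, so a real component sitting exactly
  one rule-delta from another co-eluting component will be removed.
* Intact-mass matching is a necessary-but-weak identification: a 1.0 Da
  match on an average mass is consistent with many sequences. Coverage from
  fragmentation data is the stronger evidence and is handled separately.
* The nomenclature assumes at most 99 novel transcripts per subtype per
  species; beyond that the naming scheme itself is the limiting convention.
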