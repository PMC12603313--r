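---
title: "Methods: miRNA-guided auxin signalling module discovery"
author: "miraux"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: miRNA-guided auxin signalling module discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(miraux)
```

# Scope and model

`miraux` reconstructs, as a tested pipeline, the inference route from a plant
transcriptome plus small-RNA, degradome and expression data to (a)
functionally curated auxin nuclear-signalling proteins — TIR1/AFB F-box
receptors and ARF transcription factors — and (b) degradome-confirmed
miRNA–target modules with precursor validation and expression analytics.
Every stage is a deterministic rule with named thresholds; nothing is fitted.
This vignette records the procedures, the parameters that matter, the design
decisions that were genuinely open, and what the validation does and does not
establish.

# Sequence layer

**ORF finding.** Transcripts are stored in the DNA alphabet (U→T on ingest;
the normalisation is recorded in the reader's documentation). A complete ORF
begins `ATG`, ends at the first in-frame stop, and encodes at least `min_aa`
residues (default 50 — the classifiers target proteins of hundreds of
residues, and the floor removes spurious micro-ORFs). All ORFs on both
strands are found; mRNA-level stages use the + strand and, when several
complete ORFs coexist, classification takes the longest and reports the
count of alternatives (`n_orfs`) rather than silently choosing. Codons
containing `N` translate to `X` and are never start or stop codons.
Coordinates are 0-based half-open internally and 1-based inclusive in
user-facing reports, matching residue-numbering conventions such as Lys-410.

**Pairwise alignment.** Residue anchoring uses Needleman–Wunsch global
alignment (BLOSUM62, gap open 10, extend 1; a gap of length $L$ costs
$10 + L$). The alignment is a means of transferring reference numbering, not
a phylogenetic statement; identity is computed over columns where both
sequences have a residue.

# Protein classification

Domain calls replace profile-HMM scans with identity-threshold alignment
against packaged reference domains. This keeps every call deterministic,
self-contained and tunable; the thresholds are configuration, because
"high-quality domain" is a convention, not a measurement:

| key | default | role |
|---|---|---|
| `fbox_min_identity` | 0.35 | F-box presence (identity over the reference F-box span) |
| `lrr_min_coverage` | 0.80 | LRR ring completeness (aligned fraction of the LRR span) |
| `dbd_max_mismatch` | 1 | tolerated literal mismatches in `SxxxxHGxxSxxR` |
| `dd_min_identity` | 0.35 | dimerisation-domain presence |
| `pb1_min_identity` | 0.30 | PB1 region presence |
| `q_min`, `pg_min`, `top_k` | 0.10, 0.15, 4 | middle-domain composition rule |
| `md_min_len` | 40 | minimum believable middle domain |

**TIR1/AFB.** The verdict ladder is: no F-box → `rejected`; F-box present
but LRR coverage below threshold → `incomplete` (an unclosed LRR ring cannot
form the auxin docking pocket); otherwise `receptor`. Eleven binding-pocket
residue checks (five ligand-orientation positions — Lys-410, Ser-440,
Gly-441, Ala-464, Phe-465 — and six ligand-selectivity positions — Cys-405,
Ser-438, Leu-439, Ser-440, Ser-462, Arg-489, in AtTIR1 numbering) and three
adenylate-cyclase key positions (the first an Asn) are anchored through the
global alignment. Ser-440 belongs to both pocket sets, so it carries two
checks; editing it flips both, which the sensitivity validation accounts
for. AC substitutions are reported but do not revoke receptor status — they
bear on signalling kinetics, not on receptor identity.

**ARF.** The B3 motif `S-x4-H-G-x2-S-x2-R` is scanned directly with at most
`dbd_max_mismatch` substitutions at the five literal positions, so the
known H→G variant of the ARF17/18 subfamily is detected *and* reported as a
substitution rather than silently accepted or dropped. PB1 typing checks the
two interaction faces independently: motif I is the canonical lysine column;
motif II is the acidic OPCA window `D-x-[DE]-x-D` (at most one mismatch at
the three literal positions). We adopt the convention that *type I* means
OPCA-only and *type II* means lysine-only, and always surface both boolean
flags so the naming cannot corrupt downstream logic. A detected PB1 region
exhibiting neither face is reported as `absent` for architecture purposes
(the region coordinates remain visible).

**Middle domain.** The MD spans from the end of the aligned DBD/DD block to
the PB1 start. When PB1 is absent the right flank is the protein C-terminus:
a strict two-flank rule would make the ARF17/18-like class (DBD+MD, no PB1)
indistinguishable from DBD-only proteins, which is exactly the distinction
the architecture classes need. The composition rule is: *activator* when
Gln frequency ≥ `q_min` and Gln, Ser, Leu all rank in the `top_k` most
frequent residues; *repressor* when Pro+Gly ≥ `pg_min` with Gln below
`q_min`; otherwise *unclassified* — an explicit outcome, never coerced.
Classification depends only on frequencies (scale-invariant), and
frequencies sum to one over the 20 standard residues (`X` excluded).

**Architecture.** The five classes map deterministically from domain flags:
DBD+MD+PB1 → `full_arf`; DBD+MD → `no_pb1` (auxin-independent,
ARF17/18-like); DBD alone → `dbd_only` (can mask AuxRE elements); PB1 alone
→ `pb1_only` (modulates ARF–Aux/IAA polymerisation); no DBD → `no_dbd`. The
off-enum combination DBD+PB1 without an MD maps to `dbd_only` with an
explicit "non-canonical" note; the generator never produces it, and real
data hitting it would be visible in the note.

**References.** The real curated reference proteins are not redistributable
here, so the package ships *synthetic* stand-ins
(`inst/extdata/reference_proteins_synthetic.fasta`): random backbones with
the literature residues planted at the literature positions, plus annotated
F-box/LRR/DBD/DD/PB1 spans. They encode the residue grammar the classifiers
need, not evolutionary context; users with curated references can supply
them via `reference_set(fasta =, config =)`. The three AC key positions are
likewise fixture data, not asserted biology.

# Precursor validation

Folding is a Nussinov-style maximum base-pairing dynamic program
(Watson–Crick plus G:U, hairpin loops ≥ `min_loop` = 3) rather than an
energy-minimisation tool. The trade is deliberate: maximum pairing is
oracle-verifiable by exhaustive enumeration, and the question asked of the
fold — does the mature miRNA sit in the stem of a stem-loop? — is robust to
the energy model for designed constructs. Traceback is deterministic:
prefer leaving the 5′-most base unpaired, then the smallest pairing
partner. Folding operates on a window of `flank` = 150 nt context on each
side of the located miRNA (folding whole transcripts is cubic; windowing
bounds the cost and is configurable up to `max_window`).

A miRNA is *in the stem* when at least `min_paired_frac` = 0.6 of its bases
pair, no base pairs within the miRNA itself, all partners lie on one side
(the opposite arm), and the pairs nest in stem order. The fraction is our
construction — no quantitative criterion exists for "located outside the
stem" — and is surfaced in every output row so users can re-filter.

**A known degeneracy.** Under the maximum-pairing objective, a ~21-nt miRNA
placed wholly inside a hairpin loop can pair arm bases by displacing stem
pairs one-for-one: the pair count is unchanged, and the deterministic
traceback can select the displaced structure. This is a property of the
objective (an energy model would penalise the displaced structure), so
"miRNA in a long loop" is not structurally well-defined ground truth for
this folder. The synthetic negative class therefore plants the miRNA in an
unpaired pyrimidine region outside the stem-loop — the filter's actual
rejection condition — and the wholly-inside-loop geometry is exercised by a
designed short-span example where the loop is genuinely unpaired.

The precursor–miRNA expression filter is Spearman's rank correlation
(average ranks for ties) with a strict `rho > 0.5` pass rule; at the default
study scale, 9 of 21 planted pairs pass, and zero-variance profiles are
flagged rather than passed.

# Target scoring and degradome confirmation

The complementarity penalty follows the de-facto plant small-RNA convention:
per alignment column, Watson–Crick 0, G:U wobble 0.5, mismatch 1, gap 2,
all doubled when the column consumes a miRNA position in 2–13 (5′→3′). A
window insertion is charged with the weight of the next miRNA position —
this tie-down matters because the brute-force oracle must price the same
alignments. Sites with penalty ≤ `max_penalty` = 4.5 are kept; overlapping
windows deduplicate to the minimal penalty. The predicted cleavage position
is the transcript nucleotide opposite miRNA position 10 (1-based from the
miRNA 5′ end), stated in every report to avoid ±1 drift; degradome
positions are 1-based on the + strand.

Degradome confirmation uses the standard category ladder on the tag count
$r$ at the cleavage position: 0 — $r>1$ and unique maximum; 1 — shared
maximum; 2 — above the median of the transcript's nonzero positions; 3 — at
or below it; 4 — $r=1$; no tag, no evidence. The median is over
nonzero-count positions with average-rank ties. These conventions
(penalty scheme, thresholds, category ladder) are re-implementation choices,
not reproductions of any database's precomputed pipeline, and are echoed in
the run report's metadata.

# Expression analytics

FPKM and RPM are the standard per-million normalisations (length-corrected
for transcripts, length-free for small RNAs). Heatmap rows are Z-scored
with the population standard deviation (divisor $n$); constant rows are
flagged and emitted as zeros. For qPCR, technical replicates are averaged
on the Ct scale before ΔCt (the common 2^-ΔΔCt convention); ΔCt normalises
to the reference gene per (group, biological replicate), ΔΔCt to the *mean*
ΔCt of the calibrator's biological replicates — per-replicate versus pooled
calibrator means is genuinely underdetermined, and the choice is recorded
here and in the function documentation. Group comparisons use one-way
ANOVA with Tukey HSD and a compact letter display built by the insertion
method over the significance matrix (groups ordered by decreasing mean);
two groups fall back to a Welch t test. α is 0.05, exposed in
configuration.

# The synthetic-data generator

The generator is first-class, tested code: it produces every input the
pipeline consumes with serialisable ground truth, fully determined by
(seed, configuration).

* **Transcriptome**: decoy transcripts with random codon-structured ORFs,
  plus planted proteins back-translated with a fixed codon per amino acid
  (no codon-usage model — keeps recovery deterministic). TIR1/AFB classes:
  intact reference, C-terminally truncated (60% kept, so LRR coverage falls
  below threshold), AC Asn→Asp edit, randomised F-box. ARF classes
  assemble reference DBD/DD and PB1 segments with generated middle domains
  into the five architectures.
* **Middle domains** are drawn from two Dirichlet families (Gln/Ser/Leu-rich
  versus Ser/Leu/Pro/Gly-rich) over a restricted residue pool of the
  enriched residues plus common fillers. MDs are low-complexity domains, so
  the restriction is biologically reasonable; it also means His and Arg
  never occur in generated MDs, so a planted architecture cannot acquire a
  chance B3 motif. Noiseless mode uses the mean profile exactly.
* **Precursors**: perfect-complement arms (purine 5′ arm, pyrimidine 3′
  arm) around an 8-nt loop inside pyrimidine flanks. The alphabet
  partition makes the planted stem the optimum and keeps spurious
  flank pairings count-neutral at worst. Positive classes place the miRNA
  in either arm (≥ 3 nt from the arm ends, clear of tie-degenerate
  innermost pairs); the negative class places it in an unpaired region
  outside the stem (see the degeneracy note above).
* **Target sites** start from the perfect reverse complement and receive
  substitution edits with arithmetically known penalties; edits are spread
  out, seed region first, because clustered tail edits admit cheaper gapped
  realignments that would make the recorded penalty an overestimate.
  miRNA positions 20–21 are fixed to G so 0.5-unit (G:U) edits always
  exist.
* **Degradome**: a signal peak at each recorded cleavage position plus
  uniform low-count noise positions; the expected category is derived from
  the drawn counts by a literal transcription of the ladder.
* **Expression pairs** plant a target Spearman rho by rank coupling: the
  precursor profile's ranks are the permutation minimising
  |achieved − target| (exact enumeration over all 8! permutations at the
  default n = 8; achieved rho is recorded). Decoys plant near-zero
  correlation (targets uniform in (−0.45, 0.45)) rather than sampling
  independent profiles: with n = 8 the null standard deviation of rho is
  1/√7 ≈ 0.38, so independent decoys would cross 0.5 about 9% of the time
  and the filter's false-positive rate would measure small-n sampling
  noise, not the threshold. This is stated openly: the decoy model
  controls correlation.
* **qPCR**: planted fold changes {0.5, 1, 2, 4} between drought and
  control, 3 biological × 3 technical replicates, Gaussian Ct noise
  (sd 0.1), a constant reference gene at Ct 18 and gene baselines at
  Ct 22.

What the generator does *not* emulate: sequencing error, assembly
artefacts, isoform graphs, codon-usage bias, thermodynamically realistic
secondary structure, and read-level data. Passing the planted-truth
validations therefore demonstrates that the rules are implemented exactly
and are mutually consistent — not that the thresholds are optimal for any
real transcriptome.

# Validation strategy and problem sizes

The test suite validates each algorithm against an independent brute-force
oracle at sizes where enumeration is exact, and every stage end-to-end
against generator ground truth: folding versus exhaustive enumeration on
300 windows of ≤ 14 nt; global alignment and site scoring versus
enumeration on 200 instances each of length ≤ 12; the category ladder
versus its literal transcription on 500 random sparse profiles; recovery of
100 planted precursors (50 positive, 50 negative), 200 planted ARF
architectures, the TIR1/AFB funnel, and 20 penalty-controlled target sites;
100 single-residue edits of the receptor reference each flipping exactly
the checks anchored at the edited position; the strict-0.5 correlation
filter on planted and 500 decoy pairs; qPCR fold recovery bias under the
stated noise model over 500 simulations; Tukey family-wise error on a
1000-run 8-group null; and byte-identical reruns of the orchestrated
pipeline. These sizes were chosen so each check is exact or tightly
calibrated while the whole suite stays interactive.

# Numerical and degenerate-input conventions

Ties in the fold traceback, the motif scan (leftmost best window), top-k
composition ranks (frequency then alphabetical), site deduplication
(penalty, then leftmost, then shortest) and the letter display (means
descending) are all broken deterministically. Degenerate inputs are
explicit outcomes: empty FASTA → empty table; no ORF → empty list;
zero-variance expression → flagged failure; constant Z-score rows → flagged
zeros; missing reference-gene replicates → excluded with a warning; a
cleavage position without tags → evidence absent, never category 4.

# Limitations

The domain calls are identity-threshold alignments to single references,
not profile HMMs: remote homologues below the identity thresholds will be
missed, and the thresholds deserve re-tuning per species. Maximum-cardinality
folding overestimates pairing relative to thermodynamic models
(the `fold_window` hook accepts any window; an external folder can replace
it upstream as long as reports state the engine). Aux/IAA repressors are
annotated pass-through only. miRNA family names are parsed from identifiers
verbatim, with no nomenclature resolution.
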