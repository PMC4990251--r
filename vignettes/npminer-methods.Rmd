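---
title: "Mining neuropeptide precursors from transcriptome assemblies: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining neuropeptide precursors from transcriptome assemblies: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npminer)
```

## The problem

Neuropeptides (NPs) and peptide hormones are short secreted signals excised
from larger precursor proteins. A precursor (preprohormone) carries an
N-terminal signal peptide, one or more peptide units separated by basic
prohormone-convertase cleavage sites (mono-, di- or multi-basic runs of
K/R), and is finished by carboxypeptidase trimming of the exposed basic
residues and, frequently, C-terminal amidation of a glycine donor,
N-terminal pyroglutamate cyclization of Gln/Glu, tyrosine sulfation, and
disulfide formation. Because mature peptides are short and divergent,
they are most reliably discovered *in silico*: translated homology search
of a transcriptome assembly with a curated set of known peptide queries,
followed by inspection of the candidate transcripts for the hallmark
precursor features above.

`npminer` implements that entire procedure as composable, tested R
functions: query curation, six-frame translated search, precursor
annotation, mature-peptide derivation with PTM prediction, family
classification — plus a synthetic transcriptome generator so every stage is
testable without downloads.

## Query curation

`filter_annotation_records()` screens free-text annotation records by
case-insensitive keyword matching: a record is kept when its description
contains at least one include term ("NP", "hormone", "neurohormone" by
default) and no exclude term ("receptor", "hypothetical", ...). Exclusion
always wins, duplicates collapse to their first occurrence. Two matching
details are deliberate:

* short single-word terms (three characters or fewer, e.g. "NP") are
  matched as whole words, so they cannot fire inside longer words such as
  "snp";
* longer terms remain plain substrings, so "hormone" still matches
  "neurohormones".

Whether the original desk procedure matched keyword fields or full
description lines is not determinable from the source material; the
substring-on-description rule is this package's reproducible analogue and
is not asserted to be the original mechanism.

## Translated homology search

`run_search()` emulates a tblastn-style search at desk scale, with exact
rather than heuristic alignment:

* **Six-frame translation** (`six_frame_translate()`) uses the standard
  genetic code via Biostrings; stops render as `*`, N-containing codons as
  `X`, trailing partial codons are dropped.
* **Frames are split at stop codons** and each stop-free segment is aligned
  separately, so an alignment can never cross a stop — mirroring how
  translated-search tools treat translation segments.
* **Alignment** is optimal Smith–Waterman with affine gaps (a gap of length
  *L* costs `gap_open + gap_extend * L`), BLOSUM62 scores, and gap costs
  11/1 — common protein-search defaults; the source procedure did not
  specify them. The dynamic program lives in compiled code; its traceback
  is deterministic (ties prefer the diagonal, then the gap in the target,
  then the gap in the query; the best cell is the first maximum in
  row-major order). The test suite checks the kernel against an exhaustive
  enumeration oracle over all order-preserving residue matchings for short
  random peptides.
* **E-values** follow the closed Karlin–Altschul form
  `E = K m n exp(-lambda S)` with the standard gapped-BLOSUM62 constants
  (lambda 0.267, K 0.041) and the total translated database size as *n*.
  This ranks hits consistently but is plumbing, not a reproduction of
  BLAST's edge-corrected internal statistics — which also depend on the
  original database size. Published E-values from the original search are
  therefore packaged as fixture metadata, not treated as reproducible
  targets.
* **Candidate selection** (`select_candidates()`) keeps, per query, at most
  the three hits with the lowest E-value below 0.01 (both limits
  configurable), merging transcripts hit by several queries with their best
  evidence. The published procedure additionally checked candidates by hand;
  that step is represented by the evidence fields in the report, not
  automated.

`min_alignment_length` (default 8 residues) suppresses spurious micro-hits
from short queries.

## Precursor annotation

`annotate_precursor()` assesses a candidate transcript:

* **ORF choice.** All Met-initiated ORFs in all six frames are enumerated
  (`find_orfs()`); the annotation uses the longest ORF *in the supporting
  hit's reading frame that overlaps the hit span* — the hit defines the
  coding frame, exactly as translated-search practice reads it — falling
  back to the longest ORF overall. Selecting the longest ORF
  unconditionally is wrong surprisingly often: a transcript with a short
  true coding region can contain a longer chance ORF elsewhere.
* **Signal peptide.** `predict_signal_peptide()` is a stated, stand-alone
  heuristic (no equivalence with HMM/neural predictors is claimed): it
  scans cut positions 15–45 and scores each as the mean Kyte–Doolittle
  hydropathy of the preceding 8-residue window, plus a bonus when the
  residues at −3 and −1 relative to the cut are both small (A, G, S, C, T —
  the classical (−3,−1) rule). The call threshold is 1.6 (hydropathy units).
  The bonus defaults to 2.5: signal peptidase's small-residue requirement
  at −3/−1 is close to absolute, while raw hydropathy varies smoothly, so
  the rule must be able to outweigh any all-hydrophobic window (mean KD at
  most ≈4.2–4.5); with a small bonus the scan would systematically cut
  inside the hydrophobic core. Both values were calibrated on the synthetic
  fixtures, where the true boundary is known by construction.
* **Cleavage sites.** `find_cleavage_sites()` scans the mature region for
  maximal K/R runs. The default ruleset is the conservative dibasic subset
  {KR, RR, KK} plus multibasic runs (length ≥ 3), monobasic R off — this
  subset accounts for every flank printed in the packaged fixture table
  (KR, KK, RR, KKR, RRRR all end in an accepted pair). RK is switchable but
  off, since the available material does not resolve whether RK sites were
  accepted. Cleavage is placed C-terminal to the whole run (one site per
  run — carboxypeptidase removes the basics anyway, and one site per run
  avoids zero-length peptides). A dibasic/multibasic site closer than
  `min_peptide_len` (default 3) to the previous kept dibasic/multibasic
  site is suppressed; monobasic sites are exempt from spacing suppression
  in both directions. The exemption is deliberate: a lone Arg must neither
  be suppressed by, nor suppress, a genuine dibasic site (insulin-type
  junctions like `...LASRG·KR·...` place a lone Arg two residues before a
  real KR site), and it makes enabling monobasic cleavage strictly
  additive. Over-short leading segments are instead dropped at excision.

## Maturation

`excise_peptides()` cuts the mature region at the sites and trims each
segment's trailing K/R run, recording it as the removed flank. The entire
trailing run is trimmed regardless of length: carboxypeptidase removes
every exposed C-terminal basic residue, and printed fixture rows include a
six-basic flank (`KRRRKR`) that would otherwise leave a terminal KR on a
"mature" peptide. Dropped segments are retained (flagged) so that
`signal + sum(segment + flank)` reconstructs the precursor exactly — a
conservation property the tests enforce on every processed input.

`apply_terminal_ptms()` then:

* amidates a segment that ended in Gly followed by a removed basic flank
  (the Gly is dropped and the amide flagged). Note an amidated peptide can
  legitimately end in Arg (`...ASRG·KR` matures to `...ASR-NH2`): trimming
  precedes amidation and the amide blocks further trimming;
* flags N-terminal Gln as pyroglutamate (Glu optionally, off by default —
  both cyclize in nature, Gln far more commonly; the switch covers the
  Glu case).

Length reporting uses the trimmed, pre-amidation segment (the convention
under which the packaged NPF-like peptide counts 35 residues), with the
amidated length available separately.

**Tyrosine sulfation** (`predict_tyr_sulfation()`) flags a Tyr when at
least one acidic residue (D/E) lies within two positions. Sulfotyrosines
occur in acidic sequence context; this minimal local rule exactly separates
the marked from the unmarked tyrosines in the packaged fixture peptide and
is documented as a heuristic, not as equivalence with any server.

**Disulfides** (`predict_disulfides()`): the bridge count is
`floor(total Cys / 2)` over the chains — the only quantity used downstream —
and the nested first-with-last pairing is reported as explicitly
low-confidence evidence.

**Insulin architecture** (`detect_insulin_architecture()`): a precursor
whose three peptides are, in order, a B chain (≥2 Cys), a C chain (≤1 Cys)
and an A chain (a CC doublet and ≥3 Cys) is called B-C-A, the classical
insulin precursor organization in which A and B stay bridged and C is
excised.

## Family classification

`classify_family()` applies rules in specificity order — insulin-like
(architecture), vasopressin (Cys at positions 1 and 6 of a 9–16 residue
peptide), GPB5 (a single uncleaved mature region of 80–130 residues with
≥9 Cys, the cystine-knot pattern), pedal/orcokinin (IGxG core motif in a
10–16 residue peptide), NPF (C-terminal RXR(F/Y) amide, or — for divergent
members whose RXRF arginine is substituted — a 30–40 residue peptide with
at least two sulfation-eligible tyrosines) — and returns `unclassified`
with empty evidence when nothing fires. The first match names the family;
all satisfied rules are recorded as evidence with an ordinal confidence.
Rule parameters are data, not code: they load from a YAML profile file
(`family_profiles()`), so thresholds can be adjusted without touching the
classifier. Cross-species conservation claims (alignment figures in the
source material) are out of scope; family rules use within-sequence
patterns only. One packaged insulin fixture contributes only a 6-residue
B-chain fragment explicitly marked partial; a fragment cannot carry the
architecture rule, so that precursor is documented as unclassifiable from
the printed material rather than special-cased.

## Synthetic benchmark

`generate_dataset()` builds transcriptomes with known answers:

* **Precursors** follow the canonical organization: `M` + a hydrophobic
  signal core + `ASA` + repeated (unit + basic flank) blocks. Units come
  from the packaged fixture peptides, one template per family, so synthetic
  tests exercise the same sequences as the fixture tests. The core is
  sampled from {L, V, F}: excluding Ala keeps spurious (−3,−1) motifs out
  of the core, and excluding Ile caps the interior window mean below what
  the true boundary scores, so the generator's boundary is provably the
  argmax of the signal heuristic — the benchmark then genuinely measures
  boundary recovery rather than generator/predictor disagreement. Signal
  lengths are sampled 18–28 residues, 5'/3' UTRs 30–80/60–150 bases —
  typical invertebrate preprohormone geometry.
* **Transcripts** are uniform synonymous-codon back-translations with an
  `ATG` start, `TAA` stop and random UTRs; translating the CDS recovers the
  protein exactly.
* **Decoys** are an even split of dinucleotide-shuffled copies of precursor
  transcripts (hard decoys preserving local composition, via a random
  Eulerian-walk shuffle) and uniform-random sequences matched in length and
  GC.
* **Truth** tables list the embedded protein, the signal boundary, CDS
  coordinates and the expected processed peptide list, derived by the
  package's own maturation rules — self-consistent by construction, which
  is exactly what makes end-to-end disagreement diagnostic.

`evaluate_recovery()` scores candidate recall/precision, exact
signal-boundary agreement and exact peptide-multiset recovery. Boundary
agreement is compared in transcript nucleotide coordinates: a random 5'
UTR occasionally contains an in-frame upstream AUG, extending the annotated
ORF by a few codons; the signal cut is then at the same nucleotide but a
different residue index, and comparing indices would report a spurious
miss.

What the generator does *not* emulate: assembly fragmentation (the
dominant practical difficulty in the original study — several precursors
were recovered as partial contigs and completed by RACE), sequencing
error, realistic codon-usage bias, and UTR structure. Passing the
benchmark therefore demonstrates the pipeline's internal correctness on
well-formed transcripts, not robustness to fragmented assemblies.

The standard benchmark is 5 precursors (one per family) among 20 decoys.
The full run — search, annotation, maturation, classification, scoring —
takes well under a minute on one CPU; the test suite uses this size, and
`scripts/acceptance.R` re-runs it with a caller-supplied seed.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open internally and 1-based inclusive in
  every written output.
* Alignment traceback and best-cell ties are fixed (see above), so reruns
  are byte-identical.
* `X` residues score by the substitution matrix's own X column; proteins
  shorter than 25 residues are declined for signal prediction with a
  stated reason rather than an error; empty query sets yield empty reports
  with exit status 0.
* All generator randomness flows through one explicit integer seed; no
  global RNG state is disturbed.

## Known limitations

* The signal-peptide and sulfation rules are transparent heuristics;
  they do not replace HMM/neural predictors on real proteins and their
  false-positive behaviour outside precursor-like inputs is uncharacterized.
* E-values are comparable within a run, not across tools.
* Disulfide pairing beyond the count is a naive nesting heuristic.
* Family profiles encode the five families treated here; peptides outside
  them are reported `unclassified` by design.
* The search is exhaustive Smith–Waterman per frame segment; it is meant
  for assemblies of up to a few thousand transcripts per run, not for
  seeding-indexed genome-scale search.
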