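---
title: "Isoform cataloguing and functional consequences at an Rbfox2-like locus"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isoform cataloguing and functional consequences at an Rbfox2-like locus}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbfoxiso)
```

## The analysis and its assumptions

`rbfoxiso` reconstructs the computational side of a clone-sequencing study
of *Rbfox2* isoform diversity: given a reference transcript model and a set
of cloned cDNA sequences, it calls the splice variations that distinguish
each clone from the reference, names isoform signatures, translates each
isoform to determine frame and stop usage, flags nonsense-mediated decay
(NMD) candidates, scans the intronic neighbourhood of variable exons for
RBFOX-binding motifs, and compares isoform populations and exon-inclusion
levels between groups.

The pipeline rests on a few explicit assumptions:

* Clones are directional, full-length RT-PCR products on the sense strand,
  so strand inference is unnecessary and clone/reference length ratios are
  bounded (default `[0.5, 1.5]`; a precondition, not a discovery step).
* Every splice variation is expressible against a single linear pre-mRNA
  model: truncations and skips remove reference sequence, alternative-exon
  inclusions insert sequence that exists in the model's introns.  De novo
  splice-site discovery outside the annotated model (plus a small
  boundary-snapping window) is out of scope.
* The standard nuclear genetic code applies; selenocysteine and
  non-standard codes are unsupported.

## The reference model

A `ref_model` carries the pre-mRNA, an ordered non-overlapping exon table
(0-based half-open nucleotide coordinates; protein coordinates are 1-based
inclusive), alternative translation starts as spliced-transcript offsets of
their `ATG`, the *dual stop architecture* — two stop codons in different
reading frames near the 3' end of the CDS — a protein domain map
(NTD / RRM / CTD), and NLS patterns.  Internal introns are validated as
`GT..AG`; a violation is deliberately a warning rather than an error so
that broken fixtures can be constructed for testing.  Alternative
(normally intronic) exons are annotated separately; they are not part of
the spliced reference but are used to confirm insertions and to scan their
own intronic flanks.

We store the stop pair with a `stop_spacing` of 7, defined as the number of
nucleotides **between the end of the reference-frame stop and the start of
the alternative-frame stop**.  This convention is forced by codon
arithmetic: for a +1-shifted reading frame, alternative-stop starts can
only occur at offsets congruent to 1 (mod 3) from the reference stop start,
and a start-to-start spacing of 7 is incompatible with a shifted frame that
still translates a sensible C-terminal tetrapeptide immediately before its
stop.  An end-to-start gap of 7 (start-to-start 10) satisfies every
constraint simultaneously.

## The engineered synthetic locus

`rbfox2_reference()` builds a fully deterministic 13-exon locus (2,965 nt
pre-mRNA, 1,175 nt spliced) that emulates the biology the pipeline is
meant to analyse:

* a 12-nt 5' leader that doubles as an in-frame `MAEG` alternative start,
  followed by the `MEKK` start at offset 12;
* a 1,143-nt ORF encoding a 381-aa protein (`MEKK...FAPY`) with domains
  NTD 1–117, RRM 118–190, CTD 191–381, a 31-aa NLS at residues 122–152,
  and the pentapeptide `SLPLV` at 245–249;
* six variation loci hosting the event menu: a −3 donor truncation at the
  exon-2/3 junction and a second −3 acceptor truncation at exon 4 (the
  `-3a`/`-3b` pair), a −93 acceptor truncation of exon 5, a +73 alternative
  exon carrying an in-frame premature stop, −12/−39 acceptor truncations of
  exon 9, and the 40-nt exon 10 with two alternative exons (+32, +43) in
  its upstream intron;
* planted `(T)GCATG` motifs at known intronic offsets (120 nt upstream and
  30 nt downstream of exon 5, 60 nt downstream of the +32 alternative exon,
  80 nt upstream of exon 10) with all other sequence engineered to be
  motif-free, so scanner output is exactly the plant list.

The coding sequence is specified codon-by-codon because two reading frames
carry constraints at once.  The zero frame must encode the protein above
with exactly 33 alanines.  The +1 frame of the same nucleotides downstream
of exon 10 — the frame read by every isoform whose net deleted length is
congruent to 2 (mod 3), such as `-12-40` (net −52) and `+32` — must be
stop-free until the alternative stop, contain no alanine, and supply
exactly 6 glutamines, 13 prolines and five QP dimers so that the `-12-40`
protein shows the documented composition shift: 16 alanines versus 33,
+5 Q, +11 P, five closely spaced QP dimers, terminus `TEVT` versus `FAPY`.
The alanine/threonine run at residues 341–356 does double duty: its
`GCA/GCC/ACA/ACC` codons read as the QP repeats in the shifted frame.  The
−12 deletion is placed to straddle codon phase (it starts at the second
base of the `SLPLV` serine codon), so it removes five reference residues
and introduces a single novel isoleucine — the protein diff cannot be
computed by whole-codon arithmetic, which is why `domain_impact` aligns
proteins instead.

Two placement choices are worth recording.  First, cryptic splice-site
dinucleotides are planted so that every alternative acceptor/donor in the
menu has canonical context (`AG` immediately 5' of each alternative
acceptor, `GT` at the alternative donor, `AG..GT` flanks around the −2
micro-deletion), letting the caller's junction check return "confirmed" on
true events.  Second, the +73 alternative exon sits in the intron *after
exon 6*, one intron downstream of the −93 locus at exon 5.  With the two
events closer together, global affine-gap alignment genuinely prefers to
stitch the 73-nt insert against nearby reference sequence rather than to
open one large deletion and one large insertion; 75 nt of exact match
between the events makes the true decomposition optimal.  The locus count
is unaffected: the +73 insertion point is a zero-width interval that abuts
nothing, so the population still has six merged variation loci.

## The generators and what they do (and do not) emulate

`sim_config(seed)` fixes the study conditions: 22 clones per brain-region
group; the `-12-40` signature at probability 12/22 in SCN and 4/22 in
cortex (only these and the group totals are treated as anchored — the
remaining per-signature frequencies are a plausible reconstruction chosen
once); exon-inclusion densitometry at mean ± SEM of 7.0 ± 0.4 % (SCN) and
1.7 ± 0.4 % (cortex) with n = 3 samples per group; and a qPCR experiment
with fold changes 0.92 and 1.12 against the calibrator, SD 0.2 cycles,
n = 4.

Clone counts per group are a seeded multinomial draw; each clone is the
spliced reference with its signature's events applied exactly, plus
optional per-base substitution noise.  The default error rate is 0 —
sequenced plasmid clones are treated as error-free consensus sequences —
and robustness tests use 0.1 %.  The substitution model is a stand-in: real
clone artefacts (chimeras, indel sequencing errors, PCR recombination) are
not emulated, so a passing round-trip says the caller tolerates point
noise, not that it survives every cloning artefact.

Densitometry draws per-sample percent inclusion from a normal distribution
centred on the group mean with SD `sem * sqrt(n)` — the per-sample SD
implied by the reported SEM at the reported cohort size — clamped to
`[0, 100]` (at these means and SDs the clamp is essentially never active),
with log-normal total intensities.  Drawing a large number of samples
(e.g. 1000) at those fixed parameters is used for parameter-recovery
checks.  qPCR samples get a reference-gene Ct near 16 cycles and a target
Ct offset by a group-specific ΔCt.

All randomness flows from the single seed through documented sub-stream
seeds (`seed * 101 + offset` mod 2³¹−1, offsets 1–4 for clones, noise,
densitometry, qPCR); the reference itself is a deterministic constant.

## The caller's numerical choices

Alignment uses match +1, mismatch −2, gap open 5, gap extend 1 (an
indel-dominated regime for near-identical sequences).  Identity is
computed over **aligned (non-gap) columns**: splice-sized indels are
legitimate differences, so a clone missing 145 nt of 1,175 should not drift
toward the 80 % unalignable threshold, while a genuinely unrelated sequence
still falls far below it.

Gap normalization enumerates all content-preserving placements of each gap
(the repeat-induced equivalence range), prefers a placement aligning with
an annotated exon boundary (5' starts first, then 3' ends) within a 3-nt
snap window, and otherwise reports the leftmost placement — reproducibility
over biological certainty.  Adjacent gaps are merged after normalization;
deletions spanning internal exon boundaries are split at those boundaries
and each piece classified (whole exon → skip; abutting the 5' boundary →
alternative acceptor truncation; the 3' boundary → donor truncation;
internal → micro-deletion).  Novel junctions are checked against the
pre-mRNA: `AG` immediately upstream of an alternative acceptor, `GT` at an
alternative donor, `AG..GT` around a micro-deletion, and, for insertions
located at an exon junction, the inserted sequence must occur in the
intervening intron with `AG`/`GT` flanks.

One refinement goes beyond plain alignment: a mutually-exclusive-exon
substitution (an annotated exon replaced by an annotated alternative exon)
defeats global alignment, which stitches the two exons together with small
gaps and mismatches.  When untidy (unconfirmed) events overlap an exon
whose flanking intron hosts an annotated alternative exon and the clone's
aligned segment across that exon equals the alternative exon exactly, the
caller re-expresses the events canonically as `exon_skip` +
`alt_exon_inclusion`.  This is annotation-guided, not de novo: it never
invents sequence that is not in the model.

Signature names concatenate signed event lengths 5'→3' (`-12-40`, `+32`);
when one magnitude occurs at several loci across the population, letter
suffixes are assigned in order of reference position (`-3a` most 5').  The
registry is a pure function of the set of observed (length, locus) pairs,
so naming is independent of clone input order.  A locus is a maximal
reference-transcript interval hosting at least one event across the
population; intervals that overlap or abut are merged, and insertions are
zero-width points (which is how an alternative exon inserted at a skipped
exon's junction shares that exon's locus).

## ORF, NMD and domain-impact choices

Translation runs from the chosen start to the first in-frame stop; a
missing stop is reported as run-through rather than an error, to handle
truncated clones.  The NMD rule is distance = last exon-exon junction minus
stop-codon end, flagged when strictly greater than 55 nt, with distances in
(50, 55] labelled borderline — the literature's 50–55 nt range is exposed
rather than silently collapsed.  Junctions of a variant transcript are the
reference junctions mapped through the called events (skipped-exon
junctions collapse; included alternative exons contribute two new ones).

Domain impact aligns the variant against the non-variant protein
(Needleman–Wunsch, BLOSUM62, gap open 10 / extend 0.5) and marks every
substituted or deleted non-variant residue plus each insertion's anchor
residue; a domain is impacted when any marked position falls inside it.
Alignment rather than codon arithmetic is required because sub-codon
deletions shift codon phase (the `SLPLV` case above).  Post-frameshift
tails surface as long mismatch/deletion stretches and need no special
casing.

## Motif scanning

The scanner searches the sense strand of the pre-mRNA only (RBFOX binds
pre-mRNA co-transcriptionally), reports every `GCATG` core in the upstream
and downstream intronic windows of each requested feature (default window
500 nt), flags `TGCATG` hexamers via `extended_u`, counts overlapping
occurrences separately, and predicts inclusion enhancement for downstream
hits and skipping enhancement for upstream hits.  Windows are truncated at
neighbouring features — including annotated alternative exons — and
distances are measured from the splice site to the motif's nearest base
(1 = adjacent).  Whether real 500-nt windows should truncate at
neighbouring exons is ambiguous; we truncate and document, since a window
reaching across an exon is no longer intronic context.  Distal regulation
through RNA bridges is out of scope.

## Statistics

Clone-count comparisons use Fisher's exact test (two-tailed by summing
hypergeometric tables with probability ≤ the observed table's): the study
design compares 12/22 against 4/22 clones, and an exact test is the
appropriate tool for counts of that size even though the original
gel-based comparisons used t-tests.  Percent-inclusion comparisons use the
classical pooled-variance independent Student's t test (Welch available by
flag) and Levene's test on absolute deviations, mean-centred by default
with the median-centred Brown–Forsythe variant by flag — the mean-centred
form is the classical "Levene's test" when no variant is specified.  No
multiple-testing correction is applied by default; the analysis makes few
comparisons, and `p.adjust` is available to callers who make many.
2^−ΔΔCt quantitation normalizes each sample's target Ct to its
reference-gene Ct and anchors ΔΔCt at the calibrator group's mean;
amplification-efficiency correction beyond the exact-doubling assumption
is out of scope.

## Problem sizes and determinism in the test suite

The test suite regenerates all fixtures in code: the deterministic locus,
planted clone sets (11 noise-free signatures; 80 clones at 0.1 % noise for
the robustness property), 100 random 3-exon models for the motif
brute-force comparison, 1,000 random ORFs for the translation oracle, and
all equal-margin Fisher tables with group totals up to 30 plus 200 random
unequal-margin tables.  These sizes keep the default run in a few minutes
while leaving the properties exhaustive where exhaustiveness is cheap.
Parameter-recovery checks for the densitometry generator use n = 1000
samples per group and assert recovery within three standard errors of the
estimate.

## Known limitations

* The caller is annotation-bounded: novel alternative exons absent from the
  model are reported as unconfirmed insertions, and splice sites far from
  annotated boundaries are reported at their leftmost equivalent placement.
* Signature naming for a clone analysed in isolation omits locus suffixes
  (no second locus of the same magnitude is visible); population-level
  calling restores them.
* The NMD model is the junction-distance rule only — no exon-junction
  complex deposition model, no 5'-proximal start effects.
* NLS detection is pattern matching with a mismatch budget, not a
  position-specific scoring model.
* The synthetic locus reproduces the *arithmetic* of the documented
  isoforms (lengths, frames, composition shifts, motif geometry), not their
  actual nucleotide sequences; analyses that depend on real sequence
  content (e.g. cross-species identity percentages) are demonstrated on the
  synthetic sequences and labelled as such.
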