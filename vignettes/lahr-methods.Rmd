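---
title: "Designing sticky-end repair templates for AsCas12a: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing sticky-end repair templates for AsCas12a: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lahr)
```

## The editing strategy this package models

AsCas12a recognises a T-rich PAM (TTTV) placed 5′ of its protospacer and,
unlike the blunt cut of SpCas9, nicks the two strands at different positions:
the non-target strand (the strand carrying the PAM and protospacer sequence)
after the 18th or 19th base behind the PAM, and the target strand after the
23rd. The staggered cut therefore leaves 5-nt or 4-nt 5′ overhangs — sticky
ends — on the two genomic fragments.

Ligation-assisted homologous recombination (LAHR) exploits this geometry. A
LAHR template is a short double-stranded DNA carrying

* a **5′ sticky end** complementary to the overhang on the PAM-distal
  fragment, so the template can be ligated directly onto that end
  (an MMEJ-like, resection-free junction), and
* a **homology arm** matching the genomic region adjacent to the PAM-proximal
  end of the break, through which homology-directed repair resolves the other
  junction and copies any planted substitution into the locus.

The arm is always on the PAM-proximal side and the sticky end always targets
the PAM-distal fragment; a mirrored layout is not offered because it has no
experimental support. Cut-and-paste repair (CAPR) generalises the ligation
half: two cuts excise a region, and a double-sticky-ended insert carrying a
replacement ligates into the gap. Conventional single-stranded ODN donors are
provided for comparison, emitted on the non-target strand for AsCas12a and on
the target strand for SpCas9, following the observed strand preferences.

## Coordinate and geometry conventions

All base coordinates are 1-based inclusive on the locus top strand — the
native R and Bioconductor convention — and a nick is stored as a *boundary*:
the number of bases 5′ of it, so a nick between positions *b* and *b + 1* is
stored as *b*. BED output converts to 0-based half-open intervals at that
interface only. Minus-strand sites are computed in their own frame (the
strand on which PAM + protospacer read 5′→3′) and mirrored back, which makes
strand symmetry a testable invariant rather than a second code path.

Because every Cas12a cut is a 5′ overhang, the top-strand nick always lies
left of the bottom-strand nick regardless of site orientation. The
target-strand nick is fixed at the 23rd base behind the PAM: this is the
unique value consistent with the published non-target nick options (18/19)
and overhang lengths (5/4 nt), and it remains a profile parameter
(`cas12a_profile(nick_target = )`) rather than a hard-coded constant. The
SpCas9 blunt cut 3 bp 5′ of the NGG PAM is the standard field convention,
recorded here as an assumption. The Cas12a seed region defaults to
protospacer bases 1–6 (PAM-proximal); its exact extent is not established,
so it too is a profile parameter.

The signed mutation-to-nick distance is the number of bases strictly between
the edited base and the non-target-strand nick, positive when the nick lies
PAM-distal of the edit; for an edit at protospacer base *m* and nick choice
*k* it equals *k − m*. A mutation at the 14th base behind the PAM with the
18th-base nick is 4 bp from the cut, the geometry of the endogenous-gene
worked example reproduced in the test suite and acceptance script.

## Tunable parameters and their defaults

| parameter | default | why |
|---|---|---|
| `arm_len` | 80 bp (allowed 20–200) | 80 bp was the optimum of the arm-length series; 20 bp arms repaired poorly |
| `nick_choice` | 19 (4-nt overhang) | the template whose 4-nt end perfectly matched the PAM-distal overhang repaired best |
| `distance_window` | \[0, 20\] bp | favourable mutation-to-cut distance with an 80-bp arm |
| `total_len_warn` | 120 bp | templates over 120 bp showed decreased repair; a Discussion-style figure of 100 bp also circulates, and the package keeps the experimentally stated 120 |
| `end_type` | `"matched"` | alternatives (5-nt, 3-nt, mismatched, blunt, 3′-overhang) mirror the end-type series and exist for comparison designs |
| `disruption_mode` | `"none"` | one of PAM *or* seed may be silently disrupted to avoid re-cutting; disrupting both at once lost the benefit, so the combination is unrepresentable |

Edits inside the overhang are rejected by default (a mismatched overhang
lowers efficiency) behind an explicit `allow_overhang_edit` override. Arms of
80 bp and more necessarily extend 5′ of the PAM; this is allowed, and a note
is attached because its interaction with re-cutting is untested.

## Candidate scoring

`enumerate_designs()` scores each admissible site as a **product of five
components in \[0, 1\]**. The functional forms are the package's own
heuristics; only their directions are empirically grounded:

* **distance** — 1 inside the window, linear taper beyond it;
* **arm prior** — triangular, peaking at 80 bp (`1 − |arm − 80|/180`);
* **total length** — 1 up to 120 bp, then a linear taper;
* **mid-arm placement** — extra silent edits incorporate less efficiently
  the farther they sit from the nick, so the penalty grows with the largest
  fractional distance of any requested extra edit (`1 − 0.5·max f`); the
  PAM/seed disruption edit is scored by the re-cut component instead;
* **re-cut** — 1.0 with exactly one PAM-or-seed disruption, 0.6 otherwise.

Scores are *relative ranks only*; the package deliberately does not predict
absolute editing efficiency. Ties are broken by top-strand coordinate, then
+ strand before −, making the ranking total and deterministic.

## Silent disruption

`silent_disruption_candidates()` intersects the PAM (or seed) interval with
the locus CDS, enumerates all single-base synonymous substitutions of the
overlapping codons under the standard genetic code (stop→stop allowed), and,
in PAM mode, retains only changes after which the TTTV match is actually
destroyed (a change at the V position to another A/C/G would not be).
Without a CDS the operation refuses — silence is meaningless without codon
context — unless the non-coding override is set, in which case the codon
constraint is dropped. Within a design, the disruption edit must fall inside
the arm, outside the overhang, and off the correction edit.

## Quantifying outcomes from amplicon reads

Reads are globally aligned (Needleman–Wunsch, match +1, mismatch −1, gap −2,
deterministic traceback preferring diagonal, then up, then left — implemented
in C++ and checked against an exhaustive-enumeration oracle and an
independent dynamic-programming implementation) to the WT and expected-edit
references. Classification is window-based (default ±20 bp around the nick)
so sequencing errors far from the cut do not miscall classes: a read is
*edited* (or *wt*) when the corresponding alignment is gap- and
mismatch-free inside the window and passes an 80% outside-window identity
floor; *indel* when its best alignment has a gap inside the window; anything
else is *discarded*. Reads carrying a substitution error inside the window
match neither reference cleanly and are discarded — with a 40-bp window and
a 0.1% error rate that is about 4% of reads, affecting all classes nearly
proportionally, which is why mixture recovery stays within its binomial
interval.

The efficiency statistic is the percentage of edited reads over total reads,
with "total" interpreted as total *retained* (non-discarded) reads — the
analogous pipelines filter reads before quantification, and the discarded
count is reported separately so the choice is visible.

## What the synthetic generator does and does not emulate

`make_locus()` plants TTTC PAMs with random protospacers and an optional
marked SNV at a chosen protospacer base, then deterministically breaks any
unintended TTTV on either strand (converting one of its three T's to C, a
monotone operation that must terminate) so the found sites are exactly the
planted ones; the manifest records all planted coordinates as ground truth.
`simulate_reads()` draws class counts from a multinomial, emits reads from
the WT / edited / window-centred-deletion templates, and applies independent
per-base substitution errors. Both are bit-reproducible under a fixed seed
(base R Mersenne–Twister, seed recorded in the spec object).

What is *not* emulated: quality-dependent or homopolymer error profiles,
indel sequencing errors (kept out so the indel class remains identifiable),
PCR duplicates, paired-end reads, and chromatin or delivery effects. Passing
tests therefore demonstrate geometric and algorithmic correctness on clean
substitution-noise data, not performance on real sequencing libraries.

## Numerical and degenerate-input choices

* Loci reject IUPAC ambiguity codes (designs must be concrete); PAM patterns
  accept them. Input is upper-cased on entry.
* `apply_edits()` validates every `ref` against the locus and rejects
  overlapping edits before touching the sequence.
* `simulate_perfect_lahr()` is strict by default: the template overhang must
  be the exact reverse complement of the genomic overhang, so blunt,
  truncated, mismatched and 3′-overhang ends raise ligation-incompatible
  errors even though some repair (at reduced efficiency) in cells.
* CAPR accepts any site pair whose cut boundaries nest around the
  replacement and warns (error in strict mode) when the two insert
  protrusions are identical or mutually reverse-complementary, since insert
  orientation is then not enforced by the chemistry.
* The mismatched end type substitutes the middle overhang base with the next
  base in the fixed A→C→G→T cycle — deterministic, so designs are
  reproducible.
* The 3′-overhang end type is a mirror-image construction and is marked
  approximate: the original description is figure-only.

## Problem sizes used in the checks

The property suites run on deliberately compact inputs — loci of 120–280 nt,
1000 random LAHR fixtures, 50 CAPR fixtures, read sets of 1000 reads at 0.1%
substitution error, and alignment oracle pairs up to 8 nt (the exhaustive
enumeration is exponential). These sizes are the package's own choice: they
are large enough to exercise every strand/nick/arm combination while keeping
the whole suite fast on a laptop.

## Known limitations

* No off-target search, thermodynamic guide scoring, or efficiency
  prediction; scores rank candidates within one locus only.
* Substitution edits only (`ref` and `alt` of equal length); CAPR handles
  length-changing replacements, LAHR templates do not.
* Single-end, full-length amplicon reads; no UMI handling or variant calling
  beyond the three outcome classes.
* Standard genetic code only.
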