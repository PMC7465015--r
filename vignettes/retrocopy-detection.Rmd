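---
title: "Detecting and characterizing polymorphic gene retrocopies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and characterizing polymorphic gene retrocopies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(retroseek)
```

## The problem

A gene retrocopy (processed pseudogene) is created when the LINE-1
retrotransposition machinery reverse-transcribes a mature mRNA and
integrates the cDNA elsewhere in the genome. The product is a hallmark
structure: an intronless copy of the spliced transcript, usually with a
polyA tail, flanked by a short target site duplication (TSD) generated by
the staggered endonucleolytic nicks of target-primed reverse
transcription. Young, segregating retrocopies are easy to miss: on a
reference genome that does not carry the copy, every read derived from it
aligns back to the parental gene, so SNP/indel callers see nothing.

What those misplaced reads do produce, over the parental locus, are two
distinctive paired-end signatures:

1. **Junction-spanning (exon-to-exon) pairs.** Mates that straddle an
   exon-exon junction in the *retrocopy* land in two different exons of
   the parental gene. Their apparent genomic separation is the library
   insert size *plus* every skipped intron -- far outside library noise.
   These pairs prove an intronless template exists somewhere.
2. **Trans-mate pairs.** Fragments that straddle an insertion junction
   leave one mate inside the retrocopy (mapping to the parental gene) and
   one mate in the flanking sequence of the insertion locus. These pairs
   say *where* the copy sits.

retroseek classifies every pair over the parental locus into exactly one
of `CONCORDANT`, `JUNCTION_SPANNING`, `TRANS_MATE` or `OTHER`, clusters
the outside mates of trans pairs, and calls an insertion `CONFIDENT` only
when **both** signal classes support it. A locus with trans support but
no junction support (or vice versa) remains a `CANDIDATE`; loci
overlapping annotated reference retrocopy fragments are labelled
`FRAGMENT` and excluded from downstream interpretation.

## The calling model and its parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 4 | a junction pair must exceed `insertMean + k * insertSd` genomic span; 4 SD separates intron-scale inflation (hundreds to thousands of bp) from library-size noise |
| `transRadius` | 10 kb | a non-gene mate closer than this to the gene is local structural noise, not trans evidence |
| `clusterWindow` | `insertMean + 4*insertSd` | single-linkage gap for outside-mate clustering; two mates from the same insertion can be at most about one fragment length apart |
| `minTransCandidate` | 2 | reporting floor for a cluster |
| `minTrans`, `minJunction` | 3, 3 | both-signals thresholds for `CONFIDENT` |
| `minClip` | 12 bp | a soft clip at an exon boundary must be at least this long, and match the adjacent exon, to count as split-read junction support |

The 2/2 floor versus 3/3 confidence split is deliberate: a locus
supported by only two discordant reads is worth reporting and following
up (e.g. by PCR) but is not, on its own, a discovery. Orientation is
called from the strand consensus of the outside mates, requiring at least
80% agreement; anything weaker -- including the perfect 50/50 mix that a
well-covered insertion produces when both junctions are sampled evenly --
is reported as `unknown` rather than an arbitrary strand.

**The reported interval.** A naive cluster extent spans roughly two
fragment lengths around the true site, which is too blunt to be useful.
retroseek instead reports the innermost breakpoint interval: from the
rightmost mapped end of a forward-strand outside mate to the leftmost
mapped start of a reverse-strand outside mate. Reads clipped at the
junctions pin these bounds to the insertion point, and because sequence
from the TSD is present on *both* sides of the insertion, the two bounds
typically overlap by exactly the TSD footprint -- the interval doubles as
a first TSD estimate. The full cluster extent is retained in
`clusterStart`/`clusterEnd` columns.

## Breakpoint characterization

* **TSD detection** (`findTsd`). Given context ending at the 5' junction
  and context beginning at the 3' junction, the TSD is the longest string
  that is simultaneously a suffix of the former and a prefix of the
  latter. Because both ends are anchored at the junctions there is exactly
  one candidate per length, so the search is a descending scan over
  lengths 30 down to 6. Duplications under 6 bp are indistinguishable
  from chance (a random 6-mer recurs by chance with probability ~2.4e-4
  per position) and are never reported; 30 bp is far above anything
  L1-generated. An optional mismatch budget tolerates sequencing errors
  inside the duplication, with longer inexact duplications preferred over
  shorter exact ones.
* **G/C content** (`gcWindow`). The window is *exactly* the
  10 bp flank + TSD + 10 bp flank string, and the value is
  `100 * (G+C) / length` rounded half-up to one decimal. This is the
  normative definition used for the published canid FGF4 insertion-site
  windows bundled with the package (`fgf4InsertionSites()`); it
  reproduces all seven published values to the printed decimal
  (e.g. 12/33 = 36.4% for FGF4L1). Ambiguity codes are rejected rather
  than fractionally weighted.
* **Motif scan** (`scanMotif`). The L1 endonuclease loosely prefers
  `TTAAAA`. The default scan covers only the forward strand of the
  printed window -- insertion-site windows are conventionally reported on
  the reference forward strand regardless of retrocopy orientation -- and
  both-strand scanning is an explicit flag, so the default reproduces the
  conventional tabulation. Across the seven bundled FGF4 sites exactly
  one window (FGF4L5) contains the motif, a reminder that the consensus
  is weak.
* **Conserved elements** (`countEcr`). Conservation tracks are an
  *input* (BED), never recomputed; the count is the number of elements
  sharing at least one base with the +/-2.5 kb window around the site
  midpoint.
* **Truncation** (`classifyTruncation`). The retrocopy is aligned to the
  full parental mRNA with the mRNA ends free, so missing 5'/3' UTR
  sequence surfaces as unaligned mRNA overhang. The ORF is intact when it
  is fully covered, indel-free, and no *difference from the parent*
  introduces a stop codon. Median and range summaries of TSD lengths are
  always computed from the detected values, not taken from prior
  annotation: across the seven bundled sites the detected lengths are
  11-17 bp with a computed median of 14 bp.

## Haplotype comparison

A young retrocopy is a snapshot of one parental haplotype. Differences
between a retrocopy and the reference mRNA therefore come in two kinds:
alleles the source haplotype already carried, and genuine post-insertion
mutations. `alignAndCall` calls the differences (match 1, mismatch -2,
affine gaps 5 + 1/bp; identity below 90% is rejected as "not a retrocopy
of this gene"), projects them through the exon map to genomic
coordinates, and `classifyVariants` looks each up in a population VCF:
`HAPLOTYPE_SHARED` requires the identical alt allele at the identical
position -- positional overlap with a different allele does not count.
Indels are left-normalized against the mRNA before lookup so that
homopolymer-adjacent events have a unique representation; the polyA tail
and TSD are stripped before alignment so the tail is not called as an
insertion. `haplotypeMatch` then finds the phased parental haplotype
with the fewest allele mismatches (ties are all reported; positions no
haplotype covers make the result `UNKNOWN`).

## Population genotyping

`exonExonProductSizes` predicts the two products of an exon-to-exon PCR:
the genomic template gives primer span plus introns, an intronless
retrocopy gives the spliced span, and their difference is exactly the
summed skipped introns. `alleleFrequency` uses diploid counting,
`(het + 2 * homalt) / 2n`, with a Wilson score interval -- chosen over
the Wald interval because targeted breed cohorts are small (n = 5-30)
and frequencies are often near 0, where the Wald interval degenerates.
Copy numbers are taken as assayed; no genotyping-error model is applied.

## What the simulator emulates -- and what it does not

`buildGenome` / `plantRetrocopy` / `simulateAlignments` generate the data
structure the detector assumes, by construction rather than by running an
aligner: every read drawn from the insertion-carrying genome is projected
back onto the retrocopy-free reference the way a gapped local aligner
would place it. Retrocopy-internal reads are re-coordinated onto parental
exons; reads crossing exon-exon or insertion junctions are anchored on
their largest mappable piece and soft-clipped for the rest; polyA-derived
bases are soft-clipped at the parental 3' end. Each pair carries a truth
label (`concordant`, `junction_spanning`, `trans_mate`, `other`) derived
from its construction, independent of the detector's thresholds.

Deliberate simplifications: substitution errors only (default rate 0.001,
typical of substitution-dominated short-read chemistry) -- the detector
uses pair geometry, not base accuracy; no PCR duplicates; no base-quality
model; no reference mis-assembly; fragment lengths are truncated normal
(minimum one pair width). Defaults model the study conditions end to
end: 2 chromosomes x 200 kb, a three-exon gene with a 3.2 kb mRNA
(480 bp 5' UTR, 621 bp ORF -- planted as a genuine reading frame --
2,099 bp 3' UTR, introns 1.3 kb and 0.7 kb), insert 400 +/- 50 bp
(asserted, not derived from any published library), 150 bp reads, TSD
11-17 bp, 50 bp polyA. A fixed seed makes the SAM byte-identical across
reruns.

Consequently, passing the recovery suite shows the detector logic is
correct *under its own assumptions*; it does not show robustness to
repetitive flanks, mapping-quality artifacts, or aligner-specific clip
conventions, all of which real data add.

## Numerical and design choices

* Coordinates are 1-based inclusive everywhere inside the package;
  conversion to BED's 0-based half-open convention happens only in the
  I/O layer, and the conversions are fuzz-tested for round-trip
  identity.
* Rounding of reported percentages is half-up (half-to-even would
  produce 36.3 where the conventional tabulation prints 36.4).
* Orientation-consensus ties go to `unknown`, never to an arbitrary
  strand.
* Simulation problem sizes in the test suite: the recovery property runs
  20 seeded replicates with 1-2 planted insertions plus 20 insertion-free
  replicates at 20x coverage on the 2 x 200 kb toy genome -- large enough
  that every junction is sampled tens of times, small enough to iterate
  on quickly.
* Cohort-scale discovery (thousands of genomes, many loci) is out of
  scope; `screenCohort` loops single-locus scans over samples and is the
  supported batch surface.

## Known limitations

* Single parental locus per scan; genome-wide all-gene scanning is a
  loop over genes by the caller.
* Trans-mate evidence cannot resolve insertion loci inside long repeats
  where outside mates are unmappable (the simulator does not model
  this).
* `alignAndCall` on a minus-strand parental gene projects alleles to the
  forward strand but reports indel anchors in mRNA-normalized space;
  cross-checking such calls against forward-strand VCFs near
  homopolymers deserves care.
* The orientation consensus is conservative by design and will often
  report `unknown` for well-covered insertions sampled evenly from both
  junctions.
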