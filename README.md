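# retroseek

Discovery and characterization of polymorphic gene retrocopies from
paired-end sequencing alignments.

## The problem

Gene retrocopies (processed pseudogenes) arise when the LINE-1 machinery
reverse-transcribes a gene's mRNA and inserts the cDNA elsewhere in the
genome. The product is intronless, carries a polyA tail, and is flanked
by a short target site duplication (TSD). Recent, still-segregating
retrocopies — like the FGF4 retrocopies that drive disproportionate
dwarfism and intervertebral disc disease in dogs — are invisible to
ordinary variant callers: when the reference genome lacks the copy, all
of its reads align back to the parental gene.

They are not, however, invisible to read-pair geometry. Over the
parental locus, a retrocopy elsewhere in the genome produces:

* **junction-spanning pairs** — mates in *different exons* whose genomic
  separation is inflated by the missing introns (template had no
  introns), and
* **trans-mate pairs** — one mate on the parental gene, one mate at the
  insertion locus.

retroseek classifies every pair into exactly one of
`CONCORDANT | JUNCTION_SPANNING | TRANS_MATE | OTHER`, clusters the
outside mates of trans pairs (single linkage, gap ≤ insert mean + 4 SD),
and calls an insertion **CONFIDENT only when both evidence classes
support it** (defaults 3 junction + 3 trans; 2/2 loci are reported as
CANDIDATE). The reported interval is the innermost breakpoint interval
bracketed by the facing outside mates — which, because TSD sequence sits
on both sides of the insertion, is typically the TSD footprint itself.

Downstream, the package characterizes the insertion site (TSD by
longest anchored duplication within 6–30 bp, G/C of the
flank+TSD+flank window with half-up rounding, `TTAAAA` L1 motif scan,
conserved elements within ±2.5 kb, repeat context, UTR truncation),
classifies retrocopy–parental differences against a population VCF
(`HAPLOTYPE_SHARED` needs the identical allele at the identical
position), and supports population genotyping (exon–exon amplicon
sizing; allele frequency `(het + 2·homalt)/2n` with Wilson 95% CI).
A deterministic simulator plants retrocopies with known truth and emits
standard SAM, so every stage is verifiable without external data.

## Worked example

Simulate a 2 × 200 kb genome with a three-exon gene (3.2 kb mRNA), plant
a retrocopy with a 13 bp TSD on the other chromosome, sequence to 20×,
and scan:

```r
library(retroseek)
g   <- buildGenome(SimConfig(seed = 7))
p   <- plantRetrocopy(g, InsertionTruth("chrB", 120000, tsdLen = 13))
sim <- simulateAlignments(p, SimConfig(seed = 7, coverage = 20))
writeSam(sim, "sample.sam")
res <- scanSample("sample.sam", p@gene, verbose = TRUE)
#> [scan] sample.sam: CONCORDANT=26827 JUNCTION_SPANNING=24 TRANS_MATE=33 OTHER=0
as.data.frame(res$calls)
#>   seqnames  start    end nJunctionPairs nSplitReads nTransPairs    status
#> 1     chrB 119988 120000             24          33          33 CONFIDENT
```

The call is CONFIDENT (24 junction pairs + 33 split reads, 33 trans
mates), and its interval `chrB:119,988–120,000` is exactly the 13 bp TSD
footprint ending at the planted position 120,000.

Characterizing a real site — the package bundles the seven published
canid FGF4 retrocopy insertion-site windows (FGF4L1–L7):

```r
s <- fgf4InsertionSites()
i <- which(s$name == "FGF4L4")
findTsd(paste0(s$flank5[i], s$tsd[i]), paste0(s$tsd[i], s$flank3[i]))
#> $tsdSeq  "AAGAATATTCTGGTTGT"   $tsdLen  17   $mismatches  0
gcWindow(paste0(s$flank5[i], s$tsd[i], s$flank3[i]))
#> [1] 32.4
```

The detected 17 bp TSD and the 32.4% G/C match the published
characterization of that site; across all seven sites the detected TSD
lengths span 11–17 bp and six of seven windows fall below the 41.3%
genome-average G/C.

Cohort genotyping arithmetic:

```r
af <- alleleFrequency(c(2, 2, 1, 1, 0, 0, 0, 0, 0, 0))
#> frequency 30.0%, Wilson 95% CI 14.5–51.9%
```

An end-to-end demo (simulate → scan → characterize → compare → genopop)
runs from the bundled configuration:

```r
runPipeline(system.file("extdata", "demo_config.yaml",
                        package = "retroseek"), "demo_out")
```

A thin command-line wrapper is available at
`inst/scripts/retroseek.R` (`simulate`, `scan`, `genopop`, `run`
subcommands).

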