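---
title: "Constructing a reference transcript dataset from long and short reads"
author: "rtdforge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constructing a reference transcript dataset from long and short reads}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Full-length cDNA sequencing (PacBio Iso-seq and similar) reads whole
transcripts, so in principle a transcriptome can be annotated directly
from mapped reads: exon–intron structure from the alignment gaps,
transcription start (TSS) and end (TES) sites from the read termini. In
practice three error processes corrupt all three signals:

* **Splice-junction wander.** Long reads carry residual sequencing errors
  (a few percent), and an error near an exon boundary lets the aligner
  place the intron gap a few nucleotides off, creating a junction that
  does not exist. Reverse transcriptase adds a second junction artifact:
  at short direct repeats it can switch templates, deleting the sequence
  between the repeats and leaving a spurious, often plausible-looking
  junction.
* **End degradation.** RNA degradation and incomplete cDNA synthesis
  truncate molecules, so read 5' and 3' ends are a mixture of genuine
  TSS/TES (piled up, with small stochastic wobble) and fragment ends
  (scattered along the gene body).
* **Internal priming.** Oligo-dT primers anneal to genomic A-rich tracts
  inside transcripts, producing false 3' ends precisely at those tracts.

`rtdforge` re-implements a filtering pipeline that turns this noisy
evidence into a reference transcript dataset (RTD): a conservative,
non-redundant transcript set suitable for alignment-free quantification.
Short-read RNA-seq contributes junction support and an independently
assembled transcriptome that is integrated at the end.

## The pipeline

1. **High-confidence splice junctions** (`sjEvidence`, `hcSJLongread`,
   `hcSJShortread`, `unionHC`). A long-read junction is kept when (i) its
   donor–acceptor pair is canonical (GT-AG, GC-AG or AT-AC on the sense
   strand), (ii) at least one supporting read aligns without any
   substitution within 10 nt of either boundary on the exonic side, and
   (iii) it fails the template-switching signature. That signature
   compares the last 8 bases of the upstream exon with the last 8 bases
   of the intron, and the first 8 bases of the intron with the first 8
   bases of the downstream exon; a Hamming distance of 1 or less in
   either comparison flags the junction. Short-read junctions (STAR-style
   tables) are kept when canonical with a maximum overhang of at least
   10 nt and more than 5 unique supporting reads.
2. **TSS/TES calling** (`callEnds`). Internally primed 3' ends (more
   than 16 A in the 20 nt downstream of the end, transcript sense) are
   removed first. For each gene the read ends of each kind are tested
   for enrichment against a uniform null over the `t` distinct observed
   positions using the binomial point mass
   `Pr(Reads = h) = C(n,h) (1/t)^h (1 - 1/t)^(n-h)` at `alpha = 0.01`.
   Genes with an enriched site on **both** sides follow this binomial
   path; all other genes fall back to a fixed sliding window (±20 nt for
   starts, ±60 nt for ends, at least 2 supporting reads per cluster),
   which is the intended path for low-coverage genes. Genes with no
   callable TSS or TES form the *rescue* class.
3. **Collapse and filter** (`collapseReads`, `filterTranscripts`).
   Reads collapse into transcript models at 1 bp resolution (identical
   intron chain and identical ends). A model is kept when its start is
   within 10 nt of a called TSS of its gene, its end within 30 nt of a
   called TES, and every junction is high-confidence. Models from rescue
   genes whose junctions are all high-confidence are set aside for the
   integration stage.
4. **End-wobble merging** (`wobbleMerge`). Models with exactly the same
   intron chain whose 5' and 3' ends lie within 100 nt (transitive
   closure) merge into one model that takes the most abundant end
   positions and the summed read support.
5. **Integration** (`integrateRTD`, `monoExonicFilter`,
   `removeDuplicateSequences`). All long-read models with called ends
   are kept. A rescue model is re-admitted when a short-read model
   matches it (same chain, both ends within 100 nt) and it is at least
   80% of the mean short-read transcript length of its gene. Short-read
   models survive only in genes without retained long-read models or
   when they contribute a novel junction; exact matches of retained
   long-read models are dropped as duplicates. Finally, mono-exonic
   genes expressed above 1 TPM in fewer than 2 samples are removed
   unless a transcript codes for an open reading frame longer than
   100 amino acids, and exact spliced-sequence duplicates are removed.
6. **Validation** (`extractFlanks`, `profileMotif`, `proportionTest`,
   `chimeraCount`, `splicingRatioCorrelation`). Called ends are
   validated by positional density profiles of promoter/terminator
   motifs in ±550 nt flanks against random-site controls, with a
   two-proportion chi-square test (no continuity correction) comparing
   instance counts between datasets; candidate RTDs are benchmarked by
   counting transcripts whose genomic span overlaps more than one
   independently sequenced full-length cDNA (chimeras) and by
   correlating RT-PCR splicing ratios with TPM-derived ratios.

## Design decisions in the end caller

Three choices in step 2 were genuinely open and deserve an explanation.

**Windowed support in the enrichment test.** The ±10/±30 nt windows
exist because genuine TSS/TES are not single positions: ends scatter
stochastically around a dominant site, and the windows absorb that
variation during the determination of the sites. We therefore credit a
candidate site with the read support inside its window when computing
`h`, and call sites greedily from the strongest candidate down,
stopping at the first non-significant one. Testing each exact position
in isolation cannot work at realistic 3'-end wobble (standard deviation
around 10 nt): the pile that marks a genuine TES disperses over dozens
of positions, the per-position test never fires, every gene falls to
the fixed-window fallback, and scattered degraded ends then form
spurious 2-read clusters throughout the gene body. The binomial formula
itself is untouched.

**Never call singletons.** The point mass is small both for enriched
*and* for depleted counts, so a lone read end in a deep gene can have
`Pr < 0.01` despite being the opposite of enrichment. A called site
must carry at least 2 reads (`minSupport`).

**Gene-level dichotomy between the two methods.** The fixed-window
fallback applies to genes where the binomial approach fails to reveal
enriched TSS/TES — as a whole, not per side. This matters in the
low-noise limit: a gene in which every read shares one TSS has `t = 1`,
where the point mass is identically 1 and nothing can ever be
enriched; under a per-side mix such a gene would take binomial TES
calls while silently discarding all of its (perfectly valid) TSS
evidence. Under the gene-level rule it falls to the fixed-window path
and keeps both ends.

`t` counts distinct observed end positions with at least one read, not
the gene length: "the total number of starting or end sites in the
gene" is read as observed sites. No multiple-testing correction is
applied across sites within a gene (the threshold is a raw 0.01);
`callEnrichedEnds` exposes `alpha` for users who want it stricter.

## Other numerical and convention choices

* Internal coordinates are 1-based closed (`IRanges` convention);
  BED12 and junction-table readers convert at the boundary. BED12 uses
  the `gene_id;transcript_id` name dialect.
* Mismatch recovery prefers the MD tag and falls back to base-by-base
  comparison against the genome. Insertions and deletions near
  junctions are *not* counted as disqualifying mismatches — only
  substitutions; indel handling is not specified by the rule the filter
  implements, and substitutions are the stated mechanism of junction
  wander.
* Template-switch comparisons that reach past a contig edge are padded
  with a sentinel character that never matches, so short contexts can
  only increase the Hamming distance.
* Wobble-merge ties (equal summed support for two end positions) break
  toward the transcription-direction 5'-most coordinate, making output
  deterministic. Transitive clustering can chain ends more than 100 nt
  apart in total; this is accepted and mirrors the reference merge
  tool's behaviour.
* Gene loci are connected components of strand-aware exonic overlap
  (at least 1 bp, transitively closed), named
  `<prefix><chrom>G<counter*10>` in order of locus start.
* Chimera counting uses strand-aware, span-level overlap; nested or
  duplicate cDNA alignments count as distinct models.
* Motif scanning counts overlapping regex matches at their start
  position. The default motif consensi (TATA `TATA[AT]A[AT]`, Inr
  `[CT][CT]CA[CT][CT]`, Y patch `[CT]{8,}`, Kozak `[AG][ACGT][ACGT]ATGG`,
  PAS `AATAAA`, CFIm `TGTA`) are literature-standard stand-ins and are
  fully configurable.

## The simulator

`simulationConfig()` / `simulateDataset()` generate a genome, truth
transcripts, full-length read alignments, a short-read junction table
and a TPM matrix from a single seed, with all randomness isolated from
the global RNG stream. The defaults describe the study conditions used
throughout the test suite:

* 200 genes on 4 chromosomes, 10% mono-exonic, 2–6 exons of
  120–400 nt, introns 60–400 nt, GC fraction 0.45, intergenic gaps of
  at least 900 nt (so ±550 nt motif flanks never cross genes).
* Log-uniform read depth between 5 and 200 reads per gene; every truth
  transcript receives at least 2 reads where the gene's depth allows,
  because no end-calling rule can recover a single-read end.
* Degradation probability 0.15 per end (≈30% of reads degraded on some
  end), with the truncated end uniform over the transcript body; intact
  ends wobble with Gaussian sd 3 nt (5') and 10 nt (3'), reflecting the
  tighter definition of starts than poly(A) sites.
* Artifact rates: junction shift 5% (1–10 nt displacement plus a
  planted substitution at the shifted exon edge — the mis-mapping mode
  the junction filter targets), template switching 2% (reads splice a
  planted canonical decoy intron whose flanks carry an exact direct
  repeat), internal priming 5% (reads terminate at a planted 18-of-20
  A-tract).
* 20% of multi-exonic genes carry alternative ends: at most one
  alternative TSS and one alternative TES, 150–280 nt from the primary
  site, so same-kind sites remain mutually identifiable under the
  attachment windows. Primary/alternative usage weights are 0.6/0.25/0.15.
* A TATA consensus is planted with its first base 30 nt upstream of
  each primary TSS and a PAS ending 20 nt upstream of each TES, giving
  the motif module a known positive control.

The simulator emulates the *geometry* of the data — block structures,
end distributions, artifact junctions — but reads are emitted as
already-mapped records with perfect mapping outside the planted
artifacts. It does not model base-level quality score profiles,
fragment-length biology, alignment ambiguity in repeats, or
quantification noise beyond a log-normal; passing tests therefore
demonstrate that the filtering logic behaves as specified under
realistic end/junction noise, not that any particular aligner's output
would be filtered with the same operating characteristics.

## Problem sizes in the test suite

The test suite runs the end-calling recovery check on the default
200-gene simulation (about 11,000 reads), the junction filter
sensitivity/specificity check on a 170-gene simulation with elevated
artifact rates (about 600 true junctions), wobble-merge stability on
10,000 random transcripts, and the zero-noise identity check on 60
genes. The binomial mass is verified against an exact big-rational
arithmetic oracle over all `h ≤ n ≤ 30`, `t ≤ 10`, and for
normalisation up to `n = 1000`, `t = 100`.

## Known limitations

* The rescue matching and the 80% length rule compare *spliced*
  lengths; if the intended comparison was genomic span the rule differs
  for genes with long introns.
* rRNA removal is out of scope; `integrateRTD` accepts the result of
  any external screen simply by excluding those models beforehand.
* ORF lengths are consumed, never computed: the mono-exonic exemption
  relies on an external ORF caller.
* The fixed-window fallback will, by construction, emit a site for any
  2 reads agreeing within the window; in deep genes this is prevented
  by the binomial path, but genes sitting exactly at the boundary
  between the two regimes can gain or lose marginal sites with single
  added reads.
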