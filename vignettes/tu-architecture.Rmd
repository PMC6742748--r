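---
title: "Reconstructing transcription unit architecture from end profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing transcription unit architecture from end profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tuarch)
```

## The problem

A bacterial transcription unit (TU) is the stretch of genome transcribed as
one RNA molecule: it begins at a transcription start site (TSS) and ends at
a transcript 3'-end position (TEP), and may carry zero, one, or several
genes. Knowing the TU map of an organism pins down its promoters, 5'
untranslated regions (5'-UTRs), ribosome binding sites and terminators —
the raw material of expression engineering in industrially relevant
actinobacteria such as *Streptomyces*, whose genomes are GC-rich (~70%) and
unusually dense in leaderless transcripts.

Two complementary sequencing assays locate the TU boundaries at nucleotide
resolution:

* **dRNA-Seq** compares a library treated with RNA 5' polyphosphatase
  (TAP+) against an untreated one (TAP−). Primary transcripts carry a
  5'-triphosphate that only ligates after TAP treatment, so genuine TSSs
  are enriched in TAP(+) but not TAP(−); processed monophosphate 5' ends
  appear equally in both.
* **Term-Seq** ligates an adaptor directly to transcript 3' termini, so the
  3'-end positions of its reads mark TEPs, whether they arise from
  termination or post-transcriptional processing (the assay cannot
  distinguish the two, and neither does this package).

`tuarch` implements the full desk side of this analysis: site calling from
per-position end-count profiles, site classification against an annotation,
TU assembly and clustering, and the derived regulatory-feature statistics.
A synthetic-data generator emulates all six library types against a known
ground truth so every stage can be benchmarked without any sequencing data.

## TSS calling

The TAP(+) 5'-end profile is reduced to TSS calls in four steps
(`find_tss()`):

1. every position with at least one 5'-end read is a candidate;
2. candidates less than 100 bp apart chain into clusters;
3. each cluster is greedily sub-clustered left to right so that the
   population standard deviation of member positions stays below 10 nt —
   this isolates the tight dispersion of a real initiation site from the
   loose background of a wide cluster;
4. sub-clusters with a total count above 3 reads emit one TSS at their
   maximum-count member, and a call whose TAP(−) count strictly exceeds its
   TAP(+) count is discarded as a processed end (ties are kept, since only
   an excess in TAP(−) is evidence against a primary end).

Two points in this chain are genuinely underdetermined and were fixed as
package policy: sub-clustering is greedy on sorted positions (deterministic
and order-free), and count ties at step 4 resolve toward the 5'-most
member, which biases toward the longest transcript and therefore a
conservative TU boundary. The count filter can be applied at the cluster
level instead (`count_filter_level = "cluster"`), which is strictly more
permissive; the sub-cluster level is the default because the filter should
act on the same unit that emits a call.

## TEP calling and the leave-one-out modified z-score

Term-Seq 3'-end candidates are restricted to intergenic space, extended by
a 10-nt allowance just downstream of a stop codon (so that closely packed
operons do not mask genuine 3' ends). Candidates less than 10 bp apart
chain into clusters; a cluster spans from its first to its last
read-bearing position and zero-count positions inside the span belong to
it, so the cluster length $N$ is the span length. Each position $x$ with
count $r(x)$ is scored against the *other* positions of its cluster:

$$\mu = \frac{1}{N-1}\Big({-r(x)} + \sum_{y \in C} r(y)\Big),
  \qquad
  \sigma = \sqrt{\mu(r^2) - \mu^2},
  \qquad
  Z(x) = \frac{r(x) - \mu}{\sigma},$$

where $\mu(r^2)$ is the same leave-one-out mean applied to squared counts.
Zero-padding matters: an isolated sharp spike inside a wide span scores
very high because the other positions are mostly zeros. Degenerate cases
are defined by convention: a singleton cluster scores $+\infty$, and when
$\sigma = 0$ the score is $+\infty$ if $r(x) > \mu$ and $0$ otherwise —
so an isolated clean peak survives on the count filter alone, while a
perfectly flat cluster cannot nominate any position. Positions with fewer
than 3 reads or $Z < 3$ are discarded (both bounds inclusive).

Replicate reconciliation: for each pair of overlapping cluster spans, one
from each biological replicate, the TEP is searched inside the span
intersection (clusters spanning positions 3–25 and 13–42 are reconciled
inside 13–25). Only positions that pass the count/z filter in *both*
replicates qualify — that is the reproducibility requirement — and the one
with the highest summed replicate count is emitted (`rank = "max"` or
`"r1"` are available as alternatives; the sum is the default because no
replicate is privileged). A cluster overlapping two clusters of the other
replicate is evaluated against each independently, with duplicate
positions de-duplicated.

## Classification

TSSs: a site within 500 nt upstream to 100 nt downstream of a same-strand
start codon is assigned to that gene (nearest start when several qualify);
per gene, the strongest TAP(+) call is primary (P), the rest secondary (S).
Unassigned sites are internal (I) in a same-strand gene body, antisense (A)
in an opposite-strand body, else intergenic (N).

TEPs: a site strictly between a gene's primary TSS and its start codon, at
least 60 nt from the TSS, is cis-regulatory (C) — this rule is evaluated
*first*, so a 5'-UTR-internal TEP is not absorbed by the upstream gene's
P/S assignment. Otherwise a site less than 500 nt past a same-strand
upstream gene is assigned to it (strongest combined replicate count → P,
rest → S), then antisense inside an opposite-strand body, else intergenic.
Secondary TSS ranking uses the TAP(+) count alone (the TAP(−) count is a
screen, not a strength measure). Antisense is strictly inside the
opposite-strand gene body; no flank is applied because none is defined for
the category.

## TU assembly

From each P/S/I TSS the builder walks downstream gene by gene on the TSS
strand; the walk stops at the first intergenic gap above 500 nt, the
assumed maximum intra-operon distance. Every TEP inside the reachable
extent closes one TU, so alternative 3' ends produce nested, overlapping
TU variants rather than a single longest call — overlapping TUs sharing
genes are an observed feature of dense bacterial genomes, not an artifact.
Cis-regulatory TEPs pair only with TSSs assigned to the same gene.
Antisense and intergenic TSSs scan 1 kbp downstream: a TEP before any
start codon closes a single gene-less TU (the first TEP by default;
`scan_all = TRUE` enumerates all), and a start codon first hands over to
the walking rules.

Minus-strand inputs are mirrored into a 5'→3' frame, assembled with the
plus-strand algorithm and mirrored back, which makes strand symmetry a
structural property rather than a test hope.

TUs are categorized by their associated genes (same-strand genes fully
contained in the span, minus the host gene of an internal TSS): one gene →
mono-cistronic, several → poly-cistronic, none → cis-regulatory when the
next same-strand start codon lies within 500 nt of the TSS, else sRNA. A
TEP inside a gene body can never terminate a TU containing that gene,
because containment requires the full CDS.

The RNA-Seq consistency score (`coverage_consistency()`) is the automated
stand-in for the visual curation a human would do against the
transcriptome: the fraction of TU span positions with depth ≥ 1, passing
at 0.9. Failing TUs are flagged, never silently removed, unless
`drop_failing = TRUE` is requested explicitly. TU clusters are the
connected components of the TU–gene graph: TUs sharing a gene, directly or
transitively, form one cluster; gene-less TUs are singletons.

## Regulatory features

* 5'-UTR length is the distance from a gene's primary TSS to its start
  codon; 0–9 nt is leaderless. A TSS downstream of the start codon
  (possible through the +100 nt assignment window) records length 0 with a
  `tss_internal` flag rather than a negative length.
* Sequence windows for external motif/folding tools use inclusive spans:
  −20..+1 around the TSS (22 nt, −10 element search), −40..−25 (16 nt,
  −35 element), up to 25 nt of 5'-UTR ending at the start codon (RBS
  search, only for 5'-UTRs longer than 10 nt), −41..+20 around the TEP
  (terminator alignment) and −41..−1 (folding input). Windows truncated by
  a replicon edge are dropped with a warning rather than padded.
* The promoter spacer is the count of nucleotides strictly between the
  −35 element's 3' end and the −10 element's 5' end; on real promoter sets
  it concentrates between 8 and 27 nt.
* Nucleotide enrichment divides per-offset base frequencies around sites
  by those around seeded random intergenic positions.
* RPKM is `count / (length/1000) / (total/1e6)`; translation efficiency
  (TE) is Ribo-Seq RPKM over RNA-Seq RPKM, undefined (NA) at zero RNA-Seq
  RPKM. Because the profiles are coverage, counts are estimated as summed
  depth divided by the read length (default 50 nt, a typical short-read
  length for these assays). Library totals default to the summed per-gene
  counts, which makes TE *ratios* between genes exact and scale-free;
  absolute TE values depend on that normalisation choice, so comparisons
  should be within a run.

## The synthetic benchmark

`simulate_dataset()` plants "operon blocks": runs of same-strand genes with
internal gaps at most 500 nt, separated by gaps above 500 nt, one TU per
block. 20% of TUs are leaderless (TSS exactly on the start codon), the
rest get a 10–300 nt 5'-UTR; each TU's TEP falls 20–200 nt past its last
stop codon; the genome is drawn at GC 0.72. Start codons are planted as
ATG so codon tallies have a known truth.

Profiles emulate exactly the contrasts the callers exploit: TAP(+) peaks
at TSSs (Poisson counts, mean 10, integer Gaussian jitter of 1 nt per
read) with TAP(−) receiving a 20% binomial thinning of the same reads;
processed 5'-end sites (0.02 per kb — a deliberately small rate, standing
for the minority of stable processed termini, planted away from TSSs)
peak with equal mean in both TAP libraries; Term-Seq replicates draw
independent Poisson peaks exactly on each TEP — 3'-adaptor ligation is a
nucleotide-precise event, so no jitter is applied there, and the
leave-one-out z-score in fact requires sharp peaks to be self-consistent
at these peak sizes; uniform iid Poisson background (0.01 reads/nt) covers
everything. RNA-Seq coverage is a per-TU plateau between TSS and TEP and
Ribo-Seq scales each CDS by a planted log-normal TE factor.
`count_noise = FALSE` switches every count to its rounded mean — the
zero-noise study condition under which the callers recover the planted
architecture exactly and TU assembly equals the planted TU set.

What the generator does *not* model, and what passing tests therefore do
not show: RNA degradation gradients, position-correlated background
between the TAP libraries, sequencing-error or mappability artifacts,
rRNA contamination, condition-dependent TU switching, and genuinely
ambiguous processed ends. Two known consequences on noisy simulations:
roughly half of the planted processed sites survive the TAP(−) screen
(the screen discards only a strict excess, measured at a single position),
and iid background occasionally forms tight ≥4-read sub-clusters that the
count filter admits. Both are precisely the call classes that the original
experimental workflow removed by manual inspection against RNA-Seq; the
package flags rather than deletes them, so benchmark spurious-call rates
on noisy simulations run above what a curated set would show.

## Numerical and scale choices

Default benchmark sizes keep every stage fast: the recovery benchmark uses
200 genes (~340 kb, ~150 TUs) and runs the whole pipeline in seconds; unit
tests use 6–40 genes. All randomness flows from a single integer seed per
dataset (truth, end profiles and coverage use seed, seed+1, seed+2), so a
dataset is a pure function of its configuration. The z-score guards
against floating-point cancellation by clamping tiny negative variances to
zero, and sub-clustering computes running moments against the cluster
origin so the SD bound is numerically exact at genomic magnitudes.

## Limitations

The package deliberately stops where external tools take over: motif
discovery, RNA folding and ΔG, covariance-model searches and functional
enrichment all consume this package's window and table outputs. Multiple
replicons are not multiplexed in one call — profiles carry a sequence name
and each replicon is processed on its own, which matches the
single-chromosome organisms this workflow targets. Term-Seq processing
versus termination is not resolved, and the RNA-Seq consistency score is a
coarse surrogate for expert curation, tunable but not a replacement.
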