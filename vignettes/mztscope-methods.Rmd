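---
title: "Methods: quantifying the maternal-to-zygotic transition and curating lncRNA candidates"
author: "mztscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying the maternal-to-zygotic transition and curating lncRNA candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The analysis problem

During early embryogenesis the transcriptome is first supplied entirely by
the mother: mRNAs loaded into the oocyte drive development until, at the
mid-blastula transition (MBT), the embryonic genome takes over. Two
RNA-seq library chemistries see this handover differently. A polyA-selected
library (**PA**) reports a transcript in proportion to both its abundance
and its poly(A) tail, while a ribosomal-RNA-depleted total-RNA library
(**RZ**) reports abundance regardless of adenylation state. A transcript
that is present but deadenylated — the fate of many maternal mRNAs after
fertilisation — is visible in RZ and depleted in PA, so the log-ratio of
the two measurements acts as a proxy for relative polyadenylation state.

`mztscope` implements this analysis as a tested pipeline over four
connected pieces:

1. **Expression dynamics** — exon-model RPKM, PA/RZ ratios, and the
   maternal / embryonic / RZ-enriched classifications, plus profile
   clustering, induction timing and qPCR fold changes.
2. **Gene-model validation** — an annotation pipeline that groups,
   updates and validates transcript models against splice junctions,
   RNA-seq coverage, H3K4me3 promoter peaks and RNAPII coverage, and
   discovers new gene models (NGM).
3. **Coding potential** — six-frame maximal ORF length and a codon-bias
   log-likelihood ratio summed over 90-bp windows.
4. **lncRNA curation** — a stepwise filter chain that reduces validated
   new gene models to high-confidence stand-alone lncRNA candidates.

A fifth piece, the **synthetic-data generator**, plants a fully labelled
toy study so that every step above is testable without any external data.

## Expression model

**RPKM.** For an exon of length $L$ bp carrying $c$ uniquely mapped reads
in a library of $T$ total mapped reads,

$$\mathrm{RPKM} = \frac{c}{(L/1000)\,(T/10^6)}.$$

A gene's RPKM is the arithmetic mean over its *non-redundant* exons: the
union of exons over all isoforms of the gene, where exons identical in
chromosome, strand, start and end are counted once. `compute_gene_rpkm()`
implements exactly this rule; counts for identical exons are reconciled by
taking the maximum (they are the same reads).

**Polyadenylation ratio.** `log2_pa_rz()` computes
$\log_2\!\big((\mathrm{PA}+p)/(\mathrm{RZ}+p)\big)$ per gene and stage
with pseudocount $p$ (default $0.01$ RPKM, small relative to the working
range of the classifications, which operate at RPKM $\geq 1$). The
pseudocount makes silent genes score exactly 0 rather than 0/0; $p = 0$
is allowed for boundary-exact work on strictly positive tables.

**Classifications.** The three calls are threshold rules, applied to the
matrix only:

* *maternal*: oocyte RPKM $\geq 1$ in PA **or** RZ (`select_maternal`);
* *embryonic*: some post-oocyte stage reaches $\geq 10\times$ the oocyte
  level in the PA library (`select_embryonic`) — the PA library because
  newly made embryonic transcripts are polyadenylated and the embryonic
  gene set is defined over polyA$^+$ data;
* *RZ-enriched at a stage*: $\log_2(\mathrm{PA}/\mathrm{RZ}) \leq -0.5$
  (`select_rz_enriched`), by default restricted to maternally called
  genes so that pseudocount artifacts on silent genes can never be called
  "deadenylated". A flag disables the maternal gate.

All three boundaries are closed (the printed value is included), and the
package asserts them at equality in its tests.

**Clustering and timing.** `cluster_kmeans()` wraps `stats::kmeans` under
a fixed seed, on either $\log_2(\mathrm{RPKM}+p)$ or rows scaled to sum
to one (`scale_rows`; all-zero rows are returned as zeros and flagged
rather than dropped, so matrix shape is preserved). Defaults of $k = 7$
for ratio profiles and $k = 6$ for embryonic stage profiles follow the
cluster counts used in this style of analysis; $k$ is a free parameter.
`induction_timing()` reports, per stage, the cumulative fraction of
embryonic genes whose earliest $\geq$ 4-fold induction is at or before
that stage; `peak_stage_fractions()` assigns each gene to its expression
maximum with ties going to the earliest stage (deterministic and
biologically conservative). `ddct_fold_change()` implements
$2^{-\Delta\Delta C_t}$ relative quantification against a normaliser gene
and a reference stage.

## Gene-model validation pipeline

`run_xtev()` executes five steps in order; every status transition is
recorded in a machine-readable log.

1. **Collect.** Reference models are loaded; evidence transcripts that
   share at least one *exact* exon with a reference model are adopted as
   additional isoform models of that gene. Exact identity — not overlap —
   is also the "shared exon" relation for gene grouping
   (`group_gene_models`, connected components via union-find): grouping
   by mere overlap would fuse unrelated overlapping genes.
2. **Update.** Splice junctions are trusted at $\geq 5$ supporting reads
   (`filter_junctions`). Evidence transcripts on the same strand sharing
   at least one exact trusted junction with a model contribute their
   exons (`update_models_with_evidence`), typically extending 5′ and 3′
   ends; original exons are never removed. Junction sharing is the
   linkage criterion because it is the standard assembly-merge rule that
   avoids chimeric fusions.
3. **Expression.** A model is expressed when at least $1/3$ of its exons
   (compared as an exact rational, no rounding) carry $\geq 3$ pooled
   RNA-seq reads (`is_expressed`).
4. **TSS validation.** A model's TSS is validated (status **V**) when its
   strand-aware first exon overlaps an H3K4me3 peak by $\geq 1$ bp. For a
   gene with no validated model, `rescue_upstream_tss()` searches up to
   50 kb upstream (an explicit cap; unbounded search is ill-defined at
   chromosome scale) for a peak with (a) no model of a different gene in
   between and (b) mean RNAPII over the intervening region at least half
   the gene-body mean (first-exon start to last-exon end, introns
   included — the conventional reading of "gene body"). Success marks the
   gene **U**; otherwise models without their own peak are **X**.
   Separately, a peak inside the model span but downstream of the first
   exon flags a putative alternative TSS.
5. **Selection.** One representative model per gene, by decreasing
   importance: validated TSS (V or U), number of expressed exons, number
   of exons; remaining ties go to the longest genomic span and then the
   smallest model id, so selection is deterministic.

Evidence transcripts that were not adopted are **NGM candidates**:
spliced candidates with zero exonic overlap ($\geq 1$ bp, strand-blind —
the conservative reading for claiming novelty; a flag restricts to the
same strand) against the reference become NGM, unspliced single-exon
candidates are routed to an excluded list. NGM with expression *or* EST
support *and* a validated TSS become **NGM-vv** (a flag requires both
kinds of expression evidence instead).

The upstream-rescue blocker test deliberately considers only models of
the grouped annotation collection, not NGM candidates: a stray 5′-UTR
fragment sitting between a peak and its truncated gene must not block
that gene's rescue.

## Coding potential

`build_llr_table()` turns a coding codon-usage table and a noncoding
triplet-frequency table into per-codon log-likelihood ratios
$\mathrm{LLR}_i = \log_2(c_i/n_i)$, where $c_i$ and $n_i$ are the
likelihoods of codon $i$ conditional on its amino acid in coding and
noncoding sequence. Stop codons form their own conditional class. Classes
with a single codon (Met, Trp) are forced to $c_i = n_i = 1$, hence
LLR 0. Zero frequencies are smoothed by adding half the smallest positive
weight of the table, keeping every LLR finite without distorting
well-populated classes.

`max_orf_aa()` scans all six frames (three offsets × two strands) for
ORFs from an ATG to the first in-frame stop. Length counts Met through
the last sense codon (stop excluded); runs reaching the sequence end
without a stop are counted. Both conventions matter at the 100-aa
curation cutoff and are therefore fixed and documented rather than left
implicit. Codons containing N never match ATG or a stop and contribute
LLR 0 — the neutral treatment of ambiguity.

`max_window_llr()` sums LLRs over every run of 30 consecutive codons
(90 bp) in each frame, sliding by one codon — codon-aligned windows,
because a 1-bp slide would merely revisit the other frames — and returns
the maximum over all windows and frames. Sequences shorter than one
window score their single maximal in-frame codon run. The implementation
is checked exactly against an exhaustive enumeration oracle.

**Bundled tables.** The shipped tables are *synthetic stand-ins*, named
accordingly (`codon_usage_coding_synthetic.tsv`,
`triplet_freq_noncoding_synthetic.tsv`). The noncoding background is an
independent-nucleotide model at 33% A, 33% T, 17% C, 17% G — the AT-rich
composition typical of intergenic amphibian DNA. The coding table keeps
the amino-acid marginals of a representative vertebrate usage table but
concentrates 85% of each synonymous class on the codon rarest in the
noncoding background. This deliberately strong synonymous bias gives the
two models enough divergence (about 1.4 bits per codon under the
noncoding model) that the *sign* of the maximal window score separates
sequences sampled from the two models — the regime the generator's
recovery tests and the bundled classifier threshold assume. Real
organism tables are less divergent; with them, users should expect
distributional separation (coding scores shifted upward) rather than a
clean threshold at zero, and should calibrate any cutoff on their own
data.

## lncRNA curation

`curate()` applies four intersective filters to the NGM-vv set, then an
exclusion list:

1. maximal ORF $\leq 100$ amino acids (the standard lncRNA criterion);
2. no promoter-less downstream gene: a candidate is removed when the
   nearest downstream gene on the same strand (within 10 kb of the
   candidate's 3′ end — UTR fragments are promoter-proximal, so a bounded
   search suffices) has gene-level status X or U, i.e. the candidate is
   plausibly that gene's stray 5′-UTR fragment;
3. every exon at RPKM $\geq 1$, using the pooled **maximum** across
   stages and libraries — a transcript strongly expressed at one stage
   should not fail a stage-averaged floor;
4. at least one intron exactly matching a supported splice junction
   (donor and acceptor; an all-introns mode is available).

Because the filters are set intersections, the final set is independent
of application order; the report records each filter's verdict per
candidate and the funnel attrition. The exclusion list externalises the
homology/manual screening step (BLASTN/BLASTP against protein-coding
sequence, genome-gap inspection): that step is database-version-dependent
and not reproducible at desk scale, so the automated pipeline consumes
its result as a plain id list and stays deterministic.
`mean_conservation()` summarises a phastCons-style track over exonic
bases only (the comparison of interest is exon versus mRNA exon), with
uncovered bases excluded and an all-missing result reported as `NA`.

## The synthetic study

`simulate_mzt_study()` generates a complete input bundle — genome,
reference and evidence annotations, per-exon counts, junctions, peaks,
RNAPII coverage — deterministically from one seed, together with the
planted truth.

**Conditions.** Six stages (oocyte, st6, st9, st12, st16, st30) with one
PA and one RZ library each; 10 genes in each of five classes (maternal
polyadenylated, maternal deadenylated, maternal-embryonic,
embryonic-only, stand-alone lncRNA); 3 + 3 + 5 artifacts (5′-UTR
fragments, broken gene halves, unspliced single-exon models — the three
failure modes the curation explicitly targets); sequencing depth of 20
reads per exon kilobase at RPKM 1, i.e. $2 \times 10^7$ mapped reads per
library, the order of magnitude of a typical early-embryo RNA-seq stage
after alignment and filtering.

**Profiles.** Piecewise-constant stage profiles with one onset stage per
induced gene: maternal levels are log-normal around RPKM 10 and decay
after MBT; deadenylated genes keep their RZ level while PA drops by a
factor of $2^{r}$ with $r \sim U(-3, -0.5)$ at stages 6 and 9 (the
deadenylation window; the lower bound is a modelling choice, not an
empirical claim); maternal-embryonic genes start at RPKM 1.5–5 and rise
15–40×; embryonic-only genes are silent in the oocyte and switch on at a
random post-MBT onset; lncRNAs are spliced 2–4 exon genes expressed from
st9 at about one third of the coding median. Counts are Poisson with the
mean given by inverting the RPKM formula — the simplest count model;
overdispersion is a configuration extension, not the default.

**Chromatin.** Every expressed gene receives an H3K4me3 peak overlapping
its true first exon with probability $1-\mathrm{dropout}$, and constant
RNAPII over its body. Rescue-case genes (the UTR-fragment parents) are
emitted 5′-truncated in the reference, with the peak strictly upstream of
the omitted UTR exons and connecting RNAPII at body level — so upstream
rescue holds by construction and the fragment never overlaps a peak at
its own 5′ exon.

**What it does not emulate.** No read-level simulation (no FASTQ,
sequencing errors, positional bias, fragment-length effects), no
overdispersion by default, no isoform switching, no intergenic
transcriptional noise, and peaks/coverage are rectangles rather than
realistic ChIP shapes. Recovery of the planted labels therefore
demonstrates the correctness of the decision rules under their own
assumptions, not robustness to the full messiness of real libraries.

## Numerical and degenerate-input policy

* Pseudocount 0.01 RPKM for all log-ratios and folds; configurable, zero
  allowed where inputs are positive. 0/0 under zero pseudocount yields
  `NaN` and is treated as "not called".
* Fractions like the 1/3 expression rule are compared as exact rationals.
* All classification boundaries are closed intervals at the printed
  values.
* `scale_rows` flags, rather than drops, all-zero rows; correlations of
  zero-variance conditions are `NA`; conservation with no covered base is
  `NA`; `signal_mean` over a zero-length region is an error.
* Ties: peak stage → earliest stage; representative model → longest
  span, then smallest id; gene ids → lexicographically smallest member.
* K-means runs with 10 restarts under a caller-supplied seed, with the
  caller's RNG state restored afterwards.

## Problem sizes

The test suite and the acceptance script run the generator at its default
50 genes + 11 artifacts on a ~0.5 Mb chromosome, score 200 sequences per
class for the separation check, and verify the window scorer against
exhaustive enumeration on 200 sequences of 90–600 bp and the ORF scanner
on 1,000 sequences up to 2 kb — sizes chosen so the whole suite completes
in a few minutes on one CPU while still exercising every rule at its
boundary.

## Known limitations

* Counts are consumed as per-exon tables; producing them from BAM files
  (alignment, deduplication, multi-mapper exclusion) is upstream of this
  package, as are transcript assembly and junction calling.
* The expression classifications are threshold rules, not statistical
  tests; no variance model or multiple-testing machinery is attached, by
  design.
* Evidence-based model updating links only through exact shared splice
  junctions; it will not merge junction-free (e.g. single-exon) evidence
  into a model.
* The bundled frequency tables are synthetic (see above); organism tables
  should be substituted for real analyses.
* Conservation summaries assume a single-genome phastCons-style track;
  no alignment handling is included.
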