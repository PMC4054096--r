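---
title: "Comparing two CLIP-seq experiments with diffclip"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing two CLIP-seq experiments with diffclip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diffclip)
```

## The problem

An RNA-binding protein (RBP) leaves a genome-wide footprint that CLIP-seq
reads out as clusters of short, strand-specific tags, often decorated
with crosslink-induced mutations. Given two such experiments — two
genotypes, treatments, or tissues — the question is *where the protein
binds more strongly in one condition than the other*, quantitatively,
not merely which peak calls overlap. Two obstacles stand in the way:
libraries differ in depth *and* in signal-to-noise ratio, so no single
global scaling factor aligns them; and the signal is spatially coherent —
adjacent positions along a binding site rise and fall together — which
per-bin tests ignore.

`diffclip` works on small fixed-width bins inside tag clusters and
couples a bin-level MA normalization with a three-state hidden Markov
model (HMM) along each cluster.

## Preprocessing by protocol

Tags are read strand-specifically from SAM/BAM (1-based SAM coordinates
become 0-based half-open internally; unmapped, secondary and
supplementary records are dropped; reads are never shifted or extended).

* **HITS-CLIP / PAR-CLIP.** Reads sharing `(chrom, start, end, strand)`
  are PCR duplicates and collapse to one tag. We read "same mapping
  coordinates" strictly — both ends, not just the 5′ position — so
  different-length tags are never merged. Mutation lists of collapsed
  duplicates merge as a distinct union, so amplification cannot inflate
  mutation counts. Characteristic mutations are collected per tag:
  deletions from CIGAR `D` operations (one event per deleted base), or
  substitutions by walking the MD tag against the read laid out in
  reference space. On `−`-strand tags a transcript conversion appears
  complemented on the forward reference strand, so T→C profiling keeps
  A→G events there (G→A keeps C→T, symmetrically). Requesting
  substitution profiling without MD tags is an error rather than a
  silent empty result.
* **iCLIP.** Duplicates are removed *before* mapping: reads identical
  over their full sequence (5′ random barcode **and** insert) are PCR
  copies; barcode equality alone would collapse distinct cDNAs. After
  mapping, each cDNA's crosslink nucleotide — the base immediately
  upstream of its 5′ end (`start − 1` on `+`, `end` on `−`, by strand
  symmetry) — is expanded by `expansion_width` bases on each side, and
  these windows replace the tags. Mutant counts are always zero for
  iCLIP.

Clusters are maximal strand-specific runs of bases covered in *either*
condition; tags keep their condition identity. Each cluster is cut into
`bin_size` windows (the last bin may be shorter; it is kept as-is, not
length-normalised — bin-size choice is not critical, and terminal bins
carry little weight). The tag intensity of a bin is the sum of per-base
coverage over its bases, so a 5-bp bin fully covered by one spanning tag
scores 5.

## Stage 1: modified MA normalization

For bin counts $x_1, x_2$ and pseudocount $c > 0$,

$$M = \ln(x_1 + c) - \ln(x_2 + c), \qquad
  A = \ln(x_1 + c) + \ln(x_2 + c).$$

If most well-covered bins are commonly bound at similar strength, their
$M$ should scatter around a depth/noise offset that may drift with
abundance $A$. An ordinary least-squares line $M = a + bA$ is fitted to
bins with $x_1$ and $x_2$ both strictly above `joint_count_cutoff`, and
$M_{\mathrm{adj}} = M - (a + bA)$ is computed for **every** bin in all
clusters, extrapolating the scaling relationship to the whole dataset.
Natural logarithms and plain OLS throughout; with fewer than two
qualifying bins (or no spread in $A$) the fit aborts with advice to
lower the cutoff.

## Stage 2: mixture emissions and the three-state HMM

Bin states are $I = 0$ (stronger in condition 1), $1$ (non-differential),
$2$ (stronger in condition 2). Adjusted $M$ is modelled by a
three-component normal mixture with means $+\mu, 0, -\mu$, shared
variance $\sigma^2$, and outer weights $p$ each:

$$f(M) = p\,\varphi(M; \mu, \sigma) + (1 - 2p)\,\varphi(M; 0, \sigma)
       + p\,\varphi(M; -\mu, \sigma).$$

The zero-mean component is pinned at 0 because normalization centres
common binding there; shared variance avoids degenerate assignments at
extreme $M$; the $\pm\mu$ symmetry keeps the model minimal. Estimation
is deliberately not a full EM:

1. $\hat\sigma = \mathrm{median}(|M - \mathrm{median}(M)|) \times
   1.4826$, treating the outer components as outliers of the dominant
   middle one. This is consistent when common binding dominates and
   degrades gracefully (inflates) as the outer mass grows — one reason
   the method insists on a majority of common sites.
2. The mixture's second moment equals the sample second moment
   $\hat\mu_2 = \sum M^2 / n$ exactly when
   $\hat\mu_2 = 2p\mu^2 + \hat\sigma^2$, so each candidate $p$ implies
   $\mu(p) = \sqrt{(\hat\mu_2 - \hat\sigma^2)/(2p)}$.
3. The likelihood is maximised over the grid
   $p \in \{0.001, 0.002, \ldots, 0.499\}$ with $\mu$ tied by the
   constraint; $\mu$ is never gridded independently. Log-space sums of
   the three weighted densities guard against underflow. Grid points
   with $\hat\mu_2 \le \hat\sigma^2$ are infeasible; if all are, there
   is no detectable differential signal and the run aborts.

One caveat worth knowing: under the constraint, $2p\mu^2$ is pinned to
the excess second moment at *every* grid point, so when there is no real
outer mass the profile likelihood in $p$ is nearly flat and $\hat p$
itself is weakly identified — the fitted *density* is still essentially
the null normal. When $1 - 2\hat p < 0.5$ (strictly) a warning reports
that the common-binding assumption may not hold; analysis continues.

Emission densities $\varphi(M_{\mathrm{adj}}; \pm\mu\ \mathrm{or}\ 0,
\hat\sigma)$ are computed once per bin and frozen. State 0 pairs with
$+\mu$ because $M > 0$ means condition 1 is higher. Every cluster is one
observation sequence; all sequences share one 3×3 transition matrix and
the fixed emissions. Training is Baum–Welch restricted to the transition
matrix (the canonical completion of "iterate with frozen emissions"):
scaled forward–backward per cluster, expected transition counts pooled,
rows renormalised. The initial state distribution stays uniform
(1/3, 1/3, 1/3) and is never re-estimated. Decoding is per-cluster
Viterbi in log space with ties broken toward the lowest state index, so
output is deterministic. Adjacent same-state bins merge into regions
(never across clusters), which can be screened by state and mean
intensity (`filter_regions()`), e.g. keeping stronger-in-condition-1
regions averaging at least 30 tags in condition 1.

## Parameters

| parameter | default | meaning |
|---|---|---|
| `bin_size` | 5 bp | observation unit; small keeps near-nucleotide resolution |
| `min_cluster_tags` | 10 | drops singleton noise clusters (combined count; clusters are defined jointly) |
| `pseudocount` | 1 | guards $\ln 0$; "a small number" on count scale |
| `joint_count_cutoff` | 5 | strict lower bound on both counts for regression bins, about one tag-depth unit per base at the default bin size |
| `expansion_width` | 2 | iCLIP crosslink window half-width (5 nt window), matching the bin-size scale |
| `mutation_type` | by protocol | deletion (HITS-CLIP/AGO), T2C or G2A (PAR-CLIP), none (iCLIP) |
| `hmm_max_iterations`, `hmm_tolerance` | 100, 1e-4 | stop when every transition entry moves less than the tolerance |
| starting transitions | diag 0.9 | encodes spatial persistence without favouring a state; re-estimated anyway |

## What the synthetic data does and does not emulate

`simulate_clip_pair()` plants regions of known type on a toy genome (two
100-kb contigs of uniform random sequence): a `common_fraction` of
regions bind equally, the rest are stronger in one condition with their
expected depth multiplied by `diff_ratio` (default 4); `depth_ratio`
additionally scales all of condition 2 to emulate unequal sequencing
depth. Reads (default up to 36 nt, lengths varying as after adapter
trimming — constant-length reads would saturate coordinate-based
duplicate collapsing and mute planted depth effects) fall uniformly in
their region; a `dup_fraction` of PCR copies exercises deduplication.
Crosslink footprints are planted at region centres: deletions
(HITS-CLIP), T→C conversions with the reference base forced to T/A so
the event is representable on the forward strand (PAR-CLIP), or
truncation-start cDNAs plus barcode-carrying FASTQ (iCLIP).
`simulate_bin_sequences()` and `simulate_mixture_draws()` generate
directly from the HMM and mixture for estimator-level validation with
known truth.

Deliberately **not** emulated: transcriptome-aware read placement,
expression-dependent background, sequencing errors beyond the planted
mutations, mappability structure, and within-region binding-strength
gradients. Passing tests therefore demonstrate the correctness of the
algorithmics and the estimators under the stated generative model, not
performance on any particular real library.

A note on protocol regimes: iCLIP bins count expanded crosslink windows,
so each cDNA contributes $2w+1$ correlated base counts and the per-bin
log-ratio noise corresponds to the cDNA events, not the summed counts.
At equal nominal depth an iCLIP comparison is therefore noisier per bin
than a HITS-CLIP one, and with shallow simulated depth the mixture can
approach its degenerate corner (large $p$, small $\mu$) — correctly
flagged by the common-fraction warning. iCLIP examples in the test suite
use a cDNA depth of 80 per region, a realistic order for published
libraries.

## Numerical and degenerate-input choices

* Forward–backward uses per-position scaling; Viterbi and the mixture
  likelihood work in log space.
* A transition row whose state is never visited resets to uniform with a
  warning rather than propagating 0/0.
* All-identical adjusted $M$ (MAD 0) and infeasible moment constraints
  are fatal with explanatory messages.
* Chromosomes are processed in lexicographic order, clusters
  left-to-right, so equal inputs give byte-identical outputs; there is
  no hidden randomness anywhere in the pipeline (seeds matter only to
  the simulators).
* Crosslink windows truncate at position 0 with a logged note.
* Paired-end mode: a properly-paired fragment contributes one tag over
  the outer fragment span; orphan mates count as single-end.

## Problem sizes used in validation

The shipped validation works at desk scale, chosen so the full suite
runs in minutes: exhaustive-enumeration oracles check Viterbi and
forward–backward on all $3^L$ paths for sequences up to length 6;
mixture recovery uses 200,000 draws; transition recovery uses 500
simulated clusters of 50 bins; end-to-end recovery uses 60 planted
regions at a 4× differential effect. `scripts/acceptance.R` recomputes
all of these from a single seed.

## Limitations

* Exactly two conditions; a multi-sample extension would need a larger
  state space and a different normalization (e.g. TMM-style).
* Transcript abundance is not modelled; a binding change is not
  distinguishable from an expression change without external data.
* The independence assumption used during mixture estimation is at odds
  with the spatial dependency the HMM then models; this two-step
  pragmatism is inherited by design.
* MAD-based $\sigma$ inflates when differential mass is large; results
  outside the majority-common regime (the <50% warning) should be
  treated with caution.
* Regions are reported with hard Viterbi labels; no posterior
  probabilities are emitted.
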