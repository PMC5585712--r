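---
title: "Models and methods behind tnseqr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind tnseqr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

tnseqr analyzes mariner (Himar1) transposon-insertion sequencing data: from
barcoded MmeI junction reads to per-feature essentiality calls and
conditional-fitness estimates. This vignette describes the underlying models,
the conventions the implementation commits to where the experimental
literature leaves room, and what the synthetic-data generator does and does
not emulate.

## The insertion-site model

Mariner transposons insert only at TA dinucleotides. A site is identified by
the 0-based offset of its T on the forward strand; since TA is its own
reverse complement, this one key canonically names the site regardless of
which junction orientation a read later comes from. Multi-record FASTA
genomes are treated as separate replicons and keys become (replicon, offset)
pairs. Ambiguity codes are a hard error by default because zero-mismatch
matching is undefined over N; an optional masking mode keeps N bases, which
silently removes any site or alignment overlapping them.

**Site-to-feature assignment.** A TA site belongs to a feature when its
strand-aware *first base* — the T for a `+` feature, the A for a `-` feature
— lies within the feature's coordinates. This tie-break for boundary-
straddling sites was chosen because it is exactly symmetric under reverse
complementation of the genome (a property-tested invariant), so annotations
on either strand are treated identically.

**The 5' exclusion rule.** Insertions in the first 5% of a coding feature
frequently fail to produce a knockout phenotype, so sites whose 5' offset is
less than `floor(exclusion_fraction * length)` bases are discounted from all
per-feature statistics. The floor makes the window deterministic and
conservative; offsets are clamped at zero so that `exclusion_fraction = 0`
always retains every overlapping site.

## Read processing

Reads are demultiplexed by exact barcode match (zero barcode mismatches is
the default because junction reads are short and fixed-layout; the barcode
may sit in the FASTQ header comment, the post-demultiplexing convention of
the simulator, or in-line at the read start). The transposon tag must appear
at its expected offset; the remaining genomic portion is kept only if at
least 16 bp, and truncated to 21 bp from the junction end because MmeI
releases 20 ± 1 bp and longer remainders indicate adaptor read-through.

Mapping is exact and full-length over both strands of every replicon
(dictionary matching with a 16-bp seed equal to the minimum read length plus
full-length verification). Exactly one matching locus makes a read unique;
two or more make it ambiguous — excluded from site assignment but retained
in the totals that normalization uses, since they are genuine library
molecules; zero make it unmapped. A unique alignment is inverted to its TA
site by the junction-geometry convention below; alignments adjacent to no TA
are tallied separately as `off_ta`. The accounting invariant — unique +
ambiguous + unmapped + off_ta + too_short + undemultiplexed equals the input
read count — is enforced in tests. Reads whose barcode or tag cannot be
recognized are both counted as `undemultiplexed` (demultiplexing here means
barcode *and* tag recognition), and reads assignable to no sample are
accounted under a `<undemultiplexed>` pseudo-sample so no read is dropped
silently.

**Junction geometry.** For orientation `+` the read is `read_length` bases
starting at the TA's T rightward on the forward strand; for `-`, the
`read_length` bases ending at the A leftward, reverse-complemented. This is
one concrete, invertible convention among several consistent with a 20-bp
MmeI junction; it is declared rather than inferred, and the simulator and
mapper share it, which the round-trip tests exploit.

## Normalization and essentiality

Counts are scaled so each sample's `unique_mapped + ambiguous` total equals
a reference total (default 4e7 reads, the depth at which the classification
thresholds are defined). Per feature, raw and normalized reads are summed
over available (beyond-window) sites only; insertion density is distinct
sites hit per kb of *full* feature length.

A feature is called **essential** when it has fewer than 300 normalized
reads and fewer than 4 insertion sites per kb. The read threshold scales
linearly with the reference total (it derives from sequencing depth); the
density threshold does not (site density saturates). The default combination
mode requires *both* criteria, which corrects small genes with few TA sites
and large genes tolerating inter-domain insertions; an `either` mode is
provided because the criterion can also be read as an OR, and it always
yields a superset of calls (property-tested). Features with fewer than 3
available sites, or containing sites affected by ambiguous-read exclusion
(e.g. tandemly duplicated loci), are called `low-confidence` instead of
either class, since their evidence cannot distinguish essentiality from
unmappability.

## The fitness model

For feature abundance measured after `G_p` generations of selective growth
at parent doubling time `td_p`, the read ratio between condition and control
under exponential growth is

$$\frac{R_\text{cond}}{R_\text{ctrl}} = \frac{2^{T/x}}{2^{T/t_{dp}}},
\qquad T = G_p \, t_{dp},$$

so the log2 ratio $L$ gives the apparent doubling time
$x = T / (G_p + L)$. With the defaults ($t_{dp} = 10$ h, $G_p = 6$, so
$T = 60$ h): $L = 0 \Rightarrow x = 10$ h, $L = -2 \Rightarrow x = 15$ h (a
50% increase in apparent doubling time — the default defect cutoff), and
$L = -3 \Rightarrow x = 20$ h. An absolute-time override (`total_time_h`) is
available for designs where elapsed time is known independently of
generation count; the default time base is $G_p t_{dp}$ because it makes the
−2 ↔ 15 h correspondence exact. When $G_p + L \le 0$ the mutant shows a net
decline over the experiment and no finite doubling time exists; such
features keep their (very negative) $L$ and growth class but are flagged
`declining` with `td_h = NA` rather than being assigned a negative doubling
time, which the model does not define. Note that any `declining` feature
necessarily satisfies $L \le -G_p$, far below the defect cutoff, so the flag
never changes a classification.

**Pseudocount.** One normalized read is added to numerator and denominator
so zero-read features stay finite. At the reference depth a feature's
normalized reads are in the thousands, so the shrinkage is negligible except
exactly where it is needed.

**Replicates.** Fixed thresholds, not hypothesis tests, define calls —
mirroring the two-reactor-replicate design this models — so no p-values are
computed. When both conditions carry ≥ 2 replicates with matching replicate
numbers, a consistency filter (default on) demotes a `defective` call unless
every replicate pair is at or below the cutoff. `L` and `td` are reported
unrounded, with 1-decimal display columns; classification always uses
unrounded values.

## What the simulator emulates

The generator reproduces the logical structure of a two-condition selection
experiment with known ground truth:

* a seeded random genome at a configurable GC content (default 0.60,
  matching a high-GC metal-reducing deltaproteobacterium) with
  non-overlapping features tiled at ~85% coverage; every feature is
  guaranteed ≥ 2 TA sites beyond its 5' window, locally planting TA
  dinucleotides if the random sequence violates this;
* a library of K distinct insertions sampled uniformly without replacement,
  with a **colony-selection bottleneck**: clones disrupting the available
  region of a condition-lethal feature never form colonies and are removed
  at pooling, not during propagation — matching a plating protocol.
  Survivors start at equal abundance (the post-pooling abundance
  distribution is not otherwise constrained by anything we model, so
  equality is the flagged, minimal assumption);
* deterministic exponential propagation: abundance × $2^{T/t_{d,i}}$ with
  $T$ = generations × parent doubling time; intergenic insertions and
  5'-window insertions are always neutral; infinite doubling times give a
  factor of 1;
* the two-arm design: both the test arm and the parallel control arm
  receive the same post-selection outgrowth, so it cancels in ratios —
  which is precisely why such experiments use a parallel control;
* multinomial sequencing at depth D with equal-probability junction
  orientations, constant-quality Phred 33 FASTQ, per-sample barcodes, and
  an exact per-site truth table; optional per-base substitution errors
  (which make reads unmappable under zero-mismatch mapping; the expected
  mappable fraction is exposed for assertions) and optional 19–21 nt MmeI
  length jitter (default off, mirroring the canonical 20 bp).

Not modeled: PCR duplicates, GC amplification bias, realistic quality
scores, or bottleneck drift beyond multinomial sampling. Replicate samples
differ only by the sequencing draw, so simulated replicate correlations are
an upper bound on what messy biology delivers; passing recovery tests shows
the estimator chain is correct, not that real libraries are this clean.
Library construction samples only sites far enough from replicon ends for
both junction orientations to yield full-length reads (the genome is
treated as linear).

A composition caveat: normalization re-expresses abundances relative to the
whole population, so when defective clones make up a non-trivial share, all
ratios shift by $-\log_2$(total relative growth) — a second-order effect the
exponential-growth equation ignores. With the default 5% defective share
this shift is ~0.06 log2 units; recovery tolerances assume defective clones
remain a minority.

## Problem sizes and defaults

The full-scale synthetic study used by the acceptance checks runs a 0.5-Mb
genome, 400 features (uniform 500–1600 bp, mean ≈ 1 kb), K = 5,000
insertions, 2M reads per sample across 2 fumarate + 2 electrode samples,
10% fumarate-lethal features and 5% electrode-defective features at a 15-h
doubling time. These sizes scale the real experiment's structure (tens of
thousands of insertions, >40M reads, ~10 reads-per-insertion saturation)
down by roughly an order of magnitude while keeping every per-feature
statistic deeply sampled (~400 reads per clone); unit tests use a 60-kb
configuration of the same shape.

## Known limitations

* Exact matching only: no mismatch- or indel-tolerant alignment, no
  quality trimming, no paired-end support; SAM/BAM is neither read nor
  written (per-site count tables are the product).
* Essentiality and defect calls are threshold-based; no uncertainty is
  attached to individual features beyond the replicate-consistency filter
  and the low-confidence guards.
* The apparent doubling time inherits the exponential-growth and
  constant-rate assumptions; lag phases, density-dependent growth and
  cross-feeding between mutants (which can mask true essentiality in
  pooled experiments) are outside the model.
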