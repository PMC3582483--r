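---
title: "Methods: PSV-based duplicate detection and transcript annotation in doubled-haploid transcriptomes"
author: "dhtrans authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: PSV-based duplicate detection and transcript annotation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The genetic premise

A doubled haploid individual carries two identical chromosome sets, so
reads sequenced from it contain no allelic variants. If such reads are
mapped back to the de novo assembled transcripts at high identity, every
well-supported variant column in the pileup must come from somewhere
other than heterozygosity. The dominant source is recent gene
duplication: two diverged gene copies whose transcripts were collapsed
into one assembled contig contribute reads that disagree exactly at
their paralogous sequence variants (PSVs) and multisite variants (MSVs).
This package turns that observation into a duplicate-gene screen and
surrounds it with the standard post-assembly annotation stages it
depends on.

## PSV calling model

Reads are mapped by a seed-and-extend, **ungapped, end-to-end** mapper
(exact 21-mer seeds at regular offsets across the read, both strands).
A placement is accepted iff its identity, `(aligned_len − mismatches) /
aligned_len`, is at least 0.99. The ungapped design is deliberate: on
100-bp reads the 99% threshold admits at most one mismatch, so indel
tolerance cannot change the accepted set, and exact mismatch accounting
is what the threshold is about. A read tied between several transcripts
is assigned to all of them — cross-mapping between collapsed paralogs is
precisely the signal being sought — and this is configurable only in the
sense that downstream summaries deduplicate per-site evidence.

Pileup columns accumulate transcript-forward base counts. A column is
called a PSV iff

* depth ≥ 4 reads,
* the second-most-frequent base has count ≥ 2, and
* its frequency (minor allele frequency, MAF) is ≥ 0.10.

The MAF uses the *second-most-frequent* base only, not all non-major
bases: PSVs between two collapsed copies are expected to be biallelic,
and third-allele noise is already suppressed by the minor-count rule.
Ties for the major allele are broken in fixed base order A < C < G < T
so results are deterministic. Genes are flagged as putative duplicates
when they carry at least one PSV pooled over their transcripts, with
distinct `(transcript, position)` sites counted once.

Two systematic effects are worth knowing about. First, at equal paralog
abundance the *expected* minor fraction at a PSV site is 0.5, but the
observed MAF is biased slightly below 0.5 because the minor count is by
definition the smaller of two binomial halves. Second, PSV sites with a
second PSV within a read length lose copy-B coverage: a read spanning
two PSVs carries two mismatches against the representative copy and
fails the 99% filter. The test suite therefore checks the 50/50
convergence claim at *isolated* planted sites (no neighbour within 150
bp), and the sensitivity of the screen genuinely declines once copy
divergence approaches 1% or more — the configuration object warns when
it is asked to simulate such divergences.

## Read cleaning

Reads are cleaned by removing terminal runs of `N` from both ends
(optionally after clipping a user-supplied literal adaptor; no adaptor
default is shipped because adaptor content is library-specific), then
discarding reads whose **whole-read mean** Phred quality after trimming
is below 20 or whose length is below 15 bp. The mean-quality reading of
the threshold (rather than per-base) follows the phrase "average
quality"; only Phred+33 encoding is supported, and malformed FASTQ
(truncated records, sequence/quality length mismatches) is rejected
during a streaming validation pass rather than silently repaired.

## Assembly merging and assessment

Merging pools contig sets, drops contigs under 200 bp, sorts by length
(ties by id), and removes every contig that is an exact substring — on
either strand — of an already retained contig. Exact containment is
deterministic and dependency-free; it is the right notion for merging
overlapping assemblies of the *same haploid source*, where two
assemblers reconstruct identical subsequences rather than diverged
alleles. It is not a general clustering substitute: it will not merge
contigs that differ by a single base.

N50 is computed by the descending cumulative-sum definition (the largest
length L such that contigs ≥ L hold at least half the assembled bases)
and is tested against an exhaustive oracle.

Benchmark assessment aligns contigs to a set of reference full-length
cDNAs with a Smith–Waterman local aligner (match +1, mismatch −2, −3 per
gapped position; both strands). A cDNA is COMPLETE when some contig
aligns at ≥ 90% identity over ≥ 100 columns *and* the alignment covers
the cDNA's entire ORF with no indel columns inside the ORF interval;
PARTIAL when a qualifying alignment exists but the ORF is not cleanly
covered; POOR otherwise. The identity+length criterion stands alone
here: the internal aligner computes no E-values, and "same ORF" is
operationalised as indel-free ORF coverage since no formal definition of
the manual criterion exists. Candidate contig–cDNA pairs are pre-selected
by a shared exact 21-mer (either strand) before alignment;
homopolymer-heavy k-mers (a run of 12+ of one base, as found next to
polyA tails) are excluded from seeding because they would link unrelated
sequences.

## ORF prediction and full-length classification

The translated search six-frame-translates each transcript and aligns
frames locally against the reference proteins under BLOSUM62 with affine
gaps (open 11, extend 1), keeping the best hit with score ≥ 50 (ties by
lower subject id). Frame/protein pairs are aligned only when they share
at least two distinct amino-acid 6-mers (at most the 20 best candidates
by shared-seed count): chance co-occurrence of two 6-mers between
unrelated sequences is vanishingly rare, while any genuine homology
stretch of ≥ 7 identical residues provides them. Both knobs
(`min_seed_hits`, `max_candidates`) are exposed for users who want an
exhaustive sweep on small inputs.

Guided prediction works in the hit's frame and strand. The start codon
is the in-frame `ATG` **at or nearest upstream** of the aligned region
reachable without crossing an in-frame stop; several in-frame ATGs may
exist and no rule for that case is standard, so the nearest one is
chosen — with the alignment anchored at the homologous methionine this
recovers the planted start, and it never invents upstream extensions
beyond the first chance ATG. Failing that, the first in-frame `ATG`
inside the aligned region is used; failing that the alignment start with
`has_start = FALSE`. The stop is the first in-frame terminator (TAA,
TAG, TGA — no readthrough handling) from the codon containing the
alignment end; if none exists before the transcript end,
`has_stop = FALSE` and the CDS closes at the last complete codon. All
coordinates are reported 1-based inclusive on the forward strand, the
native R/Biostrings convention used consistently in memory and in every
emitted table (the stop codon is part of the CDS interval; the reported
protein excludes it).

Classification uses a ±10-residue agreement tolerance:

* `FULL_LENGTH` — start and stop present, the chosen start maps within
  10 residues of the reference protein's first residue, and the
  alignment reaches within 10 residues of its last.
* `PARTIAL_5P` / `PARTIAL_3P` — the corresponding end is missing or out
  of agreement.
* `INCORRECT_ORF` — the claimed CDS translates with an internal stop, or
  the start choice contradicts the alignment span. The frozen rule for
  the contradiction: if the chosen start implies a position more than 10
  residues *upstream* of the protein start (a chance upstream ATG), or
  the alignment shows the protein's start region present on the
  transcript (`sstart ≤ 10`) while the only usable ATG sits more than 10
  residues *inside* the alignment (e.g. a corrupted start codon), the
  ORF is incorrect. When instead the alignment itself begins well into
  the reference protein the transcript genuinely lacks 5' sequence and
  is `PARTIAL_5P` — this keeps 5'-truncated transcripts out of the
  incorrect class even when a chance internal ATG exists.

Ab initio prediction returns the longest complete ATG→stop ORF over all
six frames (ties: plus strand first, then lowest forward-strand start),
subject to a 30-residue minimum. The ORF ratio is predicted protein
length over reference protein length; 0.9 is the conventional
full-length candidate threshold and 1.0 marks complete-or-longer CDS.

## UTR sequence-context analyses

Contexts are extracted from full-length annotations in mRNA sense: the
start window spans −4..+4 (8 bases, ATG at +1..+3 — there is no position
0), the stop window −6..+12 (18 bases, stop at +1..+3). Transcripts
whose UTR is too short for the window are skipped and counted. Position
frequency matrices store per-position counts and frequencies;
information content is `2 − H` bits with `H` the base-2 Shannon entropy
of the column, with **no pseudocounts and no small-sample correction** —
the uncorrected form is what the logo literature plots, and the package
reports the raw matrix so users can apply corrections if wanted.
Consensus calling takes the per-position argmax, rendering ties as IUPAC
ambiguity codes. Matrices are DNA internally and RNA (U) in reports.

PolyA selection takes transcripts whose exact terminal A-run is at least
7 nt; internal A-runs are irrelevant and no mixed-tail trimming is
attempted. PAS discovery counts every overlapping N-free hexamer in the
35 bp immediately upstream of the polyA start — exhaustive fixed-length
enumeration, which for exact patterns of fixed length 6 is exactly what
a combinatorial pattern-discovery run at L = W = 6 would return, so no
general discovery engine is built. Hexamers are classified against the
canonical AAUAAA (CANONICAL / SINGLE_BASE_VARIANT / OTHER). Because one
window can contain several signals, each transcript is assigned its
highest-priority hexamer: AAUAAA, then AUUAAA, then the remaining
single-base variants ordered by observed frequency (ties alphabetical),
then none. Reports print raw counts alongside integer percentages so no
information is lost to rounding.

## The synthetic doubled-haploid generator

The generator is the package's instrument for validating every stage
against planted truth. Each gene is built as
`5'UTR + CDS + stop + 3'UTR + polyA`:

* Proteins: lengths uniform over 50–600 codons, first residue M,
  otherwise i.i.d. residues. The second residue is drawn compatible with
  the Kozak +4 base (it must own a codon starting with the drawn base)
  so the start context can be planted jointly with the coding sequence.
* CDS: uniformly random synonymous codons (no codon-usage table is
  assumed), standard nuclear code.
* Start context: the −4..−1 bases and the +4 codon constraint follow a
  position-probability profile centred on a configurable 8-mer consensus
  (default `AAACATGG`) with weight `kozak_strength` (default 0.55) on
  the consensus base per free position; 1 plants a point mass.
* Stop codons drawn from TGA/TAA/TAG at 0.485/0.325/0.19.
* 3'UTR: uniform length 100–2000 bp (polyA excluded), with a PAS hexamer
  drawn from a mixture (canonical 0.61, AUUAAA 0.21, remaining 0.18
  spread over the other 17 single-base variants) planted so its 3' end
  lies 10–29 nt upstream of the polyA run — entirely within the 35-bp
  scan window. The base immediately before the polyA tail is forced
  non-A so the observed terminal run equals the planted 20-nt tail.
* Duplicates: a configurable fraction of genes (default 0.2) receives a
  second copy diverged by substitutions at `psv_rate` (default 0.005)
  over the non-polyA body; a duplicate that happened to draw zero
  substitutions would be unobservable by construction, so at least one
  is planted. Only copy A enters the transcript FASTA — emulating
  assembly collapse of recent duplicates, since simulating assemblers is
  out of scope — while both copies serve as read templates and as
  synthetic "genome" contigs.
* Reads: fragments uniform along each copy (both copies of a duplicated
  gene at equal abundance by default; a skew parameter exists to
  exercise the MAF filter), 100-bp mates from 350-bp fragments at 30×
  pooled coverage, i.i.d. substitution errors at 0.001, constant Q35,
  mate 2 reverse-complemented. Everything is deterministic given the
  seed; each generator stage derives its RNG stream from the config seed
  plus a fixed offset, so stages can be re-run independently.

What the generator does **not** emulate: expression-level variation
between genes, intron structure and alternative splicing, coverage
biases (GC, fragmentation, amplification), quality-score decay along
reads, indel sequencing errors, codon-usage bias, and divergence
profiles of real paralog families. Passing tests therefore demonstrate
the correctness of the algorithms under the stated statistical
conditions, not performance on real libraries — in particular,
real-data sensitivity depends on paralog expression ratios and
divergence distributions the way the MAF and identity filters dictate.

## Study sizes, determinism and reporting conventions

The validation suite runs the screens at sizes chosen to make the
binomial tolerances meaningful while staying desk-scale: 200 genes for
the zero-call null (error-free, no duplicates — the caller must emit
exactly zero PSVs), 500 genes for duplicate recovery (expecting ≥ 90%
gene sensitivity and ≤ 2% false gene flags at default conditions) and
for ORF recovery (≥ 99% exact planted-CDS coordinate recovery; 5'/3'
truncation fixtures classified to their partial classes at ≥ 95%), and
2,000 genes for motif recovery (planted stop and PAS mixtures within 3
binomial standard errors; planted Kozak consensus exact). Oracle checks
compare N50 to exhaustive search over 1,000 random length multisets,
hexamer tables to brute-force substring counting, and the local aligner
to a plain dynamic-programming implementation.

`run_full_pipeline()` writes its configuration (including the seed and
package version, but no timestamps) into a manifest, logs per-stage
record counts, and is byte-identical across reruns of the same
configuration. Report percentages are rounded half-away-from-zero — the
convention of printed tables — at 1 decimal for classification tables
and 0 decimals for mixture reports, and every percentage is
recomputable from the printed counts.

## Known limitations

* The duplicate screen cannot see duplicates whose copies are more
  diverged than the 99% mapping filter tolerates, nor copies so similar
  that no read covers a PSV; it flags, but cannot phase, the collapsed
  copies.
* False gene flags arise from coincident sequencing errors at
  moderate-depth positions (two identical erroneous bases at ≥ 10% of a
  small depth); the default conditions keep this at or below the 2%
  level the suite asserts, but error rates well above 0.1% would need
  stricter thresholds.
* The containment merger does not cluster diverged redundancy; the
  aligner computes no E-values; the CLI-free interface is the R API plus
  `scripts/acceptance.R`.
* `evaluate_genome_hits` and the benchmark assessment rely on shared
  high-complexity 21-mers for candidate pairing; sequences related only
  below ~95% identity over short stretches may not be paired and would
  need an exhaustive alignment pass.
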