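---
title: "Nuclear barcode discovery and mixture quantification: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nuclear barcode discovery and mixture quantification: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nucbarcode)
```

# The problem

A DNA barcode must satisfy three conditions: it must be short enough to
amplify and sequence efficiently; it must be flanked by regions conserved
enough across the species of interest that one broad-specificity primer pair
amplifies all of them; and its internal sequence must vary enough between
species to identify the source of each read. Plastid and mitochondrial
markers struggle with the third condition in plants. The nuclear genome is a
much larger search space, and its high duplication level — normally an
obstacle — becomes an asset: each additional copy of a conserved region is
an extra chance that *some* copy has diverged between close relatives.

This package implements an end-to-end route from genome collections to
usable nuclear barcodes: mine conserved candidate regions, design primer
pairs inside them, predict the amplicons those primers would generate
(in-silico PCR) to build a taxon-labelled reference set, and then use that
reference set to assign and quantify reads from real amplicon sequencing
runs.

# Coordinates and containers

All intervals in exported tables are **0-based half-open** on the forward
strand (BED convention); `start`/`end` columns everywhere follow this rule.
Sequence collections are tibbles (`id`, `description`, `sequence`,
`species_taxid`), so every stage composes with ordinary dplyr verbs; species
labels travel as `taxid=<int>` tokens in FASTA descriptions or as a sidecar
two-column TSV, because public genome/database records carry taxonomy
out-of-band.

# Stage by stage

## Seed screening and extension

`local_align_search()` finds maximal local alignments of a seed against both
strands of a subject. The engine is classic Smith–Waterman with affine gaps
(match +1, mismatch −2, gap open −5, gap extend −2, a gap of length $L$
costing $open + L \cdot ext$), preceded by an 11-mer shared-word prefilter;
multiple hits are recovered by greedily masking the subject span of each
accepted alignment and re-searching. Scores are thresholded directly
(default 40) rather than converted to E-values — at desk scale a
deterministic threshold is easier to reason about and to test. The test
suite holds this implementation to a hand-written pure-R Gotoh oracle on
instances up to 2 kb × 500 b; alignment *scores* must agree exactly, while
intervals are compared up to zero-scoring end segments, which co-optimal
alignments may include or trim.

A seed is retained only when it hits **both** anchor genomes. The
screening sentence this implements ("no hit in either genome → dropped")
could also be read as "at least one anchor"; the stricter both-anchors
reading was chosen because the stage is explicitly a screening step and the
two anchors are deliberately taken from the two major clades (one dicot,
one monocot) to avoid bias — a seed present in only one clade is exactly
what the screen should remove.

Retained hits are widened by a configurable flank (default 200 bases,
clipped at genome ends; minus-strand hits are reverse-complemented into
seed orientation). The value must comfortably contain a 350-bp design
window on either side of a short seed; 200 on each side of a typical hit
achieves that without dragging in unrelated sequence.

## Alignment and the conservation profile

`build_msa()` is a center-star progressive aligner (the center is the
sequence with the highest summed pairwise 6-mer similarity; all others are
globally aligned to it with match +1, mismatch −1, gap open −4, gap extend
−1 and merged under once-a-gap-always-a-gap). It exists so that the design
stage is hermetic and deterministic; it is *not* benchmarked against
Clustal/MAFFT, and `load_msa()` (aligned FASTA or Clustal format) is the
intended production path for large jobs. Every `build_msa()` result is
checked against the invariant that de-gapping each row reproduces its input.

`conservation_profile()` tallies A/C/G/T/N/gap per column. Two choices
matter:

* **Gaps count in the denominator** of the majority fraction, so a column
  with an indel in any species is penalised. Primer windows must be
  indel-free across species, since an indel in a binding site shifts
  annealing.
* The majority base breaks ties in the fixed order A<C<G<T (then N), making
  consensus sequences deterministic.

An HMM-based formulation of conservation (match-state probabilities) would
be a legitimate alternative; the per-column majority fraction is this
package's operationalisation, chosen for transparency and testability.
Consensus output is either strict (majority base; gap-majority columns
omitted) or IUPAC-degenerate (all bases at frequency ≥ 0.25 by default).
Logo data is exported as a per-column frequency TSV rather than an image.

## Primer design

`find_conserved_windows()` returns every 20-column window whose columns all
have majority fraction ≥ 0.90 and gap fraction ≤ 0 (both configurable).
"Sufficient conservation" is not quantified in the source description; 0.90
with zero gaps is the default because primers must anneal across species
and because the experimentally validated primer pair is non-degenerate —
strict consensus primers only make sense over highly conserved windows.

`enumerate_primer_pairs()` pairs every upstream window with every
non-overlapping downstream window whose implied amplicon — measured
**primer-inclusive**, downstream end minus upstream start — lies in
100–350 bp. Primer-inclusive measurement is fixed by the validated
architecture: a 20 + 154 + 20 locus yields the published 194-bp product,
which lies in range only under the inclusive reading. The reverse primer is
the reverse complement of the downstream window's consensus; windows are
never scanned on the minus strand of the alignment (the design is
orientation-fixed, the scan stage handles both strands). Pairs are named
`<seed>-<triplet>` with triplets counting `aaa`, `aab`, ..., `aba`, ... —
a base-26 counter incrementing the rightmost letter first, capped at
`zzz` (17 576 pairs per region).

## In-silico PCR

`find_primer_sites()` reports every forward-strand interval where a
semi-global alignment of the primer (or of its reverse complement, reported
as a minus-strand site) has at most `max_errors` mismatches plus gaps.
IUPAC degeneracy in the primer matches compatible subject bases at zero
cost; ambiguity codes in the subject are literal, so N-runs in genomes do
not spawn sites. Candidate neighbourhoods come from Biostrings'
approximate matcher; each is then made canonical by evaluating every
window of length 20 ± `max_errors` nearby and keeping the fewest-error
placement, ties going to the leftmost then narrowest — and overlapping
placements are collapsed by the same rule, because a PCR site list should
contain one entry per physical site. The error split (mismatches vs gaps)
is read off one optimal unit-cost alignment path with diagonal preference.

`predict_amplicons()` combines forward sites with downstream
reverse-complement reverse-primer sites, plus the mirror products initiated
on the minus strand, normalising `inner_sequence` to read
forward-primer-first with both primer spans removed (reference amplicons
exclude primer spans everywhere — the comparison unit between reads and
references is the inner sequence). Two presets mirror the two published
scans: genome scans cap **total** errors across both primers at 4;
database scans cap errors **per primer** at 2. Scan size bounds default to
[50, 1000] — deliberately wider than the design-time 100–350, which
applies only when choosing windows, not when predicting what a primer pair
would amplify. Predictions are deduplicated on the product interval, and
the suite asserts strand symmetry (reverse-complementing the subject
preserves the inner-sequence multiset) and budget monotonicity.

An amplicon is **diagnostic** for a species when its inner sequence occurs
in exactly one species across the reference set; this species-uniqueness
reading (rather than "single product per genome") is what
`diagnostic_species_count()` implements, and division tallies count each
diagnostic species once under Plants / Invertebrates / Vertebrates / other.

## Taxonomy

`load_taxonomy()` accepts a simplified 5-column lineage TSV (the primary
fixture dialect — hermetic tests need small, explicit taxonomies) or
NCBI-taxdump-style `nodes.dmp`/`names.dmp`, whose numeric division codes
are mapped onto the same four labels ("unassigned" maps to empty so the
nearest labelled ancestor decides). Structural validation requires exactly
one self-parent root, no orphans and no cycles, naming the offending taxid.
`lowest_common_ancestor()` walks parent chains; the tests hold it to an
independent ancestor-set-intersection oracle on random ~200-node trees.
Conclusions are reported as scientific name plus rank; a single-species
cluster concludes at that species. `poaceae_taxonomy()` ships the standard
grass/legume/rosaceae lineages (real NCBI taxids) plus vertebrate and
invertebrate branches for worked examples.

## Read assignment

The NGS half consumes **error-corrected** reads: dedicated read-error
correction (e.g. coral) is published elsewhere and out of scope here, and
its absence simply inflates the unassigned fraction (see below).

* `demultiplex()` routes each read by its 5' MID prefix to the unique
  matching sample, exactly by default (a read matching zero or several
  samples is unassigned, and every read lands in exactly one bin). MIDs in
  a scheme must be pairwise ≥ 2 substitutions apart, so a budget of 1
  cannot create ambiguity.
* `orient_and_trim()` decides orientation by which primer matches the 5'
  end within 2 errors (semi-global, anchored), reverse-complements
  reverse-oriented reads, always removes the matched primer span, and
  removes the opposite span best-effort — a short read without its 3'
  primer is kept rather than rejected, but under full-length identity it
  will usually land in a reads-only cluster, which mirrors strict
  `-aL 1 -aS 1` clustering semantics.
* `cluster_exact()` forms equivalence classes of exact full-length string
  identity over reads plus references (the cd-hit-at-100% contract, checked
  against a hash-partition oracle on 10⁴ sequences). Categories: `mixed`,
  `reads_only` (unassigned), `refs_only`.
* `conclude_clusters()` concludes mixed clusters (single species, or the
  LCA of several), orders the ranked table by descending read count with
  ties broken by representative sequence (deterministic reports), keeps
  refs-only clusters out of the ranked table but inside the totals, and
  enforces count conservation: assigned + unassigned = trimmed at every
  stage.

## Quantification

Raw read totals per species are a poor quantity estimator for three
published reasons: copy numbers of the target region differ between species
(19 vs 13 predicted sites for the two validated species), some reference
sequences are shared between species, and read counts vary strongly
between copies within one genome (PCR efficiency). `select_marker_reference()`
therefore picks, per species, the single best-amplifying species-specific
locus: among mixed clusters with exactly one reference of that species, the
one with most reads in a pure-sample run (tie → first in report order).
`quantify_mixture()` then counts the mixture-run reads of each marker's
cluster and corrects multiplicatively by the species' 1C genome mass:
$corrected = reads \times C_{pg}$, the direction consistent with the
published arithmetic (2688 × 1.13 = 3037.44) — reads are proportional to
template copies, and mass per template is proportional to genome mass.
Percentages are rounded half-up to one decimal, matching the published
presentation. Two of the published corrected maize cells (1848.21 and
2765.49) are inconsistent with their own printed raw counts
(667 × 2.73 = 1820.91; 1103 × 2.73 = 3011.19), presumably transcription
slips; the package's checks anchor only on internally consistent cells.

# The synthetic-data generator

`simulate_genomes()` plants, per species, `copies` cassettes of
`forward + inner + revcomp(reverse)` at non-overlapping positions on random
strands in random background. Defaults encode the validated locus
architecture: the printed 20-mer primer pair, a 154-base inner region
(194-bp product), 2 copies per genome, 5% inner divergence between species,
1% between copies (copies are redrawn on collision so that within-genome
loci are distinguishable — the marker-selection logic presumes
distinguishable loci, as the published per-locus clusters are), and exact
primer sites. `simulate_reads()` draws species with probability
proportional to $weight / C$ (template copies per unit mass), copies
uniformly, and emits fusion-style reads — `MID + forward + inner +
revcomp(reverse)`, with the bidirectional half sequenced from the other
end as `MID + reverse + revcomp(inner) + revcomp(forward)` so that every
read still begins with a MID, as fusion-primer amplicons do. Errors are
substitution-only at a configurable per-base rate (default 1%): 454-style
homopolymer indels are deliberately omitted because full-length exact
clustering makes any indel read unassigned regardless, so the substitution
model exercises the pipeline's logic rather than the instrument. Every
genome locus and every read is recorded in a ledger, and emissions are
byte-identical across runs with the same seed.

What passing simulations do **not** show about real data: no chimeras, no
PCR bias beyond per-locus uniformity, no quality profile, and reference
sets that perfectly match the simulated genomes. Real runs add
reference-database gaps and polymorphism, which appear as extra unassigned
reads or near-miss clusters.

# Numerical choices and degenerate inputs

* Percent rounding is half away from zero (`floor(x·10 + 0.5)/10`), so
  printed percentages always sum to 100 ± 0.1.
* Majority/consensus ties use the fixed base order A<C<G<T; site-placement
  ties use fewest errors, then leftmost, then narrowest; cluster-rank ties
  use the representative's lexicographic order; strand ties in local
  alignment prefer plus. Everything downstream of a seed is deterministic.
* Empty inputs flow through: empty FASTA → zero-row table; empty read sets
  → empty bins; an empty reference set yields all-zero division tallies. A
  mixture whose markers are all absent yields `NA` percentages rather than
  division by zero.
* Degenerate letters are carried verbatim in sequences, matched
  compatibly when they appear in primers, and mapped to N only inside
  alignment scoring.

# Problem sizes used by the test suite

The packaged checks run entirely on synthetic data sized for a single CPU:
oracle equivalences up to 2 kb × 500 b for local alignment and 2-kb
subjects for primer-site scans; clustering oracles at 10⁴ sequences; random
taxonomies of ~200 nodes; and the end-to-end mixture study at 10⁴ reads per
mixture (25:75, 50:50, 75:25, seeds 200–202, with pure-sample marker
selection at 3 × 10³ reads, seeds 203–204), which recovers each true
percentage within ±3 points. Larger instances change nothing structurally;
these sizes were chosen as the smallest at which the statistical checks are
meaningful.

# Known limitations

* The internal aligners are for desk-scale, hermetic operation;
  whole-genome screens should feed externally computed alignments and
  search results through `load_msa()` and the adapter-friendly TSV
  interfaces.
* No melting-temperature, GC, hairpin or dimer filters: window conservation
  is the only primer-quality criterion, as in the source pipeline.
* Error correction of reads is out of scope; with uncorrected reads the
  unassigned fraction grows (at a 1% substitution rate and a 154-base inner
  sequence, roughly 80% of reads carry at least one inner error and cannot
  join a reference cluster; the published experiments report ~28% unassigned
  after correction).
* Absolute reproduction of the published genome-scan and read-count tables
  requires the original genome/database collections and sequencing runs;
  the package covers their structure with fixtures and their arithmetic
  with exact checks.
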