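---
title: "Methods: measuring the tryptic search space of protein collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: measuring the tryptic search space of protein collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pepspace)
```

## The problem

A bottom-up proteomics experiment identifies peptides, not proteins, and it
can only identify peptides that exist in the searched sequence database.
Decisions that look innocuous at the sequence level — dropping isoforms,
clustering away redundant records, ignoring annotated variants — reshape the
*tryptic search space*: the set of peptides the search engine can match.
`pepspace` treats that search space as the primary object. Every analysis in
the package reduces to set operations over exact peptide strings, which is
deliberately the same criterion MS repositories use for peptide-level
matching (100% full-length identity; isobaric I/L are *not* equated, since
equating them would silently inflate evidence percentages).

## Digestion model

Cleavage is modelled as a per-bond predicate. For the default `trypsin` rule
the bond after residue $i$ is cleaved iff $s_i \in \{K, R\}$ and
$s_{i+1} \neq P$ (the Keil rule); `trypsin_p` drops the proline exception.
Only literal K/R cleave: the ambiguity codes B (N/D), Z (Q/E) and X never do
— vacuously for B/Z, which never denote K/R, but stated as an invariant so
ambiguous sequences cannot create phantom cleavage sites. With
`missed_cleavages = m`, every concatenation of at most $m+1$ consecutive
fully-cleaved fragments is emitted. Two boundary conventions matter and are
fixed as follows:

* **Initiator methionine.** Digestion never generates Met-trimmed peptide
  forms. The alternative reading (always trim the initiator Met) would make
  the digest of a sequence depend on annotation the FASTA record does not
  carry; leaving the Met in place is the conservative choice and matches how
  fully-tryptic database digests are conventionally counted.
* **Sequence ends.** The sequence start and end are always valid peptide
  boundaries, so a C-terminal fragment without a tryptic end is retained.

The length filter (default: keep peptides of ≥ 6 aa) reflects that shorter
peptides are rarely detected and carry little sequence-specific information;
it is applied after fragment construction, so missed-cleavage products are
filtered on their own length.

Monoisotopic masses are the sum of residue masses plus one water
(18.010565 Da), using the standard Unimod/ExPASy residue table at six
decimals (embedded in `R/digestion.R`); selenocysteine (U) has its own mass
(150.953636 Da), while X/B/Z make the mass indeterminate (`NA`) rather than
approximated.

### Degenerate inputs and determinism

Empty sequences and empty collections are errors, not empty results.
Peptide sets are always reported in C-locale (radix) order and every
iteration is by accession then offset, so identical inputs give
byte-identical reports on any platform — a property the test suite asserts
end-to-end through the command-line interface.

## Redundancy clustering

Two records are linked when their sequences are equal or one is a contiguous
substring of the other; clusters are the *connected components* of this
relation. Closure is chosen over greedy assignment because it is
order-independent: a fragment contained in two otherwise-unrelated sequences
merges all three, deterministically. The representative is the longest
member, with ties broken by lexicographically smallest sequence (C
collation) and then smallest accession. A `min_fragment_length` knob (default
1, i.e. no minimum; some production clustering pipelines impose ~11 residues)
exempts very short fragments from merging; exact duplicates always merge.

The scientifically interesting output is not the clusters but the **lost
peptides**: peptides producible from a clustered-away member and from no
representative. These arise whenever a fragment's trimming boundaries fall
inside tryptic peptides, and each loss is classified by where it sat in the
member (N-terminal, C-terminal, internal) — the classes that explain *why*
clustering loses information. `dedup_exact()` is provided as the loss-free
alternative: removing only records with identical sequences provably
preserves the peptide set, and the tests assert exactly that.

## Variant expansion

Each applicable single-AA variant produces one additional full-length
sequence (no combinatorial stacking), accessioned
`<source>|<feature_id>` so the entry accession remains recoverable. A
variant applies to a record of its entry when the record's residue at the
annotated canonical position equals the reference residue. For isoforms this
verbatim check is the whole rule: **no alignment-based coordinate remapping
is attempted**. Annotation pipelines that remap canonical coordinates onto
isoforms will apply more variants than this package does; the verbatim check
was chosen because it is conservative, fully testable, and never applies a
variant to the wrong residue. Real-data users should expect isoform
application to undercount accordingly. Skips (position out of range,
reference mismatch) are never fatal and always logged with a reason.

The expansion accounting distinguishes three collision kinds: peptides newly
added to the search space, additions that also occur in a second collection,
and peptides from variant-bearing records that happen to equal peptides the
unexpanded collection already produced.

## Unicity

A peptide is sequence-unique when all its occurrences lie in one accession;
multiple occurrences *within* that sequence do not disqualify it, because
the peptide still identifies a single protein. Entry-level uniqueness
(peptides shared only among the canonical and isoforms of one entry) is
reported as a separate additional count and never folded into the headline
percentage — folding it in would make the headline number depend on isoform
annotation depth rather than on the sequence space. X/B/Z-containing
peptides are excluded from unique counts by default (they cannot be
unambiguously matched) but remain in the denominator; whether the
denominator should also exclude them is genuinely ambiguous, so both modes
are supported via `exclude_ambiguous` and the setting is echoed in the
report. U-containing peptides are ordinary and never excluded. An optional
`max_length` cap restricts the peptide universe before counting, for
analyses limited to lengths actually observable in MS repositories (the
repositories' own length profiles, via `length_profile()`, justify such a
cap).

## Repository evidence

Evidence sets are peptide → experiment-count maps. The only filter is a
minimum experiment count (conventionally ≥ 5 for PRIDE-style heterogeneous
submission repositories; curated/reprocessed sources are used as provided
with count 1). Lookup supports `any` (≥ 1 repository, the default for
evidence percentages) and `all` (concurrent presence in every repository,
the strictest evidence tier). Filtering is idempotent and monotone in the
threshold; both properties are tested.

## The synthetic generator and what passing tests mean

`generate_proteome()` emulates the *structure* of an organism-scale
collection, not its biology:

* sequences are i.i.d. draws from a fixed amino-acid frequency vector with
  the combined K/R frequency set to ≈ 0.083, giving a mean fully-tryptic
  fragment length of ≈ 12 residues (the 10–15 range typical of real
  proteome digests); each sequence starts with M;
* isoforms delete one internal block of 10–30% of the canonical (an
  exon-loss caricature), which guarantees isoform-specific junction
  peptides — the structure the isoform-unicity analysis needs;
* duplicates and fragments are planted in an unreviewed section; fragment
  boundaries are drawn independently of cleavage sites, so trimming usually
  falls mid-peptide and produces predictable losses;
* variants respect the reference residue on the canonical by construction;
  ~34% are disease-labelled and ~0.5% are I/L interchanges, the proportions
  of real human variant tables;
* evidence is a Bernoulli sample of the true digest per repository
  (defaults 0.25/0.20/0.20), with PRIDE-style counts 1 + Geom(p = 0.3) — so
  the ≥ 5 filter has closed-form survival $(1-p)^4 \approx 0.24$ — plus 2%
  decoy peptides not from the digest.

The ground-truth manifest predicts cluster membership, representatives and
lost peptides (per-planted-group containment closure — including the subtle
case where a fragment drawn from a region an isoform retains links that
isoform into the canonical's cluster), variant application outcomes, and
sequence-unique peptides. `recovery_suite()` replays the pipeline against
the manifest. One caveat is intrinsic: the per-repository evidence-fraction
check is a 99% binomial interval applied to a genuinely binomial draw, so it
has a nominal ~1% false-alarm rate per repository per run; a single
evidence-fraction miss in an otherwise-passing suite is expected behaviour,
not a defect.

What passing does **not** show about real data: real proteomes have
homologous families, low-complexity regions and shared domains (the
generator's near-zero cross-entry peptide sharing is optimistic); real
isoforms arise from alternative splicing with coordinate remapping the
package deliberately does not model; real repository evidence is biased by
what was searched, not a uniform sample. The generator validates the
*machinery*, while conclusions about any concrete database require running
the pipeline on that database.

## Problem sizes and numerical choices

The shipped test suite runs the digestion oracle comparison on 1000 random
sequences × {trypsin, trypsin/P} × 0–2 missed cleavages, and the end-to-end
suites on generated collections of 15–200 entries; the acceptance script
uses the generator defaults (300 entries, ≈ 570 records, ≈ 7400 distinct
peptides), chosen so a full run completes in seconds while every planted
structure class is exercised many times. Mass assertions use frozen values
from an independent proteomics mass library at 10⁻⁶ Da; percentages are
reported to one decimal (an exact zero prints as `0`, matching the
comparison-table convention; positive values below 0.05 print as `0.0`).

## Known limitations

* No gene-level grouping of accessions across databases; unicity stops at
  the entry level.
* No semi-tryptic digestion, PTM-aware masses, or charge states; other
  proteases are out of scope beyond the trypsin/trypsin_p pair.
* Whether a given published count used trypsin or trypsin/P is often
  unstated; both are supported and the choice is recorded in every report's
  provenance header, but comparisons across rules are refused rather than
  reconciled.
* Clustering is quadratic in the number of distinct sequences with a
  per-pair `fixed = TRUE` substring scan; it is intended for desk-scale
  collections (≤ 10⁵ sequences), not full UniProtKB.
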