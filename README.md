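# pepspace

Tools for analysing the **tryptic search space** of protein sequence
collections — the set of peptides a bottom-up MS proteomics search engine can
actually match against a given FASTA database.

Which database to search (reviewed canonical sequences only? with isoforms?
with annotated disease variants? after redundancy clustering?) changes the
peptide search space in ways that are hard to see from record counts alone.
`pepspace` makes those differences measurable: it digests collections in
silico, expands them with annotated single-amino-acid variants, removes
100%-identity redundancy while accounting for the tryptic peptides that
clustering destroys, compares any two collections peptide-by-peptide, scores
peptide unicity, and matches peptides against MS-repository evidence lists.
It is aimed at proteomics bioinformaticians choosing or curating search
databases, and at database maintainers quantifying what their release
decisions cost in peptide space.

## What it computes

* **In-silico digestion.** Full tryptic cleavage C-terminal to K/R with the
  Keil proline exception (`trypsin`), or cleaving every K/R (`trypsin_p`);
  configurable missed cleavages *m* (every concatenation of ≤ *m*+1
  consecutive fragments) and a minimum peptide length (default 6 aa). The
  initiator methionine is never trimmed. Each peptide is indexed with every
  (accession, offset) occurrence and its monoisotopic mass
  *M* = Σ residue masses + *M*(H₂O); peptides containing the ambiguity codes
  X/B/Z have indeterminate mass.
* **Three-compartment comparison.** For collections DB1 and DB2, the peptide
  universe splits into I = unique to DB1, II = shared, III = unique to DB2
  (exact full-length string identity), with accession-level coverage derived
  from the compartments and per-compartment repository-evidence percentages.
* **Peptide unicity.** A peptide is unique when all its occurrences lie in
  one sequence (repeats within that sequence allowed); entry-level uniqueness
  (shared only among isoforms of one entry) is reported separately.
* **Redundancy clustering.** UniRef100-style merging of identical sequences
  and subfragments (connected components of the equal-or-substring relation,
  longest member as representative), with a report of the tryptic peptides
  lost by clustering and their N-terminal / C-terminal / internal origin —
  versus exact-duplicate removal, which provably loses nothing.
* **Variant expansion.** One additional sequence per applicable single-AA
  variant (optionally disease-only), plus accounting of how many new
  peptides the expansion adds and how many collide with peptides already in
  the search space.
* **Synthetic proteomes.** A seeded generator with a ground-truth manifest
  (planted isoforms, duplicates, fragments, variants, sampled evidence) so
  the whole pipeline is testable end-to-end without downloading any database
  release.

## Worked example

```r
library(pepspace)

sim <- generate_proteome(synthetic_config(seed = 7, n_entries = 50))
sim$records
#> Protein collection: 100 records (54 entries, 46 isoforms)

idx <- digest_collection(sim$records)
idx
#> Digest index: 2272 occurrences, 1323 distinct peptides, 100 accessions
#> Digestion: trypsin, missed cleavages 0, length 6..Inf

unicity_report(idx, sim$records)
#> Peptide unicity: 787 / 1323 unique (59.5%)
#>   isoform-specific unique: 44; ambiguous excluded: 16

res <- expand_variants(sim$records, sim$variants, mode = "disease_only")
cmp <- compare_indexes(idx, digest_collection(res$records))
cmp
#> Comparison: I (DB1 only) 0 | II (shared) 1323 | III (DB2 only) 36
annotate_with_evidence(cmp, sim$evidence)
#>   compartment n_peptides n_with_evidence evidence_percent evidence_percent_label
#> 1  db1_unique          0               0              0.0                      0
#> 2      common       1323             731             55.3                   55.3
#> 3  db2_unique         36               0              0.0                      0
```

Read it as: of 1323 tryptic peptides in the base collection, 59.5% map to a
single sequence (44 of them only to an isoform). Disease-only variant
expansion adds 36 peptides (compartment III) and removes none (compartment I
is structurally empty because the base collection is a subset of its
expansion); 55.3% of the shared peptides have repository evidence, while the
newly created variant peptides have none — exactly the "if you don't search
for it, you'll never find it" situation variant-expanded databases address.

The same operations are available on real FASTA/TSV inputs from the command
line via the `inst/scripts/pepspace` wrapper
(`pepspace <digest|expand|cluster|compare|unicity|evidence|simulate> [flags]`).

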