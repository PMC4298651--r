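# Reading and writing FASTA collections, variant tables and evidence sets.

write_tmp_fasta <- function(lines) {
  f <- tempfile(fileext = ".fasta")
  writeLines(lines, f)
  f
}

test_that("uniprot headers parse into accession, section and isoform status", {
  f <- write_tmp_fasta(c(">sp|P12345|TEST Some protein", "ACDEFGHIK",
                         ">sp|P12345-2|TEST Isoform 2", "ACDEFGIK",
                         ">tr|A00001|A00001_HUMAN", "MMMMKRRRDDD"))
  recs <- read_fasta(f)
  expect_s3_class(recs, "protein_records")
  expect_equal(recs$accession, c("P12345", "P12345-2", "A00001"))
  expect_equal(recs$section, c("reviewed", "reviewed", "unreviewed"))
  expect_equal(recs$is_isoform, c(FALSE, TRUE, FALSE))
  expect_equal(recs$entry_accession, c("P12345", "P12345", "A00001"))
  expect_equal(recs$description[1], "Some protein")
})

test_that("plain dialect takes the first token and section 'other'", {
  f <- write_tmp_fasta(c(">ENSP00000354687.2 some description", "ACDEFGHIK"))
  recs <- read_fasta(f, header_dialect = "plain")
  expect_equal(recs$accession, "ENSP00000354687.2")
  expect_equal(recs$section, "other")
})

test_that("sequences are uppercased at ingest", {
  f <- write_tmp_fasta(c(">sp|P1|X", "acdefghik"))
  expect_equal(read_fasta(f)$sequence, "ACDEFGHIK")
})

test_that("duplicate accessions are rejected", {
  f <- write_tmp_fasta(c(">sp|P12345|A", "ACDK", ">sp|P12345|B", "ACDK"))
  expect_error(read_fasta(f), "duplicate accession 'P12345'")
})

test_that("malformed headers and illegal residues raise pointed errors", {
  f <- write_tmp_fasta(c(">just_one_token", "ACDK"))
  expect_error(read_fasta(f), "malformed UniProtKB header at record 1")
  f2 <- write_tmp_fasta(c(">sp|P1|X", "ACD*EFK"))
  expect_error(read_fasta(f2), "illegal residue '\\*' in accession 'P1' at position 4")
  # U, X, B, Z are accepted, not cleaned away
  f3 <- write_tmp_fasta(c(">sp|P1|X", "ACDUXBZK"))
  expect_equal(read_fasta(f3)$sequence, "ACDUXBZK")
})

test_that("FASTA round-trips preserve records and order in both dialects", {
  set.seed(11)
  recs <- random_records(8)
  recs$section <- sample(c("reviewed", "unreviewed"), 8, replace = TRUE)
  recs$description <- sprintf("synthetic record %d", 1:8)
  # include an isoform and a variant-expanded-style accession
  recs$accession[7] <- "P0007-2"
  recs$accession[8] <- "P0008|VAR_000001"
  recs <- protein_records(recs$accession, recs$sequence,
                          section = recs$section,
                          description = recs$description)
  for (dialect in c("uniprot", "plain")) {
    f <- tempfile(fileext = ".fasta")
    write_fasta(recs, f, dialect)
    back <- read_fasta(f, dialect)
    expect_equal(back$accession, recs$accession)
    expect_equal(back$sequence, recs$sequence)
    expect_equal(back$description, recs$description)
    if (dialect == "uniprot") expect_equal(back$section, recs$section)
  }
})

test_that("variant change tokens parse in both notations", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("# comment line",
               "entry_accession\tfeature_id\tchange\tcategory",
               "P1\tVAR_1\tp.Asp3Asn\tDisease",
               "P1\tVAR_2\tI45L\tPolymorphism",
               "P2\tVAR_3\tK10R\tunclassified"), f)
  v <- read_variants(f)
  expect_equal(v$ref_aa, c("D", "I", "K"))
  expect_equal(v$position, c(3L, 45L, 10L))
  expect_equal(v$alt_aa, c("N", "L", "R"))
  expect_equal(v$category, c("disease", "polymorphism", "unclassified"))
  expect_equal(v$is_il_variant, c(FALSE, TRUE, FALSE))
})

test_that("bad variant rows fail or warn as specified", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("entry_accession\tfeature_id\tchange\tcategory",
               "P1\tVAR_1\tD3D\tdisease"), f)
  expect_error(read_variants(f), "identical reference and alternate")
  writeLines(c("entry_accession\tfeature_id\tchange\tcategory",
               "P1\tVAR_1\tnot_a_change\tdisease"), f)
  expect_error(read_variants(f), "unparseable variant change 'not_a_change' at row 1")
  writeLines(c("entry_accession\tfeature_id\tchange\tcategory",
               "P1\tVAR_1\tD3N\tsomething_new"), f)
  expect_warning(v <- read_variants(f), "unknown variant category")
  expect_equal(v$category, "unclassified")
})

test_that("variant tables round-trip", {
  v <- variant_records(c("P1", "P2"), c("VAR_1", "VAR_2"), c(3L, 45L),
                       c("D", "I"), c("N", "L"),
                       c("disease", "polymorphism"),
                       disease_name = c("Disorder", ""))
  f <- tempfile(fileext = ".tsv")
  write_variants(v, f)
  back <- read_variants(f)
  expect_equal(back, v, ignore_attr = TRUE)
})

test_that("evidence rows collapse, normalise and default as specified", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("peptide\texperiment_count",
               "AAAAAK\t3", "AAAAAK\t2", "aaacck\t1"), f)
  ev <- read_evidence(f, repository = "PRIDE")
  expect_equal(ev$peptide, c("AAAAAK", "AAACCK"))
  expect_equal(ev$experiment_count, c(5L, 1L))
  expect_equal(attr(ev, "repository"), "PRIDE")

  # no count column -> all counts 1
  writeLines(c("peptide", "DDDDDK", "EEEEEK"), f)
  ev2 <- read_evidence(f)
  expect_equal(ev2$experiment_count, c(1L, 1L))

  # empty file -> empty set with warning
  writeLines("peptide", f)
  expect_warning(ev3 <- read_evidence(f), "no peptides")
  expect_equal(nrow(ev3), 0L)
})

test_that("evidence sets round-trip", {
  ev <- evidence_set(c("AAAAAK", "CCCCCK", "DDDDDK"), c(5L, 1L, 2L), "PRIDE")
  f <- tempfile(fileext = ".tsv")
  write_evidence(ev, f)
  expect_equal(read_evidence(f, "PRIDE"), ev, ignore_attr = TRUE)
})
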