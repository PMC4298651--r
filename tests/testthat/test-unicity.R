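# Peptide unicity at sequence and entry level.

test_that("unicity counts peptides mapping to exactly one accession", {
  recs <- protein_records(c("S1", "S2"),
                          c("AAAAAKCCCCCCR", "CCCCCCRDDDDDDK"))
  rep <- unicity_report(digest_collection(recs), recs)
  # peptides: AAAAAK (S1 only), CCCCCCR (shared), DDDDDDK (S2 only)
  expect_equal(rep$total_peptides, 3L)
  expect_equal(rep$unique_peptides, 2L)
  expect_equal(rep$unicity_percent, 66.7)
  expect_equal(rep$per_accession_unique_counts$n_unique, c(1L, 1L))
})

test_that("a peptide repeated within a single sequence is still unique", {
  recs <- protein_records("Q1", "LTMMGTRLTMMGTR")
  rep <- unicity_report(digest_collection(recs), recs)
  expect_equal(rep$unique_peptides, 1L)
  tab <- rep$unique_peptide_table
  expect_equal(tab$peptide, "LTMMGTR")
  expect_equal(tab$n_occurrences, 2L)
})

test_that("entry-level uniqueness is reported separately, not folded in", {
  recs <- protein_records(c("P1", "P1-2", "P2"),
                          c("AAAAAKCCCCCCR", "AAAAAKDDDDDDR", "EEEEEEKFFFFFFK"))
  rep <- unicity_report(digest_collection(recs), recs, entry_level = TRUE)
  # AAAAAK is shared by P1 and P1-2 (one entry): entry-level unique only
  expect_equal(rep$entry_level_additional_unique, 1L)
  expect_false("AAAAAK" %in% rep$unique_peptide_table$peptide)
  # sequence-level count unaffected by entry_level flag
  rep0 <- unicity_report(digest_collection(recs), recs)
  expect_equal(rep0$unique_peptides, rep$unique_peptides)
  expect_true(is.na(rep0$entry_level_additional_unique))
})

test_that("ambiguous peptides are excludable but U peptides never are", {
  recs <- protein_records(c("S1", "S2"),
                          c("AXAAAKUUUUUUK", "CCCCCCR"))
  idx <- digest_collection(recs)
  rep <- unicity_report(idx, recs, exclude_ambiguous = TRUE)
  expect_equal(rep$excluded_ambiguous, 1L)   # AXAAAK
  expect_true("UUUUUUK" %in% rep$unique_peptide_table$peptide)
  expect_false("AXAAAK" %in% rep$unique_peptide_table$peptide)
  expect_equal(rep$total_peptides, 3L)       # ambiguous stays in the universe
  rep2 <- unicity_report(idx, recs, exclude_ambiguous = FALSE)
  expect_true("AXAAAK" %in% rep2$unique_peptide_table$peptide)
  expect_equal(rep2$excluded_ambiguous, 0L)
})

test_that("isoform-specific unique peptides are identified", {
  recs <- protein_records(c("P1", "P1-2"),
                          c("AAAAAKCCCCCCR", "AAAAAKDDDDDDR"))
  rep <- unicity_report(digest_collection(recs), recs)
  expect_equal(rep$isoform_specific_unique, 1L)  # DDDDDDR on P1-2
})

test_that("a max_length cap filters the peptide universe before counting", {
  recs <- protein_records(c("S1", "S2"),
                          c("AAAAAKCCCCCCCCCCCCCCR", "DDDDDDK"))
  rep <- unicity_report(digest_collection(recs), recs, max_length = 10)
  expect_equal(rep$total_peptides, 2L)  # the 14-mer is out of the universe
  expect_equal(rep$unique_peptides, 2L)
})

test_that("adding a record can only demote peptides from unique to shared", {
  set.seed(101)
  for (i in 1:5) {
    recs <- random_records(10)
    rep1 <- unicity_report(digest_collection(recs), recs)
    # duplicate one record under a new accession
    bigger <- protein_records(c(recs$accession, "X9999"),
                              c(recs$sequence, recs$sequence[1]))
    rep2 <- unicity_report(digest_collection(bigger), bigger)
    demoted <- setdiff(rep1$unique_peptide_table$peptide,
                       rep2$unique_peptide_table$peptide)
    promoted <- setdiff(rep2$unique_peptide_table$peptide,
                        rep1$unique_peptide_table$peptide)
    expect_length(promoted, 0L)
    expect_true(all(demoted %in% rep1$unique_peptide_table$peptide))
  }
})

test_that("removing exact duplicates never lowers unicity", {
  set.seed(111)
  recs <- random_records(8)
  with_dup <- protein_records(c(recs$accession, "D1", "D2"),
                              c(recs$sequence, recs$sequence[1:2]))
  u_before <- unicity_report(digest_collection(with_dup), with_dup)
  deduped <- dedup_exact(with_dup)
  u_after <- unicity_report(digest_collection(deduped), deduped)
  expect_gte(u_after$unicity_percent, u_before$unicity_percent)
})

test_that("identical sequences have no unique peptides and are not counted", {
  recs <- protein_records(c("A", "B"), c("AAAAAKCCCCCCR", "AAAAAKCCCCCCR"))
  rep <- unicity_report(digest_collection(recs), recs)
  expect_equal(rep$unique_peptides, 0L)
  smry <- entries_with_unique_peptides(rep, recs)
  expect_equal(smry$n_with_unique, 0L)
})

test_that("entry summary splits by section and finds extremes", {
  recs <- protein_records(c("P1", "P1-2", "T1"),
                          c("AAAAAKCCCCCCR", "AAAAAKDDDDDDR",
                            "LTMMGTRLTMMGTRWWWWWWK"),
                          section = c("reviewed", "reviewed", "unreviewed"))
  rep <- unicity_report(digest_collection(recs), recs)
  smry <- entries_with_unique_peptides(rep, recs)
  expect_equal(smry$n_with_unique, 3L)
  expect_equal(as.integer(smry$by_section[c("reviewed", "unreviewed")]),
               c(2L, 1L))
  expect_equal(smry$n_isoforms, 1L)
  expect_equal(smry$max_unique_per_accession$accession, "T1")
  expect_equal(smry$most_repeated$peptide, "LTMMGTR")
  expect_equal(smry$most_repeated$n_occurrences, 2L)
})
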