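# In-silico digestion, occurrence indexing and monoisotopic masses.

test_that("default tryptic digestion applies cleavage and length rules", {
  expect_same_digest(digest_sequence("AAAAAKCCCCCCR"),
                     data.frame(peptide = c("AAAAAK", "CCCCCCR"),
                                start = c(0L, 6L)))
  # K followed by P: no cleavage under the Keil rule
  expect_same_digest(digest_sequence("AAAAAKPCCCCCR"),
                     data.frame(peptide = "AAAAAKPCCCCCR", start = 0L))
  # fragments shorter than six residues are filtered
  expect_equal(nrow(digest_sequence("ACKDEK")), 0L)
  # the initiator methionine stays: no Met-trimmed forms
  expect_same_digest(digest_sequence("MAAAAAKCCCCCCR"),
                     data.frame(peptide = c("MAAAAAK", "CCCCCCR"),
                                start = c(0L, 7L)))
})

test_that("trypsin_p cleaves before proline too", {
  d <- digest_sequence("AAAAAKPCCCCCR",
                       digestion_config(rule = "trypsin_p", min_length = 1))
  expect_equal(d$peptide, c("AAAAAK", "PCCCCCR"))
})

test_that("missed cleavages emit concatenations of consecutive fragments", {
  cfg <- digestion_config(missed_cleavages = 1, min_length = 1)
  d <- digest_sequence("AAKCCRDDK", cfg)
  expect_setequal(d$peptide,
                  c("AAK", "CCR", "DDK", "AAKCCR", "CCRDDK"))
})

test_that("ambiguity codes are never cleavage sites", {
  # B may denote N/D but never K/R; only literal K/R cleave
  d <- digest_sequence("AAABBBKCCCCCC", digestion_config(min_length = 1))
  expect_equal(d$peptide, c("AAABBBK", "CCCCCC"))
})

test_that("empty inputs are errors", {
  expect_error(digest_sequence(""), "non-empty")
  expect_error(digest_collection(protein_records(character(), character())),
               "empty collection")
})

test_that("collection digests record every occurrence across accessions", {
  recs <- protein_records(c("A1", "A2"), c("AAAAAKCCCCCCR", "AAAAAKCCCCCCR"))
  idx <- digest_collection(recs)
  expect_equal(sort(unique(idx$accession[idx$peptide == "AAAAAK"])),
               c("A1", "A2"))
  # a peptide repeated within one sequence keeps both offsets
  recs2 <- protein_records("Q1", "LTMMGTRLTMMGTR")
  idx2 <- digest_collection(recs2)
  expect_equal(idx2$peptide, c("LTMMGTR", "LTMMGTR"))
  expect_equal(idx2$start, c(0L, 7L))
})

test_that("monoisotopic masses match independently computed values", {
  # reference values computed with an independent proteomics mass library
  expect_equal(mono_mass("GGGGGG"), 360.139347, tolerance = 1e-6)
  expect_equal(mono_mass("AAAAAK"), 501.291097, tolerance = 1e-6)
  expect_equal(mono_mass("CCCCCCR"), 792.166784, tolerance = 1e-6)
  expect_equal(mono_mass("LTMMGTR"), 808.393530, tolerance = 1e-6)
  expect_equal(mono_mass("ACDEFGHIK"), 1018.454216, tolerance = 1e-6)
  expect_true(is.na(mono_mass("GX")))
  expect_true(is.na(mono_mass("ABR")))
  expect_false(is.na(mono_mass("UUUK")))  # selenocysteine has a mass
  expect_error(mono_mass(""), "empty peptide")
})

test_that("mass is additive up to one water per bond", {
  set.seed(21)
  for (i in 1:20) {
    p1 <- random_seq(sample(3:15, 1))
    p2 <- random_seq(sample(3:15, 1))
    expect_equal(mono_mass(paste0(p1, p2)),
                 mono_mass(p1) + mono_mass(p2) - 18.010565,
                 tolerance = 1e-9)
  }
})

test_that("digestion agrees with the brute-force oracle", {
  set.seed(31)
  for (i in 1:200) {
    s <- random_seq(sample(10:60, 1))
    rule <- sample(c("trypsin", "trypsin_p"), 1)
    m <- sample(0:2, 1)
    cfg <- digestion_config(rule = rule, missed_cleavages = m, min_length = 1)
    expect_same_digest(digest_sequence(s, cfg), oracle_digest(s, rule, m, 1))
  }
})

test_that("zero-missed-cleavage peptides partition the sequence", {
  set.seed(41)
  cfg <- digestion_config(min_length = 1)
  for (i in 1:50) {
    s <- random_seq(sample(10:80, 1))
    d <- digest_sequence(s, cfg)
    expect_equal(paste(d$peptide, collapse = ""), s)
    expect_equal(d$start, head(c(0L, cumsum(nchar(d$peptide))), -1))
  }
})

test_that("raising min_length never adds peptides", {
  set.seed(51)
  for (i in 1:20) {
    s <- random_seq(60)
    p6 <- digest_sequence(s, digestion_config(min_length = 6))$peptide
    p8 <- digest_sequence(s, digestion_config(min_length = 8))$peptide
    expect_true(all(p8 %in% p6))
  }
})

test_that("trypsin peptides are concatenations of trypsin_p fragments", {
  set.seed(61)
  for (i in 1:20) {
    s <- random_seq(60, p_kr = 0.2)
    tryp <- digest_sequence(s, digestion_config(min_length = 1))$peptide
    closure <- digest_sequence(
      s, digestion_config(rule = "trypsin_p", missed_cleavages = 20,
                          min_length = 1))$peptide
    expect_true(all(tryp %in% closure))
  }
})

test_that("peptide tables list mass, occurrences and accessions", {
  recs <- protein_records(c("A1", "A2"), c("AAAAAKCCCCCCR", "AAAAAKDDDDDDR"))
  f <- tempfile(fileext = ".tsv")
  write_peptide_table(digest_collection(recs), f)
  tab <- read.delim(f)
  row <- tab[tab$peptide == "AAAAAK", ]
  expect_equal(row$n_occurrences, 2L)
  expect_equal(row$accessions, "A1;A2")
  expect_equal(row$mono_mass, 501.2911, tolerance = 1e-6)
})
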