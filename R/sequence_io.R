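# Reading and writing the three input dialects: FASTA protein collections
# (UniProtKB-style "db|ACC|NAME" headers or plain headers), humsavar-like
# variant tables, and repository peptide-evidence tables.

#' Construct a protein record collection
#'
#' A protein collection is an ordered data frame with one row per sequence
#' record, the container consumed by every downstream stage. Sequences are
#' uppercased and validated against the residue alphabet (20 standard amino
#' acids plus U, X, B, Z); anything else, including `*` and gap characters,
#' is an error rather than being silently dropped, because silent cleanup
#' would corrupt downstream peptide counts.
#'
#' @param accession Character vector of unique accessions. Isoforms carry a
#'   `"-n"` suffix (e.g. `"P12345-2"`).
#' @param sequence Character vector of amino-acid sequences.
#' @param section One of `"reviewed"`, `"unreviewed"`, `"other"` per record
#'   (recycled if length one).
#' @param description Free-text description per record (recycled).
#' @return A data frame of class `protein_records` with columns `accession`,
#'   `entry_accession`, `section`, `is_isoform`, `description`, `sequence`.
#' @examples
#' protein_records(c("P1", "P1-2"), c("MAAAKCCCR", "MAAAKCCR"))
#' @export
protein_records <- function(accession, sequence,
                            section = "other", description = "") {
  n <- length(accession)
  stopifnot(length(sequence) == n)
  section <- rep_len(section, n)
  description <- rep_len(description, n)
  sequence <- toupper(sequence)
  accession <- as.character(accession)

  if (anyDuplicated(accession)) {
    dup <- accession[duplicated(accession)][1]
    stop_pepspace("duplicate accession '%s' in collection", dup)
  }
  bad_section <- setdiff(unique(section), c("reviewed", "unreviewed", "other"))
  if (length(bad_section)) {
    stop_pepspace("unknown section '%s'", bad_section[1])
  }
  if (n > 0 && any(!nzchar(sequence))) {
    stop_pepspace("empty sequence for accession '%s'",
                  accession[!nzchar(sequence)][1])
  }
  bad <- first_bad_residue(sequence)
  if (any(bad > 0L)) {
    i <- which(bad > 0L)[1]
    stop_pepspace("illegal residue '%s' in accession '%s' at position %d",
                  substr(sequence[i], bad[i], bad[i]), accession[i], bad[i])
  }

  out <- data.frame(
    accession = accession,
    entry_accession = entry_accession(accession),
    section = section,
    is_isoform = is_isoform_accession(accession),
    description = description,
    sequence = sequence,
    stringsAsFactors = FALSE
  )
  class(out) <- c("protein_records", "data.frame")
  out
}

#' @export
print.protein_records <- function(x, ...) {
  cat(sprintf("Protein collection: %d records (%d entries, %d isoforms)\n",
              nrow(x), length(unique(x$entry_accession)), sum(x$is_isoform)))
  if (nrow(x)) {
    preview <- utils::head(x, 5)
    preview$sequence <- paste0(substr(preview$sequence, 1, 30),
                               ifelse(nchar(preview$sequence) > 30, "...", ""))
    print.data.frame(preview, row.names = FALSE)
    if (nrow(x) > 5) cat(sprintf("... and %d more\n", nrow(x) - 5))
  }
  invisible(x)
}

#' Read a protein collection from FASTA
#'
#' Parses a FASTA file into a [protein_records()] collection. The `uniprot`
#' dialect interprets headers of the form `sp|ACC|NAME desc` / `tr|ACC|NAME
#' desc`, mapping `sp` to section `reviewed` and `tr` to `unreviewed`; extra
#' `|`-separated fields between the database tag and the final name token are
#' folded into the accession (variant-expanded accessions are written that
#' way). The `plain` dialect takes the first whitespace-delimited token of the
#' header as the accession and assigns section `other`, which is how
#' non-UniProt collections (Ensembl, RefSeq, IPI exports) are read: their
#' identifiers are taken verbatim.
#'
#' @param path Path to a FASTA file.
#' @param header_dialect `"uniprot"` (default) or `"plain"`.
#' @return A `protein_records` collection, in file order.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">sp|P12345|TEST Example", "ACDEFGHIK"), f)
#' read_fasta(f)
#' @export
read_fasta <- function(path, header_dialect = c("uniprot", "plain")) {
  header_dialect <- match.arg(header_dialect)
  if (!file.exists(path)) stop_pepspace("FASTA file not found: %s", path)
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  seqs <- as.character(aa)

  if (header_dialect == "uniprot") {
    first_tok <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    parts <- strsplit(first_tok, "|", fixed = TRUE)
    np <- lengths(parts)
    bad <- which(np < 3 |
                   !vapply(parts, function(p) p[1] %in% c("sp", "tr"),
                           logical(1)))
    if (length(bad)) {
      stop_pepspace("malformed UniProtKB header at record %d: '%s'",
                    bad[1], headers[bad[1]])
    }
    db <- vapply(parts, `[`, character(1), 1)
    accession <- vapply(parts, function(p) {
      paste(p[2:(length(p) - 1)], collapse = "|")
    }, character(1))
    section <- ifelse(db == "sp", "reviewed", "unreviewed")
  } else {
    accession <- sub("\\s.*$", "", headers)
    desc <- ifelse(grepl("\\s", headers),
                   sub("^\\S+\\s+", "", headers), "")
    section <- "other"
  }
  if (any(!nzchar(accession))) {
    stop_pepspace("malformed header at record %d: '%s'",
                  which(!nzchar(accession))[1],
                  headers[!nzchar(accession)][1])
  }
  protein_records(accession, seqs, section = section, description = desc)
}

#' Write a protein collection to FASTA
#'
#' Inverse of [read_fasta()]: the `uniprot` dialect writes
#' `db|ACC|NAME description` headers (`sp` for reviewed, `tr` otherwise; the
#' name token is the accession with `|` replaced by `_` so headers remain
#' parseable), the `plain` dialect writes `ACC description`.
#'
#' @param records A `protein_records` collection.
#' @param path Output path.
#' @param header_dialect `"uniprot"` or `"plain"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, header_dialect = c("uniprot", "plain")) {
  header_dialect <- match.arg(header_dialect)
  if (header_dialect == "uniprot") {
    db <- ifelse(records$section == "reviewed", "sp", "tr")
    name <- gsub("|", "_", records$accession, fixed = TRUE)
    headers <- paste0(db, "|", records$accession, "|", name)
  } else {
    headers <- records$accession
  }
  headers <- ifelse(nzchar(records$description),
                    paste(headers, records$description), headers)
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- headers
  Biostrings::writeXStringSet(aa, filepath = path, width = 60L)
  invisible(path)
}

# --- variant tables ---------------------------------------------------------

THREE_LETTER_AA <- c(
  Ala = "A", Arg = "R", Asn = "N", Asp = "D", Cys = "C", Gln = "Q",
  Glu = "E", Gly = "G", His = "H", Ile = "I", Leu = "L", Lys = "K",
  Met = "M", Phe = "F", Pro = "P", Ser = "S", Thr = "T", Trp = "W",
  Tyr = "Y", Val = "V", Sec = "U"
)

# "D123N" or "p.Asp123Asn" -> list(ref, position, alt); NULL when unparseable.
parse_change <- function(change) {
  change <- trimws(change)
  m <- regmatches(change, regexec("^([A-Z])([0-9]+)([A-Z])$", change))[[1]]
  if (length(m) == 4) {
    return(list(ref = m[2], position = as.integer(m[3]), alt = m[4]))
  }
  m <- regmatches(change,
                  regexec("^p\\.([A-Z][a-z]{2})([0-9]+)([A-Z][a-z]{2})$",
                          change))[[1]]
  if (length(m) == 4 &&
      m[2] %in% names(THREE_LETTER_AA) && m[4] %in% names(THREE_LETTER_AA)) {
    return(list(ref = unname(THREE_LETTER_AA[m[2]]),
                position = as.integer(m[3]),
                alt = unname(THREE_LETTER_AA[m[4]])))
  }
  NULL
}

#' Construct a variant table
#'
#' One row per annotated single-amino-acid substitution, in canonical-sequence
#' coordinates (1-based). The `is_il_variant` flag marks isoleucine/leucine
#' interchanges, which are isobaric and therefore invisible to standard
#' MS workflows.
#'
#' @param entry_accession Entry accession the variant is annotated on.
#' @param feature_id Stable feature identifier (e.g. `"VAR_000123"`).
#' @param position 1-based residue position on the canonical sequence.
#' @param ref_aa,alt_aa Single-letter reference and alternate residues.
#' @param category `"disease"`, `"polymorphism"` or `"unclassified"`.
#' @param disease_name,dbsnp Optional annotation columns.
#' @return A data frame of class `variant_records`.
#' @export
variant_records <- function(entry_accession, feature_id, position,
                            ref_aa, alt_aa, category = "unclassified",
                            disease_name = "", dbsnp = "") {
  n <- length(feature_id)
  category <- rep_len(category, n)
  out <- data.frame(
    entry_accession = as.character(entry_accession),
    feature_id = as.character(feature_id),
    position = as.integer(position),
    ref_aa = as.character(ref_aa),
    alt_aa = as.character(alt_aa),
    category = category,
    disease_name = rep_len(as.character(disease_name), n),
    dbsnp = rep_len(as.character(dbsnp), n),
    stringsAsFactors = FALSE
  )
  if (any(out$position < 1L)) {
    stop_pepspace("variant position must be >= 1 (feature %s)",
                  out$feature_id[out$position < 1L][1])
  }
  same <- out$ref_aa == out$alt_aa
  if (any(same)) {
    stop_pepspace("variant %s has identical reference and alternate residue",
                  out$feature_id[same][1])
  }
  bad_cat <- !out$category %in% c("disease", "polymorphism", "unclassified")
  if (any(bad_cat)) {
    stop_pepspace("unknown variant category '%s'", out$category[bad_cat][1])
  }
  out$is_il_variant <- out$ref_aa %in% c("I", "L") & out$alt_aa %in% c("I", "L")
  class(out) <- c("variant_records", "data.frame")
  out
}

#' Read a humsavar-like variant table
#'
#' Tab-separated with a single header line and `#`-prefixed comment lines
#' ignored. Required columns: `entry_accession`, `feature_id`, `change`,
#' `category`; optional: `disease`, `dbsnp`. The `change` column accepts both
#' compact (`"D123N"`) and HGVS-protein (`"p.Asp123Asn"`) notation. Category
#' strings are matched case-insensitively; `"LP/P"` and `"disease"` map to
#' disease, `"LB/B"` and `"polymorphism"` to polymorphism, anything unknown
#' becomes `unclassified` with a warning.
#'
#' @param path Path to the TSV file.
#' @return A `variant_records` table.
#' @export
read_variants <- function(path) {
  if (!file.exists(path)) stop_pepspace("variant file not found: %s", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                    colClasses = "character")
  needed <- c("entry_accession", "feature_id", "change", "category")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop_pepspace("variant table lacks column(s): %s",
                  paste(missing_cols, collapse = ", "))
  }
  parsed <- lapply(tab$change, parse_change)
  bad <- which(vapply(parsed, is.null, logical(1)))
  if (length(bad)) {
    stop_pepspace("unparseable variant change '%s' at row %d",
                  tab$change[bad[1]], bad[1])
  }
  cat_raw <- tolower(tab$category)
  category <- ifelse(cat_raw %in% c("disease", "lp/p"), "disease",
              ifelse(cat_raw %in% c("polymorphism", "lb/b"), "polymorphism",
              ifelse(cat_raw == "unclassified", "unclassified", NA)))
  if (anyNA(category)) {
    warning(sprintf("unknown variant category '%s' mapped to 'unclassified'",
                    tab$category[is.na(category)][1]), call. = FALSE)
    category[is.na(category)] <- "unclassified"
  }
  variant_records(
    entry_accession = tab$entry_accession,
    feature_id = tab$feature_id,
    position = vapply(parsed, function(p) p$position, integer(1)),
    ref_aa = vapply(parsed, function(p) p$ref, character(1)),
    alt_aa = vapply(parsed, function(p) p$alt, character(1)),
    category = category,
    disease_name = if ("disease" %in% names(tab)) tab$disease else "",
    dbsnp = if ("dbsnp" %in% names(tab)) tab$dbsnp else ""
  )
}

#' Write a variant table
#'
#' Writes the TSV dialect read by [read_variants()], with changes in compact
#' `"D123N"` notation.
#'
#' @param variants A `variant_records` table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants <- function(variants, path) {
  out <- data.frame(
    entry_accession = variants$entry_accession,
    feature_id = variants$feature_id,
    change = paste0(variants$ref_aa, variants$position, variants$alt_aa),
    category = variants$category,
    disease = variants$disease_name,
    dbsnp = variants$dbsnp,
    stringsAsFactors = FALSE
  )
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# --- evidence tables --------------------------------------------------------

#' Construct a repository evidence set
#'
#' Peptide-level identifications exported from an MS proteomics repository:
#' one row per distinct peptide with the number of experiments it was
#' identified in. Experiment counts are meaningful for PRIDE-like sources;
#' repositories that do not report them get count 1. Duplicate peptide rows
#' are collapsed by summing counts; peptides are uppercased.
#'
#' @param peptide Character vector of peptide sequences.
#' @param experiment_count Integer vector of experiment counts (default 1).
#' @param repository Repository label (e.g. `"PRIDE"`).
#' @return A data frame of class `evidence_set`, sorted by peptide, with
#'   attribute `repository`.
#' @export
evidence_set <- function(peptide, experiment_count = 1L,
                         repository = "unknown") {
  peptide <- toupper(as.character(peptide))
  experiment_count <- rep_len(as.integer(experiment_count), length(peptide))
  if (length(peptide) && any(!nzchar(peptide))) {
    stop_pepspace("empty peptide in evidence set")
  }
  if (length(peptide) && any(experiment_count < 0L)) {
    stop_pepspace("negative experiment count in evidence set")
  }
  if (length(peptide)) {
    agg <- rowsum(experiment_count, group = peptide)
    out <- data.frame(peptide = rownames(agg),
                      experiment_count = as.integer(agg[, 1]),
                      stringsAsFactors = FALSE)
    out <- out[corder(out$peptide), , drop = FALSE]
    rownames(out) <- NULL
  } else {
    out <- data.frame(peptide = character(), experiment_count = integer(),
                      stringsAsFactors = FALSE)
  }
  attr(out, "repository") <- repository
  class(out) <- c("evidence_set", "data.frame")
  out
}

#' Read a repository evidence table
#'
#' Tab-separated with a `peptide` column and an optional `experiment_count`
#' column (missing counts default to 1). Duplicate peptide rows are collapsed
#' by summing their counts. An empty table yields an empty set with a warning.
#'
#' @param path Path to the TSV file.
#' @param repository Repository label attached to the set.
#' @return An `evidence_set`.
#' @export
read_evidence <- function(path, repository = "unknown") {
  if (!file.exists(path)) stop_pepspace("evidence file not found: %s", path)
  tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!"peptide" %in% names(tab)) {
    stop_pepspace("evidence table lacks a 'peptide' column")
  }
  if (nrow(tab) == 0) {
    warning(sprintf("evidence file '%s' contains no peptides", path),
            call. = FALSE)
    return(evidence_set(character(), repository = repository))
  }
  counts <- if ("experiment_count" %in% names(tab)) {
    as.integer(tab$experiment_count)
  } else {
    1L
  }
  evidence_set(tab$peptide, counts, repository = repository)
}

#' Write a repository evidence table
#'
#' @param evidence An `evidence_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  write.table(as.data.frame(evidence), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
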