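# Peptide unicity: sequence-level and entry-level uniqueness of tryptic
# peptides within a collection, with ambiguous-residue exclusion.

#' Evaluate peptide unicity within a digested collection
#'
#' A peptide is sequence-unique when all of its occurrences lie in exactly
#' one accession; multiple occurrences within that single sequence do not
#' disqualify it (a repeated peptide still identifies one protein). With
#' `entry_level = TRUE`, peptides shared only among records of one entry
#' (canonical plus its isoforms) are additionally counted as
#' `entry_level_additional_unique`; they are reported separately and never
#' folded into the headline sequence-level count or percentage.
#'
#' Peptides containing the ambiguity codes X, B or Z cannot be matched to a
#' determinate sequence; with `exclude_ambiguous = TRUE` (the default) they
#' are excluded from the unique counts (but remain in `total_peptides`) and
#' tallied in `excluded_ambiguous`. Selenocysteine (U) peptides are ordinary
#' and never excluded.
#'
#' @param index A `digest_index` built from `records`.
#' @param records The digested `protein_records` collection.
#' @param exclude_ambiguous Exclude X/B/Z-containing peptides from unique
#'   counts (default `TRUE`).
#' @param entry_level Also evaluate entry-level uniqueness (default `FALSE`).
#' @param max_length Optional cap on peptide length; peptides longer than
#'   this are removed from the peptide universe before any counting (used to
#'   restrict to lengths observable in MS repositories).
#' @return A list of class `unicity_report`: `total_peptides`,
#'   `unique_peptides`, `unicity_percent`, `excluded_ambiguous`,
#'   `isoform_specific_unique`, `entry_level_additional_unique` (`NA` unless
#'   `entry_level`), `per_accession_unique_counts` (data frame),
#'   `unique_peptide_table` (data frame `peptide`, `accession`,
#'   `n_occurrences`), and the applied settings.
#' @examples
#' recs <- protein_records(c("P1", "P2"),
#'                         c("AAAAAKCCCCCCR", "CCCCCCRDDDDDDK"))
#' unicity_report(digest_collection(recs), recs)
#' @export
unicity_report <- function(index, records, exclude_ambiguous = TRUE,
                           entry_level = FALSE, max_length = Inf) {
  stopifnot(inherits(index, "digest_index"),
            inherits(records, "protein_records"))
  idx <- index
  if (is.finite(max_length)) {
    idx <- idx[nchar(idx$peptide) <= max_length, , drop = FALSE]
  }
  occ <- unique(data.frame(peptide = idx$peptide, accession = idx$accession,
                           stringsAsFactors = FALSE))
  peptides <- csort(unique(occ$peptide))
  total <- length(peptides)

  acc_by_pep <- split(occ$accession, factor(occ$peptide, levels = peptides))
  n_acc <- lengths(acc_by_pep)
  ambiguous <- is_ambiguous_peptide(peptides)

  single <- n_acc == 1L
  counted_unique <- single & (!exclude_ambiguous | !ambiguous)
  excluded_ambiguous <- if (exclude_ambiguous) sum(single & ambiguous) else 0L

  unique_peps <- peptides[counted_unique]
  unique_acc <- vapply(acc_by_pep[counted_unique], `[`, character(1), 1)
  iso <- records$is_isoform[match(unique_acc, records$accession)]
  isoform_specific <- sum(iso)

  entry_additional <- NA_integer_
  if (entry_level) {
    multi <- which(!single & (!exclude_ambiguous | !ambiguous))
    entry_additional <- sum(vapply(acc_by_pep[multi], function(a) {
      length(unique(entry_accession(a))) == 1L
    }, logical(1)))
  }

  per_acc <- if (length(unique_acc)) {
    tab <- table(unique_acc)
    data.frame(accession = names(tab), n_unique = as.integer(tab),
               stringsAsFactors = FALSE)
  } else {
    data.frame(accession = character(), n_unique = integer(),
               stringsAsFactors = FALSE)
  }
  per_acc <- per_acc[corder(per_acc$accession), , drop = FALSE]
  rownames(per_acc) <- NULL

  # within-sequence occurrence counts of the unique peptides
  if (length(unique_peps)) {
    sub <- idx[idx$peptide %in% unique_peps, , drop = FALSE]
    occ_counts <- table(sub$peptide)
    unique_tab <- data.frame(
      peptide = unique_peps,
      accession = unique_acc,
      n_occurrences = as.integer(occ_counts[unique_peps]),
      stringsAsFactors = FALSE
    )
  } else {
    unique_tab <- data.frame(peptide = character(), accession = character(),
                             n_occurrences = integer(),
                             stringsAsFactors = FALSE)
  }
  rownames(unique_tab) <- NULL

  structure(list(
    total_peptides = total,
    unique_peptides = length(unique_peps),
    unicity_percent = if (total == 0) 0 else
      round(100 * length(unique_peps) / total, 1),
    excluded_ambiguous = as.integer(excluded_ambiguous),
    isoform_specific_unique = as.integer(isoform_specific),
    entry_level_additional_unique = entry_additional,
    per_accession_unique_counts = per_acc,
    unique_peptide_table = unique_tab,
    exclude_ambiguous = exclude_ambiguous,
    entry_level = entry_level,
    max_length = max_length
  ), class = "unicity_report")
}

#' @export
print.unicity_report <- function(x, ...) {
  cat(sprintf("Peptide unicity: %d / %d unique (%.1f%%)\n",
              x$unique_peptides, x$total_peptides, x$unicity_percent))
  cat(sprintf("  isoform-specific unique: %d; ambiguous excluded: %d\n",
              x$isoform_specific_unique, x$excluded_ambiguous))
  if (!is.na(x$entry_level_additional_unique)) {
    cat(sprintf("  entry-level additional unique: %d\n",
                x$entry_level_additional_unique))
  }
  invisible(x)
}

#' Accessions carrying unique peptides
#'
#' Summarises which records of the collection are identifiable by at least
#' one sequence-unique tryptic peptide, split by section and isoform status,
#' plus the accession with most unique peptides and the unique peptide with
#' most repeats inside its single sequence.
#'
#' @param report A [unicity_report()].
#' @param records The `protein_records` collection the report was built from.
#' @return A list: `n_with_unique`, `by_section` (table), `n_isoforms`,
#'   `max_unique_per_accession` (list `accession`, `n`), `most_repeated`
#'   (list `peptide`, `accession`, `n_occurrences`).
#' @export
entries_with_unique_peptides <- function(report, records) {
  stopifnot(inherits(report, "unicity_report"),
            inherits(records, "protein_records"))
  per_acc <- report$per_accession_unique_counts
  m <- match(per_acc$accession, records$accession)
  by_section <- table(factor(records$section[m],
                             levels = c("reviewed", "unreviewed", "other")))
  max_u <- if (nrow(per_acc)) {
    i <- which.max(per_acc$n_unique)
    list(accession = per_acc$accession[i], n = per_acc$n_unique[i])
  } else {
    list(accession = NA_character_, n = 0L)
  }
  most_rep <- if (nrow(report$unique_peptide_table)) {
    i <- which.max(report$unique_peptide_table$n_occurrences)
    as.list(report$unique_peptide_table[i, ])
  } else {
    list(peptide = NA_character_, accession = NA_character_,
         n_occurrences = 0L)
  }
  list(n_with_unique = nrow(per_acc),
       by_section = by_section,
       n_isoforms = sum(records$is_isoform[m]),
       max_unique_per_accession = max_u,
       most_repeated = most_rep)
}

#' Write a unicity report
#'
#' One summary row (total, unique, percent, exclusions) plus an optional
#' per-accession detail file.
#'
#' @param report A [unicity_report()].
#' @param path Output TSV path.
#' @param detail_path Optional path for the per-accession detail TSV.
#' @param config Optional [digestion_config()] echoed in the header comment.
#' @return `path`, invisibly.
#' @export
write_unicity_report <- function(report, path, detail_path = NULL,
                                 config = NULL) {
  tab <- data.frame(
    total_peptides = report$total_peptides,
    unique_peptides = report$unique_peptides,
    unicity_percent = sprintf("%.1f", report$unicity_percent),
    excluded_ambiguous = report$excluded_ambiguous,
    isoform_specific_unique = report$isoform_specific_unique,
    entry_level_additional_unique = report$entry_level_additional_unique,
    stringsAsFactors = FALSE
  )
  write_report_tsv(tab, path, config)
  if (!is.null(detail_path)) {
    write_report_tsv(report$per_accession_unique_counts, detail_path, config)
  }
  invisible(path)
}
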