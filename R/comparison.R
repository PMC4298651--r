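# Pairwise three-compartment comparison of two digested collections and
# repository-evidence annotation of the compartments.

check_same_config <- function(index1, index2) {
  c1 <- attr(index1, "config")
  c2 <- attr(index2, "config")
  if (!identical(unclass(c1), unclass(c2))) {
    stop_pepspace(
      "digest indexes were built with different digestion configs (%s vs %s)",
      config_string(c1), config_string(c2))
  }
  invisible(TRUE)
}

#' Compare two digested collections
#'
#' Splits the tryptic peptides of two collections into three compartments by
#' exact full-string identity: unique to DB1 (`compartment_I`), shared
#' (`compartment_II`) and unique to DB2 (`compartment_III`). Accession
#' coverage is derived from the peptide compartments: an accession of DB1 is
#' unrepresented in DB2 when it contributes at least one compartment-I
#' peptide, i.e. its peptide set is not fully contained in DB2's (and
#' symmetrically for DB2).
#'
#' Both indexes must have been built with the same [digestion_config()];
#' comparing digests produced under different rules is refused.
#'
#' @param index1,index2 `digest_index` objects for DB1 and DB2.
#' @return A list of class `comparison_result` with components
#'   `compartment_I`, `compartment_II`, `compartment_III` (sorted peptide
#'   vectors), `db1_unrepresented_accessions`, `db2_unrepresented_accessions`.
#' @examples
#' r1 <- protein_records("A1", "AAAAAKCCCCCCR")
#' r2 <- protein_records("B1", "AAAAAKDDDDDDR")
#' compare_indexes(digest_collection(r1), digest_collection(r2))
#' @export
compare_indexes <- function(index1, index2) {
  stopifnot(inherits(index1, "digest_index"), inherits(index2, "digest_index"))
  check_same_config(index1, index2)
  p1 <- index_peptides(index1)
  p2 <- index_peptides(index2)
  comp_i <- csort(setdiff(p1, p2))
  comp_ii <- csort(intersect(p1, p2))
  comp_iii <- csort(setdiff(p2, p1))

  db1_unrep <- csort(unique(index1$accession[index1$peptide %in% comp_i]))
  db2_unrep <- csort(unique(index2$accession[index2$peptide %in% comp_iii]))

  structure(list(compartment_I = comp_i,
                 compartment_II = comp_ii,
                 compartment_III = comp_iii,
                 db1_unrepresented_accessions = db1_unrep,
                 db2_unrepresented_accessions = db2_unrep),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("Comparison: I (DB1 only) %d | II (shared) %d | III (DB2 only) %d\n",
              length(x$compartment_I), length(x$compartment_II),
              length(x$compartment_III)))
  cat(sprintf("DB1 accessions unrepresented in DB2: %d; DB2 in DB1: %d\n",
              length(x$db1_unrepresented_accessions),
              length(x$db2_unrepresented_accessions)))
  invisible(x)
}

#' Annotate comparison compartments with repository evidence
#'
#' For each compartment, counts the peptides present in the evidence (exact
#' full-length string match; isoleucine and leucine are not equated) and the
#' corresponding percentage of the compartment.
#'
#' @param result A [compare_indexes()] result.
#' @param evidence An `evidence_set`, a list of them (a peptide matches when
#'   present in at least one), or a character vector of peptides.
#' @return A data frame with rows `db1_unique`, `common`, `db2_unique` and
#'   columns `n_peptides`, `n_with_evidence`, `evidence_percent` (numeric) and
#'   `evidence_percent_label` (Table-style: 1 decimal, exact zero as `"0"`).
#' @export
annotate_with_evidence <- function(result, evidence) {
  stopifnot(inherits(result, "comparison_result"))
  ev_peps <- evidence_peptides(evidence)
  rows <- list(db1_unique = result$compartment_I,
               common = result$compartment_II,
               db2_unique = result$compartment_III)
  n <- vapply(rows, length, integer(1))
  hit <- vapply(rows, function(p) sum(p %in% ev_peps), integer(1))
  out <- data.frame(
    compartment = names(rows),
    n_peptides = n,
    n_with_evidence = hit,
    evidence_percent = ifelse(n == 0, 0, round(100 * hit / n, 1)),
    evidence_percent_label = mapply(format_percent, hit, n, USE.NAMES = FALSE),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

# Flatten the accepted evidence shapes to a peptide character vector.
evidence_peptides <- function(evidence) {
  if (is.character(evidence)) return(unique(toupper(evidence)))
  if (inherits(evidence, "evidence_set")) return(evidence$peptide)
  if (is.list(evidence)) {
    return(unique(unlist(lapply(evidence, evidence_peptides),
                         use.names = FALSE)))
  }
  stop_pepspace("unsupported evidence object of class '%s'",
                paste(class(evidence), collapse = "/"))
}

#' Write a comparison report
#'
#' Tab-separated block with one row per compartment (DB1-unique, DB2-unique,
#' common): peptide count, evidence count and evidence percentage. A leading
#' `#` comment line records the tool version and digestion config.
#'
#' @param result A [compare_indexes()] result.
#' @param evidence Evidence passed to [annotate_with_evidence()]; `NULL`
#'   writes zero evidence columns.
#' @param path Output TSV path.
#' @param config Optional [digestion_config()] echoed in the header comment.
#' @param labels Length-2 character vector naming DB1 and DB2.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(result, evidence = NULL, path,
                                    config = NULL,
                                    labels = c("DB1", "DB2")) {
  ann <- annotate_with_evidence(result,
                                if (is.null(evidence)) character() else evidence)
  ann$db <- c(labels[1], "Com.", labels[2])
  ann <- ann[c(1, 3, 2), c("db", "n_peptides", "n_with_evidence",
                           "evidence_percent_label")]
  names(ann) <- c("db", "peptides", "evidence", "evidence_percent")
  write_report_tsv(ann, path, config)
}

# Shared writer: "#" provenance comment + single header line + rows.
write_report_tsv <- function(tab, path, config = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  cfg <- if (is.null(config)) "" else paste0(" ", config_string(config))
  writeLines(sprintf("# pepspace %s%s",
                     as.character(packageVersion("pepspace")), cfg), con)
  write.table(tab, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
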