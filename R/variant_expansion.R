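# Variant expansion: one additional full-length sequence per applicable
# single-amino-acid variant, applied to canonical and isoform records.

#' Expand a collection with single-amino-acid variants
#'
#' For each variant (restricted to disease-associated ones when
#' `mode = "disease_only"`) and each record of the variant's entry (canonical
#' and isoforms), the variant is applied when the record's residue at the
#' stated position equals the variant's reference residue; one new record is
#' then emitted with the alternate residue substituted and accession
#' `"<source accession>|<feature_id>"`. Original records are always retained,
#' and no variants are stacked: each expanded sequence carries exactly one
#' substitution.
#'
#' Variant positions are canonical-sequence coordinates. Isoform records are
#' expanded only when the reference-residue check passes verbatim at the same
#' position on the isoform sequence; no alignment-based coordinate remapping
#' is attempted, so isoform expansion is conservative and may undercount
#' relative to annotation pipelines that remap coordinates.
#'
#' @param records A `protein_records` collection.
#' @param variants A `variant_records` table.
#' @param mode `"all"` (default) or `"disease_only"`.
#' @return A list with components:
#'   \describe{
#'     \item{records}{the expanded `protein_records` collection (originals
#'       first, then expanded records); expanded rows carry the extra columns
#'       `source_accession` and `applied_feature_id` (`NA` on originals);}
#'     \item{log}{a data frame with one row per (variant, record) pair
#'       considered: `feature_id`, `target_accession`, `status`
#'       (`applied`/`skipped`), `reason`, `target_is_isoform`.}
#'   }
#' @examples
#' recs <- protein_records("P1", "ACDEFGHIK", section = "reviewed")
#' vars <- variant_records("P1", "VAR_000001", 3, "D", "N", "disease")
#' expand_variants(recs, vars)$records$sequence
#' @export
expand_variants <- function(records, variants, mode = c("all", "disease_only")) {
  mode <- match.arg(mode)
  stopifnot(inherits(records, "protein_records"),
            inherits(variants, "variant_records"))
  use <- if (mode == "disease_only") {
    variants[variants$category == "disease", , drop = FALSE]
  } else {
    variants
  }

  log_rows <- list()
  new_rows <- list()
  k <- 0L
  for (v in seq_len(nrow(use))) {
    ent <- use$entry_accession[v]
    pos <- use$position[v]
    targets <- which(records$entry_accession == ent)
    for (i in targets) {
      k <- k + 1L
      acc <- records$accession[i]
      seqlen <- nchar(records$sequence[i])
      if (pos > seqlen) {
        status <- "skipped"; reason <- "position_out_of_range"
      } else if (substr(records$sequence[i], pos, pos) != use$ref_aa[v]) {
        status <- "skipped"; reason <- "reference_mismatch"
      } else {
        status <- "applied"; reason <- ""
        newseq <- records$sequence[i]
        substr(newseq, pos, pos) <- use$alt_aa[v]
        new_rows[[length(new_rows) + 1L]] <- data.frame(
          accession = paste0(acc, "|", use$feature_id[v]),
          section = records$section[i],
          description = records$description[i],
          sequence = newseq,
          source_accession = acc,
          applied_feature_id = use$feature_id[v],
          stringsAsFactors = FALSE
        )
      }
      log_rows[[k]] <- data.frame(
        feature_id = use$feature_id[v],
        target_accession = acc,
        status = status,
        reason = reason,
        target_is_isoform = records$is_isoform[i],
        stringsAsFactors = FALSE
      )
    }
  }

  log <- if (length(log_rows)) {
    do.call(rbind, log_rows)
  } else {
    data.frame(feature_id = character(), target_accession = character(),
               status = character(), reason = character(),
               target_is_isoform = logical(), stringsAsFactors = FALSE)
  }

  if (length(new_rows)) {
    add <- do.call(rbind, new_rows)
    expanded <- protein_records(
      c(records$accession, add$accession),
      c(records$sequence, add$sequence),
      section = c(records$section, add$section),
      description = c(records$description, add$description)
    )
    expanded$source_accession <- c(rep(NA_character_, nrow(records)),
                                   add$source_accession)
    expanded$applied_feature_id <- c(rep(NA_character_, nrow(records)),
                                     add$applied_feature_id)
  } else {
    expanded <- records
    expanded$source_accession <- rep(NA_character_, nrow(records))
    expanded$applied_feature_id <- rep(NA_character_, nrow(records))
  }
  list(records = expanded, log = log)
}

#' Summarise an expansion log
#'
#' Per-variant counts of applications to canonical and isoform records and of
#' skips.
#'
#' @param log The `log` component of [expand_variants()].
#' @return A data frame with one row per feature_id.
#' @export
expansion_log_summary <- function(log) {
  if (nrow(log) == 0) {
    return(data.frame(feature_id = character(), applied_canonical = integer(),
                      applied_isoform = integer(), skipped = integer(),
                      stringsAsFactors = FALSE))
  }
  ids <- csort(unique(log$feature_id))
  out <- data.frame(
    feature_id = ids,
    applied_canonical = vapply(ids, function(f) {
      sum(log$feature_id == f & log$status == "applied" & !log$target_is_isoform)
    }, integer(1)),
    applied_isoform = vapply(ids, function(f) {
      sum(log$feature_id == f & log$status == "applied" & log$target_is_isoform)
    }, integer(1)),
    skipped = vapply(ids, function(f) {
      sum(log$feature_id == f & log$status == "skipped")
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Peptide accounting for a variant expansion
#'
#' Quantifies what variant expansion adds to a search space and how much of
#' it collides with peptides that exist elsewhere:
#'
#' * `additional` — peptides of the expanded digest absent from the base
#'   digest (the new search-space content);
#' * `n_coincident_other` — how many of those additional peptides also occur
#'   in a second, independent collection's digest (e.g. variant peptides that
#'   happen to equal unreviewed-section peptides);
#' * `n_coincident_within_base` — peptides produced by the variant-bearing
#'   records that happen to equal peptides already derivable from the
#'   unexpanded records of the same collection (by construction these are not
#'   in `additional`).
#'
#' @param base_index Digest of the unexpanded collection.
#' @param expanded_index Digest of the variant-expanded collection (built with
#'   the same [digestion_config()]).
#' @param other_index Optional digest of another collection.
#' @return A list with `additional` (character vector), `n_additional`,
#'   `n_coincident_other` (`NA` when `other_index` is missing) and
#'   `n_coincident_within_base`.
#' @export
coincident_peptide_report <- function(base_index, expanded_index,
                                      other_index = NULL) {
  stopifnot(inherits(base_index, "digest_index"),
            inherits(expanded_index, "digest_index"))
  check_same_config(base_index, expanded_index)
  base_peps <- index_peptides(base_index)
  exp_peps <- index_peptides(expanded_index)
  additional <- csort(setdiff(exp_peps, base_peps))

  n_other <- NA_integer_
  if (!is.null(other_index)) {
    check_same_config(base_index, other_index)
    n_other <- length(intersect(additional, index_peptides(other_index)))
  }

  from_variant_records <- grepl("|", expanded_index$accession, fixed = TRUE)
  variant_peps <- unique(expanded_index$peptide[from_variant_records])
  n_within <- length(intersect(variant_peps, base_peps))

  list(additional = additional,
       n_additional = length(additional),
       n_coincident_other = n_other,
       n_coincident_within_base = n_within)
}
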