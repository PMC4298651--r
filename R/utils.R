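# Shared internal helpers: residue alphabet, locale-independent ordering,
# percentage formatting for reports.

# 20 standard residues plus selenocysteine (U) and the ambiguity codes
# X (any), B (N/D) and Z (Q/E). Anything else is rejected at ingest.
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
AA_ALLOWED <- c(AA_STANDARD, "U", "X", "B", "Z")
AA_AMBIGUOUS <- c("X", "B", "Z")

#' @noRd
is_ambiguous_peptide <- function(peptide) {
  grepl("[XBZ]", peptide)
}

# Locale-independent (C-order) sort; all user-visible orderings go through
# this so reports are byte-identical across platforms.
csort <- function(x) sort(x, method = "radix")

corder <- function(...) order(..., method = "radix")

# First offending character outside the allowed alphabet, or 0L.
first_bad_residue <- function(sequence) {
  bad <- regexpr(sprintf("[^%s]", paste(AA_ALLOWED, collapse = "")), sequence)
  as.integer(bad)
}

stop_pepspace <- function(fmt, ...) {
  stop(sprintf(fmt, ...), call. = FALSE)
}

# Accession helpers. Variant-expanded accessions are "<source>|<feature_id>";
# isoforms carry a "-<n>" suffix on the entry accession. Both conventions are
# undone here so every derived record still maps to its entry.
strip_feature_suffix <- function(accession) {
  sub("\\|.*$", "", accession)
}

#' Entry accession of an accession string
#'
#' Strips a variant-expansion suffix (`"|VAR_..."`) and an isoform suffix
#' (`"-n"`) so that canonical, isoform and variant-expanded accessions of the
#' same database entry all map to one entry accession.
#'
#' @param accession Character vector of accessions.
#' @return Character vector of entry accessions.
#' @examples
#' entry_accession(c("P12345", "P12345-2", "P12345-2|VAR_000001"))
#' @export
entry_accession <- function(accession) {
  sub("-[0-9]+$", "", strip_feature_suffix(accession))
}

#' @noRd
is_isoform_accession <- function(accession) {
  grepl("-[0-9]+$", strip_feature_suffix(accession))
}

# Table-style percentage: one decimal, except the exact-zero case which is
# printed as plain "0".
format_percent <- function(count, total) {
  if (total == 0 || count == 0) {
    return("0")
  }
  sprintf("%.1f", 100 * count / total)
}

# Compact key=value serialisation of a config list, used in report headers so
# every output file records how it was produced.
config_string <- function(config) {
  flat <- vapply(names(config), function(k) {
    v <- config[[k]]
    paste0(k, "=", paste(format(v, trim = TRUE), collapse = ","))
  }, character(1))
  paste(flat, collapse = " ")
}
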