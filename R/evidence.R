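# Filtering, merging and querying MS-repository peptide-evidence sets.

#' Filter an evidence set by experiment count
#'
#' Keeps peptides identified in at least `min_count` experiments. Applying a
#' minimum-experiment threshold compensates for the heterogeneity of
#' submission-based repositories, where a peptide seen once may be a
#' low-confidence identification; 5 is the conventional threshold for
#' PRIDE-style sources.
#'
#' @param evidence An `evidence_set`.
#' @param min_count Minimum experiment count (>= 1).
#' @return The filtered `evidence_set` (repository label preserved).
#' @examples
#' ev <- evidence_set(c("AAAAAK", "CCCCCK"), c(5L, 4L), "PRIDE")
#' filter_min_experiments(ev, 5)
#' @export
filter_min_experiments <- function(evidence, min_count) {
  stopifnot(inherits(evidence, "evidence_set"), min_count >= 1)
  out <- evidence[evidence$experiment_count >= min_count, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "repository") <- attr(evidence, "repository")
  class(out) <- class(evidence)
  out
}

#' Look up peptides in repository evidence
#'
#' Matching is exact full-length string equality after uppercase
#' normalisation; isoleucine and leucine are not equated and no mass
#' tolerance is applied, so evidence percentages are never inflated by
#' near-matches. Mode `"any"` keeps peptides present in at least one
#' repository, mode `"all"` keeps peptides present concurrently in every
#' repository supplied.
#'
#' @param peptides Character vector of query peptides.
#' @param evidence_sets A single `evidence_set` or a list of them.
#' @param mode `"any"` (default) or `"all"`.
#' @return A list: `matched` (sorted character vector) and `by_repository`
#'   (data frame `repository`, `n_matched`).
#' @examples
#' sets <- list(evidence_set(c("AAAAAK", "CCCCCK"), repository = "PRIDE"),
#'              evidence_set("AAAAAK", repository = "GPMDB"))
#' evidence_lookup(c("AAAAAK", "CCCCCK", "DDDDDK"), sets, mode = "all")
#' @export
evidence_lookup <- function(peptides, evidence_sets, mode = c("any", "all")) {
  mode <- match.arg(mode)
  if (inherits(evidence_sets, "evidence_set")) {
    evidence_sets <- list(evidence_sets)
  }
  stopifnot(all(vapply(evidence_sets, inherits, logical(1), "evidence_set")))
  peptides <- unique(toupper(peptides))

  per_rep <- lapply(evidence_sets, function(ev) peptides %in% ev$peptide)
  hit <- if (!length(per_rep)) {
    logical(length(peptides))
  } else if (mode == "any") {
    Reduce(`|`, per_rep)
  } else {
    Reduce(`&`, per_rep)
  }
  by_repository <- data.frame(
    repository = vapply(evidence_sets, attr, character(1), "repository"),
    n_matched = vapply(per_rep, sum, integer(1)),
    stringsAsFactors = FALSE
  )
  list(matched = csort(peptides[hit]), by_repository = by_repository)
}

#' Length profile of an evidence set
#'
#' Maximum peptide length and a length histogram; used to choose a length
#' cap for unicity analyses restricted to repository-observable peptides
#' (peptides longer than anything a repository holds can never gain
#' evidence).
#'
#' @param evidence An `evidence_set`.
#' @return A list: `max_length` (0 for an empty set) and `histogram` (a
#'   `table` of lengths).
#' @export
length_profile <- function(evidence) {
  stopifnot(inherits(evidence, "evidence_set"))
  if (nrow(evidence) == 0) {
    return(list(max_length = 0L, histogram = table(integer())))
  }
  lens <- nchar(evidence$peptide)
  list(max_length = max(lens), histogram = table(lens))
}

#' Write matched peptides with their repository breakdown
#'
#' @param peptides Query peptides.
#' @param evidence_sets A list of `evidence_set` objects.
#' @param path Output TSV path (columns: peptide, repositories, counts).
#' @param mode Match mode passed to [evidence_lookup()].
#' @return `path`, invisibly.
#' @export
write_evidence_matches <- function(peptides, evidence_sets, path,
                                   mode = "any") {
  if (inherits(evidence_sets, "evidence_set")) {
    evidence_sets <- list(evidence_sets)
  }
  hit <- evidence_lookup(peptides, evidence_sets, mode)$matched
  rows <- lapply(hit, function(p) {
    in_rep <- vapply(evidence_sets, function(ev) p %in% ev$peptide, logical(1))
    counts <- vapply(evidence_sets[in_rep], function(ev) {
      ev$experiment_count[match(p, ev$peptide)]
    }, integer(1))
    data.frame(
      peptide = p,
      repositories = paste(vapply(evidence_sets[in_rep], attr, character(1),
                                  "repository"), collapse = ";"),
      counts = paste(counts, collapse = ";"),
      stringsAsFactors = FALSE
    )
  })
  tab <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(peptide = character(), repositories = character(),
               counts = character(), stringsAsFactors = FALSE)
  }
  write_report_tsv(tab, path)
}
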