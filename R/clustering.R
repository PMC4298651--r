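# 100%-identity redundancy clustering (exact duplicates and subfragments),
# loss-free exact deduplication, and accounting of tryptic peptides lost by
# clustering.

# Containment edges between distinct sequences: (i, j) when sequence i is a
# proper substring of sequence j. Sequences are pre-sorted by length so each
# candidate is only matched against longer ones.
containment_edges <- function(seqs, min_fragment_length = 1L) {
  n <- length(seqs)
  lens <- nchar(seqs)
  ord <- order(lens)
  from <- integer(0)
  to <- integer(0)
  for (k in seq_len(n)) {
    i <- ord[k]
    if (lens[i] < min_fragment_length) next
    longer <- ord[k:n][lens[ord[k:n]] > lens[i]]
    if (!length(longer)) next
    hit <- longer[grepl(seqs[i], seqs[longer], fixed = TRUE)]
    from <- c(from, rep.int(i, length(hit)))
    to <- c(to, hit)
  }
  cbind(from, to)
}

#' Cluster a collection at 100% identity
#'
#' Two records are linked when their sequences are identical or one is a
#' contiguous substring of the other; clusters are the connected components
#' of this relation (so a fragment shared by two otherwise-unrelated longer
#' sequences merges all three). The representative of a cluster is its
#' longest sequence, with ties broken by lexicographically smallest sequence
#' and then smallest accession, making the outcome deterministic. The reduced
#' collection keeps representatives only.
#'
#' @param records A `protein_records` collection.
#' @param min_fragment_length Minimum length for a shorter sequence to be
#'   merged as a subfragment (default 1, i.e. no minimum; exact duplicates
#'   always merge).
#' @return A list with components:
#'   \describe{
#'     \item{clusters}{data frame `representative`, `member`, `relation`
#'       (`representative`, `identical` or `fragment`), one row per record;}
#'     \item{reduced}{the representative-only `protein_records` collection,
#'       in original record order.}
#'   }
#' @examples
#' recs <- protein_records(c("B", "A"), c("MAAAAAKCCCCCCR", "AAAAAKCCCCCCR"))
#' cluster_collection(recs)$clusters
#' @export
cluster_collection <- function(records, min_fragment_length = 1L) {
  stopifnot(inherits(records, "protein_records"))
  n <- nrow(records)
  if (n == 0) {
    return(list(clusters = data.frame(representative = character(),
                                      member = character(),
                                      relation = character(),
                                      stringsAsFactors = FALSE),
                reduced = records))
  }
  useq <- unique(records$sequence)
  seq_id <- match(records$sequence, useq)

  edges <- containment_edges(useq, min_fragment_length)
  g <- igraph::make_empty_graph(n = length(useq), directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  cluster_of <- comp[seq_id]

  # representative: longest sequence, then lexicographically smallest
  # sequence (C order), then smallest accession
  rep_acc <- character(max(comp))
  for (cl in seq_len(max(comp))) {
    members <- which(cluster_of == cl)
    lens <- nchar(records$sequence[members])
    cand <- members[lens == max(lens)]
    if (length(cand) > 1) {
      smallest_seq <- csort(records$sequence[cand])[1]
      cand <- cand[records$sequence[cand] == smallest_seq]
    }
    rep_acc[cl] <- csort(records$accession[cand])[1]
  }

  rep_for_record <- rep_acc[cluster_of]
  rep_seq <- records$sequence[match(rep_for_record, records$accession)]
  relation <- ifelse(records$accession == rep_for_record, "representative",
              ifelse(records$sequence == rep_seq, "identical", "fragment"))
  clusters <- data.frame(representative = rep_for_record,
                         member = records$accession,
                         relation = relation,
                         stringsAsFactors = FALSE)
  ord <- corder(clusters$representative, clusters$member)
  clusters <- clusters[ord, , drop = FALSE]
  rownames(clusters) <- NULL

  reduced <- records[records$accession %in% rep_acc, , drop = FALSE]
  class(reduced) <- class(records)
  list(clusters = clusters, reduced = reduced)
}

#' Tryptic peptides lost by clustering
#'
#' A lost peptide is producible from a clustered-away member sequence but not
#' from any cluster representative: clustering a fragment whose trimming
#' boundaries fall inside tryptic peptides of the fragment removes those
#' peptides from the search space. Each lost peptide is classified per
#' contributing member occurrence: `n_terminal` when it starts at the
#' member's first residue, `c_terminal` when it ends at the member's last
#' residue, `internal` otherwise (one peptide may carry several classes via
#' different members).
#'
#' @param clustering Result of [cluster_collection()] on `records`.
#' @param records The `protein_records` collection that was clustered.
#' @param config A [digestion_config()].
#' @return A data frame `peptide`, `member_accession`, `terminal_class`
#'   (deduplicated, C-collation sorted), with the full lost peptide set as
#'   attribute `lost_peptides`.
#' @export
lost_peptides <- function(clustering, records, config = digestion_config()) {
  stopifnot(inherits(records, "protein_records"))
  full_index <- digest_collection(records, config)
  rep_accs <- unique(clustering$clusters$representative)
  rep_records <- records[records$accession %in% rep_accs, , drop = FALSE]
  class(rep_records) <- class(records)
  rep_index <- digest_collection(rep_records, config)

  lost <- setdiff(index_peptides(full_index), index_peptides(rep_index))
  empty <- data.frame(peptide = character(), member_accession = character(),
                      terminal_class = character(), stringsAsFactors = FALSE)
  attr(empty, "lost_peptides") <- csort(lost)
  if (!length(lost)) return(empty)

  occ <- full_index[full_index$peptide %in% lost, , drop = FALSE]
  member_len <- nchar(records$sequence)[match(occ$accession, records$accession)]
  pep_len <- nchar(occ$peptide)
  terminal_class <- ifelse(occ$start == 0L, "n_terminal",
                    ifelse(occ$start + pep_len == member_len, "c_terminal",
                           "internal"))
  out <- unique(data.frame(peptide = occ$peptide,
                           member_accession = occ$accession,
                           terminal_class = terminal_class,
                           stringsAsFactors = FALSE))
  out <- out[corder(out$peptide, out$member_accession, out$terminal_class), ,
             drop = FALSE]
  rownames(out) <- NULL
  attr(out, "lost_peptides") <- csort(lost)
  out
}

#' Remove exact-duplicate records only
#'
#' Drops records whose sequence is identical (same length and content) to an
#' earlier record's, keeping the first occurrence. Unlike subfragment
#' clustering this is guaranteed to lose no tryptic peptides: the digest of
#' the reduced collection equals the digest of the input as a peptide set.
#'
#' @param records A `protein_records` collection.
#' @return The reduced `protein_records` collection.
#' @export
dedup_exact <- function(records) {
  stopifnot(inherits(records, "protein_records"))
  out <- records[!duplicated(records$sequence), , drop = FALSE]
  class(out) <- class(records)
  out
}
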