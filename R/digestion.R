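# In-silico proteolytic digestion, peptide occurrence indexing and
# monoisotopic mass computation.

#' Digestion configuration
#'
#' Defaults follow the conventional bottom-up comparison setting: full tryptic
#' cleavage, no missed cleavages, and peptides of six or more residues
#' (shorter peptides are rarely detected and carry little sequence-specific
#' information). The initiator methionine is left in place: no Met-trimmed
#' peptide forms are generated.
#'
#' @param rule `"trypsin"` (cleave after K/R except before P, the Keil rule)
#'   or `"trypsin_p"` (cleave after every K/R).
#' @param missed_cleavages Maximum number of retained internal cleavage sites
#'   per peptide (default 0).
#' @param min_length Minimum peptide length kept (default 6).
#' @param max_length Optional maximum peptide length (default `Inf`).
#' @return A list of class `digestion_config`.
#' @examples
#' digestion_config()
#' digestion_config(rule = "trypsin_p", missed_cleavages = 2)
#' @export
digestion_config <- function(rule = c("trypsin", "trypsin_p"),
                             missed_cleavages = 0L,
                             min_length = 6L,
                             max_length = Inf) {
  rule <- match.arg(rule)
  missed_cleavages <- as.integer(missed_cleavages)
  min_length <- as.integer(min_length)
  stopifnot(missed_cleavages >= 0L, min_length >= 1L,
            is.infinite(max_length) || max_length >= min_length)
  structure(list(rule = rule,
                 missed_cleavages = missed_cleavages,
                 min_length = min_length,
                 max_length = max_length),
            class = "digestion_config")
}

#' @export
print.digestion_config <- function(x, ...) {
  cat(sprintf("Digestion: %s, missed cleavages %d, length %d..%s\n",
              x$rule, x$missed_cleavages, x$min_length,
              if (is.infinite(x$max_length)) "Inf" else x$max_length))
  invisible(x)
}

# Internal cleavage sites of a sequence: position i in 1..(n-1) means the
# bond between residues i and i+1 is cleaved. Only literal K/R cleave;
# the ambiguity codes B/Z/X never do.
cleavage_sites <- function(chars, rule) {
  n <- length(chars)
  if (n < 2L) return(integer())
  kr <- chars == "K" | chars == "R"
  if (rule == "trypsin") {
    kr <- kr & c(chars[-1] != "P", TRUE)
  }
  which(kr[-n])
}

#' Digest one sequence
#'
#' Cleaves a sequence with the configured rule and returns the peptides that
#' pass the length filters, together with their 0-based start offsets. With
#' `missed_cleavages = m`, every concatenation of up to `m + 1` consecutive
#' fully-cleaved fragments is emitted. A sequence that does not end in a
#' cleavage site yields a C-terminal peptide with a non-tryptic end, which is
#' retained (the conventional way database digests are counted).
#'
#' @param sequence A single amino-acid sequence.
#' @param config A [digestion_config()].
#' @return A data frame with columns `peptide` and `start` (0-based), ordered
#'   by start offset then peptide end.
#' @examples
#' digest_sequence("AAAAAKCCCCCCR", digestion_config())
#' @export
digest_sequence <- function(sequence, config = digestion_config()) {
  stopifnot(inherits(config, "digestion_config"))
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence)) {
    stop_pepspace("digest_sequence() needs one non-empty sequence")
  }
  sequence <- toupper(sequence)
  bad <- first_bad_residue(sequence)
  if (bad > 0L) {
    stop_pepspace("illegal residue '%s' at position %d",
                  substr(sequence, bad, bad), bad)
  }
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  bounds <- c(0L, cleavage_sites(chars, config$rule), n)
  nf <- length(bounds) - 1L                      # number of fragments
  m <- config$missed_cleavages

  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(nf)) {
    j_max <- min(nf, i + m)
    starts <- c(starts, rep.int(bounds[i] + 1L, j_max - i + 1L))
    ends <- c(ends, bounds[(i + 1L):(j_max + 1L)])
  }
  len <- ends - starts + 1L
  keep <- len >= config$min_length & len <= config$max_length
  starts <- starts[keep]
  ends <- ends[keep]
  if (!length(starts)) {
    return(data.frame(peptide = character(), start = integer(),
                      stringsAsFactors = FALSE))
  }
  ord <- order(starts, ends)
  out <- data.frame(peptide = substring(sequence, starts[ord], ends[ord]),
                    start = starts[ord] - 1L,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Digest a protein collection into a peptide occurrence index
#'
#' Applies [digest_sequence()] to every record and records every occurrence
#' (accession, 0-based offset) of every peptide. Iteration order is
#' deterministic: by accession (C collation), then offset.
#'
#' @param records A `protein_records` collection.
#' @param config A [digestion_config()].
#' @return A data frame of class `digest_index` with columns `peptide`,
#'   `accession`, `start`, carrying the config as attribute `config`.
#' @export
digest_collection <- function(records, config = digestion_config()) {
  stopifnot(inherits(records, "protein_records"))
  if (nrow(records) == 0) {
    stop_pepspace("cannot digest an empty collection")
  }
  ord <- corder(records$accession)
  pieces <- lapply(ord, function(i) {
    d <- digest_sequence(records$sequence[i], config)
    if (nrow(d)) d$accession <- records$accession[i]
    d
  })
  pieces <- pieces[vapply(pieces, nrow, integer(1)) > 0]
  if (length(pieces)) {
    out <- do.call(rbind, pieces)[, c("peptide", "accession", "start")]
  } else {
    out <- data.frame(peptide = character(), accession = character(),
                      start = integer(), stringsAsFactors = FALSE)
  }
  rownames(out) <- NULL
  attr(out, "config") <- config
  class(out) <- c("digest_index", "data.frame")
  out
}

#' @export
print.digest_index <- function(x, ...) {
  cat(sprintf(
    "Digest index: %d occurrences, %d distinct peptides, %d accessions\n",
    nrow(x), length(unique(x$peptide)), length(unique(x$accession))))
  print(attr(x, "config"))
  invisible(x)
}

#' Distinct peptide sequences of a digest index
#'
#' @param index A `digest_index`.
#' @return Character vector of distinct peptides, C-collation sorted.
#' @export
index_peptides <- function(index) {
  stopifnot(inherits(index, "digest_index"))
  csort(unique(index$peptide))
}

# Monoisotopic residue masses in Daltons (Unimod/ExPASy values, 6 decimals);
# U is selenocysteine. Mass of one water molecule added per peptide.
MONO_RESIDUE_MASS <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313,
  U = 150.953636
)
MONO_WATER <- 18.010565

#' Monoisotopic peptide mass
#'
#' Sum of residue monoisotopic masses plus one water (18.010565 Da).
#' Selenocysteine (U) contributes its own residue mass; peptides containing
#' the ambiguity codes X, B or Z have no determinate mass and return `NA`.
#'
#' @param peptide Character vector of peptide sequences.
#' @return Numeric vector of masses in Daltons; `NA` where indeterminate.
#' @examples
#' mono_mass("GGGGGG")   # 360.1393
#' mono_mass("GX")       # NA: ambiguous residue
#' @export
mono_mass <- function(peptide) {
  if (length(peptide) == 0) return(numeric())
  peptide <- toupper(peptide)
  if (any(!nzchar(peptide))) stop_pepspace("empty peptide has no mass")
  vapply(peptide, function(p) {
    chars <- strsplit(p, "")[[1]]
    if (any(chars %in% AA_AMBIGUOUS)) return(NA_real_)
    if (any(!chars %in% names(MONO_RESIDUE_MASS))) {
      stop_pepspace("illegal residue in peptide '%s'", p)
    }
    sum(MONO_RESIDUE_MASS[chars]) + MONO_WATER
  }, numeric(1), USE.NAMES = FALSE)
}

#' Write a peptide table for a digest index
#'
#' One row per distinct peptide: length, monoisotopic mass (empty when
#' indeterminate), number of occurrences, and the semicolon-joined accessions
#' carrying it.
#'
#' @param index A `digest_index`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(index, path) {
  stopifnot(inherits(index, "digest_index"))
  peps <- index_peptides(index)
  occ <- split(index$accession, index$peptide)
  tab <- data.frame(
    peptide = peps,
    length = nchar(peps),
    mono_mass = ifelse(is.na(mono_mass(peps)), "",
                       sprintf("%.4f", mono_mass(peps))),
    n_occurrences = vapply(occ[peps], length, integer(1)),
    accessions = vapply(occ[peps], function(a) {
      paste(csort(unique(a)), collapse = ";")
    }, character(1)),
    stringsAsFactors = FALSE
  )
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
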