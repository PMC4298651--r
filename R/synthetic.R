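# Synthetic proteome generator: collections with isoforms, single-AA
# variants, planted exact-duplicate and subfragment redundancy, and
# repository evidence sampled from the true digest -- together with a
# ground-truth manifest sufficient to predict clustering, expansion and
# unicity outcomes without running the pipeline.

# Background amino-acid frequencies: roughly vertebrate-proteome composition
# with the combined K+R frequency lowered to ~0.083 so that the mean fully
# tryptic peptide length lands in the 10-15 residue range typical of
# proteome digests.
SYNTH_AA_FREQ <- c(
  A = 0.074, R = 0.040, N = 0.044, D = 0.053, C = 0.020, Q = 0.044,
  E = 0.069, G = 0.066, H = 0.026, I = 0.043, L = 0.097, K = 0.040,
  M = 0.022, F = 0.037, P = 0.050, S = 0.083, T = 0.055, W = 0.012,
  Y = 0.027, V = 0.063
)

#' Configuration for the synthetic proteome generator
#'
#' Defaults emulate the structure of an organism-scale UniProtKB-style
#' collection at desk scale: reviewed canonical entries with occasional
#' isoforms (generated by deleting one internal exon-like block, which
#' guarantees isoform-specific junction peptides), a humsavar-like variant
#' table in canonical coordinates (about a third disease-labelled and 0.5%
#' isobaric I/L interchanges, the proportions seen in real human variant
#' tables), planted exact duplicates and subfragments in the unreviewed
#' section, rare X/B/Z ambiguity codes, and per-repository evidence sampled
#' from the true digest with geometric experiment counts plus a small decoy
#' fraction.
#'
#' @param seed Integer RNG seed; all generation is deterministic given it.
#' @param n_entries Number of canonical entries.
#' @param mean_length,sd_length Canonical sequence length distribution
#'   (normal, truncated below at 60 residues).
#' @param isoform_probability Probability that an entry has isoforms.
#' @param max_isoforms Maximum isoforms per entry.
#' @param variant_rate Poisson mean of variants per entry.
#' @param disease_fraction Fraction of variants labelled `disease`.
#' @param il_variant_fraction Fraction of variants that are I/L interchanges.
#' @param duplicate_rate Fraction of entries spawning an exact-duplicate
#'   unreviewed record.
#' @param fragment_rate Fraction of entries spawning a subfragment record
#'   (trimmed at positions chosen independently of cleavage sites, so
#'   trimming usually falls mid-peptide).
#' @param ambiguous_residue_rate Per-residue probability of an X/B/Z code.
#' @param evidence_sampling Named numeric vector: per-repository sampling
#'   fraction of true digest peptides.
#' @param experiment_count_p Geometric success parameter for PRIDE-style
#'   experiment counts (count = 1 + Geom(p); the survival fraction of an
#'   at-least-`k` filter is `(1 - p)^(k - 1)`).
#' @param decoy_evidence_rate Fraction of decoy peptides (not from the
#'   digest) added per repository.
#' @param digestion [digestion_config()] defining the true digest evidence is
#'   sampled from.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_entries = 300L,
                             mean_length = 450,
                             sd_length = 150,
                             isoform_probability = 0.3,
                             max_isoforms = 3L,
                             variant_rate = 2,
                             disease_fraction = 0.34,
                             il_variant_fraction = 0.005,
                             duplicate_rate = 0.05,
                             fragment_rate = 0.10,
                             ambiguous_residue_rate = 0.001,
                             evidence_sampling = c(PRIDE = 0.25,
                                                   PeptideAtlas = 0.20,
                                                   GPMDB = 0.20),
                             experiment_count_p = 0.3,
                             decoy_evidence_rate = 0.02,
                             digestion = digestion_config()) {
  cfg <- list(seed = as.integer(seed), n_entries = as.integer(n_entries),
              mean_length = mean_length, sd_length = sd_length,
              isoform_probability = isoform_probability,
              max_isoforms = as.integer(max_isoforms),
              variant_rate = variant_rate,
              disease_fraction = disease_fraction,
              il_variant_fraction = il_variant_fraction,
              duplicate_rate = duplicate_rate,
              fragment_rate = fragment_rate,
              ambiguous_residue_rate = ambiguous_residue_rate,
              evidence_sampling = evidence_sampling,
              experiment_count_p = experiment_count_p,
              decoy_evidence_rate = decoy_evidence_rate,
              digestion = digestion)
  rates <- c(cfg$isoform_probability, cfg$disease_fraction,
             cfg$il_variant_fraction, cfg$duplicate_rate, cfg$fragment_rate,
             cfg$ambiguous_residue_rate, cfg$evidence_sampling,
             cfg$experiment_count_p, cfg$decoy_evidence_rate)
  if (any(rates < 0 | rates > 1)) {
    stop_pepspace("all synthetic rates and fractions must lie in [0, 1]")
  }
  if (cfg$n_entries < 1L) stop_pepspace("n_entries must be >= 1")
  if (cfg$variant_rate < 0) stop_pepspace("variant_rate must be >= 0")
  if (cfg$mean_length < 60) stop_pepspace("mean_length must be >= 60")
  if (is.null(names(cfg$evidence_sampling)) ||
      any(!nzchar(names(cfg$evidence_sampling)))) {
    stop_pepspace("evidence_sampling must be a named vector of repositories")
  }
  if (cfg$experiment_count_p <= 0) {
    stop_pepspace("experiment_count_p must be in (0, 1]")
  }
  class(cfg) <- "synthetic_config"
  cfg
}

random_sequence <- function(length) {
  paste(c("M", sample(names(SYNTH_AA_FREQ), length - 1L, replace = TRUE,
                      prob = SYNTH_AA_FREQ)), collapse = "")
}

inject_ambiguous <- function(sequence, rate) {
  if (rate <= 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit)) {
    chars[hit] <- sample(AA_AMBIGUOUS, length(hit), replace = TRUE)
    sequence <- paste(chars, collapse = "")
  }
  sequence
}

# Isoform by deletion of one internal block (10-30% of the sequence),
# emulating the loss of an exon: the deletion junction creates
# isoform-specific peptides.
make_isoform <- function(sequence) {
  n <- nchar(sequence)
  block <- max(5L, round(n * runif(1, 0.10, 0.30)))
  start <- sample(seq(2L, n - block), 1L)
  paste0(substr(sequence, 1L, start - 1L),
         substr(sequence, start + block, n))
}

#' Generate a synthetic proteome with ground truth
#'
#' Produces a protein collection, a variant table, per-repository evidence
#' sets and a ground-truth manifest. Everything is deterministic under the
#' config seed. Canonical and isoform records are `reviewed`; planted
#' duplicate and fragment records are `unreviewed` (mimicking redundancy
#' contributed by an unreviewed section).
#'
#' The manifest predicts, without running the pipeline: which records each
#' planted duplicate/fragment clusters with (`cluster_source`), the peptides
#' lost by clustering them away (`predicted_lost`), per-variant application
#' targets and skip reasons (`variant_applications`), the sequence-unique
#' peptides per accession (`unique_peptides`), and the true per-repository
#' evidence membership including decoys (`evidence`).
#'
#' @param config A [synthetic_config()].
#' @return A list of class `synthetic_proteome`: `records`
#'   (`protein_records`), `variants` (`variant_records`), `evidence` (named
#'   list of `evidence_set`), `manifest` (list), `config`.
#' @examples
#' sim <- generate_proteome(synthetic_config(seed = 7, n_entries = 20))
#' sim$records
#' @export
generate_proteome <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "synthetic_config"))
  set.seed(config$seed)

  n <- config$n_entries
  entry_acc <- sprintf("P%05d", seq_len(n))
  lens <- pmax(60L, round(rnorm(n, config$mean_length, config$sd_length)))
  canonical <- vapply(lens, random_sequence, character(1))
  canonical <- vapply(canonical, inject_ambiguous, character(1),
                      rate = config$ambiguous_residue_rate, USE.NAMES = FALSE)

  acc <- entry_acc
  seqs <- canonical
  section <- rep("reviewed", n)

  # isoforms
  has_iso <- runif(n) < config$isoform_probability
  iso_acc <- character(0)
  iso_seq <- character(0)
  for (i in which(has_iso)) {
    k <- sample.int(config$max_isoforms, 1L)
    for (j in seq_len(k)) {
      iso_acc <- c(iso_acc, sprintf("%s-%d", entry_acc[i], j + 1L))
      iso_seq <- c(iso_seq, make_isoform(canonical[i]))
    }
  }
  acc <- c(acc, iso_acc)
  seqs <- c(seqs, iso_seq)
  section <- c(section, rep("reviewed", length(iso_acc)))

  # planted exact duplicates and subfragments (unreviewed section)
  dup_src <- entry_acc[runif(n) < config$duplicate_rate]
  dup_acc <- sub("^P", "TD", dup_src)
  dup_seq <- canonical[match(dup_src, entry_acc)]

  frag_src <- entry_acc[runif(n) < config$fragment_rate]
  frag_acc <- sub("^P", "TF", frag_src)
  frag_seq <- vapply(match(frag_src, entry_acc), function(i) {
    L <- nchar(canonical[i])
    start <- sample(seq(2L, max(2L, L %/% 4L)), 1L)
    end <- sample(seq(min(L - 1L, 3L * L %/% 4L), L - 1L), 1L)
    substr(canonical[i], start, end)
  }, character(1))

  acc <- c(acc, dup_acc, frag_acc)
  seqs <- c(seqs, dup_seq, frag_seq)
  section <- c(section, rep("unreviewed", length(dup_acc) + length(frag_acc)))

  records <- protein_records(acc, seqs, section = section,
                             description = "synthetic")

  # variants (canonical coordinates, reference residue respected)
  v_entry <- character(0); v_pos <- integer(0)
  v_ref <- character(0); v_alt <- character(0)
  for (i in seq_len(n)) {
    nv <- rpois(1L, config$variant_rate)
    if (nv == 0L) next
    chars <- strsplit(canonical[i], "")[[1]]
    standard_pos <- which(chars %in% AA_STANDARD)
    for (j in seq_len(nv)) {
      il <- runif(1) < config$il_variant_fraction
      il_pos <- standard_pos[chars[standard_pos] %in% c("I", "L")]
      if (il && length(il_pos)) {
        p <- il_pos[sample.int(length(il_pos), 1L)]
        ref <- chars[p]
        alt <- setdiff(c("I", "L"), ref)
      } else {
        p <- standard_pos[sample.int(length(standard_pos), 1L)]
        ref <- chars[p]
        alt <- sample(setdiff(AA_STANDARD, ref), 1L)
      }
      v_entry <- c(v_entry, entry_acc[i]); v_pos <- c(v_pos, p)
      v_ref <- c(v_ref, ref); v_alt <- c(v_alt, alt)
    }
  }
  nv_total <- length(v_entry)
  v_cat <- ifelse(runif(nv_total) < config$disease_fraction,
                  "disease", "polymorphism")
  variants <- variant_records(
    entry_accession = v_entry,
    feature_id = sprintf("VAR_%06d", seq_len(nv_total)),
    position = v_pos, ref_aa = v_ref, alt_aa = v_alt, category = v_cat,
    disease_name = ifelse(v_cat == "disease",
                          sprintf("Synthetic disorder %d", seq_len(nv_total)),
                          "")
  )

  # true digest and sampled repository evidence
  index <- digest_collection(records, config$digestion)
  true_peps <- index_peptides(index)
  evidence <- list()
  ev_manifest <- list()
  for (repo in names(config$evidence_sampling)) {
    frac <- config$evidence_sampling[[repo]]
    pick <- true_peps[runif(length(true_peps)) < frac]
    counts <- if (repo == "PRIDE") {
      1L + rgeom(length(pick), config$experiment_count_p)
    } else {
      rep(1L, length(pick))
    }
    n_decoy <- round(config$decoy_evidence_rate * length(pick))
    decoys <- character(0)
    while (length(decoys) < n_decoy) {
      cand <- vapply(sample(6:24, n_decoy, replace = TRUE), function(L) {
        paste(c(sample(AA_STANDARD, L - 1L, replace = TRUE),
                sample(c("K", "R"), 1L)), collapse = "")
      }, character(1))
      decoys <- unique(c(decoys, setdiff(cand, true_peps)))
    }
    decoys <- decoys[seq_len(n_decoy)]
    evidence[[repo]] <- evidence_set(c(pick, decoys),
                                     c(counts, rep(1L, n_decoy)),
                                     repository = repo)
    ev_manifest[[repo]] <- data.frame(
      peptide = c(pick, decoys),
      experiment_count = c(counts, rep(1L, n_decoy)),
      decoy = c(rep(FALSE, length(pick)), rep(TRUE, n_decoy)),
      stringsAsFactors = FALSE
    )
  }

  planted_group <- c(entry_acc, entry_accession(iso_acc), dup_src, frag_src)
  cluster_source <- manifest_cluster_source(records, planted_group)
  manifest <- list(
    entry_accessions = entry_acc,
    isoform_accessions = iso_acc,
    duplicate_pairs = data.frame(source = dup_src, accession = dup_acc,
                                 stringsAsFactors = FALSE),
    fragment_pairs = data.frame(source = frag_src, accession = frag_acc,
                                stringsAsFactors = FALSE),
    cluster_source = cluster_source,
    predicted_lost = manifest_predicted_lost(records, cluster_source,
                                             config$digestion),
    variant_applications = manifest_variant_applications(records, variants),
    unique_peptides = manifest_unique_peptides(index),
    evidence = ev_manifest,
    n_true_digest_peptides = length(true_peps)
  )

  structure(list(records = records, variants = variants,
                 evidence = evidence, manifest = manifest, config = config),
            class = "synthetic_proteome")
}

#' @export
print.synthetic_proteome <- function(x, ...) {
  cat(sprintf(paste0("Synthetic proteome (seed %d): %d records, ",
                     "%d variants, %d repositories\n"),
              x$config$seed, nrow(x$records), nrow(x$variants),
              length(x$evidence)))
  invisible(x)
}

# Predicted cluster representative for every record. Records of one entry
# (canonical, isoforms, planted duplicate and fragment) are linked when
# equal or substring-contained -- notably, a planted fragment taken from a
# region an isoform retains links that isoform into the canonical's cluster.
# Cross-entry sequence collisions are assumed absent, which random sequences
# of these lengths guarantee in practice.
manifest_cluster_source <- function(records, planted_group) {
  rep_for <- records$accession
  for (ent in unique(planted_group)) {
    idx <- which(planted_group == ent)
    if (length(idx) < 2L) next
    seqs <- records$sequence[idx]
    k <- length(idx)
    parent <- seq_len(k)
    find <- function(i) {
      while (parent[i] != i) i <- parent[i]
      i
    }
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        linked <- seqs[i] == seqs[j] ||
          grepl(seqs[i], seqs[j], fixed = TRUE) ||
          grepl(seqs[j], seqs[i], fixed = TRUE)
        if (linked) parent[find(j)] <- find(i)
      }
    }
    roots <- vapply(seq_len(k), find, integer(1))
    for (r in unique(roots)) {
      members <- idx[roots == r]
      lens <- nchar(records$sequence[members])
      cand <- members[lens == max(lens)]
      if (length(cand) > 1) {
        smallest <- csort(records$sequence[cand])[1]
        cand <- cand[records$sequence[cand] == smallest]
      }
      rep_for[members] <- csort(records$accession[cand])[1]
    }
  }
  data.frame(accession = records$accession, cluster_source = rep_for,
             stringsAsFactors = FALSE)
}

# Peptides producible from the clustered-away records but from no surviving
# representative.
manifest_predicted_lost <- function(records, cluster_source, dig_config) {
  away_acc <- cluster_source$accession[
    cluster_source$accession != cluster_source$cluster_source]
  if (!length(away_acc)) return(character(0))
  keep <- records[!records$accession %in% away_acc, , drop = FALSE]
  class(keep) <- class(records)
  gone <- records[records$accession %in% away_acc, , drop = FALSE]
  class(gone) <- class(records)
  csort(setdiff(index_peptides(digest_collection(gone, dig_config)),
                index_peptides(digest_collection(keep, dig_config))))
}

# Verbatim reference-residue check per (variant, entry record): this is the
# generator's own statement of which applications must succeed.
manifest_variant_applications <- function(records, variants) {
  rows <- list()
  for (v in seq_len(nrow(variants))) {
    targets <- which(records$entry_accession == variants$entry_accession[v])
    for (i in targets) {
      pos <- variants$position[v]
      ok <- pos <= nchar(records$sequence[i]) &&
        substr(records$sequence[i], pos, pos) == variants$ref_aa[v]
      rows[[length(rows) + 1L]] <- data.frame(
        feature_id = variants$feature_id[v],
        accession = records$accession[i],
        applied = ok,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(data.frame(feature_id = character(), accession = character(),
                      applied = logical(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Sequence-unique peptides by direct occurrence counting on the index.
manifest_unique_peptides <- function(index) {
  occ <- unique(data.frame(peptide = index$peptide,
                           accession = index$accession,
                           stringsAsFactors = FALSE))
  tab <- table(occ$peptide)
  single <- names(tab)[tab == 1L]
  out <- occ[occ$peptide %in% single, , drop = FALSE]
  out$ambiguous <- is_ambiguous_peptide(out$peptide)
  out <- out[corder(out$peptide), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the generator's recovery harness
#'
#' Generates a synthetic proteome and runs the full pipeline on it, checking
#' that each stage recovers the manifest's ground truth: variant application
#' outcomes, planted cluster membership and representatives, predicted
#' clustering peptide losses, sequence-unique peptides, and per-repository
#' evidence fractions (within the binomial 99% interval of the configured
#' sampling fraction).
#'
#' @param config A [synthetic_config()].
#' @return A data frame with columns `check`, `pass`, `detail`.
#' @export
recovery_suite <- function(config = synthetic_config()) {
  sim <- generate_proteome(config)
  checks <- list()
  add <- function(check, pass, detail = "") {
    checks[[length(checks) + 1L]] <<- data.frame(
      check = check, pass = pass, detail = detail, stringsAsFactors = FALSE)
  }

  # variant expansion
  exp_all <- expand_variants(sim$records, sim$variants, mode = "all")
  got <- exp_all$log[, c("feature_id", "target_accession", "status")]
  want <- sim$manifest$variant_applications
  got_key <- paste(got$feature_id, got$target_accession,
                   got$status == "applied")
  want_key <- paste(want$feature_id, want$accession, want$applied)
  add("variant_applications",
      setequal(got_key, want_key) && nrow(got) == nrow(want),
      sprintf("%d applications checked", nrow(want)))

  # clustering membership and losses
  cl <- cluster_collection(sim$records)
  src <- sim$manifest$cluster_source
  rep_of <- cl$clusters$representative[match(src$accession,
                                             cl$clusters$member)]
  expected_rep <- src$cluster_source
  add("cluster_membership", identical(rep_of, expected_rep),
      sprintf("%d records", nrow(src)))

  lost <- lost_peptides(cl, sim$records, sim$config$digestion)
  add("predicted_lost_peptides",
      setequal(attr(lost, "lost_peptides"), sim$manifest$predicted_lost),
      sprintf("%d lost peptides", length(sim$manifest$predicted_lost)))

  # unicity
  index <- digest_collection(sim$records, sim$config$digestion)
  uni <- unicity_report(index, sim$records, exclude_ambiguous = TRUE)
  want_u <- sim$manifest$unique_peptides
  want_u <- want_u[!want_u$ambiguous, , drop = FALSE]
  add("unique_peptides",
      setequal(paste(uni$unique_peptide_table$peptide,
                     uni$unique_peptide_table$accession),
               paste(want_u$peptide, want_u$accession)),
      sprintf("%d unique peptides", nrow(want_u)))

  # evidence sampling fractions
  n_true <- sim$manifest$n_true_digest_peptides
  true_peps <- index_peptides(index)
  for (repo in names(sim$evidence)) {
    frac <- sim$config$evidence_sampling[[repo]]
    k <- sum(true_peps %in% sim$evidence[[repo]]$peptide)
    ci <- stats::qbinom(c(0.005, 0.995), n_true, frac)
    add(paste0("evidence_fraction_", repo),
        k >= ci[1] && k <= ci[2],
        sprintf("observed %d/%d, 99%% CI [%d, %d]", k, n_true, ci[1], ci[2]))
  }

  do.call(rbind, checks)
}
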