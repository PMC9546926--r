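#' Default giant-virus marker gene set
#'
#' The seven phylogenetic marker genes used to place candidate scaffolds:
#' family B DNA polymerase, the two largest RNA polymerase subunits, the viral
#' late transcription factor 3 (VLTF3), the major capsid protein, the A32
#' packaging ATPase and the D5 primase/helicase. The transcription elongation
#' factor TFIIS is deliberately not included (its phylogeny conflicts with
#' well-established clades).
#'
#' @return Character vector of marker ids.
#' @export
default_marker_set <- function() {
  c("polB", "rnapL", "rnapS", "vltf3", "mcp", "a32", "d5")
}

#' Rank marker-gene hits within each scaffold
#'
#' Groups hits by (scaffold, marker) and assigns copy ranks by ascending
#' E-value: rank 1 is the scaffold's best copy of that marker, rank 2 its
#' second-best, and so on. Ties are broken by descending bit score, then by
#' `orf_id`, so ranking is invariant to input row order. Duplicate
#' (orf, marker) rows are deduplicated to the best row with a warning.
#'
#' @param hits Data frame: `scaffold_id`, `marker_id`, `orf_id`, `evalue`,
#'   optional `bitscore`.
#' @param initial_cutoff Inclusive E-value cutoff applied before ranking
#'   (default 1e-5, the initial marker-search threshold).
#' @return The filtered hit table with a `rank` column, ranks contiguous
#'   from 1 within each (scaffold, marker).
#' @export
rank_marker_hits <- function(hits, initial_cutoff = 1e-5) {
  assert_cols(hits, c("scaffold_id", "marker_id", "orf_id", "evalue"), "hits")
  if (is.null(hits$bitscore)) hits$bitscore <- 0
  if (any(hits$evalue <= 0)) stop_gv("E-values must be positive")
  hits <- hits[hits$evalue <= initial_cutoff, , drop = FALSE]
  dup <- duplicated(hits[, c("orf_id", "marker_id")]) |
    duplicated(hits[, c("orf_id", "marker_id")], fromLast = TRUE)
  if (any(dup)) {
    warn_gv("duplicate (orf, marker) rows deduplicated to best E-value")
    hits <- hits[order(hits$evalue, -hits$bitscore), , drop = FALSE]
    hits <- hits[!duplicated(hits[, c("orf_id", "marker_id")]), , drop = FALSE]
  }
  o <- order(hits$scaffold_id, hits$marker_id, hits$evalue, -hits$bitscore,
             hits$orf_id, method = "radix")
  hits <- hits[o, , drop = FALSE]
  grp <- paste(hits$scaffold_id, hits$marker_id, sep = "\r")
  hits$rank <- stats::ave(seq_len(nrow(hits)), grp, FUN = seq_along)
  rownames(hits) <- NULL
  hits
}

# Nearest-rank first quartile: order statistic at index ceiling(n / 4).
nearest_rank_q1 <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 4)]
}

#' Per-marker stringent threshold from second-best copies
#'
#' Derives the paralog-suppressing E-value cutoff for each marker: the
#' E-values of all rank-2 hits (scaffolds carrying multiple copies of the
#' marker) are sorted in ascending order and the threshold is their first
#' quartile. The default quartile convention is nearest-rank (the order
#' statistic at index `ceiling(n/4)`), which is scale-free across the many
#' orders of magnitude E-values span; `quartile = "log-interp"` instead
#' interpolates the quartile of log10(E). Markers with no multi-copy
#' scaffolds fall back to the initial cutoff with a warning (no paralog
#' evidence implies no extra stringency).
#'
#' @param ranked Output of [rank_marker_hits()].
#' @param markers Marker ids to compute thresholds for (default: all present
#'   plus [default_marker_set()] entries found in the data).
#' @param initial_cutoff Fallback and upper bound for thresholds.
#' @param quartile `"nearest"` (default) or `"log-interp"`.
#' @return Data frame: `marker_id`, `threshold`, `n_second_matches`.
#' @export
stringent_thresholds <- function(ranked, markers = NULL,
                                 initial_cutoff = 1e-5,
                                 quartile = c("nearest", "log-interp")) {
  quartile <- match.arg(quartile)
  assert_cols(ranked, c("scaffold_id", "marker_id", "evalue", "rank"),
              "ranked hits")
  if (is.null(markers)) markers <- sort(unique(ranked$marker_id))
  rows <- lapply(markers, function(mk) {
    e2 <- ranked$evalue[ranked$marker_id == mk & ranked$rank == 2L]
    if (length(e2) == 0L) {
      warn_gv("marker %s has no multi-copy scaffolds; stringent threshold %s",
              mk, format(initial_cutoff))
      thr <- initial_cutoff
    } else if (quartile == "nearest") {
      thr <- nearest_rank_q1(e2)
    } else {
      thr <- 10^stats::quantile(log10(e2), 0.25, type = 7, names = FALSE)
    }
    data.frame(marker_id = mk, threshold = min(thr, initial_cutoff),
               n_second_matches = length(e2), stringsAsFactors = FALSE)
  })
  rbind_rows(rows) %||%
    data.frame(marker_id = character(), threshold = numeric(),
               n_second_matches = integer(), stringsAsFactors = FALSE)
}

#' Select one marker hit per scaffold under the stringent thresholds
#'
#' Keeps, for each (scaffold, marker), only the best copy (rank 1) and only
#' when its E-value is strictly better (smaller) than the marker's stringent
#' threshold.
#'
#' @param ranked Output of [rank_marker_hits()].
#' @param thresholds Output of [stringent_thresholds()].
#' @return Data frame: `scaffold_id`, `marker_id`, `orf_id`, `evalue`.
#' @export
select_marker_hits <- function(ranked, thresholds) {
  assert_cols(thresholds, c("marker_id", "threshold"), "thresholds")
  thr <- stats::setNames(thresholds$threshold, thresholds$marker_id)
  unknown <- setdiff(unique(ranked$marker_id), names(thr))
  if (length(unknown) > 0L) {
    stop_gv("no stringent threshold for marker(s): %s",
            paste(unknown, collapse = ", "))
  }
  keep <- ranked$rank == 1L & ranked$evalue < unname(thr[ranked$marker_id])
  out <- ranked[keep, c("scaffold_id", "marker_id", "orf_id", "evalue")]
  rownames(out) <- NULL
  out
}

#' Partition scaffolds by marker-gene count
#'
#' Splits marker-bearing scaffolds into the `high_confidence` set (at least
#' `min_high` distinct markers, used for the scaffold phylogeny to avoid
#' placing split genomes) and the `extended` set (at least one marker, used
#' for the broad taxonomic census). `high_confidence` is always a subset of
#' `extended`. The per-scaffold presence/absence matrix backing the partition
#' is also returned.
#'
#' @param selected Output of [select_marker_hits()].
#' @param markers Marker universe for the presence/absence matrix columns.
#' @param min_high Minimum distinct markers for the high-confidence set.
#' @return List with `high_confidence`, `extended` (character vectors of
#'   scaffold ids) and `presence` (logical matrix, scaffolds x markers).
#' @export
partition_by_marker_count <- function(selected,
                                      markers = default_marker_set(),
                                      min_high = 3L) {
  assert_cols(selected, c("scaffold_id", "marker_id"), "selected hits")
  markers <- union(markers, unique(selected$marker_id))
  scaffolds <- sort(unique(selected$scaffold_id))
  presence <- matrix(FALSE, length(scaffolds), length(markers),
                     dimnames = list(scaffolds, markers))
  if (nrow(selected) > 0L) {
    presence[cbind(selected$scaffold_id, selected$marker_id)] <- TRUE
  }
  counts <- rowSums(presence)
  list(
    high_confidence = scaffolds[counts >= min_high],
    extended = scaffolds[counts >= 1L],
    presence = presence
  )
}

#' Retain low-copy profiles
#'
#' Filters a table of per-profile mean copy numbers (copies per reference
#' genome) to the profiles suitable for single-copy-style completeness and
#' contamination checks: mean copy number of at most `max_mean` (default 1.1).
#'
#' @param stats Data frame: `profile_id`, `mean_copies_per_genome`.
#' @param max_mean Inclusive upper bound on the mean copy number.
#' @return The retained subset of `stats`.
#' @export
select_low_copy_profiles <- function(stats, max_mean = 1.1) {
  assert_cols(stats, c("profile_id", "mean_copies_per_genome"), "stats")
  if (nrow(stats) == 0L) stop_gv("profile copy stats are empty")
  if (any(stats$mean_copies_per_genome < 0)) {
    stop_gv("mean copy numbers must be non-negative")
  }
  out <- stats[stats$mean_copies_per_genome <= max_mean, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export per-marker protein FASTA files
#'
#' Writes one protein FASTA per marker from the selected hits, ready for
#' external alignment and tree inference. Headers are
#' `<scaffold_id>|<marker_id>|<orf_id>`; records are ordered by scaffold id,
#' so output is stable across runs. An empty selection writes nothing and
#' says so.
#'
#' @param selected Output of [select_marker_hits()].
#' @param proteins An `AAStringSet` (or named character vector) keyed by
#'   `orf_id`; every selected ORF must be present.
#' @param dir Output directory (created if missing).
#' @return Invisibly, a named character vector of written paths (possibly
#'   empty).
#' @export
export_marker_sets <- function(selected, proteins, dir) {
  assert_cols(selected, c("scaffold_id", "marker_id", "orf_id"), "selected")
  if (nrow(selected) == 0L) {
    message("no selected marker hits; nothing to export")
    return(invisible(character(0)))
  }
  if (is.character(proteins)) proteins <- Biostrings::AAStringSet(proteins)
  missing <- setdiff(selected$orf_id, names(proteins))
  if (length(missing) > 0L) {
    stop_gv("no protein sequence for orf_id(s): %s",
            paste(utils::head(missing, 10L), collapse = ", "))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (mk in sort(unique(selected$marker_id))) {
    rows <- selected[selected$marker_id == mk, , drop = FALSE]
    rows <- rows[order(rows$scaffold_id), , drop = FALSE]
    seqs <- proteins[rows$orf_id]
    names(seqs) <- sprintf("%s|%s|%s", rows$scaffold_id, mk, rows$orf_id)
    p <- file.path(dir, sprintf("%s.faa", mk))
    Biostrings::writeXStringSet(seqs, p)
    paths[mk] <- p
  }
  invisible(paths)
}
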