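#' Read a 12-column alignment table for chimera assessment
#'
#' Reads BLASTN-style tabular output (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) into the columns the
#' chimera workflow uses. Query intervals are 1-based inclusive.
#'
#' @param path Path to the tabular file.
#' @return Data frame: `query_id`, `reference_genome_id`, `qstart`, `qend`,
#'   `percent_identity`, `score`, `evalue`.
#' @export
read_alignment_tab <- function(path) {
  raw <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(raw) < 12L) {
    stop_gv("expected 12 tab-separated columns, found %d", ncol(raw))
  }
  data.frame(
    query_id = as.character(raw[[1L]]),
    reference_genome_id = as.character(raw[[2L]]),
    qstart = as.integer(raw[[7L]]),
    qend = as.integer(raw[[8L]]),
    percent_identity = as.numeric(raw[[3L]]),
    score = as.numeric(raw[[12L]]),
    evalue = as.numeric(raw[[11L]]),
    stringsAsFactors = FALSE
  )
}

# Documented processing order: descending score, then ascending evalue,
# ascending start, reference id lexicographic.
order_matches <- function(m) {
  order(-m$score, m$evalue, m$qstart,
        as.character(m$reference_genome_id), method = "radix")
}

#' Trim overlapping reference matches on one query
#'
#' Implements the match-trimming rule used to assess assembly chimerism
#' against reference genomes: matches below `min_identity` are discarded;
#' the rest are processed from best to worst (descending score), each match
#' has its overlap with all previously retained segments removed, and each
#' resulting fragment is kept iff it is at least `min_len` nucleotides.
#' Retained segments on a query are therefore mutually non-overlapping.
#'
#' @param matches Data frame of alignments for a single query: columns
#'   `query_id`, `reference_genome_id`, `qstart`, `qend` (1-based inclusive),
#'   `percent_identity`, `score`, and optionally `evalue`.
#' @param min_identity Minimum percent identity retained (default 99.99).
#' @param min_len Minimum fragment length retained in nucleotides
#'   (default 500).
#' @return Data frame of retained segments: `query_id`,
#'   `reference_genome_id`, `qstart`, `qend`, `length`.
#' @examples
#' m <- data.frame(query_id = "q", reference_genome_id = c("g1", "g2"),
#'                 qstart = c(1, 1000), qend = c(1500, 2000),
#'                 percent_identity = 100, score = c(3000, 1800))
#' trim_overlaps(m)
#' @export
trim_overlaps <- function(matches, min_identity = 99.99, min_len = 500L) {
  assert_cols(matches, c("query_id", "reference_genome_id", "qstart", "qend",
                         "percent_identity", "score"), "matches")
  if (length(unique(matches$query_id)) > 1L) {
    stop_gv("trim_overlaps expects matches for a single query")
  }
  if (any(matches$qstart > matches$qend)) stop_gv("inverted query interval")
  if (is.null(matches$evalue)) matches$evalue <- NA_real_
  m <- matches[matches$percent_identity >= min_identity, , drop = FALSE]
  empty <- data.frame(query_id = character(), reference_genome_id = character(),
                      qstart = integer(), qend = integer(), length = integer(),
                      stringsAsFactors = FALSE)
  if (nrow(m) == 0L) return(empty)
  m <- m[order_matches(m), , drop = FALSE]
  retained <- IRanges::IRanges()
  out <- list()
  for (i in seq_len(nrow(m))) {
    frag <- IRanges::setdiff(IRanges::IRanges(m$qstart[i], m$qend[i]), retained)
    frag <- frag[IRanges::width(frag) >= min_len]
    if (length(frag) > 0L) {
      retained <- IRanges::union(retained, frag)
      out[[length(out) + 1L]] <- data.frame(
        query_id = m$query_id[i],
        reference_genome_id = m$reference_genome_id[i],
        qstart = IRanges::start(frag),
        qend = IRanges::end(frag),
        length = IRanges::width(frag),
        stringsAsFactors = FALSE
      )
    }
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  res <- res[order(res$qstart), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Chimera verdict for one query's retained segments
#'
#' A query is `chimeric` when its retained segments name at least two
#' distinct reference genomes, `clean` when they all name one, and
#' `unassessed` when no segment was retained (no alignable evidence either
#' way; unassessed queries are excluded from proportion denominators).
#'
#' @param segments Retained segments for one query (see [trim_overlaps()]).
#' @return One of `"clean"`, `"chimeric"`, `"unassessed"`.
#' @export
label_chimera <- function(segments) {
  if (is.null(segments) || nrow(segments) == 0L) return("unassessed")
  n_genomes <- length(unique(segments$reference_genome_id))
  if (n_genomes >= 2L) "chimeric" else "clean"
}

#' Per-query chimera verdicts from an alignment table
#'
#' Runs [trim_overlaps()] and [label_chimera()] for every query in an
#' alignment table. Queries listed in `all_queries` but absent from the table
#' are reported as `unassessed`.
#'
#' @param matches Alignment table covering any number of queries.
#' @param all_queries Optional character vector of query ids to report.
#' @inheritParams trim_overlaps
#' @return List with `verdicts` (data frame `query_id`, `verdict`,
#'   `n_genomes`, `retained_length`) and `segments` (row-bound retained
#'   segments).
#' @export
chimera_verdicts <- function(matches, all_queries = NULL,
                             min_identity = 99.99, min_len = 500L) {
  split_m <- split(matches, matches$query_id)
  segs <- lapply(split_m, trim_overlaps, min_identity = min_identity,
                 min_len = min_len)
  ids <- unique(c(names(segs), all_queries))
  verdicts <- data.frame(
    query_id = ids,
    verdict = vapply(ids, function(q) label_chimera(segs[[q]]), character(1)),
    n_genomes = vapply(ids, function(q) {
      s <- segs[[q]]
      if (is.null(s)) 0L else length(unique(s$reference_genome_id))
    }, integer(1)),
    retained_length = vapply(ids, function(q) {
      s <- segs[[q]]
      if (is.null(s)) 0L else as.integer(sum(s$length))
    }, integer(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  segments <- rbind_rows(segs)
  list(verdicts = verdicts, segments = segments)
}

#' Chimera proportions at contig and bin level
#'
#' Summarises per-query verdicts into chimera proportions. At contig level the
#' denominator is the number of assessed queries (verdict `clean` or
#' `chimeric`); the proportion over all queries including unassessed ones is
#' also reported. With a bin membership table, a bin is chimeric when the
#' retained segments of its contigs jointly span at least two reference
#' genomes; bins with a single contig are excluded from the bin-level
#' denominator, and bins whose contigs are all unassessed are unassessed.
#'
#' @param verdicts Output of [chimera_verdicts()] (the full list, so bin-level
#'   genome spans can be computed), or its `verdicts` data frame for
#'   contig-level reporting only.
#' @param bin_membership Optional data frame `contig_id`, `bin_id`; a contig
#'   assigned to more than one bin is an error.
#' @param level Name used for the per-item level in the report
#'   (`"contig"` or `"scaffold"`).
#' @return An object of class `gv_chimera_report`: list of per-level
#'   summaries, each with `n_assessed`, `n_chimeric`, `proportion`,
#'   `proportion_all` (denominator including unassessed), and per-item
#'   verdicts.
#' @export
chimera_report <- function(verdicts, bin_membership = NULL,
                           level = c("contig", "scaffold")) {
  level <- match.arg(level)
  if (is.data.frame(verdicts)) {
    vdf <- verdicts
    segments <- NULL
  } else {
    vdf <- verdicts$verdicts
    segments <- verdicts$segments
  }
  assert_cols(vdf, c("query_id", "verdict"), "verdicts")
  assessed <- vdf$verdict %in% c("clean", "chimeric")
  n_chim <- sum(vdf$verdict == "chimeric")
  out <- list()
  out[[level]] <- list(
    n_assessed = sum(assessed),
    n_chimeric = n_chim,
    proportion = if (sum(assessed) > 0L) n_chim / sum(assessed) else NA_real_,
    proportion_all = if (nrow(vdf) > 0L) n_chim / nrow(vdf) else NA_real_,
    verdicts = vdf
  )
  if (!is.null(bin_membership)) {
    assert_cols(bin_membership, c("contig_id", "bin_id"), "bin_membership")
    multi <- tapply(bin_membership$bin_id, bin_membership$contig_id,
                    function(b) length(unique(b)))
    if (any(multi > 1L)) {
      stop_gv("contig(s) assigned to more than one bin: %s",
              paste(utils::head(names(multi)[multi > 1L], 5L), collapse = ", "))
    }
    if (is.null(segments)) {
      stop_gv("bin-level reporting needs the full chimera_verdicts() output")
    }
    bm <- bin_membership[!duplicated(bin_membership), , drop = FALSE]
    sizes <- table(bm$bin_id)
    eligible <- names(sizes)[sizes >= 2L]
    bin_rows <- lapply(eligible, function(b) {
      contigs <- bm$contig_id[bm$bin_id == b]
      segs <- segments[segments$query_id %in% contigs, , drop = FALSE]
      if (is.null(segs) || nrow(segs) == 0L) {
        return(data.frame(bin_id = b, verdict = "unassessed", n_genomes = 0L,
                          stringsAsFactors = FALSE))
      }
      ng <- length(unique(segs$reference_genome_id))
      data.frame(bin_id = b,
                 verdict = if (ng >= 2L) "chimeric" else "clean",
                 n_genomes = ng, stringsAsFactors = FALSE)
    })
    bins <- rbind_rows(bin_rows) %||%
      data.frame(bin_id = character(), verdict = character(),
                 n_genomes = integer(), stringsAsFactors = FALSE)
    b_assessed <- bins$verdict %in% c("clean", "chimeric")
    b_chim <- sum(bins$verdict == "chimeric")
    out$bin <- list(
      n_assessed = sum(b_assessed),
      n_chimeric = b_chim,
      proportion = if (sum(b_assessed) > 0L) b_chim / sum(b_assessed)
                   else NA_real_,
      proportion_all = if (nrow(bins) > 0L) b_chim / nrow(bins) else NA_real_,
      verdicts = bins,
      n_excluded_single_contig = sum(sizes == 1L)
    )
  }
  structure(out, class = "gv_chimera_report")
}

#' @export
print.gv_chimera_report <- function(x, ...) {
  for (lv in names(x)) {
    s <- x[[lv]]
    cat(sprintf("%s level: %d assessed, %d chimeric (proportion %.4g)\n",
                lv, s$n_assessed, s$n_chimeric, s$proportion))
  }
  invisible(x)
}
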