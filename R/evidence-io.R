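#' Extract open reading frames from scaffolds
#'
#' Minimal deterministic six-frame stop-to-stop ORF caller used as plumbing
#' when externally predicted genes are not supplied. Every maximal run of
#' unambiguous amino acids between stops (start codon not required) of at
#' least `min_aa` residues is reported, on both strands, under the standard
#' genetic code. Ambiguous codons (translated as `X`, e.g. over `N` runs)
#' break ORFs the same way stops do, so a scaffold of all `N` yields no ORFs.
#'
#' @param scaffolds A `DNAStringSet`, or path to a nucleotide FASTA file.
#' @param min_aa Minimum ORF length in amino acids (default 50).
#' @return A list with `orfs` — data frame `orf_id`, `scaffold_id`, `start`,
#'   `end` (0-based half-open nucleotide coordinates on the scaffold),
#'   `strand`, `length_aa` — and `proteins`, an `AAStringSet` named by
#'   `orf_id`.
#' @examples
#' s <- Biostrings::DNAStringSet(c(sc1 = paste(rep("ATG", 60), collapse = "")))
#' extract_orfs(s, min_aa = 50)$orfs
#' @export
extract_orfs <- function(scaffolds, min_aa = 50L) {
  if (is.character(scaffolds)) {
    scaffolds <- Biostrings::readDNAStringSet(scaffolds)
  }
  stopifnot(methods::is(scaffolds, "DNAStringSet"))
  if (is.null(names(scaffolds)) || anyDuplicated(names(scaffolds))) {
    stop_gv("scaffolds must carry unique FASTA names")
  }
  rows <- list(); prots <- character(0)
  for (si in seq_along(scaffolds)) {
    sc_id <- names(scaffolds)[si]
    sq <- scaffolds[[si]]
    slen <- length(sq)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") sq else Biostrings::reverseComplement(sq)
      for (frame in 0:2) {
        naa <- (slen - frame) %/% 3L
        if (naa < min_aa) next
        aa <- as.character(Biostrings::translate(
          Biostrings::subseq(s, frame + 1L, frame + 3L * naa),
          if.fuzzy.codon = "X"))
        # maximal runs of residues that are neither stop nor ambiguous
        mt <- gregexpr("[^*X]+", aa)[[1L]]
        if (mt[1L] == -1L) next
        lens <- attr(mt, "match.length")
        keep <- lens >= min_aa
        for (k in which(keep)) {
          aa_start <- mt[k]            # 1-based on the translated frame
          aa_len <- lens[k]
          nt_start_f <- frame + 3L * (aa_start - 1L)   # 0-based on strand s
          nt_end_f <- nt_start_f + 3L * aa_len
          if (strand == "+") {
            start <- nt_start_f; end <- nt_end_f
          } else {
            start <- slen - nt_end_f; end <- slen - nt_start_f
          }
          orf_id <- sprintf("%s_orf_%s%d_%d", sc_id, strand, frame, start)
          rows[[length(rows) + 1L]] <- data.frame(
            orf_id = orf_id, scaffold_id = sc_id,
            start = start, end = end, strand = strand, length_aa = aa_len,
            stringsAsFactors = FALSE)
          prots[orf_id] <- substr(aa, aa_start, aa_start + aa_len - 1L)
        }
      }
    }
  }
  orfs <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(orf_id = character(), scaffold_id = character(),
               start = integer(), end = integer(), strand = character(),
               length_aa = integer(), stringsAsFactors = FALSE)
  o <- order(orfs$scaffold_id, orfs$start, orfs$strand)
  orfs <- orfs[o, ]; rownames(orfs) <- NULL
  proteins <- Biostrings::AAStringSet(prots[orfs$orf_id] %||% character(0))
  list(orfs = orfs, proteins = proteins)
}

#' Filter an ORF table by minimum length
#'
#' Applies the minimum-length rule (default: at least 50 amino acids) to a
#' table of externally predicted ORFs.
#'
#' @param orfs Data frame with at least `orf_id` and `length_aa`.
#' @param min_aa Minimum length in amino acids; ORFs strictly shorter are
#'   dropped.
#' @return The filtered data frame.
#' @export
filter_orfs <- function(orfs, min_aa = 50L) {
  assert_cols(orfs, c("orf_id", "length_aa"), "orfs")
  out <- orfs[orfs$length_aa >= min_aa, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Load viral-profile search hits
#'
#' Reads a whitespace-delimited profile-search table in HMMER per-target
#' (`--tblout`) layout: target name, target accession, query (profile) name,
#' query accession, full-sequence E-value, score, ... `#` lines are skipped.
#' Hits are filtered to `evalue <= max_evalue` (default 1e-10, the profile
#' threshold used to call an ORF a giant-virus match) and deduplicated to one
#' best (lowest-E-value) row per (ORF, profile) pair.
#'
#' @param path Path to the table, or a data frame already carrying columns
#'   `orf_id`, `profile_id`, `evalue`, `score`.
#' @param max_evalue Inclusive E-value cutoff.
#' @return Data frame: `orf_id`, `profile_id`, `evalue`, `score`.
#' @export
load_profile_hits <- function(path, max_evalue = 1e-10) {
  if (is.character(path)) {
    lines <- readLines(path)
    lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
    if (length(lines) == 0L) {
      warn_gv("profile hit file %s contains no hit rows", path)
      return(data.frame(orf_id = character(), profile_id = character(),
                        evalue = numeric(), score = numeric(),
                        stringsAsFactors = FALSE))
    }
    fields <- strsplit(trimws(lines), "[ \t]+")
    nf <- lengths(fields)
    if (any(nf < 6L)) {
      stop_gv("unparseable profile hit row at line %d (fewer than 6 fields)",
              which(nf < 6L)[1L])
    }
    hits <- data.frame(
      orf_id = vapply(fields, `[[`, character(1), 1L),
      profile_id = vapply(fields, `[[`, character(1), 3L),
      evalue = as.numeric(vapply(fields, `[[`, character(1), 5L)),
      score = as.numeric(vapply(fields, `[[`, character(1), 6L)),
      stringsAsFactors = FALSE
    )
    if (anyNA(hits$evalue)) {
      stop_gv("unparseable E-value at line %d", which(is.na(hits$evalue))[1L])
    }
  } else {
    hits <- path
    assert_cols(hits, c("orf_id", "profile_id", "evalue"), "profile hits")
    if (is.null(hits$score)) hits$score <- NA_real_
  }
  if (any(hits$evalue <= 0)) stop_gv("E-values must be positive")
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  hits <- hits[order(hits$orf_id, hits$profile_id, hits$evalue), , drop = FALSE]
  hits <- hits[!duplicated(hits[, c("orf_id", "profile_id")]), , drop = FALSE]
  rownames(hits) <- NULL
  hits[, c("orf_id", "profile_id", "evalue", "score")]
}

#' Load cellular similarity-search hits
#'
#' Reads 12-column BLAST/DIAMOND tabular output (qseqid sseqid pident length
#' mismatch gapopen qstart qend sstart send evalue bitscore), optionally with a
#' 13th column naming the subject's cellular domain. Hits are retained when
#' `pident >= min_identity` AND `evalue <= max_evalue` AND the subject's
#' domain is in `domains` (default: the three cellular domains). Defaults are
#' the published cellular-side thresholds: 35% identity and E-value 1e-5.
#'
#' @param path Path to the tabular file, or a data frame with columns
#'   `orf_id`, `subject_id`, `percent_identity`, `evalue` (plus optional
#'   `subject_domain`).
#' @param min_identity Inclusive percent-identity cutoff.
#' @param max_evalue Inclusive E-value cutoff.
#' @param domains Accepted subject domains.
#' @param domain_map Optional named character vector mapping `subject_id` to
#'   domain, used when the table has no domain column.
#' @param on_unknown What to do with subjects whose domain is unknown:
#'   `"drop"` (default, with a warning), `"keep"`, or `"error"`.
#' @return Data frame: `orf_id`, `subject_id`, `percent_identity`, `evalue`,
#'   `subject_domain`.
#' @export
load_cellular_hits <- function(path, min_identity = 35, max_evalue = 1e-5,
                               domains = c("Bacteria", "Archaea", "Eukaryota"),
                               domain_map = NULL,
                               on_unknown = c("drop", "keep", "error")) {
  on_unknown <- match.arg(on_unknown)
  if (is.character(path)) {
    raw <- utils::read.table(path, sep = "\t", quote = "", comment.char = "#",
                             stringsAsFactors = FALSE, fill = FALSE)
    if (ncol(raw) < 12L) {
      stop_gv("expected >= 12 tab-separated columns, found %d", ncol(raw))
    }
    hits <- data.frame(
      orf_id = as.character(raw[[1L]]),
      subject_id = as.character(raw[[2L]]),
      percent_identity = as.numeric(raw[[3L]]),
      evalue = as.numeric(raw[[11L]]),
      subject_domain = if (ncol(raw) >= 13L) as.character(raw[[13L]])
                       else NA_character_,
      stringsAsFactors = FALSE
    )
  } else {
    hits <- path
    assert_cols(hits, c("orf_id", "subject_id", "percent_identity", "evalue"),
                "cellular hits")
    if (is.null(hits$subject_domain)) hits$subject_domain <- NA_character_
  }
  if (!is.null(domain_map)) {
    unmapped <- is.na(hits$subject_domain)
    hits$subject_domain[unmapped] <-
      unname(domain_map[hits$subject_id[unmapped]])
  }
  if (any(hits$percent_identity < 0 | hits$percent_identity > 100)) {
    stop_gv("percent identity outside [0, 100]")
  }
  unknown <- is.na(hits$subject_domain)
  if (any(unknown)) {
    msg <- sprintf("%d hit(s) with unknown subject domain", sum(unknown))
    if (on_unknown == "error") stop_gv("%s", msg)
    if (on_unknown == "drop") {
      warn_gv("%s dropped", msg)
      hits <- hits[!unknown, , drop = FALSE]
    }
  }
  keep <- hits$percent_identity >= min_identity & hits$evalue <= max_evalue &
    (is.na(hits$subject_domain) | hits$subject_domain %in% domains)
  out <- hits[keep, c("orf_id", "subject_id", "percent_identity", "evalue",
                      "subject_domain")]
  rownames(out) <- NULL
  out
}

#' Reduce hits to per-scaffold evidence counts
#'
#' Produces the coordinate pair the scaffold classifier operates on:
#' `viral_orf_count`, the number of distinct ORFs on the scaffold with at
#' least one qualifying viral-profile hit, and `cellular_match_count`, the
#' number of qualifying cellular hit rows on the scaffold. Because row counts
#' depend on the upstream search tool's per-query reporting limit, each ORF's
#' contribution to the cellular count is capped at `per_orf_cap` rows
#' (default 25); `cellular_mode = "orfs"` instead counts distinct ORFs with
#' at least one cellular hit. Scaffolds with no hits are still emitted with
#' zero counts.
#'
#' @param orfs ORF table (`orf_id`, `scaffold_id`, and `length_aa` if
#'   available).
#' @param profile_hits Output of [load_profile_hits()].
#' @param cellular_hits Output of [load_cellular_hits()].
#' @param scaffold_lengths Optional named vector of scaffold lengths (nt);
#'   scaffolds named here but absent from `orfs` are emitted with zero ORFs.
#' @param per_orf_cap Maximum cellular hit rows counted per ORF.
#' @param cellular_mode `"rows"` (capped row count, default) or `"orfs"`
#'   (distinct ORFs with a cellular hit).
#' @return Data frame: `scaffold_id`, `length`, `n_orfs`, `viral_orf_count`,
#'   `cellular_match_count`.
#' @export
count_evidence <- function(orfs, profile_hits, cellular_hits,
                           scaffold_lengths = NULL, per_orf_cap = 25L,
                           cellular_mode = c("rows", "orfs")) {
  cellular_mode <- match.arg(cellular_mode)
  assert_cols(orfs, c("orf_id", "scaffold_id"), "orfs")
  orphans <- unique(c(
    setdiff(profile_hits$orf_id, orfs$orf_id),
    setdiff(cellular_hits$orf_id, orfs$orf_id)
  ))
  if (length(orphans) > 0L) {
    stop_gv("hit rows reference unknown orf_id(s): %s",
            paste(utils::head(orphans, 10L), collapse = ", "))
  }
  scaffold_ids <- unique(c(orfs$scaffold_id, names(scaffold_lengths)))
  orf2sc <- stats::setNames(orfs$scaffold_id, orfs$orf_id)

  viral_orfs <- unique(profile_hits$orf_id)
  v <- table(factor(unname(orf2sc[viral_orfs]), levels = scaffold_ids))

  if (nrow(cellular_hits) > 0L) {
    per_orf <- table(cellular_hits$orf_id)
    contrib <- if (cellular_mode == "rows") pmin(as.integer(per_orf),
                                                 as.integer(per_orf_cap))
               else rep(1L, length(per_orf))
    csc <- unname(orf2sc[names(per_orf)])
    cc <- tapply(contrib, factor(csc, levels = scaffold_ids), sum,
                 default = 0L)
  } else {
    cc <- stats::setNames(rep(0L, length(scaffold_ids)), scaffold_ids)
  }
  n_orfs <- table(factor(orfs$scaffold_id, levels = scaffold_ids))
  lens <- if (is.null(scaffold_lengths)) rep(NA_integer_, length(scaffold_ids))
          else unname(scaffold_lengths[scaffold_ids])
  out <- data.frame(
    scaffold_id = scaffold_ids,
    length = as.integer(lens),
    n_orfs = as.integer(n_orfs[scaffold_ids]),
    viral_orf_count = as.integer(v[scaffold_ids]),
    cellular_match_count = as.integer(cc[scaffold_ids]),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$scaffold_id), ]
  rownames(out) <- NULL
  out
}

#' Per-scaffold coverage from a SAM file
#'
#' Computes mean coverage and covered length per scaffold from read mappings,
#' after excluding alignments with mapping quality below `min_mapq` (the
#' abundance workflow uses 3, the cross-sample presence workflow 30) and reads
#' shorter than `min_read_len` nucleotides (the published pipelines discard
#' reads of at most 30 nt). `mean_coverage` is aligned bases divided by
#' scaffold length; `covered_length` is the number of positions with depth at
#' least 1. Scaffolds in the header with no retained alignments are reported
#' with zero coverage.
#'
#' @param path Path to a SAM file with an `@SQ` header.
#' @param sample_id Sample identifier recorded in the output.
#' @param min_mapq Minimum mapping quality retained.
#' @param min_read_len Minimum read length retained (nt).
#' @return Data frame: `scaffold_id`, `sample_id`, `mean_coverage`,
#'   `covered_length`, `length`.
#' @export
coverage_from_sam <- function(path, sample_id = "sample", min_mapq = 3L,
                              min_read_len = 31L) {
  bam <- Rsamtools::asBam(path,
                          destination = tempfile(fileext = ""),
                          overwrite = TRUE, indexDestination = TRUE)
  hdr <- Rsamtools::scanBamHeader(bam)[[1L]]$targets
  if (is.null(hdr) || length(hdr) == 0L) {
    stop_gv("SAM header carries no @SQ sequence lengths")
  }
  param <- Rsamtools::ScanBamParam(
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE),
    mapqFilter = min_mapq
  )
  aln <- GenomicAlignments::readGAlignments(bam, param = param)
  aln <- aln[GenomicAlignments::qwidth(aln) >= min_read_len]
  cov <- GenomicAlignments::coverage(aln)
  scaffolds <- names(hdr)
  mean_cov <- vapply(scaffolds, function(s) {
    if (!s %in% names(cov)) return(0)
    sum(as.numeric(S4Vectors::runValue(cov[[s]])) *
          S4Vectors::runLength(cov[[s]])) / hdr[[s]]
  }, numeric(1))
  covered <- vapply(scaffolds, function(s) {
    if (!s %in% names(cov)) return(0L)
    as.integer(sum(S4Vectors::runLength(cov[[s]])[
      S4Vectors::runValue(cov[[s]]) >= 1L]))
  }, integer(1))
  data.frame(
    scaffold_id = scaffolds,
    sample_id = sample_id,
    mean_coverage = unname(mean_cov),
    covered_length = unname(covered),
    length = unname(as.integer(hdr)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Write a per-scaffold evidence table
#'
#' @param evidence Output of [count_evidence()].
#' @param path Destination TSV path.
#' @return `path`, invisibly.
#' @export
write_evidence <- function(evidence, path) {
  assert_cols(evidence,
              c("scaffold_id", "n_orfs", "viral_orf_count",
                "cellular_match_count"), "evidence")
  write_tsv_table(evidence, path)
}
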