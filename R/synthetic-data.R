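#' Contig length distribution specification
#'
#' Describes the length distribution used when cutting simulated metagenomic
#' contigs out of source genomes. The default is a lognormal with log-mean 9.8
#' and log-sd 0.6 truncated to \[10, 200\] kb, matching the scaffold size range
#' the downstream analyses operate on (all scaffold-level statistics use
#' sequences of at least 10 kb). An `empirical` family resamples a user-supplied
#' vector of observed lengths instead.
#'
#' @param family `"lognormal"` or `"empirical"`.
#' @param meanlog,sdlog Lognormal parameters (natural log scale).
#' @param min_len,max_len Truncation bounds in nucleotides.
#' @param lengths Observed lengths to resample when `family = "empirical"`.
#' @return An object of class `gv_length_dist`.
#' @examples
#' length_dist_spec()
#' @export
length_dist_spec <- function(family = c("lognormal", "empirical"),
                             meanlog = 9.8, sdlog = 0.6,
                             min_len = 10000L, max_len = 200000L,
                             lengths = NULL) {
  family <- match.arg(family)
  if (min_len < 1L) stop_gv("min_len must be >= 1")
  if (max_len < min_len) stop_gv("max_len must be >= min_len")
  if (family == "empirical") {
    if (is.null(lengths)) stop_gv("empirical family requires `lengths`")
    lengths <- lengths[lengths >= min_len & lengths <= max_len]
    if (length(lengths) == 0L) {
      stop_gv("no supplied lengths fall inside [min_len, max_len]")
    }
  }
  structure(list(family = family, meanlog = meanlog, sdlog = sdlog,
                 min_len = as.integer(min_len), max_len = as.integer(max_len),
                 lengths = lengths),
            class = "gv_length_dist")
}

# Draw n contig lengths from the spec; caller manages the RNG state.
draw_lengths <- function(dist, n) {
  if (n == 0L) return(integer(0))
  if (dist$family == "lognormal") {
    lo <- stats::plnorm(dist$min_len, dist$meanlog, dist$sdlog)
    hi <- stats::plnorm(dist$max_len, dist$meanlog, dist$sdlog)
    u <- stats::runif(n, lo, hi)
    len <- round(stats::qlnorm(u, dist$meanlog, dist$sdlog))
  } else {
    len <- sample(dist$lengths, n, replace = TRUE)
  }
  as.integer(pmin(pmax(len, dist$min_len), dist$max_len))
}

#' Simulate source genomes
#'
#' Generates random nucleotide sequences with class labels, standing in for the
#' reference genome collection (viral plus cellular) that a control database is
#' shredded from. Purely uniform base composition; see the methods vignette for
#' what this does and does not emulate.
#'
#' @param n_per_class Named integer vector: genomes per class label.
#' @param genome_length Length of every simulated genome in nucleotides.
#' @param seed Integer seed; identical seeds give identical genomes.
#' @return A data frame with columns `genome_id`, `class_label`, `sequence`.
#' @examples
#' g <- simulate_source_genomes(c(viral = 1, bacterial = 1),
#'                              genome_length = 50000, seed = 1)
#' nchar(g$sequence)
#' @export
simulate_source_genomes <- function(n_per_class = c(viral = 2L, bacterial = 2L,
                                                    archaeal = 1L,
                                                    eukaryotic = 2L),
                                    genome_length = 200000L, seed = 1L) {
  classes <- rep(names(n_per_class), n_per_class)
  if (length(classes) == 0L) stop_gv("no genomes requested")
  local_seed_eval(seed, {
    seqs <- vapply(seq_along(classes), function(i) {
      paste(sample(c("A", "C", "G", "T"), genome_length, replace = TRUE),
            collapse = "")
    }, character(1))
    data.frame(
      genome_id = sprintf("%s_g%02d", classes, stats::ave(
        seq_along(classes), classes, FUN = seq_along)),
      class_label = classes,
      sequence = seqs,
      stringsAsFactors = FALSE
    )
  })
}

new_sim_contigs <- function(contigs, segments, genomes, dist) {
  structure(list(contigs = contigs, segments = segments,
                 genomes = genomes, dist = dist),
            class = "gv_sim_contigs")
}

#' @export
print.gv_sim_contigs <- function(x, ...) {
  cat(sprintf("Simulated contigs: %d contigs from %d genome(s), %d chimeric\n",
              nrow(x$contigs), nrow(x$genomes), sum(x$contigs$is_chimera)))
  invisible(x)
}

#' Cut non-overlapping simulated contigs from source genomes
#'
#' Walks along each genome cutting consecutive, non-overlapping fragments with
#' lengths drawn from `dist`, emulating how a control metagenomic database is
#' built by shredding reference genomes into contig-sized pieces. Cutting stops
#' when the remaining tail is shorter than `dist$min_len`; the final contig is
#' truncated to the remaining length when necessary (still at least
#' `dist$min_len`).
#'
#' @param genomes Data frame with `genome_id`, `class_label`, and either
#'   `sequence` or `seq_length` columns (as from [simulate_source_genomes()]).
#' @param dist A [length_dist_spec()].
#' @param seed Integer seed; output is bit-reproducible.
#' @return A `gv_sim_contigs` object: `$contigs` (contig_id, length,
#'   truth_class, is_chimera), `$segments` (contig_id, genome_id, start, end;
#'   0-based half-open on the source genome), `$genomes`, `$dist`.
#'   Genomes shorter than `dist$min_len` contribute no contigs (with a warning).
#' @examples
#' g <- simulate_source_genomes(c(viral = 1), genome_length = 60000, seed = 1)
#' sc <- shred_genomes(g, length_dist_spec(), seed = 1)
#' sc$contigs
#' @export
shred_genomes <- function(genomes, dist = length_dist_spec(), seed = 1L) {
  assert_cols(genomes, c("genome_id", "class_label"), "genomes")
  if (!"seq_length" %in% names(genomes)) {
    assert_cols(genomes, "sequence", "genomes")
    genomes$seq_length <- nchar(genomes$sequence)
  }
  seeds <- fan_seed(seed, seq_len(nrow(genomes)) - 1L)
  pieces <- lapply(seq_len(nrow(genomes)), function(i) {
    shred_one(genomes$genome_id[i], genomes$class_label[i],
              genomes$seq_length[i], dist, seeds[i])
  })
  contigs <- do.call(rbind, lapply(pieces, `[[`, "contigs"))
  segments <- do.call(rbind, lapply(pieces, `[[`, "segments"))
  if (is.null(contigs)) {
    contigs <- data.frame(contig_id = character(), length = integer(),
                          truth_class = character(), is_chimera = logical(),
                          stringsAsFactors = FALSE)
    segments <- data.frame(contig_id = character(), genome_id = character(),
                           start = integer(), end = integer(),
                           stringsAsFactors = FALSE)
  }
  gcols <- intersect(c("genome_id", "class_label", "seq_length", "sequence"),
                     names(genomes))
  new_sim_contigs(contigs, segments, genomes[, gcols], dist)
}

shred_one <- function(genome_id, class_label, glen, dist, seed) {
  if (glen < dist$min_len) {
    warn_gv("genome %s (%d nt) is shorter than min_len (%d nt); no contigs",
            genome_id, glen, dist$min_len)
    return(NULL)
  }
  local_seed_eval(seed, {
    # Draw a generous batch of lengths up front so the walk is vectorisable.
    lens <- draw_lengths(dist, max(2L, ceiling(glen / dist$min_len)))
    starts <- integer(0); ends <- integer(0)
    pos <- 0L
    k <- 0L
    while (glen - pos >= dist$min_len) {
      k <- k + 1L
      if (k > length(lens)) lens <- c(lens, draw_lengths(dist, length(lens)))
      take <- min(lens[k], glen - pos)
      starts <- c(starts, pos)
      ends <- c(ends, pos + take)
      pos <- pos + take
    }
    ids <- sprintf("%s_c%03d", genome_id, seq_along(starts))
    list(
      contigs = data.frame(contig_id = ids, length = ends - starts,
                           truth_class = class_label, is_chimera = FALSE,
                           stringsAsFactors = FALSE),
      segments = data.frame(contig_id = ids, genome_id = genome_id,
                            start = starts, end = ends,
                            stringsAsFactors = FALSE)
    )
  })
}

#' Plant chimeric contigs
#'
#' Replaces an expected fraction `rate` of contigs with two-genome junctions:
#' the head of the original contig is kept and the tail is replaced by a
#' segment drawn from a different source genome, preserving total contig
#' length. The junction point is uniform over
#' `[min_len/2, length - min_len/2]` so both halves remain long enough to be
#' retained by the 500-nt alignment-trimming rule downstream. `is_chimera`
#' flags are set truthfully (a contig is chimeric iff its segments name at
#' least two distinct genomes); `truth_class` keeps the head segment's class.
#'
#' @param contigs A `gv_sim_contigs` object.
#' @param rate Fraction in \[0, 1\] of contigs to convert.
#' @param seed Integer seed.
#' @return A `gv_sim_contigs` object with the same number of contigs.
#' @examples
#' g <- simulate_source_genomes(c(viral = 1, bacterial = 1),
#'                              genome_length = 100000, seed = 1)
#' sc <- plant_chimeras(shred_genomes(g, seed = 1), rate = 0.5, seed = 2)
#' sum(sc$contigs$is_chimera)
#' @export
plant_chimeras <- function(contigs, rate, seed = 1L) {
  stopifnot(inherits(contigs, "gv_sim_contigs"))
  if (rate < 0 || rate > 1) stop_gv("rate must be in [0, 1]")
  if (rate == 0 || nrow(contigs$contigs) == 0L) return(contigs)
  genomes <- contigs$genomes
  if (length(unique(genomes$genome_id)) < 2L) {
    stop_gv("planting chimeras requires at least two distinct source genomes")
  }
  min_len <- contigs$dist$min_len
  ctg <- contigs$contigs
  seg <- contigs$segments
  local_seed_eval(seed, {
    pick <- stats::rbinom(nrow(ctg), 1L, rate) == 1L
    for (i in which(pick)) {
      id <- ctg$contig_id[i]
      len <- ctg$length[i]
      half <- ceiling(min_len / 2)
      if (len < 2L * half) next # too short to split detectably
      b <- draw_int(half, len - half)
      own <- seg[seg$contig_id == id, , drop = FALSE][1L, ]
      donors <- genomes[genomes$genome_id != own$genome_id, , drop = FALSE]
      donor <- donors[sample.int(nrow(donors), 1L), ]
      tail_len <- len - b
      dstart <- draw_int(0L, donor$seq_length - tail_len)
      seg <- seg[seg$contig_id != id, , drop = FALSE]
      seg <- rbind(seg,
                   data.frame(contig_id = id, genome_id = own$genome_id,
                              start = own$start, end = own$start + b,
                              stringsAsFactors = FALSE),
                   data.frame(contig_id = id, genome_id = donor$genome_id,
                              start = dstart, end = dstart + tail_len,
                              stringsAsFactors = FALSE))
      ctg$is_chimera[i] <- TRUE
    }
    seg <- seg[order(match(seg$contig_id, ctg$contig_id), seg$start), ]
    rownames(seg) <- NULL
    new_sim_contigs(ctg, seg, genomes, contigs$dist)
  })
}

#' Hit-count model for simulated evidence
#'
#' Per-class rates (counts per kb of contig) for viral-profile ORF matches and
#' cellular protein matches, emulating the two-population structure that
#' separates giant-virus scaffolds from cellular ones: viral contigs carry many
#' viral-profile matches and few cellular matches, cellular contigs the
#' reverse. Counts are negative binomial with mean `rate * length_kb` and size
#' `dispersion`; `dispersion = Inf` gives Poisson counts.
#'
#' Defaults correspond to well-separated populations: viral contigs at 5
#' viral-ORF and 1 cellular match per 10 kb; cellular contigs at 0.05 viral-ORF
#' and 20 cellular matches per 10 kb.
#'
#' @param rates Data frame with columns `class_label`, `viral_rate`,
#'   `cellular_rate` (per kb).
#' @param dispersion Negative-binomial size parameter; `Inf` for Poisson.
#' @param seed Default seed used by [simulate_hit_counts()].
#' @return An object of class `gv_hit_model`.
#' @export
hit_count_model <- function(rates = NULL, dispersion = Inf, seed = 1L) {
  if (is.null(rates)) {
    rates <- data.frame(
      class_label = c("viral", "bacterial", "archaeal", "eukaryotic"),
      viral_rate = c(0.5, 0.005, 0.005, 0.005),
      cellular_rate = c(0.1, 2, 2, 2),
      stringsAsFactors = FALSE
    )
  }
  assert_cols(rates, c("class_label", "viral_rate", "cellular_rate"), "rates")
  if (any(rates$viral_rate < 0) || any(rates$cellular_rate < 0)) {
    stop_gv("rates must be non-negative")
  }
  if (dispersion <= 0) stop_gv("dispersion must be positive")
  structure(list(rates = rates, dispersion = dispersion,
                 seed = as.integer(seed)),
            class = "gv_hit_model")
}

rcount <- function(n, mu, dispersion) {
  if (is.infinite(dispersion)) stats::rpois(n, mu)
  else stats::rnbinom(n, size = dispersion, mu = mu)
}

#' Simulate per-contig evidence counts
#'
#' Draws viral-ORF and cellular-match counts for each simulated contig from
#' the class-conditional rates of a [hit_count_model()]. Expected counts scale
#' linearly with contig length.
#'
#' @param contigs A `gv_sim_contigs` object or a data frame with `contig_id`,
#'   `length`, `truth_class`.
#' @param model A [hit_count_model()].
#' @param seed Integer seed; defaults to the model's seed.
#' @return Data frame: `contig_id`, `length`, `viral_orf_count`,
#'   `cellular_match_count`, `truth_class`.
#' @examples
#' g <- simulate_source_genomes(c(viral = 1), genome_length = 60000, seed = 1)
#' ev <- simulate_hit_counts(shred_genomes(g, seed = 1), hit_count_model())
#' head(ev)
#' @export
simulate_hit_counts <- function(contigs, model = hit_count_model(),
                                seed = model$seed) {
  stopifnot(inherits(model, "gv_hit_model"))
  ctg <- if (inherits(contigs, "gv_sim_contigs")) contigs$contigs else contigs
  assert_cols(ctg, c("contig_id", "length", "truth_class"), "contigs")
  missing <- setdiff(unique(ctg$truth_class), model$rates$class_label)
  if (length(missing) > 0L) {
    stop_gv("no hit-count rates defined for class(es): %s",
            paste(missing, collapse = ", "))
  }
  i <- match(ctg$truth_class, model$rates$class_label)
  kb <- ctg$length / 1000
  local_seed_eval(seed, {
    data.frame(
      contig_id = ctg$contig_id,
      length = ctg$length,
      viral_orf_count = rcount(nrow(ctg), model$rates$viral_rate[i] * kb,
                               model$dispersion),
      cellular_match_count = rcount(nrow(ctg),
                                    model$rates$cellular_rate[i] * kb,
                                    model$dispersion),
      truth_class = ctg$truth_class,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate a sample-by-taxon abundance matrix with planted associations
#'
#' Generates lognormal abundances via a Gaussian copula. For each planted
#' (virus, eukaryote) pair the virus's latent normal is
#' `strength * z_euk + sqrt(1 - strength^2) * z_own`, so the pair's population
#' rank correlation has the sign and magnitude of `strength` (`strength = 1`
#' gives identical sample ranks); non-planted taxa are mutually independent.
#' The default of 11 samples matches the permafrost study design this generator
#' emulates.
#'
#' @param n_samples Number of samples (rows); at least 3.
#' @param taxa Character vector of unique taxon names (columns).
#' @param planted_pairs `NULL`, or a data frame with columns `virus`, `euk`,
#'   `strength` (each strength in \[-1, 1\]).
#' @param seed Integer seed.
#' @param meanlog,sdlog Lognormal marginal parameters.
#' @return Numeric matrix, samples in rows, taxa in columns, all entries >= 0.
#' @examples
#' m <- simulate_abundance_matrix(
#'   taxa = c("pitho1", "amoeba1", "fungus1"),
#'   planted_pairs = data.frame(virus = "pitho1", euk = "amoeba1",
#'                              strength = 0.9),
#'   seed = 1)
#' cor(m[, "pitho1"], m[, "amoeba1"], method = "spearman")
#' @export
simulate_abundance_matrix <- function(n_samples = 11L, taxa,
                                      planted_pairs = NULL, seed = 1L,
                                      meanlog = 0, sdlog = 1) {
  if (n_samples < 3L) stop_gv("n_samples must be >= 3")
  if (anyDuplicated(taxa)) {
    stop_gv("duplicate taxon names: %s",
            paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  }
  if (!is.null(planted_pairs)) {
    assert_cols(planted_pairs, c("virus", "euk", "strength"), "planted_pairs")
    if (any(abs(planted_pairs$strength) > 1)) {
      stop_gv("strengths must lie in [-1, 1]")
    }
    bad <- setdiff(c(planted_pairs$virus, planted_pairs$euk), taxa)
    if (length(bad) > 0L) {
      stop_gv("planted pair taxa not in `taxa`: %s", paste(bad, collapse = ", "))
    }
  }
  local_seed_eval(seed, {
    z <- matrix(stats::rnorm(n_samples * length(taxa)), n_samples,
                dimnames = list(sprintf("sample_%02d", seq_len(n_samples)),
                                taxa))
    if (!is.null(planted_pairs)) {
      for (i in seq_len(nrow(planted_pairs))) {
        v <- planted_pairs$virus[i]; e <- planted_pairs$euk[i]
        s <- planted_pairs$strength[i]
        z[, v] <- s * z[, e] + sqrt(1 - s^2) * z[, v]
      }
    }
    exp(meanlog + sdlog * z)
  })
}

#' Reference alignments implied by contig provenance
#'
#' Converts the segment provenance of simulated contigs into the 12-column
#' alignment rows an aligner would report against the source genomes: one
#' perfect-identity match per segment, in contig coordinates (1-based
#' inclusive). This is the ground-truth input for the chimera-assessment
#' workflow.
#'
#' @param contigs A `gv_sim_contigs` object.
#' @return Data frame with columns `query_id`, `reference_genome_id`,
#'   `qstart`, `qend`, `percent_identity`, `score`, `evalue`.
#' @export
truth_alignments <- function(contigs) {
  stopifnot(inherits(contigs, "gv_sim_contigs"))
  seg <- contigs$segments
  if (nrow(seg) == 0L) {
    return(data.frame(query_id = character(), reference_genome_id = character(),
                      qstart = integer(), qend = integer(),
                      percent_identity = numeric(), score = numeric(),
                      evalue = numeric(), stringsAsFactors = FALSE))
  }
  seg <- seg[order(match(seg$contig_id, contigs$contigs$contig_id), seg$start), ]
  lens <- seg$end - seg$start
  off <- unlist(lapply(split(lens, seg$contig_id)[unique(seg$contig_id)],
                       function(x) cumsum(c(0L, x[-length(x)]))),
                use.names = FALSE)
  data.frame(
    query_id = seg$contig_id,
    reference_genome_id = seg$genome_id,
    qstart = off + 1L,
    qend = off + lens,
    percent_identity = 100,
    score = 2 * lens,
    evalue = 1e-180,
    stringsAsFactors = FALSE
  )
}

#' Write simulated contigs and truth tables to disk
#'
#' Emits the simulated contigs as FASTA (sequences are extracted from the
#' source genomes, so `$genomes` must carry a `sequence` column), the contig
#' and segment truth tables as TSV, and a plain-text manifest recording the
#' generator parameters.
#'
#' @param contigs A `gv_sim_contigs` object whose genomes include sequences.
#' @param dir Output directory (created if missing).
#' @param seed Seed value recorded in the manifest.
#' @return Invisibly, the paths written.
#' @export
write_sim_contigs <- function(contigs, dir, seed = NA) {
  stopifnot(inherits(contigs, "gv_sim_contigs"))
  assert_cols(contigs$genomes, "sequence", "genomes")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  seg <- contigs$segments
  gseq <- stats::setNames(contigs$genomes$sequence, contigs$genomes$genome_id)
  parts <- substring(gseq[seg$genome_id], seg$start + 1L, seg$end)
  seqs <- vapply(split(parts, seg$contig_id)[contigs$contigs$contig_id],
                 paste, character(1), collapse = "")
  fa <- Biostrings::DNAStringSet(seqs)
  names(fa) <- contigs$contigs$contig_id
  paths <- c(
    fasta = file.path(dir, "contigs.fasta"),
    contigs = file.path(dir, "contigs_truth.tsv"),
    segments = file.path(dir, "segments_truth.tsv"),
    manifest = file.path(dir, "manifest.txt")
  )
  Biostrings::writeXStringSet(fa, paths[["fasta"]])
  write_tsv_table(contigs$contigs, paths[["contigs"]])
  write_tsv_table(seg, paths[["segments"]])
  writeLines(c(
    sprintf("seed\t%s", seed),
    sprintf("n_contigs\t%d", nrow(contigs$contigs)),
    sprintf("n_chimeric\t%d", sum(contigs$contigs$is_chimera)),
    sprintf("length_family\t%s", contigs$dist$family),
    sprintf("length_meanlog\t%s", contigs$dist$meanlog),
    sprintf("length_sdlog\t%s", contigs$dist$sdlog),
    sprintf("min_len\t%d", contigs$dist$min_len),
    sprintf("max_len\t%d", contigs$dist$max_len)
  ), paths[["manifest"]])
  invisible(paths)
}
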