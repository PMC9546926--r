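# Independent oracles used across tests. Each re-derives the expected result
# by a different route than the implementation (brute force, per-base
# bookkeeping, closed forms), so agreement is informative.

# Brute-force calibration: scan every grid point with an explicit loop and
# hand-computed rates, applying the strict eukaryotic-FP constraint and the
# documented tie-break (max sensitivity, then higher intercept, then slope).
oracle_calibrate <- function(ev, slope_grid, intercept_grid,
                             max_euk_fp = 0.01) {
  best <- NULL
  for (ic in sort(intercept_grid, decreasing = TRUE)) {
    for (sl in sort(slope_grid, decreasing = TRUE)) {
      called <- ev$viral_orf_count > sl * ev$cellular_match_count + ic
      fp_euk <- mean(called[ev$truth_class == "eukaryotic"])
      if (fp_euk >= max_euk_fp) next
      sens <- mean(called[ev$truth_class == "viral"])
      if (is.null(best) || sens > best$sens + 1e-12) {
        best <- list(slope = sl, intercept = ic, sens = sens)
      }
    }
  }
  best
}

# Confusion counts recomputed record by record.
oracle_confusion <- function(ev, slope, intercept) {
  tp <- fn <- 0L
  fp <- tn <- stats::setNames(integer(3),
                              c("bacterial", "archaeal", "eukaryotic"))
  for (i in seq_len(nrow(ev))) {
    called <- ev$viral_orf_count[i] > slope * ev$cellular_match_count[i] +
      intercept
    k <- ev$truth_class[i]
    if (k == "viral") {
      if (called) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (called) fp[k] <- fp[k] + 1L else tn[k] <- tn[k] + 1L
    }
  }
  list(tp = tp, fn = fn, fp = fp, tn = tn)
}

# Per-base greedy trimming: mark query positions owned by retained segments
# in the documented match order; fragments are runs of unowned positions.
oracle_trim <- function(matches, min_identity = 99.99, min_len = 500L) {
  m <- matches[matches$percent_identity >= min_identity, , drop = FALSE]
  if (nrow(m) == 0L) return(m[0, c("reference_genome_id", "qstart", "qend")])
  if (is.null(m$evalue)) m$evalue <- NA_real_
  o <- order(-m$score, m$evalue, m$qstart, as.character(m$reference_genome_id),
             method = "radix")
  m <- m[o, , drop = FALSE]
  owned <- logical(max(m$qend))
  segs <- list()
  for (i in seq_len(nrow(m))) {
    span <- m$qstart[i]:m$qend[i]
    free <- span[!owned[span]]
    if (length(free) == 0L) next
    # runs of consecutive free positions
    brk <- c(0L, which(diff(free) != 1L), length(free))
    for (r in seq_len(length(brk) - 1L)) {
      run <- free[(brk[r] + 1L):brk[r + 1L]]
      if (length(run) >= min_len) {
        owned[run] <- TRUE
        segs[[length(segs) + 1L]] <- data.frame(
          reference_genome_id = m$reference_genome_id[i],
          qstart = min(run), qend = max(run), stringsAsFactors = FALSE)
      }
    }
  }
  segs <- segs[!vapply(segs, is.null, logical(1))]
  if (length(segs) == 0L) {
    return(m[0, c("reference_genome_id", "qstart", "qend")])
  }
  out <- do.call(rbind, c(segs, list(make.row.names = FALSE)))
  out[order(out$qstart), , drop = FALSE]
}

# Nearest-rank first quartile by explicit sort-and-index.
oracle_q1 <- function(x) sort(x)[ceiling(length(x) / 4)]

# Benjamini-Hochberg step-up from the definition, preserving input order.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- numeric(n)
  prev <- 1
  for (i in n:1) {
    prev <- min(prev, p[o[i]] * n / i)
    q[o[i]] <- prev
  }
  q
}

# Random alignment-match instances for the trimming oracle.
random_matches <- function(n_matches, seed, qlen = 5000L) {
  withr::with_seed(seed, {
    qs <- sample.int(qlen - 200L, n_matches, replace = TRUE)
    qe <- pmin(qlen, qs + sample.int(3000L, n_matches, replace = TRUE))
    data.frame(
      query_id = "q",
      reference_genome_id = sample(paste0("g", 1:4), n_matches, replace = TRUE),
      qstart = qs, qend = qe,
      percent_identity = sample(c(100, 100, 99.995, 99.9), n_matches,
                                replace = TRUE),
      score = sample.int(5000L, n_matches, replace = TRUE),
      evalue = 10^-sample.int(100L, n_matches, replace = TRUE),
      stringsAsFactors = FALSE
    )
  })
}

# Labeled evidence sets with overlapping class clouds, for calibration tests.
random_labeled_evidence <- function(n, seed) {
  withr::with_seed(seed, {
    cls <- sample(c("viral", "bacterial", "archaeal", "eukaryotic"), n,
                  replace = TRUE, prob = c(0.4, 0.25, 0.1, 0.25))
    v <- ifelse(cls == "viral", stats::rpois(n, 4), stats::rpois(n, 0.8))
    cc <- ifelse(cls == "viral", stats::rpois(n, 2), stats::rpois(n, 6))
    data.frame(viral_orf_count = v, cellular_match_count = cc,
               truth_class = cls, stringsAsFactors = FALSE)
  })
}

toy_path <- function(...) system.file("extdata", "toy", ..., package = "gvmine")

toy_manifest <- function() {
  txt <- paste(readLines(toy_path("manifest.json")), collapse = "")
  # minimal flat key:number JSON reader (keeps the test free of extra deps)
  pairs <- regmatches(txt, gregexpr('"[^"]+"\\s*:\\s*[0-9.]+', txt))[[1]]
  keys <- sub('^"([^"]+)".*$', "\\1", pairs)
  vals <- as.numeric(sub('^.*:\\s*', "", pairs))
  stats::setNames(vals, keys)
}
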