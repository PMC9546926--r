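#' Coverage-based relative abundance matrix
#'
#' For each sample, the relative abundance of a taxonomic group is the sum of
#' mean scaffold coverages of the group's scaffolds divided by the total mean
#' coverage of ALL scaffolds in the sample — restricted, on both sides, to
#' scaffolds of at least `min_len` nucleotides (default 10 kb, the scale at
#' which scaffold-level statistics are computed). Scaffolds without a
#' taxonomy entry are pooled into an `"unclassified"` group so that rows sum
#' to 1 over exhaustive disjoint groups.
#'
#' @param coverage Data frame: `scaffold_id`, `sample_id`, `mean_coverage`,
#'   and `length` (or supply `lengths`).
#' @param taxonomy Data frame mapping `scaffold_id` to `group`.
#' @param lengths Optional named vector of scaffold lengths, used when
#'   `coverage` has no `length` column.
#' @param min_len Minimum scaffold length included (inclusive).
#' @return Numeric matrix, samples in rows, groups in columns; entries in
#'   \[0, 1\], rows summing to 1. A sample whose total coverage over
#'   qualifying scaffolds is zero is an error.
#' @export
relative_abundance <- function(coverage, taxonomy, lengths = NULL,
                               min_len = 10000L) {
  assert_cols(coverage, c("scaffold_id", "sample_id", "mean_coverage"),
              "coverage")
  assert_cols(taxonomy, c("scaffold_id", "group"), "taxonomy")
  if (is.null(coverage$length)) {
    if (is.null(lengths)) stop_gv("scaffold lengths are required")
    coverage$length <- unname(lengths[coverage$scaffold_id])
  }
  if (anyNA(coverage$length)) stop_gv("missing scaffold length(s)")
  if (any(coverage$mean_coverage < 0)) stop_gv("coverage must be non-negative")
  cov <- coverage[coverage$length >= min_len, , drop = FALSE]
  grp <- taxonomy$group[match(cov$scaffold_id, taxonomy$scaffold_id)]
  grp[is.na(grp)] <- "unclassified"
  samples <- sort(unique(coverage$sample_id))
  groups <- sort(unique(grp))
  m <- matrix(0, length(samples), length(groups),
              dimnames = list(samples, groups))
  agg <- tapply(cov$mean_coverage,
                list(factor(cov$sample_id, levels = samples),
                     factor(grp, levels = groups)),
                sum, default = 0)
  m[] <- agg
  totals <- rowSums(m)
  zero <- totals == 0
  if (any(zero)) {
    stop_gv("zero total coverage among scaffolds >= %d nt in sample(s): %s",
            min_len, paste(samples[zero], collapse = ", "))
  }
  sweep(m, 1L, totals, "/")
}

#' Per-sample abundance ratio between two groups
#'
#' Computes, per sample, the ratio of one group's relative abundance to
#' another's (e.g. giant viruses to eukaryotes), plus the mean and sample
#' (n-1) standard deviation over samples. Samples where the denominator group
#' is absent are flagged and excluded from the summary.
#'
#' @param matrix Abundance matrix from [relative_abundance()] (or any
#'   samples x groups matrix).
#' @param num_group,den_group Column names of numerator and denominator.
#' @return List: `ratios` (named per-sample vector, `NA` where the
#'   denominator is zero), `excluded` (sample names with zero denominator),
#'   `mean`, `sd`.
#' @export
group_ratio <- function(matrix, num_group, den_group) {
  for (g in c(num_group, den_group)) {
    if (!g %in% colnames(matrix)) stop_gv("group %s not in matrix", g)
  }
  num <- matrix[, num_group]
  den <- matrix[, den_group]
  ratios <- ifelse(den > 0, num / den, NA_real_)
  ok <- !is.na(ratios)
  list(
    ratios = ratios,
    excluded = rownames(matrix)[!ok] %||% character(0),
    mean = if (any(ok)) mean(ratios[ok]) else NA_real_,
    sd = if (sum(ok) > 1L) stats::sd(ratios[ok]) else NA_real_
  )
}

# All permutations of 1..n as an (n!, n) index matrix; n <= 9 in practice.
perm_indices <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  p <- perm_indices(n - 1L)
  out <- matrix(0L, n * nrow(p), n)
  for (i in seq_len(n)) {
    rows <- (i - 1L) * nrow(p) + seq_len(nrow(p))
    rest <- seq_len(n)[-i]
    out[rows, 1L] <- i
    out[rows, -1L] <- matrix(rest[p], nrow(p))
  }
  out
}

#' Spearman correlation test with a choice of null distribution
#'
#' Computes the Spearman rank correlation (midranks for ties) and a two-sided
#' p-value, either from the t approximation
#' `t = rho * sqrt((n-2) / (1-rho^2))` on `n - 2` degrees of freedom, or from
#' the exact permutation distribution (all `n!` arrangements, tie-aware).
#' `method = "auto"` uses the exact distribution below 10 samples and the t
#' approximation from 10 on — study-sized designs (11 samples) sit just
#' inside the approximation.
#'
#' @param x,y Numeric vectors of equal length (at least 3).
#' @param method `"auto"`, `"exact"` or `"approx"`.
#' @return List: `rho`, `p_value`, `method` (the method actually used).
#'   Constant input vectors give `rho = NA`.
#' @export
spearman_test <- function(x, y, method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  n <- length(x)
  if (length(y) != n || n < 3L) stop_gv("x and y must share length >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, method = "undefined"))
  }
  rho <- stats::cor(x, y, method = "spearman")
  if (method == "auto") method <- if (n < 10L) "exact" else "approx"
  if (method == "exact") {
    if (n > 9L) stop_gv("exact permutation null is limited to n <= 9")
    rx <- rank(x) - mean(rank(x))
    ry <- rank(y)
    perms <- perm_indices(n)
    # sd terms are permutation-invariant, so compare raw cross-products
    t_obs <- sum(rx * ry)
    t_perm <- as.vector(matrix(ry[t(perms)], ncol = n, byrow = TRUE) %*% rx)
    mu <- mean(t_perm)
    p <- mean(abs(t_perm - mu) >= abs(t_obs - mu) - 1e-12)
  } else {
    tt <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * stats::pt(-abs(tt), df = n - 2)
    p <- min(p, 1)
  }
  list(rho = rho, p_value = p, method = method)
}

#' Virus-eukaryote co-occurrence across samples
#'
#' Tests each (virus group, eukaryote group) pair whose members are both
#' present (non-zero abundance) in at least `min_presence` samples, using the
#' Spearman rank correlation over all samples (zeros included), and adjusts
#' the resulting p-values with the Benjamini-Hochberg step-up procedure as a
#' single family. Pairs with an undefined correlation (constant abundance
#' vector) are emitted flagged and excluded from the family.
#'
#' @param matrix Samples x taxa abundance matrix (at least 3 samples).
#' @param virus_taxa,euk_taxa Column names of the virus and eukaryote groups.
#' @param min_presence Minimum number of samples with non-zero abundance for
#'   each pair member.
#' @param method p-value method, see [spearman_test()].
#' @return Data frame: `virus`, `euk`, `n_samples_used`, `rho`, `p_value`,
#'   `q_value`, `undefined`. Pairs failing the presence filter are absent.
#' @export
cooccurrence <- function(matrix, virus_taxa, euk_taxa, min_presence = 2L,
                         method = c("auto", "exact", "approx")) {
  method <- match.arg(method)
  if (nrow(matrix) < 3L) stop_gv("co-occurrence requires at least 3 samples")
  missing <- setdiff(c(virus_taxa, euk_taxa), colnames(matrix))
  if (length(missing) > 0L) {
    stop_gv("taxa not in matrix: %s", paste(missing, collapse = ", "))
  }
  present_n <- colSums(matrix[, unique(c(virus_taxa, euk_taxa)),
                              drop = FALSE] > 0)
  rows <- list()
  for (v in virus_taxa) {
    for (e in euk_taxa) {
      if (present_n[[v]] < min_presence || present_n[[e]] < min_presence) next
      st <- spearman_test(matrix[, v], matrix[, e], method = method)
      rows[[length(rows) + 1L]] <- data.frame(
        virus = v, euk = e, n_samples_used = nrow(matrix),
        rho = st$rho, p_value = st$p_value,
        undefined = is.na(st$rho), stringsAsFactors = FALSE)
    }
  }
  out <- rbind_rows(rows) %||%
    data.frame(virus = character(), euk = character(),
               n_samples_used = integer(), rho = numeric(),
               p_value = numeric(), undefined = logical(),
               stringsAsFactors = FALSE)
  out$q_value <- NA_real_
  fam <- !out$undefined
  if (any(fam)) out$q_value[fam] <- stats::p.adjust(out$p_value[fam],
                                                    method = "BH")
  out[, c("virus", "euk", "n_samples_used", "rho", "p_value", "q_value",
          "undefined")]
}

#' Cross-sample presence calls and sharing matrix
#'
#' A scaffold is called present in a sample when strictly more than
#' `min_covered` nucleotides of it are covered by reads (under the upstream
#' mapping-quality filter, 30 for this workflow). The sharing matrix counts,
#' for each pair of samples, the scaffolds present in both; its diagonal is
#' the per-sample presence count.
#'
#' @param coverage Data frame: `scaffold_id`, `sample_id`, `covered_length`.
#' @param min_covered Strict lower bound on covered length (default 10 kb).
#' @return List: `calls` (the input with a logical `present` column) and
#'   `sharing` (samples x samples integer matrix).
#' @export
presence_calls <- function(coverage, min_covered = 10000L) {
  assert_cols(coverage, c("scaffold_id", "sample_id", "covered_length"),
              "coverage")
  coverage$present <- coverage$covered_length > min_covered
  samples <- sort(unique(coverage$sample_id))
  pres <- coverage[coverage$present, , drop = FALSE]
  inc <- table(factor(pres$scaffold_id),
               factor(pres$sample_id, levels = samples))
  inc <- matrix(as.integer(inc > 0), nrow(inc), ncol(inc),
                dimnames = dimnames(inc))
  sharing <- if (nrow(inc) > 0L) t(inc) %*% inc else
    matrix(0L, length(samples), length(samples),
           dimnames = list(samples, samples))
  storage.mode(sharing) <- "integer"
  list(calls = coverage, sharing = sharing)
}
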