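#' Linear decision boundary for scaffold classification
#'
#' The classifier separates giant-virus scaffolds from cellular ones in the
#' (cellular matches, viral matches) plane with a straight line: a scaffold is
#' called Nucleocytoviricota iff `v > slope * c + intercept`, strictly —
#' points under or on the line are excluded. The published calibration on a
#' control database gives slope 0.1 and intercept 1. In `proportions` mode
#' both counts are first divided by the scaffold's ORF count.
#'
#' @param slope Non-negative slope (viral matches per cellular match).
#' @param intercept Non-negative intercept (viral matches).
#' @param mode `"counts"` (default) or `"proportions"`.
#' @return An object of class `gv_boundary`.
#' @examples
#' decision_boundary(0.1, 1)
#' @export
decision_boundary <- function(slope = 0.1, intercept = 1,
                              mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  if (slope < 0 || intercept < 0) {
    stop_gv("slope and intercept must be non-negative")
  }
  structure(list(slope = slope, intercept = intercept, mode = mode),
            class = "gv_boundary")
}

#' @export
print.gv_boundary <- function(x, ...) {
  cat(sprintf("Decision boundary: viral iff v > %g * c + %g (%s mode)\n",
              x$slope, x$intercept, x$mode))
  invisible(x)
}

# Vector of labels from count vectors; shared by classify/calibrate/evaluate.
classify_counts <- function(v, c_, boundary, n_orfs = NULL) {
  if (any(v < 0) || any(c_ < 0)) stop_gv("evidence counts must be non-negative")
  if (boundary$mode == "proportions") {
    if (is.null(n_orfs)) stop_gv("proportions mode requires n_orfs")
    if (any(n_orfs <= 0)) {
      stop_gv("proportions mode requires n_orfs > 0 for every scaffold")
    }
    v <- v / n_orfs
    c_ <- c_ / n_orfs
  }
  ifelse(v > boundary$slope * c_ + boundary$intercept,
         "nucleocytoviricota", "non_viral")
}

#' Classify scaffolds from evidence counts
#'
#' Applies a [decision_boundary()] to a per-scaffold evidence table. The rule
#' is strict: scaffolds on the line are non-viral.
#'
#' @param evidence Data frame with `viral_orf_count` and
#'   `cellular_match_count` (and `n_orfs` in proportions mode).
#' @param boundary A [decision_boundary()].
#' @return The evidence data frame with a `label` column appended
#'   (`"nucleocytoviricota"` or `"non_viral"`).
#' @examples
#' ev <- data.frame(scaffold_id = c("a", "b"),
#'                  viral_orf_count = c(12, 1),
#'                  cellular_match_count = c(100, 0))
#' classify_scaffolds(ev, decision_boundary(0.1, 1))
#' @export
classify_scaffolds <- function(evidence, boundary = decision_boundary()) {
  assert_cols(evidence, c("viral_orf_count", "cellular_match_count"),
              "evidence")
  evidence$label <- classify_counts(evidence$viral_orf_count,
                                    evidence$cellular_match_count,
                                    boundary, evidence$n_orfs)
  evidence
}

#' Calibrate the decision boundary on a labeled control set
#'
#' Exhaustive grid search over (slope, intercept) pairs. A grid point is
#' feasible when its eukaryotic false-positive rate is strictly below
#' `max_euk_fp` (the published constraint is "less than 1% of false
#' eukaryotic positives", read strictly, so 1 misclassified eukaryote in 100
#' fails at the default). Among feasible points the one maximizing sensitivity
#' is returned; ties are broken towards the more conservative boundary
#' (higher intercept, then higher slope).
#'
#' @param evidence Labeled evidence: columns `viral_orf_count`,
#'   `cellular_match_count`, `truth_class` with values in
#'   `{viral, bacterial, archaeal, eukaryotic}` (at least one viral and one
#'   eukaryotic record).
#' @param slope_grid,intercept_grid Numeric grids searched exhaustively.
#'   Defaults: slope 0 to 0.5 by 0.01, intercept 0 to 10 by 0.5.
#' @param max_euk_fp Strict upper bound on the eukaryotic FP rate.
#' @param mode Boundary mode, passed to [decision_boundary()].
#' @return A list with `boundary` (the selected [decision_boundary()]) and
#'   `report` (the [evaluate_boundary()] performance report on the same set).
#' @examples
#' ev <- data.frame(viral_orf_count = c(10, 8, 0, 0),
#'                  cellular_match_count = c(0, 1, 40, 50),
#'                  truth_class = c("viral", "viral", "eukaryotic",
#'                                  "bacterial"))
#' calibrate_boundary(ev)$boundary
#' @export
calibrate_boundary <- function(evidence,
                               slope_grid = seq(0, 0.5, by = 0.01),
                               intercept_grid = seq(0, 10, by = 0.5),
                               max_euk_fp = 0.01,
                               mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  assert_cols(evidence, c("viral_orf_count", "cellular_match_count",
                          "truth_class"), "evidence")
  if (length(slope_grid) == 0L || length(intercept_grid) == 0L) {
    stop_gv("grids must be non-empty")
  }
  if (max_euk_fp <= 0 || max_euk_fp >= 1) stop_gv("max_euk_fp must be in (0,1)")
  check_labels(evidence$truth_class)
  if (!any(evidence$truth_class == "viral") ||
      !any(evidence$truth_class == "eukaryotic")) {
    stop_gv("calibration requires at least one viral and one eukaryotic record")
  }
  v <- evidence$viral_orf_count
  c_ <- evidence$cellular_match_count
  if (mode == "proportions") {
    assert_cols(evidence, "n_orfs", "evidence")
    if (any(evidence$n_orfs <= 0)) stop_gv("proportions mode requires n_orfs > 0")
    v <- v / evidence$n_orfs
    c_ <- c_ / evidence$n_orfs
  }
  is_viral <- evidence$truth_class == "viral"
  is_euk <- evidence$truth_class == "eukaryotic"
  n_viral <- sum(is_viral)
  n_euk <- sum(is_euk)

  grid <- expand.grid(slope = slope_grid, intercept = intercept_grid,
                      KEEP.OUT.ATTRS = FALSE)
  sens <- numeric(nrow(grid))
  euk_fp <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    called <- v > grid$slope[g] * c_ + grid$intercept[g]
    sens[g] <- sum(called & is_viral) / n_viral
    euk_fp[g] <- sum(called & is_euk) / n_euk
  }
  feasible <- euk_fp < max_euk_fp
  if (!any(feasible)) {
    stop_gv(paste0("no grid point satisfies eukaryotic FP rate < %g; ",
                   "minimal achievable rate on this grid is %g"),
            max_euk_fp, min(euk_fp))
  }
  ord <- order(-sens, -grid$intercept, -grid$slope)
  best <- ord[feasible[ord]][1L]
  boundary <- decision_boundary(grid$slope[best], grid$intercept[best],
                                mode = mode)
  list(boundary = boundary, report = evaluate_boundary(evidence, boundary))
}

known_classes <- c("viral", "bacterial", "archaeal", "eukaryotic")

check_labels <- function(labels) {
  bad <- setdiff(unique(labels), known_classes)
  if (length(bad) > 0L) {
    stop_gv("unknown truth_class label(s): %s", paste(bad, collapse = ", "))
  }
  invisible(TRUE)
}

#' Evaluate a boundary on labeled evidence
#'
#' Sensitivity is the fraction of viral records called viral; one specificity
#' is reported per non-viral class present (the fraction of that class called
#' non-viral). Confusion counts are exact and sum to the input size.
#'
#' @param evidence Labeled evidence (see [calibrate_boundary()]).
#' @param boundary A [decision_boundary()].
#' @return An object of class `gv_performance`: a list with `sensitivity`,
#'   `specificity` (named vector per non-viral class), `confusion` (data frame
#'   of per-class called/not-called counts), and `n`.
#' @export
evaluate_boundary <- function(evidence, boundary) {
  assert_cols(evidence, c("viral_orf_count", "cellular_match_count",
                          "truth_class"), "evidence")
  check_labels(evidence$truth_class)
  labels <- classify_counts(evidence$viral_orf_count,
                            evidence$cellular_match_count, boundary,
                            evidence$n_orfs)
  called <- labels == "nucleocytoviricota"
  cls <- factor(evidence$truth_class, levels = known_classes)
  confusion <- data.frame(
    truth_class = known_classes,
    called_viral = as.integer(table(cls[called])[known_classes]),
    called_non_viral = as.integer(table(cls[!called])[known_classes]),
    stringsAsFactors = FALSE
  )
  confusion[is.na(confusion)] <- 0L
  confusion <- confusion[confusion$called_viral + confusion$called_non_viral > 0
                         | confusion$truth_class %in% evidence$truth_class, ]
  rownames(confusion) <- NULL
  n_viral <- sum(cls == "viral")
  sens <- if (n_viral > 0L) sum(called & cls == "viral") / n_viral else NA_real_
  spec_classes <- setdiff(intersect(known_classes, evidence$truth_class),
                          "viral")
  spec <- vapply(spec_classes, function(k) {
    sum(!called & cls == k) / sum(cls == k)
  }, numeric(1))
  structure(list(sensitivity = sens, specificity = spec,
                 confusion = confusion, n = nrow(evidence)),
            class = "gv_performance")
}

#' @export
print.gv_performance <- function(x, ...) {
  cat(sprintf("Classification performance on %d scaffolds\n", x$n))
  cat(sprintf("  sensitivity: %.4f\n", x$sensitivity))
  for (k in names(x$specificity)) {
    cat(sprintf("  specificity (%s): %.4f\n", k, x$specificity[[k]]))
  }
  invisible(x)
}

#' Apply contamination post-filters
#'
#' Removes classified scaffolds flagged by external contamination checks:
#' ribosomal-RNA detection (a cellular signature) or manual exclusion (e.g.
#' scaffolds re-annotated as intracellular bacteria, phages or other
#' non-target viruses). Endogenization flags only annotate — they never
#' remove. Every removal is logged with its reason.
#'
#' @param classified Data frame with a `scaffold_id` column (typically the
#'   output of [classify_scaffolds()] restricted to viral calls).
#' @param flags Data frame: `scaffold_id`, logical `has_rrna`,
#'   logical `manual_exclusion`, optional `reason`, optional logical
#'   `endogenization_flag`. Flags naming unknown scaffolds trigger a warning.
#' @return List with `kept` (filtered data frame, with an
#'   `endogenization_flag` column appended) and `removed` (data frame
#'   `scaffold_id`, `reason`).
#' @export
apply_post_filters <- function(classified, flags) {
  assert_cols(classified, "scaffold_id", "classified")
  assert_cols(flags, c("scaffold_id", "has_rrna", "manual_exclusion"), "flags")
  if (is.null(flags$reason)) flags$reason <- NA_character_
  if (is.null(flags$endogenization_flag)) flags$endogenization_flag <- FALSE
  unknown <- setdiff(flags$scaffold_id, classified$scaffold_id)
  if (length(unknown) > 0L) {
    warn_gv("flags reference %d scaffold(s) not in the classified set: %s",
            length(unknown), paste(utils::head(unknown, 5L), collapse = ", "))
  }
  i <- match(classified$scaffold_id, flags$scaffold_id)
  has_rrna <- !is.na(i) & flags$has_rrna[i] %in% TRUE
  manual <- !is.na(i) & flags$manual_exclusion[i] %in% TRUE
  drop <- has_rrna | manual
  reason <- character(sum(drop))
  reason_all <- ifelse(has_rrna, "rRNA detected",
                       ifelse(!is.na(i) & !is.na(flags$reason[i]) &
                                nzchar(flags$reason[i]),
                              flags$reason[i], "manual exclusion"))
  removed <- data.frame(scaffold_id = classified$scaffold_id[drop],
                        reason = reason_all[drop],
                        stringsAsFactors = FALSE)
  kept <- classified[!drop, , drop = FALSE]
  kept$endogenization_flag <- (!is.na(i) &
                                 flags$endogenization_flag[i] %in% TRUE)[!drop]
  rownames(kept) <- NULL
  list(kept = kept, removed = removed)
}
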