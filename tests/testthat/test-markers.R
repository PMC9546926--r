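mk_hits <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(scaffold_id = r[[1]], marker_id = r[[2]], orf_id = r[[3]],
               evalue = as.numeric(r[[4]]),
               bitscore = if (length(r) > 4) as.numeric(r[[5]]) else 0,
               stringsAsFactors = FALSE)
  }))
}

test_that("copy ranks are contiguous, E-value ordered and order-invariant", {
  h <- mk_hits(list("s1", "polB", "a", 1e-30, 100),
               list("s1", "polB", "b", 1e-12, 50),
               list("s2", "polB", "c", 1e-8, 30))
  r <- rank_marker_hits(h)
  expect_identical(r$rank[r$orf_id == "a"], 1L)
  expect_identical(r$rank[r$orf_id == "b"], 2L)
  expect_identical(r$rank[r$orf_id == "c"], 1L)

  # equal E-values: tie broken by higher bit score, then orf_id
  tie <- mk_hits(list("s1", "mcp", "x", 1e-10, 40),
                 list("s1", "mcp", "y", 1e-10, 60),
                 list("s1", "mcp", "z", 1e-10, 40))
  rt <- rank_marker_hits(tie)
  expect_identical(rt$orf_id[order(rt$rank)], c("y", "x", "z"))
  withr::with_seed(3, {
    for (i in 1:5) {
      expect_identical(rank_marker_hits(tie[sample(3), ]), rt)
    }
  })

  # hits above the initial cutoff never enter the ranking
  above <- mk_hits(list("s1", "mcp", "w", 1e-3))
  expect_identical(nrow(rank_marker_hits(above)), 0L)

  dup <- mk_hits(list("s1", "d5", "o", 1e-10, 30),
                 list("s1", "d5", "o", 1e-20, 60))
  expect_warning(rd <- rank_marker_hits(dup), "deduplicated")
  expect_identical(nrow(rd), 1L)
  expect_equal(rd$evalue, 1e-20)
})

test_that("stringent threshold is the nearest-rank Q1 of second matches", {
  h <- mk_hits(list("s1", "polB", "a", 1e-50), list("s1", "polB", "b", 1e-40),
               list("s2", "polB", "c", 1e-50), list("s2", "polB", "d", 1e-20),
               list("s3", "polB", "e", 1e-50), list("s3", "polB", "f", 1e-10),
               list("s4", "polB", "g", 1e-50), list("s4", "polB", "h", 1e-8))
  thr <- stringent_thresholds(rank_marker_hits(h))
  # rank-2 E-values {1e-40, 1e-20, 1e-10, 1e-8}: Q1 index ceil(4/4) = 1
  expect_equal(thr$threshold, 1e-40)
  expect_identical(thr$n_second_matches, 4L)

  one <- mk_hits(list("s1", "mcp", "a", 1e-30), list("s1", "mcp", "b", 1e-12))
  t1 <- stringent_thresholds(rank_marker_hits(one))
  expect_equal(t1$threshold, 1e-12)

  none <- mk_hits(list("s1", "vltf3", "a", 1e-30))
  expect_warning(t0 <- stringent_thresholds(rank_marker_hits(none)),
                 "no multi-copy")
  expect_equal(t0$threshold, 1e-5)
})

test_that("nearest-rank quartile equals the sort-and-index oracle", {
  withr::with_seed(17, {
    for (i in 1:200) {
      n <- sample(1:40, 1)
      e2 <- 10^-stats::runif(n, 6, 60)
      h <- data.frame(scaffold_id = sprintf("s%03d", seq_len(n)),
                      marker_id = "polB",
                      orf_id = sprintf("r2_%03d", seq_len(n)),
                      evalue = e2, rank = 2L)
      thr <- stringent_thresholds(h)
      expect_equal(thr$threshold, oracle_q1(e2))
    }
  })
})

test_that("selection keeps best hits strictly better than the threshold", {
  thr <- data.frame(marker_id = "polB", threshold = 1e-20)
  r <- rank_marker_hits(mk_hits(list("s1", "polB", "a", 1e-30),
                                list("s2", "polB", "b", 1e-15),
                                list("s3", "polB", "c", 1e-20)))
  sel <- select_marker_hits(r, thr)
  expect_identical(sel$scaffold_id, "s1")   # 1e-15 fails, 1e-20 on boundary fails
  expect_identical(nrow(sel), 1L)

  # at most one hit per (scaffold, marker)
  multi <- rank_marker_hits(mk_hits(list("s1", "polB", "a", 1e-40),
                                    list("s1", "polB", "b", 1e-35)))
  sel2 <- select_marker_hits(multi, thr)
  expect_identical(nrow(sel2), 1L)
  expect_identical(sel2$orf_id, "a")
})

test_that("relaxing thresholds toward the initial cutoff is monotone", {
  withr::with_seed(31, {
    for (i in 1:20) {
      n <- 60
      h <- data.frame(
        scaffold_id = sample(sprintf("s%02d", 1:15), n, replace = TRUE),
        marker_id = sample(default_marker_set()[1:3], n, replace = TRUE),
        orf_id = sprintf("o%03d", seq_len(n)),
        evalue = 10^-stats::runif(n, 5.1, 50),
        bitscore = stats::runif(n, 20, 200))
      r <- rank_marker_hits(h)
      thr <- stringent_thresholds(r, markers = default_marker_set()[1:3])
      counts <- vapply(c(1, 10, 100, 1e10), function(f) {
        relaxed <- transform(thr, threshold = pmin(threshold * f, 1e-5))
        nrow(select_marker_hits(r, relaxed))
      }, numeric(1))
      expect_true(all(diff(counts) >= 0))
      # thresholds never exceed the initial cutoff
      expect_true(all(thr$threshold <= 1e-5))
    }
  })
})

test_that("marker-count partition nests and matches the stated cutoffs", {
  sel <- data.frame(
    scaffold_id = c("s1", "s1", "s1", "s2", "s3", "s3"),
    marker_id = c("polB", "rnapL", "vltf3", "mcp", "polB", "mcp"),
    orf_id = sprintf("o%d", 1:6), stringsAsFactors = FALSE)
  p <- partition_by_marker_count(sel)
  expect_identical(p$high_confidence, "s1")       # 3 of the 7 markers
  expect_setequal(p$extended, c("s1", "s2", "s3")) # >= 1 marker
  expect_true(all(p$high_confidence %in% p$extended))
  expect_identical(dim(p$presence), c(3L, 7L))
  expect_identical(sum(p$presence), 6L)

  withr::with_seed(8, {
    for (i in 1:20) {
      n <- sample(1:50, 1)
      rsel <- data.frame(
        scaffold_id = sample(sprintf("s%02d", 1:12), n, replace = TRUE),
        marker_id = sample(default_marker_set(), n, replace = TRUE),
        orf_id = sprintf("o%03d", seq_len(n)))
      rp <- partition_by_marker_count(rsel)
      expect_true(all(rp$high_confidence %in% rp$extended))
    }
  })
})

test_that("low-copy profile selection is inclusive at the bound", {
  stats_df <- data.frame(profile_id = c("p1", "p2", "p3"),
                         mean_copies_per_genome = c(1.1, 1.11, 1.0))
  kept <- select_low_copy_profiles(stats_df)
  expect_setequal(kept$profile_id, c("p1", "p3"))
  all_one <- data.frame(profile_id = c("a", "b"),
                        mean_copies_per_genome = 1.0)
  expect_identical(nrow(select_low_copy_profiles(all_one)), 2L)
})

test_that("marker FASTA export is complete, stable and validates inputs", {
  sel <- data.frame(scaffold_id = rep(c("s1", "s2", "s3"), 2),
                    marker_id = rep(c("polB", "mcp"), each = 3),
                    orf_id = sprintf("o%d", 1:6), stringsAsFactors = FALSE)
  prot <- Biostrings::AAStringSet(stats::setNames(
    strrep(c("M", "A", "C", "D", "E", "F"), 60), sprintf("o%d", 1:6)))
  dir <- withr::local_tempdir()
  paths <- export_marker_sets(sel, prot, dir)
  expect_identical(sort(names(paths)), c("mcp", "polB"))
  polb <- Biostrings::readAAStringSet(paths[["polB"]])
  expect_identical(length(polb), 3L)
  expect_identical(names(polb)[1], "s1|polB|o1")
  # stable record order across runs
  paths2 <- export_marker_sets(sel[sample(6), ], prot, withr::local_tempdir())
  expect_identical(names(Biostrings::readAAStringSet(paths2[["polB"]])),
                   names(polb))

  expect_error(export_marker_sets(sel, prot[1:3], dir), "no protein sequence")
  expect_message(out <- export_marker_sets(sel[0, ], prot, dir),
                 "nothing to export")
  expect_length(out, 0)
})
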