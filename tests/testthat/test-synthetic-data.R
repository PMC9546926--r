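test_that("shredding cuts non-overlapping in-bound fragments, deterministically", {
  g <- data.frame(genome_id = "gA", class_label = "viral", seq_length = 100000L)
  d <- length_dist_spec(min_len = 10000L, max_len = 200000L)
  sc <- shred_genomes(g, d, seed = 7)

  # pigeonhole: at most 10 contigs of >= 10 kb fit in 100 kb
  expect_lte(nrow(sc$contigs), 10L)
  expect_lte(sum(sc$contigs$length), 100000L)
  expect_true(all(sc$contigs$length >= d$min_len &
                    sc$contigs$length <= d$max_len))
  expect_true(all(sc$contigs$truth_class == "viral"))

  # exhaustive interval-overlap check on the source genome
  seg <- sc$segments[order(sc$segments$start), ]
  expect_true(all(seg$end[-nrow(seg)] <= seg$start[-1]))
  expect_true(all(seg$end <= 100000L))

  sc2 <- shred_genomes(g, d, seed = 7)
  expect_identical(sc, sc2)
  sc3 <- shred_genomes(g, d, seed = 8)
  expect_false(identical(sc$contigs$length, sc3$contigs$length))
})

test_that("genomes shorter than min_len yield no contigs, with a warning", {
  g <- data.frame(genome_id = "tiny", class_label = "bacterial",
                  seq_length = 9999L)
  expect_warning(sc <- shred_genomes(g, length_dist_spec(), seed = 1),
                 "shorter than min_len")
  expect_identical(nrow(sc$contigs), 0L)
})

test_that("chimera planting preserves counts and sets truthful flags", {
  g <- data.frame(genome_id = c("gA", "gB", "gC"),
                  class_label = c("viral", "bacterial", "eukaryotic"),
                  seq_length = 500000L)
  sc <- shred_genomes(g, length_dist_spec(), seed = 3)

  same <- plant_chimeras(sc, rate = 0, seed = 1)
  expect_identical(same, sc)
  expect_false(any(same$contigs$is_chimera))

  all_ch <- plant_chimeras(sc, rate = 1, seed = 5)
  expect_identical(nrow(all_ch$contigs), nrow(sc$contigs))
  multi <- tapply(all_ch$segments$genome_id, all_ch$segments$contig_id,
                  function(x) length(unique(x)))
  # flags recoverable from segment provenance: chimera <=> >= 2 genomes
  expect_identical(as.vector(multi[all_ch$contigs$contig_id] >= 2L),
                   all_ch$contigs$is_chimera)
  expect_true(all(all_ch$contigs$is_chimera))

  # planted lengths conserved
  seg_len <- tapply(all_ch$segments$end - all_ch$segments$start,
                    all_ch$segments$contig_id, sum)
  expect_identical(as.integer(unname(seg_len[all_ch$contigs$contig_id])),
                   all_ch$contigs$length)

  one <- shred_genomes(g[1, ], length_dist_spec(), seed = 3)
  expect_error(plant_chimeras(one, rate = 0.5, seed = 1),
               "two distinct source genomes")
})

test_that("planted chimera count lands inside the exact binomial CI", {
  g <- data.frame(genome_id = sprintf("g%02d", 1:13),
                  class_label = "bacterial", seq_length = 800000L)
  d <- length_dist_spec(family = "empirical", lengths = 10000L)
  sc <- shred_genomes(g, d, seed = 11)
  expect_gte(nrow(sc$contigs), 1000L)
  sc$contigs <- sc$contigs[1:1000, ]
  sc$segments <- sc$segments[sc$segments$contig_id %in% sc$contigs$contig_id, ]
  planted <- plant_chimeras(sc, rate = 0.05, seed = 1)
  ci <- stats::qbinom(c(0.025, 0.975), 1000, 0.05)
  n_ch <- sum(planted$contigs$is_chimera)
  expect_gte(n_ch, ci[1])
  expect_lte(n_ch, ci[2])
})

test_that("hit counts follow the class rates and the seed contract", {
  ctg <- data.frame(contig_id = sprintf("c%05d", 1:10000), length = 10000L,
                    truth_class = "viral", stringsAsFactors = FALSE)
  model <- hit_count_model()
  ev <- simulate_hit_counts(ctg, model, seed = 2)
  expect_true(all(ev$viral_orf_count >= 0 & ev$viral_orf_count %% 1 == 0))

  # law of large numbers: mean within 3 SE of rate * length (Poisson)
  mu_v <- 0.5 * 10   # 5 per 10 kb
  mu_c <- 0.1 * 10   # 1 per 10 kb
  expect_lt(abs(mean(ev$viral_orf_count) - mu_v), 3 * sqrt(mu_v / 10000))
  expect_lt(abs(mean(ev$cellular_match_count) - mu_c), 3 * sqrt(mu_c / 10000))

  expect_identical(ev, simulate_hit_counts(ctg, model, seed = 2))

  zero <- hit_count_model(data.frame(class_label = "viral", viral_rate = 0,
                                     cellular_rate = 1))
  ev0 <- simulate_hit_counts(ctg[1:100, ], zero, seed = 1)
  expect_true(all(ev0$viral_orf_count == 0))

  expect_error(
    simulate_hit_counts(transform(ctg[1:5, ], truth_class = "fungal"), model),
    "fungal")
})

test_that("overdispersed counts vary more than Poisson at the same mean", {
  ctg <- data.frame(contig_id = sprintf("c%04d", 1:5000), length = 10000L,
                    truth_class = "eukaryotic", stringsAsFactors = FALSE)
  pois <- simulate_hit_counts(ctg, hit_count_model(dispersion = Inf), seed = 4)
  nb <- simulate_hit_counts(ctg, hit_count_model(dispersion = 2), seed = 4)
  expect_gt(stats::var(nb$cellular_match_count),
            stats::var(pois$cellular_match_count))
})

test_that("abundance generator plants monotone associations", {
  taxa <- c("pitho1", "amoeba1", "alga1", "fungus1")
  perfect <- simulate_abundance_matrix(
    n_samples = 11, taxa = taxa,
    planted_pairs = data.frame(virus = "pitho1", euk = "amoeba1",
                               strength = 1),
    seed = 9)
  expect_identical(rank(perfect[, "pitho1"]), rank(perfect[, "amoeba1"]))
  expect_true(all(perfect >= 0))
  expect_identical(dim(perfect), c(11L, 4L))

  neg <- simulate_abundance_matrix(
    n_samples = 11, taxa = taxa,
    planted_pairs = data.frame(virus = "pitho1", euk = "amoeba1",
                               strength = -1),
    seed = 9)
  expect_identical(rank(neg[, "pitho1"]), 12 - rank(neg[, "amoeba1"]))

  expect_error(simulate_abundance_matrix(taxa = c("a", "a"), seed = 1),
               "duplicate")
  expect_error(simulate_abundance_matrix(n_samples = 2, taxa = "a", seed = 1),
               "n_samples")
})

test_that("unplanted pairs behave as independent (permutation oracle)", {
  # empirical mean |rho| of strength-0 pairs over replicates vs the exact
  # permutation expectation of |rho| at n = 11 (Monte Carlo over rank perms)
  n <- 11L
  reps <- 500
  obs <- vapply(seq_len(reps), function(i) {
    m <- simulate_abundance_matrix(n_samples = n, taxa = c("v", "e"),
                                   planted_pairs = NULL, seed = 1000 + i)
    abs(stats::cor(m[, "v"], m[, "e"], method = "spearman"))
  }, numeric(1))
  null_dist <- withr::with_seed(42, {
    vapply(seq_len(20000), function(i) {
      abs(stats::cor(seq_len(n), sample(n), method = "spearman"))
    }, numeric(1))
  })
  se <- sqrt(stats::var(obs) / reps + stats::var(null_dist) / 20000)
  expect_lt(abs(mean(obs) - mean(null_dist)), 3 * se)
})

test_that("truth alignments reconstruct contig coordinates", {
  g <- data.frame(genome_id = c("gA", "gB"),
                  class_label = c("viral", "bacterial"),
                  seq_length = 300000L)
  sc <- plant_chimeras(shred_genomes(g, length_dist_spec(), seed = 2),
                       rate = 1, seed = 3)
  al <- truth_alignments(sc)
  spans <- tapply(al$qend, al$query_id, max)
  expect_identical(as.integer(unname(spans[sc$contigs$contig_id])),
                   sc$contigs$length)
  expect_true(all(al$qstart >= 1))
})

test_that("simulated contigs round-trip through FASTA and truth tables", {
  g <- simulate_source_genomes(c(viral = 1, bacterial = 1),
                               genome_length = 40000L, seed = 5)
  sc <- shred_genomes(g, length_dist_spec(min_len = 5000L, max_len = 20000L),
                      seed = 5)
  dir <- withr::local_tempdir()
  paths <- write_sim_contigs(sc, dir, seed = 5)
  fa <- Biostrings::readDNAStringSet(paths[["fasta"]])
  expect_identical(names(fa), sc$contigs$contig_id)
  expect_identical(unname(Biostrings::width(fa)), sc$contigs$length)
  back <- read_tsv_table(paths[["contigs"]])
  expect_identical(back$contig_id, sc$contigs$contig_id)
  expect_identical(back$length, sc$contigs$length)
  # sequences really come from the annotated source interval
  s1 <- sc$segments[1, ]
  expect_identical(as.character(fa[[s1$contig_id]]),
                   substr(g$sequence[g$genome_id == s1$genome_id],
                          s1$start + 1, s1$end))
})
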