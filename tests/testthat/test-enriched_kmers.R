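# constructed table: one K-mer across 3 equal-length chromosomes
three_chrom_table <- function(counts, L = 10012) {
  make_kmer_table(
    13,
    data.frame(kmer = "ACCCGGGTTTAAA", chrom = paste0("c", 1:3),
               count = counts)[counts > 0, ],
    setNames(rep(L, 3), paste0("c", 1:3)))
}

test_that("select_enriched applies both conditions", {
  p <- enrichment_params(min_global = 100, fold = 2, baseline = "max_other",
                         normalize = "raw")
  e1 <- select_enriched(three_chrom_table(c(100, 10, 10)), p)
  expect_equal(nrow(e1$entries), 1L)
  expect_identical(e1$entries$chrom, "c1")
  expect_equal(e1$entries$fold, 10)    # 100 / max(10, 10)
  expect_equal(e1$entries$global, 120)

  # 50 < 2 * 40: rejected under max_other
  p2 <- enrichment_params(min_global = 100, fold = 2,
                          baseline = "max_other", normalize = "raw")
  expect_equal(nrow(select_enriched(three_chrom_table(c(50, 40, 10)),
                                    p2)$entries), 0L)
  # but 50 >= 2 * mean(40, 10) = 50 under mean_other
  p3 <- enrichment_params(min_global = 100, fold = 2,
                          baseline = "mean_other", normalize = "raw")
  expect_equal(nrow(select_enriched(three_chrom_table(c(50, 40, 10)),
                                    p3)$entries), 1L)

  # global threshold dominates any distribution
  p4 <- enrichment_params(min_global = 1000, fold = 2,
                          baseline = "max_other", normalize = "raw")
  expect_equal(nrow(select_enriched(three_chrom_table(c(999, 0, 0)),
                                    p4)$entries), 0L)
  # baseline 0 gives infinite fold
  e5 <- select_enriched(three_chrom_table(c(120, 0, 0)), p)
  expect_equal(e5$entries$fold, Inf)

  single <- make_kmer_table(13, data.frame(kmer = "ACCCGGGTTTAAA",
                                           chrom = "c1", count = 5),
                            c(c1 = 1000))
  expect_error(select_enriched(single, p), "single chromosome")
})

test_that("profile matrix has argmax on the assigned chromosome", {
  g <- simulate_polyploid_genome(sim_config("auto", n_groups = 2, seed = 8))
  tab <- count_kmers_assembly(g, 13)
  enr <- select_enriched(tab, enrichment_params(min_global = 100, fold = 2,
                                                baseline = "mean_other"))
  prof <- build_profile_matrix(tab, enr)
  expect_identical(rownames(prof), names(g$seqs))
  expect_identical(colnames(prof), sort(enr$entries$kmer))
  assigned <- setNames(enr$entries$chrom, enr$entries$kmer)
  argmax <- rownames(prof)[apply(prof, 2, which.max)]
  expect_identical(unname(assigned[colnames(prof)]), argmax)

  # raw and density differ exactly by the effective-length factors
  enr_raw <- select_enriched(tab, enrichment_params(
    min_global = 100, fold = 2, baseline = "mean_other", normalize = "raw"))
  prof_raw <- build_profile_matrix(tab, enr_raw)
  eff <- nchar(g$seqs) - 13 + 1
  common <- intersect(colnames(prof), colnames(prof_raw))
  expect_equal(prof_raw[, common] / eff[rownames(prof_raw)],
               prof[, common])

  empty <- structure(list(entries = data.frame(), params = enr$params),
                     class = "enriched_kmers")
  expect_error(build_profile_matrix(tab, empty), "insufficient markers")
})

test_that("selection is invariant to chromosome input order", {
  g <- simulate_polyploid_genome(sim_config("auto", n_groups = 2, seed = 9))
  tab1 <- count_kmers_assembly(g$seqs, 13)
  set.seed(1)
  perm <- sample(names(g$seqs))
  tab2 <- count_kmers_assembly(g$seqs[perm], 13)
  p <- enrichment_params(min_global = 100, fold = 2,
                         baseline = "mean_other")
  e1 <- select_enriched(tab1, p)
  e2 <- select_enriched(tab2, p)
  expect_equal(e1$entries, e2$entries)
  m1 <- build_profile_matrix(tab1, e1)
  m2 <- build_profile_matrix(tab2, e2)
  expect_equal(m1, m2[rownames(m1), ])
})

test_that("raising fold or min_global never adds a K-mer", {
  g <- simulate_polyploid_genome(sim_config("auto", n_groups = 2,
                                            chrom_len = 20000,
                                            repeat_copies = 60, seed = 10))
  tab <- count_kmers_assembly(g, 13)
  for (base in c("max_other", "mean_other")) {
    loose <- select_enriched(tab, enrichment_params(40, 2, base))$entries
    tighter_fold <- select_enriched(tab, enrichment_params(40, 3, base))$entries
    tighter_glob <- select_enriched(tab, enrichment_params(80, 2, base))$entries
    expect_true(all(tighter_fold$kmer %in% loose$kmer))
    expect_true(all(tighter_glob$kmer %in% loose$kmer))
  }
})

test_that("selected K-mers concentrate in the repeat's home group (auto)", {
  g <- simulate_polyploid_genome(sim_config("auto", seed = 12))
  tab <- count_kmers_assembly(g, 13)
  enr <- select_enriched(tab, enrichment_params(min_global = 150, fold = 2,
                                                baseline = "mean_other"))
  expect_gt(nrow(enr$entries), 50)
  lab <- g$labels
  cnt <- merge(as.data.frame(tab$counts[kmer %in% enr$entries$kmer]), lab,
               by = "chrom")
  agg <- aggregate(count ~ kmer + group, cnt, sum)
  for (i in seq_len(nrow(enr$entries))) {
    km <- enr$entries$kmer[i]
    home <- lab$group[lab$chrom == enr$entries$chrom[i]]
    x <- agg[agg$kmer == km, ]
    # the assigned chromosome's group carries the bulk of all occurrences
    expect_gte(x$count[x$group == home], 0.8 * sum(x$count))
  }
})

test_that("small-genome selection equals the exhaustive oracle", {
  g <- simulate_polyploid_genome(sim_config(
    "auto", n_groups = 2, chrom_len = 10000, repeat_copies = 30, seed = 13))
  tab <- count_kmers_assembly(g, 13)
  for (base in c("max_other", "mean_other")) {
    got <- select_enriched(tab, enrichment_params(20, 2, base))$entries
    want <- oracle_select_enriched(g$seqs, 13, 20, 2, base)
    expect_identical(got$kmer, want$kmer)
    expect_identical(got$chrom, want$chrom)
    expect_equal(got$global, want$global)
  }
})
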