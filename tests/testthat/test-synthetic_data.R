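test_that("sim_config validates its invariants", {
  expect_error(sim_config("auto", n_haplotypes = 2), "tetraploid")
  expect_error(sim_config("diploid", n_haplotypes = 4), "diploid")
  expect_error(sim_config("allo", d_hap = 0.06, d_sub = 0.05), "allo mode")
  expect_error(sim_config("auto", chrom_len = 1000, repeat_len = 200),
               "chrom_len")
  expect_error(sim_config("auto", chrom_len = 2000, repeat_len = 200,
                          repeat_copies = 150), "fit")
})

test_that("auto-mode genomes have the advertised shape and divergence", {
  cfg <- sim_config("auto", n_groups = 2, chrom_len = 50000, d_hap = 0.01,
                    seed = 11)
  g <- simulate_polyploid_genome(cfg)
  expect_length(g$seqs, 8L)
  expect_true(all(nchar(g$seqs) == 50000L))
  expect_equal(as.integer(table(g$labels$group)), c(4L, 4L))

  # pairwise mismatch between two haplotypes of one group:
  # p = 2 d (1 - d) + (2/3) d^2 ~= 2 d; assert within 4 binomial SDs
  a <- strsplit(g$seqs[["g1_h1"]], "")[[1]]
  b <- strsplit(g$seqs[["g1_h2"]], "")[[1]]
  p_obs <- mean(a != b)
  p_exp <- 2 * 0.01 * (1 - 0.01) + (2 / 3) * 0.01^2
  se <- sqrt(p_exp * (1 - p_exp) / 50000)
  expect_lt(abs(p_obs - p_exp), 4 * se)
})

test_that("within-group distances are below between-group distances (auto)", {
  g <- simulate_polyploid_genome(sim_config("auto", n_groups = 2, seed = 3))
  mismatch <- function(x, y) {
    mean(strsplit(x, "")[[1]] != strsplit(y, "")[[1]])
  }
  lab <- g$labels
  ids <- lab$chrom
  within <- c(); between <- c()
  for (i in seq_along(ids)) for (j in seq_along(ids)) {
    if (i >= j) next
    m <- mismatch(g$seqs[[ids[i]]], g$seqs[[ids[j]]])
    if (lab$group[i] == lab$group[j]) within <- c(within, m)
    else between <- c(between, m)
  }
  expect_lt(max(within), min(between))
})

test_that("allo-mode subgenome repeats are subgenome-wide and denser there", {
  g <- simulate_polyploid_genome(sim_config("allo", n_groups = 3, seed = 5))
  tab <- count_kmers_assembly(g, 13)
  enr <- select_enriched(tab, enrichment_params(min_global = 100, fold = 2,
                                                baseline = "mean_other"))
  expect_gt(nrow(enr$entries), 0)
  lab <- g$labels
  counts <- merge(as.data.frame(tab$counts[kmer %in% enr$entries$kmer]),
                  lab, by = "chrom")
  for (km in unique(counts$kmer)[1:25]) {
    x <- counts[counts$kmer == km, ]
    home <- lab$subgenome[match(
      enr$entries$chrom[enr$entries$kmer == km], lab$chrom)]
    dens_home <- sum(x$count[x$subgenome == home])
    dens_away <- sum(x$count[x$subgenome != home])
    # present on every chromosome of the home subgenome
    expect_setequal(unique(x$chrom[x$subgenome == home]),
                    lab$chrom[lab$subgenome == home])
    expect_gte(dens_home, 2 * max(dens_away, 1))
  }
})

test_that("identical config and seed reproduce byte-identical FASTA", {
  cfg <- sim_config("auto", n_groups = 1, seed = 7)
  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_fasta(simulate_polyploid_genome(cfg)$seqs, f1)
  write_fasta(simulate_polyploid_genome(cfg)$seqs, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("simulate_reads honours count, determinism and purity", {
  g <- simulate_polyploid_genome(sim_config("auto", n_groups = 1, seed = 2))
  reads <- simulate_reads(g, coverage = 5, read_len = 100, error_rate = 0,
                          seed = 2)
  # round(cov * L / read_len) reads per chromosome
  expect_equal(nrow(reads), 4L * round(5 * 50000 / 100))
  # error 0: every read is a substring of some chromosome (either strand)
  genome_cat <- paste(c(g$seqs, revcomp(g$seqs)), collapse = "|")
  idx <- sample(nrow(reads), 25)
  expect_true(all(vapply(reads$seq[idx], function(s)
    grepl(s, genome_cat, fixed = TRUE), logical(1))))
  # determinism
  reads2 <- simulate_reads(g, coverage = 5, read_len = 100, error_rate = 0,
                           seed = 2)
  expect_identical(reads, reads2)
  expect_error(simulate_reads(g, read_len = 60000), "read_len")
})

test_that("simulate_vcf truth matches independent re-derivation", {
  sim <- simulate_vcf(n_records = 300, n_samples = 6, seed = 11)
  vs <- intersect_callsets(sim$a, sim$b)
  params <- filter_params(repeat_mask = sim$mask)
  pass_oracle <- oracle_filter(vs, params)
  truth_kept <- sim$truth$removed_by == "pass"
  key_surv <- paste(vs$records$chrom[pass_oracle], vs$records$pos[pass_oracle])
  key_truth <- paste(sim$truth$chrom[truth_kept], sim$truth$pos[truth_kept])
  expect_setequal(key_surv, key_truth)
  # rule-1 truth is exactly the a-minus-b difference
  expect_equal(sum(sim$truth$removed_by == "rule1"),
               n_variants(sim$a) - n_variants(vs))
})

test_that("constructed defects are marked by the expected rule", {
  sim <- simulate_vcf(n_records = 400, n_samples = 8, seed = 21,
                      frac_only_in_a = 0, frac_multiallelic = 0,
                      frac_high_missing = 0, frac_in_repeat = 0,
                      frac_close_pair = 0, frac_low_depth = 0.2,
                      frac_high_depth = 0, frac_depth_unknown = 0)
  low <- !is.na(sim$a$records$depth) & sim$a$records$depth < 5
  expect_true(all(sim$truth$removed_by[low] == "rule2"))
  expect_true(all(sim$truth$removed_by[!low] == "pass"))

  sim2 <- simulate_vcf(n_records = 400, seed = 22, frac_only_in_a = 0,
                       frac_low_depth = 0, frac_high_depth = 0,
                       frac_depth_unknown = 0, frac_multiallelic = 0,
                       frac_high_missing = 0, frac_in_repeat = 0,
                       frac_close_pair = 0.3)
  r6 <- sim2$truth$removed_by == "rule6"
  pos <- sim2$a$records$pos; ch <- sim2$a$records$chrom
  for (i in which(r6)[1:10]) {
    expect_true(any(ch == ch[i] & abs(pos - pos[i]) < 5 &
                      seq_along(pos) != i))
  }
})
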