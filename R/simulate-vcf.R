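#' Simulate a variant call set exercising the hard-filter cascade
#'
#' Generates a primary call set `a`, a secondary call set `b` (for the
#' two-pipeline intersection rule), a repeat mask, and a truth table naming
#' the first cascade rule that removes each record of `a` (or `"pass"`).
#' Records are seeded with controlled defect fractions: depth outliers,
#' unknown depth, multi-allelic sites, high missingness, repeat overlap and
#' close-position pairs. The truth is evaluated on the *generated* data (a
#' record may carry several defects; the first failing rule in cascade
#' order wins), with proximity neighbors drawn from the records surviving
#' the intersection rule, matching [apply_filters()] semantics.
#'
#' @param n_records Number of records in call set `a`.
#' @param n_samples Samples per record (genotypes `0/1` or missing `./.`).
#' @param chroms Chromosome names.
#' @param chrom_len Chromosome length (bp) positions are drawn from.
#' @param frac_only_in_a Fraction of `a` absent from `b` (rule 1).
#' @param frac_low_depth,frac_high_depth,frac_depth_unknown Depth defect
#'   fractions (rule 2).
#' @param frac_multiallelic Fraction with two ALT alleles (rule 3).
#' @param frac_high_missing Fraction with missing rate above the threshold
#'   (rule 4).
#' @param frac_in_repeat Fraction placed inside the emitted repeat mask
#'   (rule 5).
#' @param frac_close_pair Fraction of records participating in a
#'   `< min_spacing` bp pair (rule 6; counts both members).
#' @param params A [filter_params()] supplying the thresholds.
#' @param seed Integer seed.
#' @return List with elements `a`, `b` ([variant_set()]s), `mask`
#'   ([interval_set()]), `truth` (data.frame `chrom`, `pos`, `removed_by`)
#'   and `params`.
#' @export
simulate_vcf <- function(n_records = 1000L, n_samples = 8L,
                         chroms = c("chr1", "chr2"), chrom_len = 1000000L,
                         frac_only_in_a = 0.10, frac_low_depth = 0.08,
                         frac_high_depth = 0.05, frac_depth_unknown = 0.03,
                         frac_multiallelic = 0.08, frac_high_missing = 0.08,
                         frac_in_repeat = 0.10, frac_close_pair = 0.10,
                         params = filter_params(), seed = 1L) {
  stopifnot(n_records >= 10L, n_samples >= 1L)
  fr <- c(frac_only_in_a, frac_low_depth, frac_high_depth,
          frac_depth_unknown, frac_multiallelic, frac_high_missing,
          frac_in_repeat, frac_close_pair)
  if (any(fr < 0) || any(fr > 0.5)) stop("defect fractions must be in [0, 0.5]")
  set.seed(seed)
  n_pair <- as.integer(round(frac_close_pair * n_records / 2))
  n_anchor <- n_records - n_pair
  bases <- c("A", "C", "G", "T")

  # well-separated anchor positions per chromosome, partners appended later
  chrom_of <- sample(chroms, n_anchor, replace = TRUE)
  grid_by <- 4L * params$min_spacing
  pos <- integer(n_anchor)
  for (ch in chroms) {
    sel <- chrom_of == ch
    pos[sel] <- sort(sample(seq(grid_by, chrom_len - grid_by, by = grid_by),
                            sum(sel))) + sample(0:(params$min_spacing - 1L),
                                                sum(sel), replace = TRUE)
  }
  pair_anchor <- sample.int(n_anchor, n_pair)
  chrom_of <- c(chrom_of, chrom_of[pair_anchor])
  pos <- c(pos, pos[pair_anchor] +
             sample.int(params$min_spacing - 1L, n_pair, replace = TRUE))
  n <- length(pos)

  depth <- as.integer(round(stats::runif(n, 20, 200)))
  defect <- function(f) sample(c(TRUE, FALSE), n, replace = TRUE,
                               prob = c(f, 1 - f))
  low <- defect(frac_low_depth)
  high <- !low & defect(frac_high_depth)
  unknown <- !low & !high & defect(frac_depth_unknown)
  depth[low] <- sample(0:(params$depth_min - 1L), sum(low), replace = TRUE)
  depth[high] <- as.integer(round(stats::runif(sum(high), params$depth_max + 1,
                                               5 * params$depth_max)))
  depth[unknown] <- NA_integer_

  ref <- sample(bases, n, replace = TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  multi <- defect(frac_multiallelic)
  alt[multi] <- vapply(ref[multi], function(r)
    paste(sample(setdiff(bases, r), 2L), collapse = ","), character(1))

  hi_miss <- defect(frac_high_missing)
  max_ok <- floor(params$max_missing * n_samples)
  n_miss <- ifelse(hi_miss,
                   pmin(n_samples,
                        ceiling((params$max_missing + 0.01) * n_samples) +
                          sample(0:(n_samples %/% 3), n, replace = TRUE)),
                   pmin(max_ok, stats::rbinom(n, n_samples, 0.05)))
  gt <- matrix("0/1", nrow = n, ncol = n_samples)
  for (i in which(n_miss > 0L)) {
    gt[i, sample.int(n_samples, n_miss[i])] <- "./."
  }

  in_rep <- defect(frac_in_repeat)
  mask_df <- data.frame(chrom = chrom_of[in_rep],
                        start = pmax(0L, pos[in_rep] - 2L),
                        end = pos[in_rep] + 1L)
  mask <- interval_set(mask_df)

  only_a <- defect(frac_only_in_a)

  o <- order(chrom_of, pos)
  rec <- data.frame(chrom = chrom_of, pos = pos, ref = ref, alt = alt,
                    depth = depth, stringsAsFactors = FALSE)[o, ]
  rownames(rec) <- NULL
  gt <- gt[o, , drop = FALSE]
  only_a <- only_a[o]
  a <- variant_set(rec, gt, sprintf("S%02d", seq_len(n_samples)))
  b_rec <- rec[!only_a, , drop = FALSE]
  rownames(b_rec) <- NULL
  b <- variant_set(b_rec, gt[!only_a, , drop = FALSE], a$samples)

  # truth: first failing rule in cascade order; proximity neighbors are the
  # records surviving the intersection (rule 1)
  miss_frac <- rowSums(gt == "./.") / n_samples
  r2 <- is.na(rec$depth) | rec$depth < params$depth_min |
    rec$depth > params$depth_max
  r3 <- lengths(strsplit(rec$alt, ",", fixed = TRUE)) != 1L
  r4 <- miss_frac > params$max_missing
  r5 <- interval_contains(mask, rec$chrom, rec$pos)
  kept <- !only_a
  r6 <- vapply(seq_len(n), function(i) {
    if (!kept[i]) return(FALSE)
    any(kept & rec$chrom == rec$chrom[i] &
          abs(rec$pos - rec$pos[i]) < params$min_spacing &
          seq_len(n) != i)
  }, logical(1))
  removed_by <- rep("pass", n)
  removed_by[r6] <- "rule6"
  removed_by[r5] <- "rule5"
  removed_by[r4] <- "rule4"
  removed_by[r3] <- "rule3"
  removed_by[r2] <- "rule2"
  removed_by[only_a] <- "rule1"
  truth <- data.frame(chrom = rec$chrom, pos = rec$pos,
                      removed_by = removed_by, stringsAsFactors = FALSE)
  list(a = a, b = b, mask = mask, truth = truth, params = params)
}
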