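#' Extract heterozygous K-mer pairs from a read K-mer table
#'
#' Considers K-mers whose read count lies in `[L, U]`, groups them by the
#' sequence obtained by masking one position (the middle position for
#' `pairing = "middle_only"`, every position for `"any_position"`),
#' orientation-canonicalized, and emits one pair for every mask family
#' containing exactly two members. Within a pair the dominant member `A`
#' has the higher count; on count ties the lexicographically smaller K-mer
#' is `A` and the minor fraction is 0.5.
#'
#' @param read_table `kmer_table` with `source = "reads"`.
#' @param L,U Inclusive coverage bounds, `1 <= L < U`. `L` should sit above
#'   the sequencing-error band, `U` below the repeat band.
#' @param pairing `"middle_only"` (default, the established convention) or
#'   `"any_position"`.
#' @return data.table of class `kmer_pairs`: `kmerA`, `kmerB`, `covA`,
#'   `covB`, `total`, `minor_fraction`.
#' @export
find_het_pairs <- function(read_table, L = 10, U = 1000,
                           pairing = c("middle_only", "any_position")) {
  pairing <- match.arg(pairing)
  stopifnot(inherits(read_table, "kmer_table"))
  if (L >= U) stop("require L < U")
  if (L < 1) stop("require L >= 1")
  k <- read_table$k
  tab <- read_table$counts[count >= L & count <= U]
  positions <- if (pairing == "middle_only") (k + 1L) %/% 2L else seq_len(k)
  parts <- vector("list", length(positions))
  for (pi in seq_along(positions)) {
    p <- positions[pi]
    keys <- .cpp_pair_keys(tab$kmer, p)
    dt <- data.table::data.table(kmer = tab$kmer, count = tab$count,
                                 key_ = keys)
    fam <- dt[, .N, by = key_][N == 2L]
    dt <- dt[dt$key_ %in% fam$key_]
    if (nrow(dt) == 0L) next
    data.table::setorder(dt, key_, -count, kmer)
    odd <- seq(1L, nrow(dt), by = 2L)
    parts[[pi]] <- data.table::data.table(
      kmerA = dt$kmer[odd], kmerB = dt$kmer[odd + 1L],
      covA = dt$count[odd], covB = dt$count[odd + 1L])
  }
  pairs <- data.table::rbindlist(parts)
  if (nrow(pairs) > 0L) {
    pairs <- unique(pairs)
    pairs[, total := covA + covB]
    pairs[, minor_fraction := covB / total]
    data.table::setorder(pairs, kmerA, kmerB)
  } else {
    pairs <- data.table::data.table(
      kmerA = character(0), kmerB = character(0), covA = numeric(0),
      covB = numeric(0), total = numeric(0), minor_fraction = numeric(0))
  }
  class(pairs) <- c("kmer_pairs", class(pairs))
  pairs
}

# Pattern grid (n, b): total copy number n in [2, max_n], minor copies b in
# [1, floor(n/2)]; a pattern sits at (n * c, b / n).
pattern_grid <- function(max_n = 8L) {
  g <- do.call(rbind, lapply(2:max_n, function(n)
    data.frame(n = n, b = seq_len(n %/% 2L))))
  g$name <- paste0(strrep("A", g$n - g$b), strrep("B", g$b))
  g
}

# Scaled distance of pairs to one pattern point at coverage c.
pattern_distance <- function(total, f, n, b, c) {
  pmax(abs(total - n * c) / (n * c), abs(f - b / n) / (b / n))
}

#' Estimate the 1x (haploid) coverage from heterozygous pairs
#'
#' Scans a grid of candidate coverages and scores each by the fraction of
#' pairs lying within relative tolerance `tol` of some pattern point
#' `(n * c, b / n)` with `n <= max_n`, weighting each captured pair by
#' `1 / n` of its best pattern. The parsimony weight resolves the scaling
#' degeneracy whereby any `c / m` explains the same pairs at inflated copy
#' number; remaining ties go to the smaller candidate.
#'
#' @param pairs A [find_het_pairs()] result with at least 100 pairs.
#' @param c_grid Numeric vector of candidate coverages; defaults to a
#'   0.25-step grid spanning `median(total)/max_n` to `median(total)`.
#' @param tol Relative tolerance (default 0.2).
#' @param max_n Largest copy number considered (default 8).
#' @return Estimated coverage `c_hat` (numeric scalar).
#' @export
estimate_1x_coverage <- function(pairs, c_grid = NULL, tol = 0.2,
                                 max_n = 8L) {
  if (nrow(pairs) < 100L) {
    stop("too few pairs for coverage estimation (need >= 100, got ",
         nrow(pairs), ")")
  }
  med <- stats::median(pairs$total)
  if (is.null(c_grid)) {
    c_grid <- seq(max(2, floor(med / max_n / 2)), ceiling(med),
                  by = 0.25)
  }
  grid <- pattern_grid(max_n)
  best_score <- -Inf
  c_hat <- NA_real_
  for (c0 in sort(c_grid)) {
    w <- rep(0, nrow(pairs))
    d_best <- rep(Inf, nrow(pairs))
    for (i in seq_len(nrow(grid))) {
      d <- pattern_distance(pairs$total, pairs$minor_fraction,
                            grid$n[i], grid$b[i], c0)
      upd <- d < d_best
      d_best[upd] <- d[upd]
      w[upd] <- 1 / grid$n[i]
    }
    score <- sum(w[d_best <= tol]) / nrow(pairs)
    if (score > best_score + 1e-12) {  # strict improvement: smaller c wins ties
      best_score <- score
      c_hat <- c0
    }
  }
  c_hat
}

#' Assign heterozygous pairs to ploidy patterns
#'
#' Each pair is assigned to the pattern `(n, b)` minimizing the scaled
#' distance `max(|T - n c| / (n c), |f - b/n| / (b/n))`, or left
#' unassigned when that minimum exceeds `tol`.
#'
#' @param pairs A [find_het_pairs()] result.
#' @param c_hat Estimated 1x coverage (> 0).
#' @param tol Relative tolerance (default 0.2).
#' @param max_n Largest copy number considered (default 8).
#' @return List of class `smudge_report`: `c_hat`, `patterns` (data.frame
#'   `pattern`, `n_pairs`, `proportion`), `dominant`, `n_pairs_tested`,
#'   `unassigned`, and the per-pair `assignment` vector.
#' @export
assign_patterns <- function(pairs, c_hat, tol = 0.2, max_n = 8L) {
  stopifnot(is.numeric(c_hat), c_hat > 0)
  grid <- pattern_grid(max_n)
  n_pairs <- nrow(pairs)
  d_best <- rep(Inf, n_pairs)
  idx <- rep(NA_integer_, n_pairs)
  for (i in seq_len(nrow(grid))) {
    d <- pattern_distance(pairs$total, pairs$minor_fraction,
                          grid$n[i], grid$b[i], c_hat)
    upd <- d < d_best
    d_best[upd] <- d[upd]
    idx[upd] <- i
  }
  assignment <- ifelse(d_best <= tol, grid$name[idx], NA_character_)
  tab <- table(factor(assignment, levels = grid$name))
  patterns <- data.frame(pattern = names(tab),
                         n_pairs = as.integer(tab),
                         proportion = if (n_pairs > 0)
                           as.numeric(tab) / n_pairs else rep(0, length(tab)),
                         stringsAsFactors = FALSE)
  patterns <- patterns[order(-patterns$n_pairs, patterns$pattern), ]
  rownames(patterns) <- NULL
  dominant <- if (n_pairs > 0 && any(patterns$n_pairs > 0))
    patterns$pattern[1L] else NA_character_
  structure(list(c_hat = c_hat, patterns = patterns, dominant = dominant,
                 n_pairs_tested = n_pairs,
                 unassigned = sum(is.na(assignment)),
                 assignment = assignment, tol = tol, max_n = max_n),
            class = "smudge_report")
}

#' @export
print.smudge_report <- function(x, ...) {
  cat("smudge_report: c_hat =", x$c_hat, "|", x$n_pairs_tested,
      "pairs tested |", x$unassigned, "unassigned\n")
  top <- utils::head(x$patterns[x$patterns$n_pairs > 0, ], 5L)
  for (i in seq_len(nrow(top))) {
    cat(sprintf("  %-8s %6d  (%.1f%%)%s\n", top$pattern[i], top$n_pairs[i],
                100 * top$proportion[i],
                if (identical(top$pattern[i], x$dominant)) "  <- dominant"
                else ""))
  }
  invisible(x)
}

#' 2D histogram of heterozygous pairs over (total coverage, minor fraction)
#'
#' @param pairs A [find_het_pairs()] result.
#' @param T_breaks Breaks for the total-coverage axis (default 30 equal
#'   bins spanning the data).
#' @param f_breaks Breaks for the minor-fraction axis (default 20 equal
#'   bins over (0, 0.5]).
#' @return List with `counts` (matrix, T bins x f bins), `T_breaks`,
#'   `f_breaks`. Counts sum to the number of pairs.
#' @export
smudge_histogram <- function(pairs, T_breaks = NULL, f_breaks = NULL) {
  if (is.null(T_breaks)) {
    rng <- range(pairs$total)
    T_breaks <- seq(rng[1], rng[2] + 1e-9, length.out = 31L)
  }
  if (is.null(f_breaks)) f_breaks <- seq(0, 0.5, length.out = 21L)
  ti <- cut(pairs$total, T_breaks, include.lowest = TRUE)
  fi <- cut(pairs$minor_fraction, f_breaks, include.lowest = TRUE)
  counts <- table(ti, fi)
  list(counts = unclass(counts), T_breaks = T_breaks, f_breaks = f_breaks)
}
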