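#' Hard-filter thresholds
#'
#' Defaults follow the canonical resequencing cascade: site depth in
#' `[5, 1000]`, at most 40% missing genotypes, a repeat-region mask, and
#' removal of variants closer than 5 bp to any other variant.
#'
#' @param depth_min,depth_max Inclusive site-depth bounds; records with
#'   depth `< depth_min` or `> depth_max` are removed, and depth-unknown
#'   records fail conservatively.
#' @param max_missing Maximum tolerated missing-genotype fraction.
#' @param min_spacing Minimum distance (bp) to the nearest other variant;
#'   `|delta pos| < min_spacing` removes both members of the pair.
#' @param repeat_mask An [interval_set()] of repeat regions (may be empty).
#' @return List of class `filter_params`.
#' @export
filter_params <- function(depth_min = 5L, depth_max = 1000L,
                          max_missing = 0.40, min_spacing = 5L,
                          repeat_mask = NULL) {
  stopifnot(depth_min < depth_max, max_missing > 0, max_missing < 1,
            min_spacing >= 1L)
  if (is.null(repeat_mask)) {
    repeat_mask <- interval_set(data.frame(chrom = character(0),
                                           start = integer(0),
                                           end = integer(0)))
  }
  structure(list(depth_min = depth_min, depth_max = depth_max,
                 max_missing = max_missing, min_spacing = min_spacing,
                 repeat_mask = repeat_mask),
            class = "filter_params")
}

#' Intersect two call sets (the two-pipeline rule)
#'
#' Keeps records of `a` matching a record of `b` on (chrom, pos, ref,
#' ALT-allele set); depth and genotypes are taken from `a`. The number of
#' records dropped is attached as attribute `rule1_removed`.
#'
#' @param a,b [variant_set()]s, each sorted by (chrom, pos).
#' @return A [variant_set()] with `provenance = "intersection"`.
#' @export
intersect_callsets <- function(a, b) {
  stopifnot(inherits(a, "variant_set"), inherits(b, "variant_set"))
  if (!is_sorted_variants(a$records) || !is_sorted_variants(b$records)) {
    stop("intersect_callsets requires inputs sorted by (chrom, pos)")
  }
  altset <- function(x) vapply(strsplit(x, ",", fixed = TRUE),
                               function(v) paste(sort(v), collapse = ","),
                               character(1))
  key_a <- paste(a$records$chrom, a$records$pos, a$records$ref,
                 altset(a$records$alt), sep = "\r")
  key_b <- paste(b$records$chrom, b$records$pos, b$records$ref,
                 altset(b$records$alt), sep = "\r")
  keep <- key_a %in% key_b
  rec <- a$records[keep, , drop = FALSE]
  rownames(rec) <- NULL
  out <- variant_set(rec, a$gt[keep, , drop = FALSE], a$samples,
                     provenance = "intersection")
  attr(out, "rule1_removed") <- sum(!keep)
  out
}

#' Apply the six-rule hard-filter cascade
#'
#' Rules, in cascade order (each record is removed at its first failing
#' rule; rule 1, the two-pipeline intersection, is handled upstream by
#' [intersect_callsets()] and enters the report via the `rule1_removed`
#' attribute):
#' \enumerate{
#'   \item two-pipeline intersection (upstream);
#'   \item site depth `< depth_min` or `> depth_max` (depth-unknown fails,
#'     counted separately);
#'   \item not biallelic (ALT allele count != 1);
#'   \item missing-genotype fraction `> max_missing`;
#'   \item position inside the repeat mask;
#'   \item another record of the *input* set (any type, including records
#'     failing earlier rules) within `< min_spacing` bp on the same
#'     chromosome — both members of a close pair fail.
#' }
#'
#' @param vs A [variant_set()].
#' @param params A [filter_params()].
#' @return List of class `filter_report`: `input`, `removed` (named counts
#'   rule1..rule6), `depth_unknown_removed`, `survivors` (a
#'   [variant_set()]), and `reason` (per-record FILTER codes).
#' @export
apply_filters <- function(vs, params = filter_params()) {
  stopifnot(inherits(vs, "variant_set"), inherits(params, "filter_params"))
  rec <- vs$records
  n <- nrow(rec)
  ns <- ncol(vs$gt)
  miss_frac <- if (ns > 0L) rowSums(vs$gt == "./." | vs$gt == ".|." |
                                      vs$gt == ".") / ns else rep(0, n)
  depth_unknown <- is.na(rec$depth)
  f2 <- depth_unknown | rec$depth < params$depth_min |
    rec$depth > params$depth_max
  f2[is.na(f2)] <- TRUE
  f3 <- lengths(strsplit(rec$alt, ",", fixed = TRUE)) != 1L
  f4 <- miss_frac > params$max_missing
  f5 <- interval_contains(params$repeat_mask, rec$chrom, rec$pos)
  f6 <- logical(n)
  for (ch in unique(rec$chrom)) {
    sel <- which(rec$chrom == ch)
    p <- sort(rec$pos[sel])
    close_lo <- c(FALSE, diff(p) < params$min_spacing)
    close_hi <- c(diff(p) < params$min_spacing, FALSE)
    close <- close_lo | close_hi
    f6[sel[order(rec$pos[sel])]] <- close
  }
  reason <- rep("PASS", n)
  reason[f6] <- "PROXIMITY"
  reason[f5] <- "REPEAT"
  reason[f4] <- "HIGHMISS"
  reason[f3] <- "MULTIALLELIC"
  reason[f2] <- ifelse(depth_unknown[f2], "NODP",
                       ifelse(rec$depth[f2] < params$depth_min, "LOWDP",
                              "HIGHDP"))
  first_fail <- rep(0L, n)
  first_fail[f6] <- 6L
  first_fail[f5] <- 5L
  first_fail[f4] <- 4L
  first_fail[f3] <- 3L
  first_fail[f2] <- 2L
  removed <- c(
    rule1 = as.integer(attr(vs, "rule1_removed") %||% 0L),
    rule2 = sum(first_fail == 2L), rule3 = sum(first_fail == 3L),
    rule4 = sum(first_fail == 4L), rule5 = sum(first_fail == 5L),
    rule6 = sum(first_fail == 6L))
  keep <- first_fail == 0L
  surv_rec <- rec[keep, , drop = FALSE]
  rownames(surv_rec) <- NULL
  survivors <- variant_set(surv_rec, vs$gt[keep, , drop = FALSE],
                           vs$samples, provenance = vs$provenance)
  # `input` counts records entering the cascade, including any dropped by
  # the upstream intersection, so that input = survivors + sum(removed)
  structure(list(input = n + removed[["rule1"]], removed = removed,
                 depth_unknown_removed = sum(depth_unknown & first_fail == 2L),
                 survivors = survivors, reason = reason,
                 params = params),
            class = "filter_report")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.filter_report <- function(x, ...) {
  cat("filter_report:", x$input, "records in,",
      n_variants(x$survivors), "surviving\n")
  for (r in names(x$removed)) {
    cat(sprintf("  %s removed: %d\n", r, x$removed[[r]]))
  }
  cat("  (depth-unknown within rule2:", x$depth_unknown_removed, ")\n")
  invisible(x)
}
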