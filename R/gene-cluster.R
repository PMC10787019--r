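#' Find tandem gene-family clusters
#'
#' A cluster is a maximal run of at least `min_size` consecutive family
#' genes on one chromosome in which every successive gap is at most
#' `max_gap` bp. "Consecutive" means consecutive among *family* members in
#' coordinate order; intervening non-family genes are allowed unless
#' `strict_adjacency = TRUE`. Strand is ignored.
#'
#' @param features data.frame of gene features (see [read_gff3()]); sorted
#'   internally per chromosome by start.
#' @param family_ids Character vector of family member gene ids; every id
#'   must exist among `features$feature_id`.
#' @param min_size Minimum genes per cluster (default 3).
#' @param max_gap Maximum allowed gap between successive members in bp
#'   (default 8e5, i.e. 0.8 Mb).
#' @param gap_mode `"end_to_start"` (gap = next start - previous end - 1,
#'   floored at 0 for overlaps; default) or `"start_to_start"`.
#' @param strict_adjacency Require that no non-family gene lies between
#'   successive cluster members.
#' @return data.frame with one row per cluster: `chrom`, `start`, `end`,
#'   `n_members`, `max_gap_obs`, and a list-column `members` of gene ids in
#'   coordinate order.
#' @export
find_clusters <- function(features, family_ids, min_size = 3L,
                          max_gap = 800000,
                          gap_mode = c("end_to_start", "start_to_start"),
                          strict_adjacency = FALSE) {
  gap_mode <- match.arg(gap_mode)
  stopifnot(min_size >= 1L, max_gap >= 0)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  missing_ids <- setdiff(family_ids, features$feature_id)
  if (length(missing_ids)) {
    stop("family ids absent from features: ",
         paste(missing_ids, collapse = ", "))
  }
  out <- list()
  for (ch in unique(features$chrom)) {
    all_g <- features[features$chrom == ch, , drop = FALSE]
    all_g <- all_g[order(all_g$start, all_g$end), , drop = FALSE]
    fam <- all_g[all_g$feature_id %in% family_ids, , drop = FALSE]
    m <- nrow(fam)
    if (m < min_size) next
    gap <- if (gap_mode == "end_to_start") {
      pmax(fam$start[-1L] - fam$end[-m] - 1L, 0L)
    } else {
      fam$start[-1L] - fam$start[-m]
    }
    linked <- gap <= max_gap
    if (strict_adjacency && m > 1L) {
      fam_pos <- match(fam$feature_id, all_g$feature_id)
      linked <- linked & (diff(fam_pos) == 1L)
    }
    run_id <- cumsum(c(0L, !linked))
    for (r in split(seq_len(m), run_id)) {
      if (length(r) < min_size) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = ch, start = fam$start[r[1L]], end = fam$end[r[length(r)]],
        n_members = length(r),
        max_gap_obs = if (length(r) > 1L)
          max(gap[r[-length(r)]]) else 0L,
        stringsAsFactors = FALSE)
      out[[length(out)]]$members <- list(fam$feature_id[r])
    }
  }
  if (length(out) == 0L) {
    res <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), n_members = integer(0),
                      max_gap_obs = numeric(0), stringsAsFactors = FALSE)
    res$members <- list()
    return(res)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}
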