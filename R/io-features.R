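#' Read gene features from a GFF3 file
#'
#' Coordinates are kept 1-based inclusive, as in the format. Only the
#' columns the cluster caller needs are retained; the feature id is taken
#' from the `ID=` attribute (falling back to `Name=`).
#'
#' @param path Path to an uncompressed GFF3 file.
#' @param types Feature types to keep (default `"gene"`); `NULL` keeps all.
#' @return data.frame with columns `chrom`, `start`, `end`, `strand`,
#'   `feature_id`, `feature_type`.
#' @export
read_gff3 <- function(path, types = "gene") {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  idx <- which(keep)
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 9L)) {
    stop("malformed GFF3 line (fewer than 9 columns) at line ",
         idx[which(nf < 9L)[1L]])
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 4L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 5L)))
  bad <- is.na(start) | is.na(end) | start < 1L | start > end
  if (any(bad)) {
    stop("GFF3 coordinate violation at line ", idx[which(bad)[1L]])
  }
  attrs <- vapply(fields, `[`, character(1), 9L)
  fid <- sub("^.*ID=([^;]+).*$", "\\1",
             ifelse(grepl("(^|;)ID=", attrs), attrs,
                    ifelse(grepl("(^|;)Name=", attrs),
                           sub("Name=", "ID=", attrs, fixed = TRUE), NA)))
  out <- data.frame(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = start, end = end,
    strand = vapply(fields, `[`, character(1), 7L),
    feature_id = fid,
    feature_type = vapply(fields, `[`, character(1), 3L),
    stringsAsFactors = FALSE)
  if (!is.null(types)) out <- out[out$feature_type %in% types, , drop = FALSE]
  genes <- out$feature_id[out$feature_type == "gene"]
  if (anyDuplicated(genes)) {
    stop("duplicate gene id in GFF3: ", genes[duplicated(genes)][1L])
  }
  rownames(out) <- NULL
  out
}

#' Read a BED file into an interval set
#'
#' BED is 0-based half-open; the interval set keeps that convention.
#' Membership queries for 1-based positions are provided by
#' [interval_contains()].
#'
#' @param path Path to a BED file (first three columns used).
#' @return data.frame of class `interval_set` with columns `chrom`,
#'   `start` (0-based), `end` (exclusive), merged per chromosome.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L) {
    return(interval_set(data.frame(chrom = character(0), start = integer(0),
                                   end = integer(0))))
  }
  fields <- strsplit(lines, "[ \t]+")
  if (any(lengths(fields) < 3L)) {
    stop("malformed BED line at line ", which(lengths(fields) < 3L)[1L])
  }
  start <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  end <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 3L)))
  bad <- is.na(start) | is.na(end) | start < 0L | start >= end
  if (any(bad)) stop("BED coordinate violation at line ", which(bad)[1L])
  interval_set(data.frame(
    chrom = vapply(fields, `[`, character(1), 1L),
    start = start, end = end, stringsAsFactors = FALSE))
}

#' Construct an interval set (0-based half-open), merging overlaps
#'
#' @param df data.frame with columns `chrom`, `start` (0-based), `end`
#'   (exclusive).
#' @return Merged, sorted data.frame of class `interval_set`.
#' @export
interval_set <- function(df) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  if (nrow(df) > 0 && any(df$start < 0L | df$start >= df$end)) {
    stop("interval_set requires 0 <= start < end")
  }
  df <- df[order(df$chrom, df$start, df$end), , drop = FALSE]
  out <- list()
  for (ch in unique(df$chrom)) {
    x <- df[df$chrom == ch, , drop = FALSE]
    s <- x$start; e <- x$end
    ms <- s[1]; me <- e[1]; acc <- list()
    if (nrow(x) > 1) for (i in 2:nrow(x)) {
      if (s[i] <= me) me <- max(me, e[i]) else {
        acc[[length(acc) + 1L]] <- c(ms, me); ms <- s[i]; me <- e[i]
      }
    }
    acc[[length(acc) + 1L]] <- c(ms, me)
    m <- do.call(rbind, acc)
    out[[ch]] <- data.frame(chrom = ch, start = m[, 1], end = m[, 2],
                            stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else df
  rownames(res) <- NULL
  class(res) <- c("interval_set", "data.frame")
  res
}

#' Test 1-based positions for membership in an interval set
#'
#' @param iset An [interval_set()] (0-based half-open).
#' @param chrom Character vector of chromosome ids.
#' @param pos Integer vector of 1-based positions.
#' @return Logical vector; strand-agnostic.
#' @export
interval_contains <- function(iset, chrom, pos) {
  stopifnot(length(chrom) == length(pos))
  out <- logical(length(pos))
  for (ch in unique(chrom)) {
    iv <- iset[iset$chrom == ch, , drop = FALSE]
    sel <- chrom == ch
    if (nrow(iv) == 0L) next
    p0 <- pos[sel] - 1L  # to 0-based
    j <- findInterval(p0, iv$start)
    out[sel] <- j >= 1L & p0 < iv$end[pmax(j, 1L)]
  }
  out
}

#' Write a chromosome tree to a newick file
#'
#' @param tree A `chromosome_tree` (see [cluster_chromosomes()]) or an
#'   `ape::phylo` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- if (inherits(tree, "chromosome_tree")) tree$phylo else tree
  stopifnot(inherits(phy, "phylo"))
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' Read a two/three-column TSV mapping (e.g. chromosome labels)
#'
#' @param path Path to a TSV file.
#' @param header Logical; does the file carry a header line?
#' @return data.frame with the file's columns.
#' @export
read_tsv_map <- function(path, header = TRUE) {
  if (!file.exists(path)) stop("TSV file not found: ", path)
  utils::read.table(path, header = header, sep = "\t",
                    stringsAsFactors = FALSE, comment.char = "",
                    quote = "")
}
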