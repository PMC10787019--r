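#' Variant set container
#'
#' A light VCF-backed container holding what the hard-filter cascade needs:
#' coordinates, alleles, a resolved per-record depth and per-sample
#' genotypes. Depth resolution follows the GATK convention: `INFO/DP` if
#' present, else the sum of per-sample `FORMAT/DP` values, else the record
#' is flagged depth-unknown (`depth = NA`).
#'
#' @param records A data.frame with columns `chrom`, `pos` (1-based
#'   integer), `ref`, `alt` (comma-separated alternate alleles), `depth`
#'   (integer, `NA` = unknown).
#' @param gt Character matrix of genotypes, `nrow(records)` x n_samples
#'   (may have 0 columns).
#' @param samples Character vector of sample names.
#' @param provenance `"single"` or `"intersection"`.
#' @return An object of class `variant_set`.
#' @export
variant_set <- function(records, gt = NULL, samples = character(0),
                        provenance = "single") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  stopifnot(all(c("chrom", "pos", "ref", "alt", "depth") %in% names(records)))
  if (any(records$pos < 1L)) stop("VCF POS must be >= 1")
  if (is.null(gt)) {
    gt <- matrix(character(0), nrow = nrow(records), ncol = 0L)
  }
  stopifnot(nrow(gt) == nrow(records))
  structure(list(records = records, gt = gt, samples = samples,
                 provenance = provenance),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat("variant_set:", nrow(x$records), "records,",
      length(x$samples), "samples, provenance =", x$provenance, "\n")
  invisible(x)
}

#' Number of records in a variant set
#' @param vs A `variant_set`.
#' @return Integer record count.
#' @export
n_variants <- function(vs) nrow(vs$records)

is_sorted_variants <- function(records) {
  o <- order(records$chrom, records$pos)
  identical(o, seq_len(nrow(records)))
}

#' Read a VCF file
#'
#' Minimal VCF v4.x reader. Preserves CHROM, POS, REF, the ALT allele list,
#' per-sample genotypes (GT) and a resolved depth (see [variant_set()]).
#'
#' @param path Path to an uncompressed VCF.
#' @return A [variant_set()].
#' @export
read_vcf <- function(path) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  lines <- readLines(path)
  body_idx <- which(!startsWith(lines, "#"))
  hdr <- grep("^#CHROM\t", lines, value = TRUE)
  samples <- character(0)
  if (length(hdr) == 1L) {
    cols <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
    if (length(cols) > 9L) samples <- cols[-(1:9)]
  }
  n <- length(body_idx)
  if (n == 0L) {
    rec <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      depth = integer(0), stringsAsFactors = FALSE)
    return(variant_set(rec, matrix(character(0), 0, length(samples)), samples))
  }
  fields <- strsplit(lines[body_idx], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 8L)) {
    stop("malformed VCF line (fewer than 8 columns) at line ",
         body_idx[which(nf < 8L)[1L]])
  }
  chrom <- vapply(fields, `[`, character(1), 1L)
  pos <- suppressWarnings(as.integer(vapply(fields, `[`, character(1), 2L)))
  if (anyNA(pos)) {
    stop("malformed VCF POS at line ", body_idx[which(is.na(pos))[1L]])
  }
  ref <- vapply(fields, `[`, character(1), 4L)
  alt <- vapply(fields, `[`, character(1), 5L)
  info <- vapply(fields, `[`, character(1), 8L)
  dp_match <- regexpr("(^|;)DP=[0-9]+", info)
  info_dp <- rep(NA_integer_, n)
  has_dp <- dp_match > 0L
  info_dp[has_dp] <- as.integer(
    sub("^;?DP=", "", regmatches(info, dp_match)))
  ns <- length(samples)
  gt <- matrix(".", nrow = n, ncol = ns)
  dp_sum <- rep(NA_integer_, n)
  if (ns > 0L) {
    fmt <- vapply(fields, function(f) if (length(f) >= 9L) f[9L] else "",
                  character(1))
    for (i in seq_len(n)) {
      keys <- strsplit(fmt[i], ":", fixed = TRUE)[[1]]
      gt_j <- match("GT", keys)
      dp_j <- match("DP", keys)
      svals <- fields[[i]][-(1:9)]
      parts <- strsplit(svals, ":", fixed = TRUE)
      if (!is.na(gt_j)) {
        gt[i, ] <- vapply(parts, function(p)
          if (length(p) >= gt_j) p[gt_j] else ".", character(1))
      }
      if (!is.na(dp_j)) {
        dps <- suppressWarnings(as.integer(vapply(parts, function(p)
          if (length(p) >= dp_j) p[dp_j] else NA_character_, character(1))))
        if (!all(is.na(dps))) dp_sum[i] <- sum(dps, na.rm = TRUE)
      }
    }
  }
  depth <- ifelse(!is.na(info_dp), info_dp, dp_sum)
  rec <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    depth = depth, stringsAsFactors = FALSE)
  variant_set(rec, gt, samples)
}

#' Write a variant set to VCF
#'
#' @param vs A [variant_set()].
#' @param path Output path.
#' @param filter Optional character vector of FILTER codes, one per record
#'   (default `"PASS"` everywhere).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(vs, path, filter = NULL) {
  rec <- vs$records
  n <- nrow(rec)
  if (is.null(filter)) filter <- rep("PASS", n)
  stopifnot(length(filter) == n)
  ns <- length(vs$samples)
  hdr <- c("##fileformat=VCFv4.2",
           "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Total depth\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", if (ns > 0) c("FORMAT", vs$samples)),
                 collapse = "\t"))
  info <- ifelse(is.na(rec$depth), ".", paste0("DP=", rec$depth))
  body <- paste(rec$chrom, rec$pos, ".", rec$ref, rec$alt, ".",
                filter, info, sep = "\t")
  if (ns > 0L) {
    gts <- apply(vs$gt, 1L, paste, collapse = "\t")
    body <- paste(body, "GT", gts, sep = "\t")
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
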