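#' Run the chromosome-enriched K-mer tetraploidy pipeline end to end
#'
#' Counts canonical K-mers per chromosome, selects chromosome-enriched
#' K-mers, builds the abundance profile matrix, clusters chromosomes by
#' UPGMA and classifies the genome as auto- or allo-polyploid from
#' homologous-group monophyly.
#'
#' The pipeline default `baseline = "mean_other"` differs from the
#' [select_enriched()] default: for a polyploid assembly, the diagnostic
#' repeat K-mers are shared by the homologous (or subgenomic) chromosome
#' set, so a strict max-over-others baseline would discard exactly the
#' markers the co-clustering needs.
#'
#' @param genome A [genome_map()], or a FASTA path (then `label_map` must
#'   be a TSV path with columns chrom/group/haplotype).
#' @param label_map Optional label TSV path or data.frame (unused when
#'   `genome` is a `genome_map`).
#' @param k K-mer length (default 13).
#' @param min_global,fold,baseline,normalize See [enrichment_params()].
#' @param metric Distance metric, see [chromosome_distance()].
#' @param auto_threshold,n_permutations,seed See [classify_origin()].
#' @param outdir Optional output directory; when given, writes
#'   `enriched_kmers.tsv`, `chromosome_tree.nwk`, `distance_matrix.tsv` and
#'   `ploidy_call.json`.
#' @return List with `table`, `enriched`, `profile`, `dist`, `tree`,
#'   `call`, and `config`.
#' @export
run_tetrasig_pipeline <- function(genome, label_map = NULL, k = 13L,
                                  min_global = 100, fold = 2,
                                  baseline = "mean_other",
                                  normalize = "density",
                                  metric = "braycurtis",
                                  auto_threshold = 1,
                                  n_permutations = 1000L, seed = 1L,
                                  outdir = NULL) {
  if (is.character(genome)) {
    seqs <- read_fasta(genome)
    if (is.null(label_map)) stop("label_map required with a FASTA input")
    lab <- if (is.character(label_map)) read_tsv_map(label_map) else label_map
    names(lab)[1:2] <- c("chrom", "group")
    if (nrow(lab) == 0L) stop("empty label map")
    genome <- genome_map(seqs, lab)
  }
  stopifnot(inherits(genome, "genome_map"))
  config <- list(k = k, min_global = min_global, fold = fold,
                 baseline = baseline, normalize = normalize,
                 metric = metric, auto_threshold = auto_threshold,
                 n_permutations = n_permutations, seed = seed,
                 version = as.character(utils::packageVersion("tetrasig")))
  table <- count_kmers_assembly(genome, k)
  enriched <- select_enriched(table, enrichment_params(
    min_global = min_global, fold = fold, baseline = baseline,
    normalize = normalize))
  profile <- build_profile_matrix(table, enriched)
  d <- chromosome_distance(profile, metric)
  tree <- cluster_chromosomes(d)
  call <- classify_origin(tree, genome$labels, auto_threshold,
                          n_permutations, seed)
  res <- list(table = table, enriched = enriched, profile = profile,
              dist = d, tree = tree, call = call, config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(enriched$entries,
                       file.path(outdir, "enriched_kmers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    write_newick(tree, file.path(outdir, "chromosome_tree.nwk"))
    utils::write.table(round(d, 6), file.path(outdir, "distance_matrix.tsv"),
                       sep = "\t", quote = FALSE)
    report <- list(verdict = call$verdict, S = call$S,
                   per_group = as.list(call$per_group),
                   subgenome_score = call$subgenome_score,
                   permutation_p = call$permutation_p,
                   n_enriched_kmers = nrow(enriched$entries),
                   config = config)
    jsonlite::write_json(report, file.path(outdir, "ploidy_call.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}

#' Run the smudge (heterozygous K-mer pair) pipeline end to end
#'
#' Counts canonical K-mers across the read set, extracts heterozygous
#' pairs, estimates the 1x coverage and assigns pairs to ploidy patterns.
#' The run parameters (`k`, `L`, `U`, `tol`) shape the reported
#' proportions and are embedded in the JSON report.
#'
#' @param fastq FASTQ path(s) or an in-memory read data.frame.
#' @param k K-mer length (default 21, the smudge convention).
#' @param L,U Coverage bounds for pair extraction (defaults 10, 1000).
#' @param pairing See [find_het_pairs()].
#' @param tol Relative tolerance for coverage estimation and assignment.
#' @param c_grid Optional coverage grid for [estimate_1x_coverage()].
#' @param outdir Optional output directory; writes `pairs.tsv`,
#'   `smudge_histogram.tsv` and `smudge_report.json`.
#' @return List with `table`, `pairs`, `report` and `config`.
#' @export
run_smudge_pipeline <- function(fastq, k = 21L, L = 10, U = 1000,
                                pairing = "middle_only", tol = 0.2,
                                c_grid = NULL, outdir = NULL) {
  if (is.character(fastq)) {
    missing <- fastq[!file.exists(fastq)]
    if (length(missing)) stop("missing input file: ",
                              paste(missing, collapse = ", "))
  }
  config <- list(k = k, L = L, U = U, pairing = pairing, tol = tol,
                 version = as.character(utils::packageVersion("tetrasig")))
  table <- count_kmers_reads(fastq, k)
  pairs <- find_het_pairs(table, L, U, pairing)
  c_hat <- estimate_1x_coverage(pairs, c_grid, tol)
  report <- assign_patterns(pairs, c_hat, tol)
  res <- list(table = table, pairs = pairs, report = report,
              config = config)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(pairs, file.path(outdir, "pairs.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    h <- smudge_histogram(pairs)
    utils::write.table(h$counts,
                       file.path(outdir, "smudge_histogram.tsv"),
                       sep = "\t", quote = FALSE)
    out <- list(c_hat = report$c_hat, dominant = report$dominant,
                n_pairs_tested = report$n_pairs_tested,
                unassigned = report$unassigned,
                proportions = stats::setNames(
                  as.list(report$patterns$proportion),
                  report$patterns$pattern),
                config = config)
    jsonlite::write_json(out, file.path(outdir, "smudge_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  res
}
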