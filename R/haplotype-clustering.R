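#' Pairwise distances between chromosomes from enriched-K-mer profiles
#'
#' @param profile Matrix from [build_profile_matrix()] (chromosomes x
#'   K-mers, non-negative).
#' @param metric `"braycurtis"` (default; standard for abundance
#'   profiles), `"jaccard_presence"` (binarizes at value > 0) or
#'   `"one_minus_spearman"` (1 - rank correlation between rows; range
#'   [0, 2]).
#' @return Symmetric `dist`-compatible matrix with zero diagonal.
#' @export
chromosome_distance <- function(profile,
                                metric = c("braycurtis", "jaccard_presence",
                                           "one_minus_spearman")) {
  metric <- match.arg(metric)
  stopifnot(is.matrix(profile), nrow(profile) >= 2L)
  zero <- rowSums(profile) == 0
  if (any(zero)) {
    stop("all-zero profile row for chromosome: ",
         paste(rownames(profile)[zero], collapse = ", "))
  }
  d <- switch(metric,
    braycurtis = vegan::vegdist(profile, method = "bray"),
    jaccard_presence = vegan::vegdist(profile > 0, method = "jaccard"),
    one_minus_spearman = as.dist(1 - stats::cor(t(profile),
                                                method = "spearman")))
  m <- as.matrix(d)
  diag(m) <- 0
  m
}

#' UPGMA clustering of chromosomes
#'
#' Agglomerative average-linkage clustering. Leaves are ordered
#' lexicographically before clustering so that distance ties break
#' deterministically by label.
#'
#' @param dist_mat Symmetric distance matrix with chromosome rownames.
#' @return List of class `chromosome_tree` with elements `hclust`,
#'   `phylo` (ape tree with branch lengths) and `cophenetic`.
#' @export
cluster_chromosomes <- function(dist_mat) {
  stopifnot(is.matrix(dist_mat), nrow(dist_mat) >= 2L,
            !is.null(rownames(dist_mat)))
  ord <- order(rownames(dist_mat))
  dist_mat <- dist_mat[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(dist_mat), method = "average")
  structure(list(hclust = hc, phylo = ape::as.phylo(hc),
                 cophenetic = as.matrix(stats::cophenetic(hc))),
            class = "chromosome_tree")
}

#' @export
print.chromosome_tree <- function(x, ...) {
  cat("chromosome_tree (UPGMA):", length(x$hclust$labels), "leaves\n")
  invisible(x)
}

# Leaf sets of every internal node of an hclust tree, as a list of
# character vectors (sorted).
clade_leaf_sets <- function(hc) {
  n <- length(hc$labels)
  sets <- vector("list", n - 1L)
  for (i in seq_len(n - 1L)) {
    members <- integer(0)
    for (j in 1:2) {
      m <- hc$merge[i, j]
      members <- c(members, if (m < 0) -m else NULL)
      if (m > 0) members <- c(members, match(sets[[m]], hc$labels))
    }
    sets[[i]] <- sort(hc$labels[members])
  }
  sets
}

monophyly_score <- function(clades, labels_vec) {
  groups <- split(names(labels_vec), labels_vec)
  keys <- vapply(clades, paste, character(1), collapse = "\r")
  mono <- vapply(groups, function(g) {
    paste(sort(g), collapse = "\r") %in% keys
  }, logical(1))
  list(per_group = mono, S = mean(mono))
}

#' Classify a polyploid genome as auto- or allo-polyploid
#'
#' A homologous group is monophyletic when some clade of the chromosome
#' tree contains exactly that group's leaves. The score `S` is the
#' fraction of monophyletic groups; the verdict is `"auto"` when
#' `S >= auto_threshold`. Otherwise the tree is cut into two clusters
#' (candidate subgenomes): if at least `auto_threshold` of the groups have
#' their haplotypes split into two equal halves by that cut, the verdict
#' is `"allo"`, else `"ambiguous"`. A permutation p-value for `S` is
#' computed by shuffling group labels over leaves (group sizes preserved).
#'
#' @param tree A [cluster_chromosomes()] result.
#' @param labels data.frame with columns `chrom` and `group` covering every
#'   leaf (e.g. `genome$labels`).
#' @param auto_threshold Minimum fraction of monophyletic groups for the
#'   auto verdict (default 1: every group must co-cluster).
#' @param n_permutations Label shufflings for the permutation null.
#' @param seed Integer seed for the permutations.
#' @return List of class `ploidy_call`: `verdict`, `S`, `per_group`,
#'   `subgenome_score`, `permutation_p`, `n_permutations`.
#' @export
classify_origin <- function(tree, labels, auto_threshold = 1,
                            n_permutations = 1000L, seed = 1L) {
  stopifnot(inherits(tree, "chromosome_tree"))
  hc <- tree$hclust
  leaves <- hc$labels
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  lab <- stats::setNames(labels$group, labels$chrom)[leaves]
  if (anyNA(lab)) {
    stop("unlabeled leaf: ",
         paste(leaves[is.na(lab)], collapse = ", "))
  }
  names(lab) <- leaves
  sizes <- table(lab)
  if (any(sizes < 2L)) {
    stop("group of size 1: ", paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  clades <- clade_leaf_sets(hc)
  obs <- monophyly_score(clades, lab)
  S <- obs$S

  # candidate-subgenome diagnostics: 2-cluster cut of the tree
  cut2 <- stats::cutree(hc, k = 2L)
  balanced <- vapply(split(names(lab), lab), function(g) {
    tb <- table(cut2[g])
    length(tb) == 2L && tb[1L] == tb[2L]
  }, logical(1))
  subgenome_score <- {
    # fraction of chromosomes whose nearest neighbor shares their side of
    # the 2-cut (cohesion of the candidate subgenomes)
    coph <- tree$cophenetic
    diag(coph) <- Inf
    nn <- leaves[apply(coph[leaves, leaves, drop = FALSE], 1L, which.min)]
    mean(cut2[leaves] == cut2[nn])
  }

  verdict <- if (S >= auto_threshold) {
    "auto"
  } else if (mean(balanced) >= auto_threshold) {
    "allo"
  } else {
    "ambiguous"
  }

  set.seed(seed)
  perm_S <- replicate(n_permutations, {
    shuffled <- stats::setNames(sample(unname(lab)), leaves)
    monophyly_score(clades, shuffled)$S
  })
  structure(list(verdict = verdict, S = S, per_group = obs$per_group,
                 balanced_groups = balanced,
                 subgenome_score = subgenome_score,
                 permutation_p = mean(perm_S >= S),
                 n_permutations = n_permutations),
            class = "ploidy_call")
}

#' @export
print.ploidy_call <- function(x, ...) {
  cat("ploidy_call: verdict =", x$verdict,
      sprintf("| S = %.3f | permutation p = %.4g (n = %d)\n",
              x$S, x$permutation_p, x$n_permutations))
  invisible(x)
}
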