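#' Pearson correlation matrix of traits
#'
#' Pairwise Pearson correlations between trait columns. Traits with zero
#' variance cannot be correlated; their rows/columns are set to 0 (unit
#' diagonal kept) and their names are recorded in the `constant_traits`
#' attribute.
#'
#' @param logmat Numeric matrix, samples x traits, at least 3 samples.
#' @return Symmetric traits x traits matrix with unit diagonal.
#' @export
pearson_matrix <- function(logmat) {
  logmat <- as.matrix(logmat)
  if (nrow(logmat) < 3) stop("need at least 3 samples")
  v <- apply(logmat, 2, stats::var)
  flat <- v <= 0 | !is.finite(v)
  r <- suppressWarnings(stats::cor(logmat, method = "pearson"))
  if (any(flat)) {
    r[flat, ] <- 0
    r[, flat] <- 0
  }
  diag(r) <- 1
  attr(r, "constant_traits") <- colnames(logmat)[flat]
  r
}

#' Correlation-network groups (connected components)
#'
#' Builds the correlation network: an undirected edge joins two traits
#' when the absolute Pearson correlation strictly exceeds the threshold.
#' Groups are the connected components, reported by decreasing size
#' (ties: by the lexicographically smallest member).
#'
#' @param corr Symmetric correlation matrix with trait dimnames.
#' @param threshold Edge cutoff on `|r|` (strict `>`; default 0.7).
#' @return List with `edges` (data.frame `trait_a`, `trait_b`, `r`),
#'   `groups` (list of character vectors), `membership` (named integer
#'   vector, group id per trait).
#' @export
cna_groups <- function(corr, threshold = 0.7) {
  stopifnot(is.matrix(corr), nrow(corr) == ncol(corr))
  if (is.null(rownames(corr))) {
    rownames(corr) <- colnames(corr) <- paste0("t", seq_len(nrow(corr)))
  }
  nm <- rownames(corr)
  ut <- which(upper.tri(corr) & abs(corr) > threshold, arr.ind = TRUE)
  edges <- data.frame(trait_a = nm[ut[, 1]], trait_b = nm[ut[, 2]],
                      r = corr[ut], stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges[, 1:2], directed = FALSE,
                                     vertices = nm)
  comp <- igraph::components(g)$membership
  groups <- split(names(comp), comp)
  ord <- order(-lengths(groups),
               vapply(groups, function(x) sort(x)[1], character(1)))
  groups <- unname(groups[ord])
  membership <- integer(length(nm))
  names(membership) <- nm
  for (i in seq_along(groups)) membership[groups[[i]]] <- i
  list(edges = edges, groups = groups, membership = membership)
}

#' Correlation-based trait distances
#'
#' @param corr Correlation matrix.
#' @param variant `"one_minus_abs"` (default, d = 1 - |r|; sign-blind,
#'   matching an absolute-correlation heatmap) or `"one_minus_r"`
#'   (d = 1 - r; anticorrelated traits are far apart).
#' @return A symmetric distance matrix with zero diagonal.
#' @export
trait_distance <- function(corr, variant = c("one_minus_abs", "one_minus_r")) {
  variant <- match.arg(variant)
  d <- switch(variant, one_minus_abs = 1 - abs(corr), one_minus_r = 1 - corr)
  d <- (d + t(d)) / 2
  diag(d) <- 0
  d
}

#' Ward agglomerative clustering
#'
#' Agglomerative hierarchical clustering by Ward's minimum-variance
#' criterion via the Lance-Williams update on the supplied distances
#' (`stats::hclust`). `"classic"` applies the update to the distances as
#' given (ward.D); `"squared"` is the variant operating on squared
#' Euclidean distances (ward.D2).
#'
#' @param d Symmetric non-negative distance matrix (zero diagonal) or a
#'   `dist` object.
#' @param variant `"classic"` (default) or `"squared"`.
#' @return An `hclust` object.
#' @export
ward_hca <- function(d, variant = c("classic", "squared")) {
  variant <- match.arg(variant)
  if (!inherits(d, "dist")) {
    d <- as.matrix(d)
    if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)))
      stop("distance matrix must be symmetric")
    if (any(d < 0)) stop("distances must be non-negative")
    d <- stats::as.dist(d)
  }
  stats::hclust(d, method = if (variant == "classic") "ward.D" else "ward.D2")
}

#' Cut a dendrogram into k clusters
#'
#' @param hc An `hclust` object.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return Named integer vector of cluster labels.
#' @export
cut_k <- function(hc, k) {
  stopifnot(inherits(hc, "hclust"))
  n <- length(hc$order)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  stats::cutree(hc, k = k)
}

#' Two-way clustering of samples and traits
#'
#' Clusters the traits on the correlation distance and the samples on
#' the same metric applied to sample profiles, then reorders the matrix
#' by both leaf orders (the layout of a two-way clustered heatmap).
#'
#' @param logmat Numeric matrix, samples x traits.
#' @param variant Distance variant, see [trait_distance()].
#' @param ward Ward variant, see [ward_hca()].
#' @return List `row_hc` (traits), `col_hc` (samples), `matrix`
#'   (reordered, traits x samples... samples x traits as input,
#'   rows/cols permuted by the two leaf orders).
#' @export
two_way_order <- function(logmat, variant = "one_minus_abs",
                          ward = "classic") {
  logmat <- as.matrix(logmat)
  if (nrow(logmat) < 3)  # too few samples to correlate anything
    return(list(row_hc = NULL, col_hc = NULL, matrix = logmat))
  trait_hc <- ward_hca(trait_distance(pearson_matrix(logmat), variant), ward)
  if (ncol(logmat) >= 3) {
    sample_hc <- ward_hca(trait_distance(pearson_matrix(t(logmat)), variant),
                          ward)
    rows <- sample_hc$order
  } else {
    sample_hc <- NULL
    rows <- seq_len(nrow(logmat))
  }
  list(row_hc = trait_hc, col_hc = sample_hc,
       matrix = logmat[rows, trait_hc$order, drop = FALSE])
}

#' Concordance between network groups and dendrogram clusters
#'
#' Cross-tabulates two partitions of the same trait set and scores each
#' (group, cluster) pair by overlap. The `agreement` is the pairwise
#' Rand-type fraction of trait pairs on which the partitions agree.
#'
#' @param groups Either the list returned by [cna_groups()] or a named
#'   membership vector.
#' @param labels Named cluster labels (e.g. from [cut_k()]).
#' @return List `table` (contingency matrix), `overlap` (data.frame
#'   `group`, `cluster`, `n`, `jaccard`), `agreement` (scalar).
#' @export
group_cluster_concordance <- function(groups, labels) {
  g <- if (is.list(groups) && !is.null(groups$membership)) groups$membership
  else groups
  common <- intersect(names(g), names(labels))
  if (!setequal(names(g), names(labels)))
    stop("groups and labels must cover the same traits")
  g <- g[common]
  l <- labels[common]
  tab <- table(group = g, cluster = l)
  ov <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(ov) <- c("group", "cluster", "n")
  ov <- ov[ov$n > 0, , drop = FALSE]
  ov$jaccard <- mapply(function(gi, ci, n) {
    n / (sum(g == gi) + sum(l == ci) - n)
  }, ov$group, ov$cluster, ov$n)
  ov <- ov[order(-ov$n), , drop = FALSE]
  rownames(ov) <- NULL
  # pairwise agreement (Rand index)
  n <- length(common)
  same_g <- outer(g, g, "==")
  same_l <- outer(l, l, "==")
  up <- upper.tri(same_g)
  agreement <- mean(same_g[up] == same_l[up])
  list(table = tab, overlap = ov, agreement = agreement)
}

#' Adjusted Rand index between two labelings
#'
#' @param a,b Cluster label vectors over the same items (matched by
#'   position, or by names when both are named).
#' @return ARI in \[-1, 1\]; 1 means identical partitions.
#' @export
adjusted_rand_index <- function(a, b) {
  if (!is.null(names(a)) && !is.null(names(b))) b <- b[names(a)]
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  mx <- (sum_a + sum_b) / 2
  if (mx == expected) return(1)
  (sum_ij - expected) / (mx - expected)
}
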