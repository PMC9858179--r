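test_that("pearson matrix matches the textbook formula", {
  set.seed(61)
  m <- matrix(stats::rnorm(60), 10, 6,
              dimnames = list(NULL, paste0("t", 1:6)))
  r <- pearson_matrix(m)
  expect_equal(diag(r), setNames(rep(1, 6), paste0("t", 1:6)))
  expect_equal(r, t(r))
  # brute-force loop oracle
  for (i in 1:6) for (j in 1:6) {
    x <- m[, i] - mean(m[, i]); y <- m[, j] - mean(m[, j])
    expect_equal(r[i, j], sum(x * y) / sqrt(sum(x^2) * sum(y^2)),
                 tolerance = 1e-12)
  }
  # exact anticorrelation
  xy <- cbind(a = 1:5, b = -(1:5))
  expect_equal(pearson_matrix(xy)["a", "b"], -1)
  expect_error(pearson_matrix(m[1:2, ]), "at least 3")
  # constant trait: flagged, zeroed off-diagonal, unit diagonal
  mc <- cbind(m, flat = rep(2, 10))
  rc <- pearson_matrix(mc)
  expect_equal(attr(rc, "constant_traits"), "flat")
  expect_true(all(rc["flat", colnames(m)] == 0))
  expect_equal(rc["flat", "flat"], 1)
})

test_that("correlation-network groups are components above a strict threshold", {
  id <- diag(4)
  dimnames(id) <- list(letters[1:4], letters[1:4])
  net <- cna_groups(id)
  expect_equal(nrow(net$edges), 0)
  expect_length(net$groups, 4)
  # 4-node chain at r = 0.8
  chain <- diag(4)
  chain[cbind(1:3, 2:4)] <- chain[cbind(2:4, 1:3)] <- 0.8
  dimnames(chain) <- list(letters[1:4], letters[1:4])
  net <- cna_groups(chain)
  expect_length(net$groups, 1)
  expect_setequal(net$groups[[1]], letters[1:4])
  # |r| equal to the threshold is NOT an edge
  eq <- diag(2); eq[1, 2] <- eq[2, 1] <- 0.7
  dimnames(eq) <- list(c("a", "b"), c("a", "b"))
  expect_length(cna_groups(eq, 0.7)$groups, 2)
  # negative correlations count through |r|
  neg <- diag(2); neg[1, 2] <- neg[2, 1] <- -0.9
  dimnames(neg) <- list(c("a", "b"), c("a", "b"))
  expect_length(cna_groups(neg)$groups, 1)
})

test_that("cna groups equal brute-force union-find on random matrices", {
  set.seed(71)
  for (i in 1:40) {
    n <- sample(3:30, 1)
    r <- matrix(stats::runif(n * n, -1, 1), n)
    r <- (r + t(r)) / 2; diag(r) <- 1
    dimnames(r) <- list(paste0("t", 1:n), paste0("t", 1:n))
    thr <- stats::runif(1, 0.3, 0.9)
    got <- cna_groups(r, thr)$groups
    want <- components_oracle(r, thr)
    expect_setequal(lapply(got, sort), lapply(want, sort))
    # groups partition the node set, sizes nonincreasing
    expect_setequal(unlist(got), rownames(r))
    expect_true(all(diff(lengths(got)) <= 0))
  }
})

test_that("trait distances follow the chosen variant", {
  r <- matrix(c(1, -1, -1, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(trait_distance(r)["a", "b"], 0)             # 1 - |r|
  expect_equal(trait_distance(r, "one_minus_r")["a", "b"], 2)
  expect_equal(diag(trait_distance(r)), c(a = 0, b = 0))
  set.seed(5)
  m <- matrix(stats::rnorm(50), 10)
  d <- trait_distance(pearson_matrix(m))
  expect_equal(d, t(d))
  expect_true(all(diag(d) == 0))
  expect_error(trait_distance(r, "nope"))
})

test_that("ward clustering matches from-scratch agglomerators", {
  # two items merge at their distance (classic variant)
  d2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("a", "b"), c("a", "b")))
  hc <- ward_hca(d2)
  expect_equal(hc$height, 3)
  # duplicate items merge first at height zero
  X <- rbind(c(0, 0), c(0, 0), c(5, 5))
  hc <- ward_hca(as.matrix(stats::dist(X)))
  expect_equal(hc$height[1], 0)
  expect_error(ward_hca(matrix(c(0, 1, 2, 0), 2)), "symmetric")

  set.seed(81)
  for (i in 1:20) {
    n <- sample(5:8, 1)
    X <- matrix(stats::rnorm(n * 2), n)
    # squared variant vs geometric minimum-variance oracle
    hc <- ward_hca(as.matrix(stats::dist(X)), variant = "squared")
    oracle <- ward_sse_oracle(X)
    expect_equal(hc$height, oracle$heights, tolerance = 1e-8)
    for (k in seq_len(n - 1))
      expect_equal(adjusted_rand_index(stats::cutree(hc, n - k),
                                       oracle$partitions[[k]]), 1)
    # classic variant vs plain Lance-Williams loop
    D <- as.matrix(stats::dist(X))
    hcc <- ward_hca(D, variant = "classic")
    lw <- ward_lw_oracle(D)
    expect_equal(hcc$height, lw$heights, tolerance = 1e-8)
    for (k in seq_len(n - 1))
      expect_equal(adjusted_rand_index(stats::cutree(hcc, n - k),
                                       lw$partitions[[k]]), 1)
    # heights nondecreasing along merges
    expect_true(all(diff(hcc$height) >= -1e-9))
  }
})

test_that("cut_k produces the requested number of clusters", {
  set.seed(9)
  X <- matrix(stats::rnorm(20), 10)
  hc <- ward_hca(as.matrix(stats::dist(X)))
  expect_equal(unname(cut_k(hc, 1)), rep(1, 10))
  expect_length(unique(cut_k(hc, 10)), 10)
  expect_error(cut_k(hc, 0), "between")
  expect_error(cut_k(hc, 11), "between")
  # three clean blocks are recovered exactly
  p <- block_panel(c(6, 6, 6), 60, rho = 0.9)
  hc <- ward_hca(trait_distance(pearson_matrix(p$x)))
  expect_equal(adjusted_rand_index(cut_k(hc, 3), p$blocks), 1)
})

test_that("two-way ordering is permutation-invariant and keeps duplicates adjacent", {
  set.seed(15)
  m <- matrix(stats::rnorm(80), 8, 10,
              dimnames = list(paste0("s", 1:8), paste0("t", 1:10)))
  tw <- two_way_order(m)
  expect_setequal(colnames(tw$matrix), colnames(m))
  expect_setequal(rownames(tw$matrix), rownames(m))
  # permuting input rows does not change trait cluster memberships
  perm <- sample(8)
  tw2 <- two_way_order(m[perm, ])
  expect_equal(adjusted_rand_index(cut_k(tw$row_hc, 3), cut_k(tw2$row_hc, 3)),
               1)
  # duplicated samples end up adjacent in the sample leaf order
  md <- rbind(m, s9 = m["s1", ] + stats::rnorm(10, sd = 1e-4))
  twd <- two_way_order(md)
  ord <- rownames(twd$matrix)
  expect_equal(abs(which(ord == "s9") - which(ord == "s1")), 1)
  # single sample: trivial column tree
  tw1 <- two_way_order(m[1, , drop = FALSE])
  expect_null(tw1$col_hc)
})

test_that("group-cluster concordance counts pair agreements", {
  g <- setNames(c(1, 1, 2, 2), letters[1:4])
  expect_equal(group_cluster_concordance(g, g)$agreement, 1)
  # a refinement maps each finer group into exactly one coarser cluster
  fine <- setNames(c(1, 2, 3, 3), letters[1:4])
  cc <- group_cluster_concordance(fine, g)
  expect_true(all(table(cc$overlap$group) == 1))
  # random partitions against brute-force pair counting
  set.seed(23)
  a <- setNames(sample(3, 12, TRUE), paste0("x", 1:12))
  b <- setNames(sample(4, 12, TRUE), paste0("x", 1:12))
  cc <- group_cluster_concordance(a, b)
  pairs <- utils::combn(12, 2)
  agree <- mean((a[pairs[1, ]] == a[pairs[2, ]]) ==
                  (b[pairs[1, ]] == b[pairs[2, ]]))
  expect_equal(cc$agreement, agree)
  expect_error(group_cluster_concordance(a, b[1:5]), "same traits")
})
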