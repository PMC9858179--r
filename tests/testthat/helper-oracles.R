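# Independent oracles and random-instance generators shared by the tests.
# Each oracle is a plain, loop-level restatement of the operation it checks,
# kept deliberately naive so it cannot share bugs with the vectorised
# implementation paths.

# Benjamini-Hochberg step-up, by definition: sort, m*p(i)/i, running min
# from the largest rank down, cap at 1, restore input order.
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  ps <- p[o]
  adj <- m * ps / seq_len(m)
  for (i in (m - 1):1) if (m > 1) adj[i] <- min(adj[i], adj[i + 1])
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# random introgression map: random marker positions, mix of contiguous
# introgression lines and fully scrambled callers (with missing calls)
random_imap <- function(n_lines, n_markers, p_na = 0.1) {
  map <- load_marker_map(data.frame(
    marker = sprintf("m%02d", seq_len(n_markers)), chrom = "chrX",
    pos_bp = sort(sample.int(5e6, n_markers))))
  lines <- sprintf("L%d", seq_len(n_lines))
  calls <- matrix("PS", n_lines, n_markers,
                  dimnames = list(lines, map$marker))
  for (i in seq_len(n_lines)) {
    if (stats::runif(1) < 0.5) {        # single contiguous introgression
      a <- sample.int(n_markers, 1)
      b <- sample(a:n_markers, 1)
      calls[i, a:b] <- "SC"
    } else {
      calls[i, ] <- sample(c("SC", "PS"), n_markers, replace = TRUE)
    }
    na <- stats::runif(n_markers) < p_na
    calls[i, na] <- NA
  }
  info <- data.frame(line = lines,
                     class = sample(c("NC", "LC_MC"), n_lines, replace = TRUE),
                     n_replicates = sample(3:9, n_lines, replace = TRUE),
                     lenient = sample(c(rep(0, n_lines - 1), 1)))
  introgression_map(map, calls, info)
}

# exhaustive clause-by-clause restatement of the substitution-mapping rule,
# one bin_state() lookup at a time
consistent_bins_oracle <- function(pattern, imap, config, exclude = character(0)) {
  use <- setdiff(names(pattern), exclude)
  sig <- use[pattern[use] != 0]
  if (!length(sig)) return(seq_len(nrow(imap$bins)))
  if (length(unique(sign(pattern[sig]))) > 1) return(integer(0))
  lenient_active <- config$use_leniency &&
    (!config$lenient_climacteric_only ||
       all(imap$lines[sig, "class"] == "LC_MC"))
  keep <- integer(0)
  for (b in seq_len(nrow(imap$bins))) {
    ok <- TRUE
    for (L in use) {
      st <- bin_state(imap, L, b)
      if (pattern[[L]] != 0) {
        if (st != "SC") ok <- FALSE
      } else if (!(lenient_active && imap$lines[L, "lenient"])) {
        if (st == "SC") ok <- FALSE
      }
    }
    if (ok) keep <- c(keep, b)
  }
  keep
}

# connected components above a threshold by union-find over all pairs
components_oracle <- function(corr, threshold) {
  n <- nrow(corr)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(corr[i, j]) > threshold) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  split(rownames(corr), roots)
}

# from-scratch Ward agglomeration on points: at each step merge the pair
# of clusters whose union least increases the total within-cluster sum of
# squares; merge height is sqrt(2 * increase) (the ward.D2 scale)
ward_sse_oracle <- function(X) {
  sse <- function(idx) {
    ctr <- colMeans(X[idx, , drop = FALSE])
    sum(sweep(X[idx, , drop = FALSE], 2, ctr)^2)
  }
  clusters <- as.list(seq_len(nrow(X)))
  heights <- numeric(0)
  partitions <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (i in seq_along(clusters)) for (j in seq_along(clusters)) {
      if (i >= j) next
      d <- sse(c(clusters[[i]], clusters[[j]])) -
        sse(clusters[[i]]) - sse(clusters[[j]])
      if (d < best_d - 1e-12) { best_d <- d; best <- c(i, j) }
    }
    heights <- c(heights, sqrt(2 * best_d))
    merged <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters <- c(clusters[-best], list(merged))
    memb <- integer(nrow(X))
    for (k in seq_along(clusters)) memb[clusters[[k]]] <- k
    partitions[[length(partitions) + 1]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# classic (ward.D-style) Lance-Williams agglomeration, plain loops
ward_lw_oracle <- function(D) {
  n <- nrow(D)
  size <- rep(1, n)
  active <- rep(TRUE, n)
  D <- as.matrix(D); diag(D) <- Inf
  heights <- numeric(0)
  memb <- seq_len(n)
  partitions <- list()
  repeat {
    idx <- which(active)
    if (length(idx) < 2) break
    best <- NULL; best_d <- Inf
    for (i in idx) for (j in idx) if (i < j && D[i, j] < best_d - 1e-12) {
      best_d <- D[i, j]; best <- c(i, j)
    }
    i <- best[1]; j <- best[2]
    heights <- c(heights, best_d)
    for (k in idx) {
      if (k == i || k == j) next
      D[i, k] <- D[k, i] <-
        ((size[i] + size[k]) * D[i, k] + (size[j] + size[k]) * D[j, k] -
           size[k] * best_d) / (size[i] + size[j] + size[k])
    }
    size[i] <- size[i] + size[j]
    active[j] <- FALSE
    memb[memb == memb[j]] <- memb[i]
    partitions[[length(partitions) + 1]] <- memb
  }
  list(heights = heights, partitions = partitions)
}

# block-correlated trait panel: latent factor per block, loading-sign
# flips so recovery must work on |r|
block_panel <- function(block_sizes, n_samples, rho = 0.9) {
  nt <- sum(block_sizes)
  blocks <- rep(seq_along(block_sizes), block_sizes)
  f <- matrix(stats::rnorm(n_samples * length(block_sizes)), n_samples)
  load_sign <- sample(c(-1, 1), nt, replace = TRUE)
  x <- sqrt(rho) * f[, blocks] * rep(load_sign, each = n_samples) +
    sqrt(1 - rho) * matrix(stats::rnorm(n_samples * nt), n_samples)
  colnames(x) <- sprintf("b%02d_t%03d", blocks, seq_len(nt))
  list(x = x, blocks = blocks)
}

# a NO_SIGNAL-padded call table for a full trait universe
pad_calls <- function(calls, traits) {
  missing <- setdiff(traits, calls$trait)
  if (!length(missing)) return(calls)
  pad <- calls[rep(1, length(missing)), ]
  pad$trait <- missing
  pad$status <- "NO_SIGNAL"
  pad$direction <- NA_integer_
  rbind(calls, pad)
}
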