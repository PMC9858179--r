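#' One-way ANOVA per trait with pedigree as factor
#'
#' Fixed-effects one-way ANOVA of each trait (column) on the line factor,
#' computed from group means and pooled sums of squares (vectorised over
#' traits). Traits with zero variance everywhere get F = 0, p = 1 by
#' convention (the trait is uninformative).
#'
#' @param logmat Numeric matrix, samples x traits (log2 scale).
#' @param groups Character/factor of length `nrow(logmat)`: line of each
#'   sample.
#' @return data.frame `trait`, `F`, `df_between`, `df_within`, `p_raw`.
#' @export
anova_per_trait <- function(logmat, groups) {
  logmat <- as.matrix(logmat)
  groups <- as.factor(groups)
  if (length(groups) != nrow(logmat))
    stop("groups must have one entry per sample (row)")
  k <- nlevels(groups)
  if (k < 2) stop("need at least 2 lines")
  n <- table(groups)
  if (any(n < 2)) stop("every line needs at least 2 samples")
  N <- nrow(logmat)
  gm <- rowsum(logmat, groups) / as.vector(n)        # k x traits group means
  grand <- colMeans(logmat)
  ss_between <- colSums(as.vector(n) * (gm - rep(grand, each = k))^2)
  ss_total <- colSums((logmat - rep(grand, each = N))^2)
  ss_within <- pmax(ss_total - ss_between, 0)
  df_b <- k - 1
  df_w <- N - k
  Fstat <- (ss_between / df_b) / (ss_within / df_w)
  p <- stats::pf(Fstat, df_b, df_w, lower.tail = FALSE)
  degenerate <- ss_within <= .Machine$double.eps * pmax(ss_total, 1)
  zero_all <- degenerate & ss_between <= .Machine$double.eps * pmax(ss_total, 1)
  Fstat[zero_all] <- 0
  p[zero_all] <- 1
  p[degenerate & !zero_all] <- 0   # perfect separation, no within noise
  traits <- colnames(logmat)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(logmat)))
  data.frame(trait = traits, F = unname(Fstat),
             df_between = df_b, df_within = df_w,
             p_raw = unname(p), stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Thin, validated wrapper around `stats::p.adjust(method = "BH")`:
#' p(i) -> min over j >= i of m * p(j) / j, capped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Retain traits passing the BH-corrected ANOVA screen
#'
#' @param anova_res Result of [anova_per_trait()].
#' @param alpha Screening level (default 0.05). Retention is strict:
#'   `p_adj < alpha`.
#' @return The input with a `p_adj` column, restricted to retained traits.
#' @export
screen_traits <- function(anova_res, alpha = 0.05) {
  stopifnot(is.data.frame(anova_res), "p_raw" %in% names(anova_res))
  anova_res$p_adj <- bh_adjust(anova_res$p_raw)
  anova_res[anova_res$p_adj < alpha, , drop = FALSE]
}

# P(max_i |T_i| >= t) for the Dunnett many-to-one statistic vector:
# equicorrelated-by-lambda multivariate t, rho_ij = lambda_i * lambda_j,
# lambda_i = sqrt(n_i / (n_i + n0)). Quasi-Monte-Carlo (Genz-Bretz) with a
# fixed seed so results are reproducible to the stated tolerance.
dunnett_tail <- function(t, lambda, df, abseps = 1e-3, qmc_seed = 20230113L) {
  if (length(lambda) == 1) # single contrast: plain two-sided t
    return(2 * stats::pt(-abs(t), df))
  R <- outer(lambda, lambda)
  diag(R) <- 1
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(qmc_seed)
  inside <- mvtnorm::pmvt(lower = rep(-abs(t), length(lambda)),
                          upper = rep(abs(t), length(lambda)),
                          df = df, corr = R,
                          algorithm = mvtnorm::GenzBretz(abseps = abseps,
                                                         maxpts = 50000L))
  min(max(1 - as.numeric(inside), 0), 1)
}

#' Dunnett many-to-one comparisons against a control line
#'
#' Simultaneously compares each non-control line mean with the control
#' mean, per trait, using the pooled within-line variance (df = N - k).
#' Two-sided adjusted p-values are tail probabilities of the maximum
#' absolute component of the joint multivariate t distribution of the
#' contrast statistics, with correlation rho_ij = lambda_i lambda_j,
#' lambda_i = sqrt(n_i / (n_i + n_control)).
#'
#' @param logmat Numeric matrix, samples x traits (log2 scale).
#' @param groups Line of each sample.
#' @param control Name of the control line (default `"PS"`).
#' @param alpha Significance level for the `significant` flag (strict
#'   `p_adj < alpha`; default 0.05).
#' @param abseps Absolute tolerance of the quasi-Monte-Carlo tail
#'   integration (default 1e-3).
#' @param qmc_seed Fixed seed of the quasi-Monte-Carlo integration.
#' @return data.frame with one row per (trait, line): `trait`, `line`,
#'   `estimate` (log2 mean difference vs control), `t`, `df`, `p_adj`,
#'   `significant`.
#' @export
dunnett_many_to_one <- function(logmat, groups, control = "PS", alpha = 0.05,
                                abseps = 1e-3, qmc_seed = 20230113L) {
  logmat <- as.matrix(logmat)
  groups <- as.character(groups)
  if (!control %in% groups) stop("control line '", control, "' not present")
  lev <- c(control, setdiff(unique(groups), control))
  if (length(lev) < 2) stop("need at least one non-control line")
  f <- factor(groups, levels = lev)
  n <- table(f)
  if (any(n < 2)) stop("every line needs at least 2 samples")
  k <- length(lev)
  N <- length(groups)
  df <- N - k
  gm <- rowsum(logmat, f) / as.vector(n)
  # pooled within-group variance per trait
  ss_w <- colSums((logmat - gm[as.integer(f), , drop = FALSE])^2)
  s2 <- ss_w / df
  trt <- lev[-1]
  lambda <- sqrt(as.vector(n[trt]) / (as.vector(n[trt]) + n[[control]]))
  se_scale <- sqrt(1 / as.vector(n[trt]) + 1 / n[[control]])
  traits <- colnames(logmat)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(logmat)))
  res <- vector("list", ncol(logmat))
  for (j in seq_len(ncol(logmat))) {
    est <- gm[trt, j] - gm[control, j]
    if (s2[j] <= 0) {
      tj <- ifelse(est == 0, 0, Inf * sign(est))
      pj <- ifelse(est == 0, 1, 0)
    } else {
      tj <- est / (sqrt(s2[j]) * se_scale)
      pj <- vapply(tj, dunnett_tail, numeric(1),
                   lambda = lambda, df = df, abseps = abseps,
                   qmc_seed = qmc_seed)
    }
    res[[j]] <- data.frame(trait = traits[j], line = trt,
                           estimate = unname(est), t = unname(tj), df = df,
                           p_adj = unname(pj),
                           significant = unname(pj < alpha),
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Per-line significance patterns from Dunnett results
#'
#' Collapses Dunnett output to the trait x line sign pattern that drives
#' substitution mapping: +1 / -1 for lines significantly above / below
#' the control, 0 otherwise.
#'
#' @param dunnett Result of [dunnett_many_to_one()].
#' @return Integer matrix, traits x lines, values in `-1, 0, 1`.
#' @export
significance_patterns <- function(dunnett) {
  stopifnot(all(c("trait", "line", "estimate", "significant") %in% names(dunnett)))
  traits <- unique(dunnett$trait)
  lines <- unique(dunnett$line)
  pat <- matrix(0L, length(traits), length(lines),
                dimnames = list(traits, lines))
  sig <- dunnett[dunnett$significant, , drop = FALSE]
  if (nrow(sig))
    pat[cbind(match(sig$trait, traits), match(sig$line, lines))] <-
      as.integer(sign(sig$estimate))
  pat
}

#' Flag potential outliers by the 1.5 IQR box-whisker rule
#'
#' Reporting aid only: observations beyond 1.5 interquartile ranges from
#' their line's quartiles are listed, never removed.
#'
#' @param mat Numeric matrix, samples x traits.
#' @param groups Line of each sample.
#' @return data.frame `sample`, `trait`, `line`, `value`.
#' @export
flag_outliers <- function(mat, groups) {
  mat <- as.matrix(mat)
  groups <- as.character(groups)
  samples <- rownames(mat)
  if (is.null(samples)) samples <- as.character(seq_len(nrow(mat)))
  traits <- colnames(mat)
  if (is.null(traits)) traits <- paste0("trait", seq_len(ncol(mat)))
  out <- list()
  for (g in unique(groups)) {
    i <- which(groups == g)
    q <- apply(mat[i, , drop = FALSE], 2, stats::quantile,
               probs = c(0.25, 0.75), names = FALSE)
    iqr <- q[2, ] - q[1, ]
    lo <- q[1, ] - 1.5 * iqr
    hi <- q[2, ] + 1.5 * iqr
    bad <- which(t(mat[i, , drop = FALSE]) < lo | t(mat[i, , drop = FALSE]) > hi,
                 arr.ind = TRUE)
    if (nrow(bad))
      out[[g]] <- data.frame(sample = samples[i][bad[, 2]],
                             trait = traits[bad[, 1]], line = g,
                             value = mat[i, , drop = FALSE][cbind(bad[, 2], bad[, 1])],
                             stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(sample = character(), trait = character(),
                      line = character(), value = numeric(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
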