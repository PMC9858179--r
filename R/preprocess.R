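#' Normalise raw peak areas to per-sample relative abundances
#'
#' Each cell becomes 100 * raw / (sample total), so every sample sums to
#' 100 over the full trait set. Relative (compositional) abundances are
#' the working scale of the whole pipeline; subsets of traits sum to less
#' than 100.
#'
#' @param raw Numeric matrix, samples x traits, non-negative.
#' @return Matrix of the same shape; rows sum to 100. Carries attribute
#'   `normalized = TRUE`.
#' @export
normalize_relative <- function(raw) {
  raw <- as.matrix(raw)
  if (any(raw < 0, na.rm = TRUE)) stop("raw areas must be non-negative")
  tot <- rowSums(raw)
  if (any(tot <= 0)) {
    bad <- which(tot <= 0)
    stop("sample(s) with all-zero areas: ",
         paste(if (is.null(rownames(raw))) bad else rownames(raw)[bad],
               collapse = ", "))
  }
  out <- 100 * raw / tot
  attr(out, "normalized") <- TRUE
  out
}

#' Substitute zeros by the minimum non-zero value
#'
#' Zeros in VOC tables are detection-limit censoring, not true absence;
#' before log transformation they are replaced by the smallest non-zero
#' value observed. The default follows the literal whole-dataset reading:
#' one global constant across all samples and traits. `per_trait`
#' substitutes each trait's own minimum non-zero value instead (traits
#' that are entirely zero fall back to the global constant).
#'
#' @param mat Numeric matrix with at least one non-zero value.
#' @param method `"global"` (default) or `"per_trait"`.
#' @return Matrix with all zeros replaced; attribute `substitution`
#'   records the constant(s) used.
#' @export
substitute_zeros <- function(mat, method = c("global", "per_trait")) {
  method <- match.arg(method)
  mat <- as.matrix(mat)
  if (any(mat < 0)) stop("abundances must be non-negative")
  nz <- mat[mat > 0]
  if (!length(nz)) stop("all-zero matrix: nothing to substitute with")
  gmin <- min(nz)
  if (method == "global") {
    mat[mat == 0] <- gmin
    attr(mat, "substitution") <- gmin
  } else {
    sub <- apply(mat, 2, function(x) if (any(x > 0)) min(x[x > 0]) else gmin)
    for (j in seq_len(ncol(mat))) mat[mat[, j] == 0, j] <- sub[j]
    attr(mat, "substitution") <- sub
  }
  mat
}

#' Elementwise log2 transform
#'
#' @param mat Strictly positive numeric matrix (run [substitute_zeros()]
#'   first).
#' @return Matrix of log2 values.
#' @export
log2_transform <- function(mat) {
  mat <- as.matrix(mat)
  if (any(mat <= 0)) stop("log2 transform needs strictly positive values")
  out <- log2(mat)
  attr(out, "substitution") <- attr(mat, "substitution")
  out
}

#' Aggregate traits into compound-class totals
#'
#' Sums the per-sample relative abundances of the member traits of each
#' compound class (acetate esters, aldehydes, ...). Class totals commute
#' with per-sample normalisation.
#'
#' @param mat Numeric matrix, samples x traits, with column names.
#' @param classes Named character vector mapping every trait (column) to
#'   its class; an empty class yields a zero column when listed in
#'   `levels`.
#' @param levels Optional class ordering (default: unique classes in
#'   `classes`).
#' @return Matrix samples x classes.
#' @export
class_totals <- function(mat, classes, levels = NULL) {
  mat <- as.matrix(mat)
  if (is.null(colnames(mat))) stop("trait matrix needs column names")
  miss <- setdiff(colnames(mat), names(classes))
  if (length(miss))
    stop("trait(s) with unknown class: ", paste(miss, collapse = ", "))
  cls <- classes[colnames(mat)]
  if (is.null(levels)) levels <- unique(unname(cls))
  out <- sapply(levels, function(k) {
    j <- which(cls == k)
    if (!length(j)) rep(0, nrow(mat)) else rowSums(mat[, j, drop = FALSE])
  })
  out <- matrix(out, nrow = nrow(mat),
                dimnames = list(rownames(mat), levels))
  out
}
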