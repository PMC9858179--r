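#' Build a validated marker map
#'
#' A marker map is an ordered table of genotyped markers on a single
#' chromosome with physical (bp) positions, the coordinate backbone of
#' substitution mapping. Positions are 1-based and must be strictly
#' increasing in map order.
#'
#' @param markers A data.frame with columns `marker`, `chrom`, `pos_bp`
#'   (coercible to integer-valued positive numbers).
#' @return A data.frame of class `marker_map` with columns
#'   `marker`, `chrom`, `pos_bp`.
#' @examples
#' m <- load_marker_map(data.frame(
#'   marker = c("A", "B"), chrom = "chr3", pos_bp = c(100L, 2000L)))
#' @export
load_marker_map <- function(markers) {
  stopifnot(is.data.frame(markers))
  need <- c("marker", "chrom", "pos_bp")
  if (!all(need %in% names(markers)))
    stop("marker map needs columns: ", paste(need, collapse = ", "))
  out <- data.frame(
    marker = as.character(markers$marker),
    chrom  = as.character(markers$chrom),
    pos_bp = markers$pos_bp,
    stringsAsFactors = FALSE
  )
  pos <- suppressWarnings(as.numeric(out$pos_bp))
  if (anyNA(pos) || any(pos < 1) || any(pos != round(pos)))
    stop("marker positions must be positive integers")
  out$pos_bp <- as.numeric(round(pos))
  if (anyDuplicated(out$marker))
    stop("duplicate marker name: ",
         paste(unique(out$marker[duplicated(out$marker)]), collapse = ", "))
  if (nrow(out) > 1 && any(diff(out$pos_bp) <= 0))
    stop("marker positions must be strictly increasing in map order")
  if (length(unique(out$chrom)) > 1)
    stop("a marker map covers a single chromosome")
  class(out) <- c("marker_map", "data.frame")
  out
}

#' Derive the marker-interval bins of a map
#'
#' Bins are the intervals between adjacent markers: the atomic resolution
#' unit of substitution mapping. For m markers there are m-1 bins, tiling
#' the interval between the first and last marker with no gaps or overlaps.
#'
#' @param map A `marker_map`.
#' @return A data.frame with columns `index`, `left_marker`, `right_marker`,
#'   `left_pos`, `right_pos`.
#' @export
derive_bins <- function(map) {
  stopifnot(inherits(map, "marker_map"))
  m <- nrow(map)
  if (m < 2) stop("need at least 2 markers to derive bins")
  data.frame(
    index = seq_len(m - 1),
    left_marker  = map$marker[-m],
    right_marker = map$marker[-1],
    left_pos  = map$pos_bp[-m],
    right_pos = map$pos_bp[-1],
    stringsAsFactors = FALSE
  )
}

#' Assemble an introgression map from marker map, genotype calls and line
#' metadata
#'
#' Ties together the marker map, the per-line genotype calls (donor `SC`,
#' recurrent `PS`, or `NA` for a failed assay) and per-line metadata:
#' climacteric class (`NC` or `LC_MC`), replicate count and the `lenient`
#' flag marking lines whose non-significant results are treated as
#' non-informative during mapping (here SC3-5-13, whose climacteric
#' behaviour was season-dependent).
#'
#' @param map A `marker_map`.
#' @param calls Character matrix, rows = lines, columns = markers, values
#'   in `SC`, `PS` or `NA`. Column names must equal the map's markers.
#' @param line_info data.frame with columns `line`, `class`
#'   (`NC`/`LC_MC`), `n_replicates`, `lenient` (logical or 0/1). Rows must
#'   cover the rownames of `calls`.
#' @return An object of class `introgression_map`: a list with elements
#'   `markers`, `bins`, `calls`, `lines`.
#' @export
introgression_map <- function(map, calls, line_info) {
  stopifnot(inherits(map, "marker_map"), is.matrix(calls))
  if (!identical(colnames(calls), map$marker))
    stop("genotype columns must match the marker map (same markers, same order)")
  bad <- setdiff(unique(as.vector(calls)), c("SC", "PS", NA))
  if (length(bad))
    stop("unknown genotype code: ", paste(bad, collapse = ", "))
  if (is.null(rownames(calls))) stop("genotype matrix needs line rownames")
  li <- as.data.frame(line_info, stringsAsFactors = FALSE)
  need <- c("line", "class", "n_replicates", "lenient")
  if (!all(need %in% names(li)))
    stop("line_info needs columns: ", paste(need, collapse = ", "))
  if (!all(rownames(calls) %in% li$line))
    stop("line_info must cover every genotyped line")
  li <- li[match(rownames(calls), li$line), , drop = FALSE]
  if (!all(li$class %in% c("NC", "LC_MC")))
    stop("climacteric class must be NC or LC_MC")
  li$n_replicates <- as.integer(li$n_replicates)
  if (any(is.na(li$n_replicates)) || any(li$n_replicates < 1))
    stop("n_replicates must be a positive integer")
  li$lenient <- as.logical(as.integer(as.logical(li$lenient)))
  rownames(li) <- li$line
  structure(
    list(markers = map, bins = derive_bins(map), calls = calls, lines = li),
    class = "introgression_map"
  )
}

#' @export
print.introgression_map <- function(x, ...) {
  cat(sprintf("introgression map: %d markers on %s (%s..%s), %d bins, %d lines\n",
              nrow(x$markers), x$markers$chrom[1],
              format(min(x$markers$pos_bp), big.mark = ","),
              format(max(x$markers$pos_bp), big.mark = ","),
              nrow(x$bins), nrow(x$calls)))
  invisible(x)
}

#' Genotype state of one line in one bin
#'
#' A bin is `SC` when both flanking marker calls are `SC`, `PS` when both
#' are `PS`, and `UNCERTAIN` otherwise: discordant flanks mean the
#' recombination breakpoint lies somewhere inside the bin, and a missing
#' flank leaves the bin unresolved.
#'
#' @param imap An `introgression_map`.
#' @param line Line name.
#' @param bin Bin index (1-based).
#' @return One of `"SC"`, `"PS"`, `"UNCERTAIN"`.
#' @export
bin_state <- function(imap, line, bin) {
  stopifnot(inherits(imap, "introgression_map"))
  if (!line %in% rownames(imap$calls)) stop("unknown line: ", line)
  b <- imap$bins[bin, ]
  l <- imap$calls[line, b$left_marker]
  r <- imap$calls[line, b$right_marker]
  if (!is.na(l) && !is.na(r) && l == r) return(unname(l))
  "UNCERTAIN"
}

#' Bin-state matrix for all lines
#'
#' @param imap An `introgression_map`.
#' @return Character matrix lines x bins with values `SC`/`PS`/`UNCERTAIN`.
#' @export
bin_states <- function(imap) {
  stopifnot(inherits(imap, "introgression_map"))
  nb <- nrow(imap$bins)
  lines <- rownames(imap$calls)
  st <- matrix("UNCERTAIN", length(lines), nb,
               dimnames = list(lines, NULL))
  lmk <- imap$bins$left_marker
  rmk <- imap$bins$right_marker
  for (i in seq_along(lines)) {
    l <- imap$calls[i, lmk]
    r <- imap$calls[i, rmk]
    same <- !is.na(l) & !is.na(r) & l == r
    st[i, same] <- l[same]
  }
  st
}

#' Donor (SC) introgression segments of a line
#'
#' Reports, for each maximal run of SC marker calls, the certain interval
#' (spanned by the outermost SC markers) and the maximal interval obtained
#' by extending through flanking UNCERTAIN bins up to the nearest PS
#' marker (or the map edge). The true breakpoints lie between the two.
#'
#' @param imap An `introgression_map`.
#' @param line Line name.
#' @return data.frame with one row per segment: `line`, `certain_left`,
#'   `certain_right`, `maximal_left`, `maximal_right`. Zero rows when the
#'   line carries no SC call.
#' @export
sc_segments <- function(imap, line) {
  stopifnot(inherits(imap, "introgression_map"))
  if (!line %in% rownames(imap$calls)) stop("unknown line: ", line)
  calls <- imap$calls[line, ]
  pos <- imap$markers$pos_bp
  is_sc <- !is.na(calls) & calls == "SC"
  is_ps <- !is.na(calls) & calls == "PS"
  empty <- data.frame(line = character(), certain_left = numeric(),
                      certain_right = numeric(), maximal_left = numeric(),
                      maximal_right = numeric(), stringsAsFactors = FALSE)
  if (!any(is_sc)) return(empty)
  r <- rle(is_sc)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  segs <- lapply(which(r$values), function(k) {
    i0 <- starts[k]; i1 <- ends[k]
    # extend through non-PS (uncertain) markers to the nearest PS marker
    j0 <- i0
    while (j0 > 1 && !is_ps[j0 - 1]) j0 <- j0 - 1
    if (j0 > 1) j0 <- j0 - 1  # the bounding PS marker itself
    j1 <- i1
    while (j1 < length(calls) && !is_ps[j1 + 1]) j1 <- j1 + 1
    if (j1 < length(calls)) j1 <- j1 + 1
    data.frame(line = line,
               certain_left = pos[i0], certain_right = pos[i1],
               maximal_left = pos[j0], maximal_right = pos[j1],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, segs)
}

#' Physical length between two markers in Mb
#'
#' @param map A `marker_map` (or `introgression_map`).
#' @param left,right Marker names, left before right in map order. Equal
#'   markers give 0.
#' @return Length in megabases, rounded half-up to 2 decimals.
#' @examples
#' # the ETHQB3.5 interval CMPSNP374..AI_14-F04 spans 1.24 Mb
#' @export
interval_length_mb <- function(map, left, right) {
  if (inherits(map, "introgression_map")) map <- map$markers
  stopifnot(inherits(map, "marker_map"))
  i <- match(left, map$marker)
  j <- match(right, map$marker)
  if (is.na(i)) stop("unknown marker: ", left)
  if (is.na(j)) stop("unknown marker: ", right)
  if (i > j) stop("markers out of order: ", left, " is after ", right)
  # round half-up at the 2nd decimal (round() would round half-to-even)
  floor((map$pos_bp[j] - map$pos_bp[i]) / 1e6 * 100 + 0.5) / 100
}

#' Define a region of interest by marker pair
#'
#' @param map A `marker_map` or `introgression_map`.
#' @param name Region name, e.g. `"ETHQB3.5"`.
#' @param left_marker,right_marker Flanking marker names.
#' @return A list of class `region_of_interest` with `name`, `chrom`,
#'   `left_pos`, `right_pos`.
#' @export
region_of_interest <- function(map, name, left_marker, right_marker) {
  if (inherits(map, "introgression_map")) map <- map$markers
  stopifnot(inherits(map, "marker_map"))
  i <- match(left_marker, map$marker); j <- match(right_marker, map$marker)
  if (is.na(i) || is.na(j)) stop("ROI markers must be in the map")
  if (map$pos_bp[i] >= map$pos_bp[j]) stop("ROI: left_pos must be < right_pos")
  structure(list(name = name, chrom = map$chrom[1],
                 left_pos = map$pos_bp[i], right_pos = map$pos_bp[j]),
            class = "region_of_interest")
}

#' The climacteric-ripening region ETHQB3.5
#'
#' Convenience constructor for the default region of interest between
#' markers CMPSNP374 and AI_14-F04 (25,197,968..26,434,021 bp on melon
#' chromosome 3, genome v4.0; 1.24 Mb).
#'
#' @param map A `marker_map` or `introgression_map` containing both markers.
#' @return A `region_of_interest`.
#' @export
ethqb35_region <- function(map) {
  region_of_interest(map, "ETHQB3.5", "CMPSNP374", "AI_14-F04")
}
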