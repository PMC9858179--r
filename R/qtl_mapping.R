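#' Mapping configuration presets
#'
#' `voc_mapping_config()` is the profile for individual volatile traits:
#' strict single-sign mapping, no dominant-direction fallback, leniency
#' active for flagged lines but only when every significant line is
#' climacteric (`LC_MC`). `class_mapping_config()` is the profile for
#' compound-class traits: dominant-direction fallback enabled (a class
#' aggregates opposite-signed member QTLs) and leniency disabled.
#'
#' @param use_leniency Honour the `lenient` flag of lines.
#' @param lenient_climacteric_only Restrict leniency to patterns whose
#'   significant lines are all climacteric.
#' @param fallback Enable the dominant-direction mode for mixed-sign
#'   patterns.
#' @return A list of class `mapping_config`.
#' @export
mapping_config <- function(use_leniency = TRUE, lenient_climacteric_only = TRUE,
                           fallback = FALSE) {
  structure(list(use_leniency = use_leniency,
                 lenient_climacteric_only = lenient_climacteric_only,
                 fallback = fallback),
            class = "mapping_config")
}

#' @rdname mapping_config
#' @export
voc_mapping_config <- function() mapping_config(TRUE, TRUE, FALSE)

#' @rdname mapping_config
#' @export
class_mapping_config <- function() mapping_config(FALSE, TRUE, TRUE)

#' Bins consistent with a significance pattern
#'
#' The substitution-mapping kernel. A bin supports a single QTL for the
#' pattern when every line with a significant effect certainly carries
#' the donor segment there (bin state `SC`; an uncertain recombination
#' gap is not evidence of presence), and no line without an effect
#' certainly carries it (state `PS` or `UNCERTAIN` required; only certain
#' donor coverage excludes). Non-significant entries of lenient lines are
#' skipped when leniency applies (see [mapping_config()]). All
#' significant entries must share one sign; a mixed-sign pattern has no
#' consistent bin in strict mode.
#'
#' @param pattern Named integer vector, line -> -1/0/+1. Names must be
#'   genotyped lines of `imap`.
#' @param imap An `introgression_map`.
#' @param config A `mapping_config`.
#' @param exclude Lines whose entries impose no constraint (used by the
#'   dominant-direction mode).
#' @param states Optional precomputed [bin_states()] matrix.
#' @return Integer vector of consistent bin indices (possibly empty).
#' @export
consistent_bins <- function(pattern, imap, config = voc_mapping_config(),
                            exclude = character(0), states = NULL) {
  stopifnot(inherits(imap, "introgression_map"))
  if (is.null(names(pattern))) stop("pattern must be named by line")
  unknown <- setdiff(names(pattern), rownames(imap$calls))
  if (length(unknown)) stop("pattern line(s) not in map: ",
                            paste(unknown, collapse = ", "))
  if (is.null(states)) states <- bin_states(imap)
  use <- setdiff(names(pattern), exclude)
  sig <- use[pattern[use] != 0]
  if (length(sig) && length(unique(sign(pattern[sig]))) > 1) return(integer(0))
  if (!length(sig)) return(seq_len(nrow(imap$bins)))  # vacuous; caller handles
  lenient_ok <- config$use_leniency &&
    (!config$lenient_climacteric_only ||
       all(imap$lines[sig, "class"] == "LC_MC"))
  ok <- rep(TRUE, nrow(imap$bins))
  for (L in use) {
    st <- states[L, ]
    if (pattern[[L]] != 0) {
      ok <- ok & (st == "SC")
    } else {
      if (lenient_ok && isTRUE(imap$lines[L, "lenient"])) next
      ok <- ok & (st != "SC")
    }
  }
  which(ok)
}

# contiguous runs of a sorted integer vector -> list of integer vectors
.bin_runs <- function(bins) {
  if (!length(bins)) return(list())
  unname(split(bins, cumsum(c(1L, diff(bins) != 1L))))
}

.run_interval <- function(run, imap) {
  c(left = imap$bins$left_pos[min(run)], right = imap$bins$right_pos[max(run)])
}

.overlaps_roi <- function(iv, roi) {
  # positive-length overlap; intervals that merely touch at a marker do not
  # colocalize
  min(iv[["right"]], roi$right_pos) - max(iv[["left"]], roi$left_pos) > 0
}

#' Map a single-QTL interval for one trait
#'
#' Applies strict substitution mapping first; on a mixed-sign (or empty)
#' outcome with fallback enabled, retries once per sign with the
#' opposite-signed lines excluded (dominant-direction mode). Among the
#' contiguous consistent runs, the primary interval is the run
#' intersecting the region of interest if any, else the run with most
#' bins (ties: leftmost); the others are retained as alternates.
#'
#' @param pattern Named line -> -1/0/+1 vector.
#' @param imap An `introgression_map`.
#' @param roi A `region_of_interest`.
#' @param config A `mapping_config`.
#' @param trait Trait label carried into the result.
#' @param states Optional precomputed [bin_states()].
#' @return One-row data.frame of class `qtl_call`: `trait`, `status`
#'   (`MAPPED`/`NO_SIGNAL`/`NOT_INTERPRETABLE`), `direction`,
#'   `left_marker`, `right_marker`, `left_pos`, `right_pos`,
#'   `colocalizes_roi`, `position_class`, `scenario`, `ethylene`,
#'   `mode_used`, `alternates` (semicolon-joined `left..right` bp spans).
#' @export
map_single_qtl <- function(pattern, imap, roi, config = voc_mapping_config(),
                           trait = "trait", states = NULL) {
  if (is.null(states)) states <- bin_states(imap)
  empty_call <- function(status) {
    data.frame(trait = trait, status = status, direction = NA_integer_,
               left_marker = NA_character_, right_marker = NA_character_,
               left_pos = NA_real_, right_pos = NA_real_,
               colocalizes_roi = NA, position_class = "none",
               scenario = if (status == "NO_SIGNAL") "none" else "iii",
               ethylene = NA_integer_,
               mode_used = NA_character_, alternates = "",
               stringsAsFactors = FALSE)
  }
  nz <- pattern[pattern != 0]
  if (!length(nz)) return(empty_call("NO_SIGNAL"))
  signs <- unique(sign(nz))
  mode_used <- "strict"
  if (length(signs) == 1) {
    bins <- consistent_bins(pattern, imap, config, states = states)
    dir <- signs
  } else {
    bins <- integer(0)
  }
  if (!length(bins) && isTRUE(config$fallback)) {
    per_sign <- lapply(signs, function(s) {
      consistent_bins(pattern, imap, config,
                      exclude = names(pattern)[sign(pattern) == -s],
                      states = states)
    })
    nonempty <- vapply(per_sign, function(b) length(b) > 0, logical(1))
    if (sum(nonempty) == 1) {
      bins <- per_sign[[which(nonempty)]]
      dir <- signs[which(nonempty)]
      mode_used <- "dominant_direction"
    } else {
      return(empty_call("NOT_INTERPRETABLE"))  # none, or both signs map
    }
  }
  if (!length(bins)) return(empty_call("NOT_INTERPRETABLE"))
  runs <- .bin_runs(bins)
  ivs <- lapply(runs, .run_interval, imap = imap)
  hits <- vapply(ivs, .overlaps_roi, logical(1), roi = roi)
  pick <- if (any(hits)) which(hits)[1] else {
    sizes <- lengths(runs)
    which(sizes == max(sizes))[1]              # ties -> leftmost
  }
  run <- runs[[pick]]
  iv <- ivs[[pick]]
  coloc <- hits[pick]
  alt <- ivs[-pick]
  pos_class <- if (coloc) "IN_ROI"
  else if (iv[["right"]] <= roi$left_pos) "LEFT_OF_ROI"
  else "RIGHT_OF_ROI"
  data.frame(trait = trait, status = "MAPPED", direction = as.integer(dir),
             left_marker = imap$bins$left_marker[min(run)],
             right_marker = imap$bins$right_marker[max(run)],
             left_pos = iv[["left"]], right_pos = iv[["right"]],
             colocalizes_roi = coloc, position_class = pos_class,
             scenario = if (coloc) "i" else "ii",
             ethylene = if (coloc) 1L else -1L,
             mode_used = mode_used,
             alternates = paste(vapply(alt, function(v)
               sprintf("%d..%d", as.integer(v[["left"]]),
                       as.integer(v[["right"]])), character(1)),
               collapse = ";"),
             stringsAsFactors = FALSE)
}

#' Map a whole panel of trait patterns
#'
#' @param patterns Integer matrix traits x lines in `-1, 0, 1` (as from
#'   [significance_patterns()]).
#' @param imap An `introgression_map`.
#' @param roi A `region_of_interest`.
#' @param config A `mapping_config`.
#' @return data.frame with one `qtl_call` row per trait.
#' @export
map_trait_panel <- function(patterns, imap, roi,
                            config = voc_mapping_config()) {
  stopifnot(is.matrix(patterns))
  states <- bin_states(imap)
  calls <- lapply(rownames(patterns), function(tr) {
    map_single_qtl(patterns[tr, ], imap, roi, config, trait = tr,
                   states = states)
  })
  out <- do.call(rbind, calls)
  rownames(out) <- NULL
  out
}

#' Ethylene-dependence label of QTL calls
#'
#' A mapped QTL whose interval colocalizes with the climacteric region is
#' ethylene-dependent (+1); a mapped QTL elsewhere is
#' ethylene-independent (-1); unmapped traits are unclassified (NA).
#'
#' @param calls data.frame of QTL calls.
#' @return Integer vector +1 / -1 / NA.
#' @export
classify_ethylene <- function(calls) {
  ifelse(calls$status == "MAPPED", ifelse(calls$colocalizes_roi, 1L, -1L),
         NA_integer_)
}

#' Mapping scenario class
#'
#' Scenario (i): mapped and colocalizing with the region of interest;
#' (ii): mapped elsewhere; (iii): the trait's segregation is not
#' compatible with a single QTL in the studied region. Traits with no
#' significant line at all have no scenario.
#'
#' @param calls data.frame of QTL calls.
#' @return Character vector `"i"`, `"ii"`, `"iii"` (errors on `NO_SIGNAL`
#'   rows when `strict = TRUE`).
#' @param strict Error on NO_SIGNAL input rows (default TRUE).
#' @export
scenario_class <- function(calls, strict = TRUE) {
  if (strict && any(calls$status == "NO_SIGNAL"))
    stop("scenario is undefined for NO_SIGNAL traits")
  calls$scenario
}

#' Count table of a panel of QTL calls
#'
#' @param calls data.frame of QTL calls.
#' @return Named list of counts: `n_traits`, `n_mapped`, `n_up`, `n_down`,
#'   `n_in_roi`, `n_in_roi_up`, `n_in_roi_down`, `n_outside`,
#'   `n_outside_left`, `n_outside_right`, `n_not_interpretable`,
#'   `n_no_signal`.
#' @export
summarize_qtl_table <- function(calls) {
  m <- calls$status == "MAPPED"
  roi <- m & calls$colocalizes_roi %in% TRUE
  list(
    n_traits = nrow(calls),
    n_mapped = sum(m),
    n_up = sum(m & calls$direction %in% 1L),
    n_down = sum(m & calls$direction %in% -1L),
    n_in_roi = sum(roi),
    n_in_roi_up = sum(roi & calls$direction %in% 1L),
    n_in_roi_down = sum(roi & calls$direction %in% -1L),
    n_outside = sum(m & !roi),
    n_outside_left = sum(m & calls$position_class == "LEFT_OF_ROI"),
    n_outside_right = sum(m & calls$position_class == "RIGHT_OF_ROI"),
    n_not_interpretable = sum(calls$status == "NOT_INTERPRETABLE"),
    n_no_signal = sum(calls$status == "NO_SIGNAL")
  )
}
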