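# Packaged fixtures: the chromosome-3 marker map, the derived NIL
# genotype reconstruction, and the transcribed printed tables of the
# source study (per-trait means, Dunnett sign patterns, mapped-QTL truth,
# correlation-network groups). Loaders run integrity checks so a
# corrupted installation fails loudly rather than silently changing
# results.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "introqtl")
  if (p == "") stop("packaged fixture not found: ", file)
  p
}

#' The chromosome-3 marker map fixture
#'
#' Fifteen markers anchored to melon genome v4.0, CMPSNP556
#' (20,373,958 bp) to ECM125 (27,145,624 bp).
#'
#' @return A `marker_map` with 15 rows.
#' @export
melon_markers <- function() {
  map <- read_marker_map(fixture_path("markers_chr3.tsv"))
  stopifnot(nrow(map) == 15, all(diff(map$pos_bp) > 0))
  map
}

#' The six-line melon introgression panel
#'
#' Marker map plus per-line genotype calls and metadata for the control
#' 'Piel de Sapo' (PS) and the five NILs SC3-5-7/8/12/13/14. The
#' genotype matrix is a derived reconstruction: the published ideogram is
#' graphical only, so introgression extents were obtained by constraint
#' satisfaction against the published per-trait mapping outcomes (see the
#' methods vignette). SC3-5-13 carries the `lenient` flag.
#'
#' @return An `introgression_map`.
#' @export
melon_introgression_map <- function() {
  map <- melon_markers()
  imap <- read_genotypes(fixture_path("genotypes_chr3_derived.tsv"),
                         fixture_path("lines_chr3.tsv"), map)
  stopifnot(nrow(imap$calls) == 6,
            identical(sum(imap$lines$n_replicates), 58L),
            all(imap$calls["PS", ] == "PS"))
  imap
}

#' Transcribed individual-VOC panel (110 screened traits)
#'
#' Per-trait compound class, printed per-line mean relative contents (%)
#' and the starred Dunnett outcomes encoded as signs (+1 above control,
#' -1 below, 0 not significant).
#'
#' @return data.frame with 110 rows.
#' @export
melon_voc_table <- function() {
  df <- utils::read.delim(fixture_path("table2_patterns.tsv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(df) == 110, !anyDuplicated(df$order))
  df
}

#' Significance patterns of the 110 screened VOC traits
#'
#' @return Integer matrix 110 x 5 (traits keyed by printed order number,
#'   columns the five NILs), entries in -1/0/+1.
#' @export
melon_voc_patterns <- function() {
  df <- melon_voc_table()
  sig_cols <- grep("^sig_", names(df), value = TRUE)
  m <- as.matrix(df[sig_cols])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(df$order)
  colnames(m) <- sub("^sig_", "", sig_cols)
  m
}

#' Compound-class panel (10 classes) with screening flags
#'
#' @return data.frame with one row per compound class: printed mean
#'   percentages, Dunnett sign patterns and whether the class passed the
#'   ANOVA screen.
#' @export
melon_class_table <- function() {
  df <- utils::read.delim(fixture_path("table1_class_patterns.tsv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(df) == 10)
  df
}

#' Published mapped-QTL truth (44 individual VOCs)
#'
#' Direction (+1 donor allele increases the trait) and ethylene
#' dependence (+1 colocalizing with ETHQB3.5, -1 not) per mapped trait.
#'
#' @return data.frame with 44 rows keyed by printed order number.
#' @export
melon_qtl_truth <- function() {
  df <- utils::read.delim(fixture_path("table4_qtl_truth.tsv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(df) == 44,
            all(df$order %in% melon_voc_table()$order))
  df
}

#' Published correlation-network groups (G1..G5)
#'
#' @return data.frame `group`, `order`, `cas`, `iupac` for the five
#'   groups with at least three members (28 + 6 + 4 + 3 + 7 traits).
#' @export
melon_network_groups <- function() {
  df <- utils::read.delim(fixture_path("table5_groups.tsv"),
                          stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(nrow(df) == 48,
            identical(as.vector(table(df$group)[paste0("G", 1:5)]),
                      c(28L, 6L, 4L, 3L, 7L)))
  df
}

#' Reproduce the published QTL table from the packaged fixtures
#'
#' Runs the substitution-mapping engine over the 110 encoded individual
#' VOC patterns (strict profile, SC3-5-13 lenient) and over the screened
#' compound-class patterns (dominant-direction fallback profile),
#' classifies ethylene dependence, and compares the per-trait labels with
#' the transcribed published QTL table.
#'
#' @return List: `voc_calls`, `class_calls` (QTL-call data.frames),
#'   `summary` (counts over individual VOCs), `combined` (counts over
#'   VOCs + classes), `truth_agreement` (data.frame comparing the 44
#'   published rows), `n_agree`, `counts` (named vector of headline
#'   numbers).
#' @export
reproduce_paper <- function() {
  imap <- melon_introgression_map()
  roi <- ethqb35_region(imap)
  pat <- melon_voc_patterns()
  voc_calls <- map_trait_panel(pat, imap, roi, voc_mapping_config())

  cls <- melon_class_table()
  cls <- cls[cls$screened == 1, , drop = FALSE]
  sig_cols <- grep("^sig_", names(cls), value = TRUE)
  cpat <- as.matrix(cls[sig_cols])
  storage.mode(cpat) <- "integer"
  rownames(cpat) <- cls$class
  colnames(cpat) <- sub("^sig_", "", sig_cols)
  class_calls <- map_trait_panel(cpat, imap, roi, class_mapping_config())

  summary <- summarize_qtl_table(voc_calls)
  combined <- summarize_qtl_table(rbind(voc_calls, class_calls))

  truth <- melon_qtl_truth()
  got <- voc_calls[match(as.character(truth$order), voc_calls$trait), ]
  truth_agreement <- data.frame(
    order = truth$order, iupac = truth$iupac,
    status = got$status,
    direction = got$direction, direction_published = truth$direction,
    ethylene = got$ethylene, ethylene_published = truth$ethylene,
    agree = got$status == "MAPPED" &
      got$direction == truth$direction & got$ethylene == truth$ethylene,
    stringsAsFactors = FALSE)

  counts <- c(
    n_screened = nrow(pat),
    n_mapped_voc = summary$n_mapped,
    n_up_voc = summary$n_up,
    n_roi_voc = summary$n_in_roi,
    n_roi_up_voc = summary$n_in_roi_up,
    n_roi_total = combined$n_in_roi,
    n_outside_total = combined$n_outside,
    n_agree = sum(truth_agreement$agree)
  )
  list(voc_calls = voc_calls, class_calls = class_calls, summary = summary,
       combined = combined, truth_agreement = truth_agreement,
       n_agree = sum(truth_agreement$agree), counts = counts)
}
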