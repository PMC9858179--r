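#' Run the full replicate-level VOC QTL pipeline
#'
#' Chains the stages applied to a raw replicate-level abundance table:
#' per-sample relative-abundance normalisation, detection-limit zero
#' substitution, log2 transform, per-trait ANOVA with
#' Benjamini-Hochberg screening, Dunnett many-to-one comparisons against
#' the control, significance-pattern extraction and substitution
#' mapping against the region of interest.
#'
#' @param abundance Samples x traits matrix of raw or relative
#'   abundances (non-negative).
#' @param sample_line Line of each sample.
#' @param imap An `introgression_map` covering those lines.
#' @param roi A `region_of_interest` (default: ETHQB3.5 from `imap`).
#' @param control Control line name (default `"PS"`).
#' @param alpha Dunnett significance level.
#' @param bh_alpha BH screening level.
#' @param config Mapping profile (default [voc_mapping_config()]).
#' @param normalize Re-normalise rows to percent (default TRUE).
#' @return List with `log2` (transformed matrix), `anova` (all traits,
#'   with `p_adj`), `screened` (retained trait names), `dunnett`,
#'   `patterns`, `calls`, `summary`.
#' @export
run_voc_pipeline <- function(abundance, sample_line, imap,
                             roi = ethqb35_region(imap), control = "PS",
                             alpha = 0.05, bh_alpha = 0.05,
                             config = voc_mapping_config(),
                             normalize = TRUE) {
  mat <- as.matrix(abundance)
  if (normalize) mat <- normalize_relative(mat)
  logm <- log2_transform(substitute_zeros(mat))
  an <- anova_per_trait(logm, sample_line)
  keep <- screen_traits(an, bh_alpha)
  an$p_adj <- bh_adjust(an$p_raw)
  screened <- keep$trait
  if (length(screened)) {
    dn <- dunnett_many_to_one(logm[, screened, drop = FALSE], sample_line,
                              control = control, alpha = alpha)
    pat <- significance_patterns(dn)
    # pattern columns must cover the map's non-control lines
    calls <- map_trait_panel(pat, imap, roi, config)
  } else {
    dn <- NULL
    pat <- matrix(integer(0), 0, 0)
    calls <- data.frame()
  }
  list(log2 = logm, anova = an, screened = screened, dunnett = dn,
       patterns = pat, calls = calls,
       summary = if (nrow(calls)) summarize_qtl_table(calls) else NULL)
}

#' End-to-end QTL recovery on simulated data
#'
#' Convenience wrapper: simulate a dataset from a [sim_config()], run
#' [run_voc_pipeline()], and score the calls against the simulation
#' truth. Traits screened out are counted as unmapped.
#'
#' @param config A `sim_config`.
#' @param ... Passed on to [run_voc_pipeline()].
#' @return List `pipeline`, `recovery` (from [evaluate_recovery()]),
#'   `truth`.
#' @export
simulate_and_recover <- function(config, ...) {
  sim <- simulate_dataset(config)
  pipe <- run_voc_pipeline(sim$abundance, sim$sample_line, config$imap,
                           normalize = FALSE, ...)
  all_traits <- colnames(sim$abundance)
  calls <- pipe$calls
  missing <- setdiff(all_traits, calls$trait)
  if (length(missing)) {
    pad <- data.frame(trait = missing, status = "NO_SIGNAL",
                      direction = NA_integer_, left_marker = NA_character_,
                      right_marker = NA_character_, left_pos = NA_real_,
                      right_pos = NA_real_, colocalizes_roi = NA,
                      position_class = "none", scenario = "none",
                      ethylene = NA_integer_, mode_used = NA_character_,
                      alternates = "", stringsAsFactors = FALSE)
    calls <- rbind(calls, pad)
  }
  list(pipeline = pipe,
       recovery = evaluate_recovery(calls, sim$truth, config$imap),
       truth = sim$truth)
}
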