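#' Configuration for the replicate-level abundance simulator
#'
#' The generator emulates the structure of an introgression-panel VOC
#' experiment: per-line replicate samples, log-normal abundance noise
#' around trait baselines, QTL effects planted in genotype bins, latent
#' per-sample factors creating correlated trait blocks, detection-limit
#' censoring to zero, and per-sample compositional normalisation.
#'
#' Defaults mirror the study design: the six-line panel with replicate
#' counts 21 (control) and 5/7/7/9/9, 161 traits, a quarter of traits
#' carrying a planted QTL with effect size `beta` = 2 (log2 units) and
#' residual scale `sigma` = 0.5, detection-limit quantile 0.05. Planted
#' bins are drawn from the bins certainly covered by at least one NIL
#' introgression (a QTL in a bin no line covers is invisible to the
#' design by construction).
#'
#' @param seed Integer seed; every draw of the generator derives from it.
#' @param imap `introgression_map` (default: the packaged melon panel).
#' @param n_traits Number of traits.
#' @param planted_frac Fraction of traits with a planted QTL.
#' @param beta QTL effect size, log2 units (scalar or per-planted-trait).
#' @param sigma Residual standard deviation on the log2 scale.
#' @param sigma_mu Spread of per-trait baseline log2 means.
#' @param mu_planted_mean,mu_planted_sd Baseline log2-mean distribution
#'   of planted traits. The default (-2, 1) makes planted QTLs act on
#'   minor compounds, mirroring introgression panels where the
#'   large-fold QTL volatiles are minor esters and sulfur compounds
#'   while the dominant aldehyde/ketone background is stable; it also
#'   keeps the compositional closure distortion of the percent scale
#'   second-order, so the planted truth stays well-defined on the
#'   relative scale (see the methods vignette).
#' @param lod_q Detection-limit quantile in \[0, 0.5): raw abundances
#'   below the q-quantile of all raw values are censored to 0 before
#'   normalisation.
#' @param n_groups Number of latent correlation blocks (0 = none).
#' @param group_size Traits per block.
#' @param gamma Loading of block traits on their latent factor.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, imap = melon_introgression_map(),
                       n_traits = 161L, planted_frac = 0.25, beta = 2,
                       sigma = 0.5, sigma_mu = 1.5, mu_planted_mean = -2,
                       mu_planted_sd = 1, lod_q = 0.05,
                       n_groups = 0L, group_size = 10L, gamma = 1) {
  stopifnot(sigma > 0, lod_q >= 0, lod_q < 0.5, planted_frac >= 0,
            planted_frac <= 1)
  structure(list(seed = as.integer(seed), imap = imap,
                 n_traits = as.integer(n_traits),
                 planted_frac = planted_frac, beta = beta, sigma = sigma,
                 sigma_mu = sigma_mu, mu_planted_mean = mu_planted_mean,
                 mu_planted_sd = mu_planted_sd, lod_q = lod_q,
                 n_groups = as.integer(n_groups),
                 group_size = as.integer(group_size), gamma = gamma),
            class = "sim_config")
}

# bins certainly covered (state SC) by at least one non-control line
.detectable_bins <- function(imap, states = bin_states(imap)) {
  which(apply(states == "SC", 2, any))
}

#' Simulate a replicate-level abundance dataset with planted QTLs
#'
#' For sample s of line L and trait t the raw abundance is
#' `2^(mu_t + beta_t * I[state(L, b_t) = SC] + gamma_t * f_gs + eps_st)`
#' with `eps ~ N(0, sigma^2)` and per-sample latent factors
#' `f ~ N(0, 1)`; values below the detection-limit quantile are censored
#' to 0, and each sample is then normalised to relative abundances
#' summing to 100. Fully reproducible from `config$seed`.
#'
#' @param config A [sim_config()].
#' @return List with `abundance` (samples x traits relative-abundance
#'   matrix), `sample_line` (line of each sample), `truth` (data.frame
#'   `trait`, `planted`, `bin`, `beta`, `sign`, `group`), and `config`.
#' @export
simulate_dataset <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  imap <- config$imap
  set.seed(config$seed)
  states <- bin_states(imap)
  li <- imap$lines
  sample_line <- rep(li$line, li$n_replicates)
  samples <- paste0(sample_line, "_r",
                    unlist(lapply(li$n_replicates, seq_len)))
  ns <- length(samples)
  nt <- config$n_traits
  traits <- sprintf("voc%03d", seq_len(nt))

  n_planted <- round(config$planted_frac * nt)
  planted <- sort(sample.int(nt, n_planted))
  bins_ok <- .detectable_bins(imap, states)
  if (n_planted > 0 && !length(bins_ok)) stop("no detectable bins in map")
  truth <- data.frame(trait = traits, planted = FALSE, bin = NA_integer_,
                      beta = 0, sign = 0L, group = 0L,
                      stringsAsFactors = FALSE)
  if (n_planted > 0) {
    truth$planted[planted] <- TRUE
    truth$bin[planted] <- sample(bins_ok, n_planted, replace = TRUE)
    sgn <- sample(c(-1L, 1L), n_planted, replace = TRUE)
    truth$sign[planted] <- sgn
    truth$beta[planted] <- rep(config$beta, length.out = n_planted) * sgn
  }
  if (config$n_groups > 0) {
    gid <- rep(seq_len(config$n_groups), each = config$group_size)
    gid <- gid[seq_len(min(length(gid), nt))]
    truth$group[seq_along(gid)] <- gid
  }

  mu <- stats::rnorm(nt, 0, config$sigma_mu)
  if (n_planted > 0)
    mu[planted] <- stats::rnorm(n_planted, config$mu_planted_mean,
                                config$mu_planted_sd)
  # line x trait QTL shifts
  shift <- matrix(0, nrow(li), nt, dimnames = list(li$line, traits))
  for (t in which(truth$planted)) {
    carrier <- states[, truth$bin[t]] == "SC"
    shift[carrier, t] <- truth$beta[t]
  }
  f <- if (config$n_groups > 0)
    matrix(stats::rnorm(ns * config$n_groups), ns, config$n_groups)
  else NULL
  logv <- matrix(rep(mu, each = ns), ns, nt) +
    shift[sample_line, , drop = FALSE] +
    matrix(stats::rnorm(ns * nt, 0, config$sigma), ns, nt)
  if (!is.null(f)) {
    in_grp <- truth$group > 0
    logv[, in_grp] <- logv[, in_grp] +
      config$gamma * f[, truth$group[in_grp], drop = FALSE]
  }
  raw <- 2^logv
  if (config$lod_q > 0) {
    lod <- stats::quantile(raw, probs = config$lod_q, names = FALSE)
    raw[raw < lod] <- 0
  }
  dimnames(raw) <- list(samples, traits)
  abundance <- normalize_relative(raw)
  list(abundance = abundance, sample_line = sample_line, truth = truth,
       config = config)
}

#' Score QTL calls against simulation truth
#'
#' @param calls QTL-call data.frame (one row per trait) from
#'   [map_trait_panel()].
#' @param truth Truth table from [simulate_dataset()].
#' @param imap The `introgression_map` used (bin coordinates).
#' @return List: `recovery` (fraction of planted traits mapped with the
#'   true bin inside the primary interval), `direction_accuracy` (among
#'   recovered), `false_map_rate` (fraction of null traits mapped),
#'   `n_planted`, `n_null`.
#' @export
evaluate_recovery <- function(calls, truth, imap) {
  if (!setequal(calls$trait, truth$trait))
    stop("calls and truth must cover the same traits")
  calls <- calls[match(truth$trait, calls$trait), , drop = FALSE]
  bins <- imap$bins
  planted <- which(truth$planted)
  nulls <- which(!truth$planted)
  hit <- logical(length(planted))
  dir_ok <- logical(length(planted))
  for (i in seq_along(planted)) {
    t <- planted[i]
    if (calls$status[t] != "MAPPED") next
    b <- truth$bin[t]
    hit[i] <- calls$left_pos[t] <= bins$left_pos[b] &&
      calls$right_pos[t] >= bins$right_pos[b]
    dir_ok[i] <- hit[i] && calls$direction[t] == truth$sign[t]
  }
  list(
    recovery = if (length(planted)) mean(hit) else NA_real_,
    direction_accuracy = if (any(hit)) mean(dir_ok[hit]) else NA_real_,
    false_map_rate = if (length(nulls))
      mean(calls$status[nulls] == "MAPPED") else NA_real_,
    n_planted = length(planted), n_null = length(nulls)
  )
}
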