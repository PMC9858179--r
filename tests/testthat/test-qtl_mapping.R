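fixture_pattern <- function(...) {
  v <- c(...)
  names(v) <- c("SC3-5-7", "SC3-5-8", "SC3-5-12", "SC3-5-13", "SC3-5-14")
  v
}

test_that("the climacteric-class pattern maps exactly onto ETHQB3.5", {
  imap <- melon_introgression_map()
  bins <- consistent_bins(fixture_pattern(0, 1, 1, 1, 1), imap)
  expect_equal(bins, 8:10)
  expect_equal(imap$bins$left_marker[8], "CMPSNP374")
  expect_equal(imap$bins$right_marker[10], "AI_14-F04")
})

test_that("vacuous and unsupported patterns behave as specified", {
  imap <- melon_introgression_map()
  # all-zero: every bin vacuously consistent; the caller reports NO_SIGNAL
  expect_equal(consistent_bins(fixture_pattern(0, 0, 0, 0, 0), imap),
               seq_len(nrow(imap$bins)))
  call <- map_single_qtl(fixture_pattern(0, 0, 0, 0, 0), imap,
                         ethqb35_region(imap))
  expect_equal(call$status, "NO_SIGNAL")
  # significant only in SC3-5-8: its introgression is everywhere covered by
  # another line, so no bin is consistent
  expect_length(consistent_bins(fixture_pattern(0, 1, 0, 0, 0), imap), 0)
  # mixed signs in strict mode are never interpretable
  expect_length(consistent_bins(fixture_pattern(1, 0, -1, 0, 0), imap), 0)
  call <- map_single_qtl(fixture_pattern(1, 0, -1, 0, 0), imap,
                         ethqb35_region(imap))
  expect_equal(call$status, "NOT_INTERPRETABLE")
  expect_equal(call$scenario, "iii")
})

test_that("published example traits map to the published intervals", {
  imap <- melon_introgression_map()
  roi <- ethqb35_region(imap)
  # butyl acetate: ns in the lenient line SC3-5-13, still colocalizes
  ba <- map_single_qtl(fixture_pattern(0, 1, 1, 0, 1), imap, roi)
  expect_equal(ba$status, "MAPPED")
  expect_true(ba$colocalizes_roi)
  expect_equal(ba$ethylene, 1L)
  expect_equal(c(ba$left_marker, ba$right_marker),
               c("CMPSNP374", "AI_14-F04"))
  # 2-methylbutyl acetate: significant in all five lines, maps to the
  # shared left segment, ethylene-independent
  mba <- map_single_qtl(fixture_pattern(1, 1, 1, 1, 1), imap, roi)
  expect_equal(mba$status, "MAPPED")
  expect_false(mba$colocalizes_roi)
  expect_equal(mba$ethylene, -1L)
  expect_equal(mba$position_class, "LEFT_OF_ROI")
  expect_equal(mba$scenario, "ii")
})

test_that("leniency is conditional on an all-climacteric significant set", {
  imap <- melon_introgression_map()
  roi <- ethqb35_region(imap)
  # same 13-ns shape, but with the non-climacteric line significant the
  # lenient line's ns is informative and the trait cannot be mapped
  r28 <- map_single_qtl(fixture_pattern(1, 1, 1, 0, 1), imap, roi)
  expect_equal(r28$status, "NOT_INTERPRETABLE")
  # disabling leniency loses the ROI colocalizations that need it
  strict <- mapping_config(use_leniency = FALSE)
  ba <- map_single_qtl(fixture_pattern(0, 1, 1, 0, 1), imap, roi, strict)
  expect_equal(ba$status, "NOT_INTERPRETABLE")
})

test_that("dominant-direction fallback maps one sign of a mixed pattern", {
  imap <- melon_introgression_map()
  roi <- ethqb35_region(imap)
  # aldehyde-class shape: up in SC3-5-7, down in SC3-5-12
  ald <- fixture_pattern(1, 0, -1, 0, 0)
  strict <- map_single_qtl(ald, imap, roi, class_mapping_config(),
                           trait = "ALD")
  expect_equal(strict$status, "MAPPED")
  expect_equal(strict$direction, -1L)
  expect_equal(strict$position_class, "RIGHT_OF_ROI")
  expect_equal(strict$mode_used, "dominant_direction")
  # without fallback the same pattern is not interpretable
  expect_equal(map_single_qtl(ald, imap, roi, voc_mapping_config())$status,
               "NOT_INTERPRETABLE")
})

test_that("consistent_bins agrees with the exhaustive oracle on random instances", {
  set.seed(2024)
  for (i in 1:120) {
    imap <- random_imap(sample(2:6, 1), sample(3:16, 1))
    lines <- rownames(imap$calls)
    pattern <- sample(c(-1L, 0L, 1L), length(lines), replace = TRUE,
                      prob = c(0.25, 0.4, 0.35))
    names(pattern) <- lines
    cfg <- mapping_config(use_leniency = sample(c(TRUE, FALSE), 1),
                          lenient_climacteric_only = sample(c(TRUE, FALSE), 1))
    expect_identical(consistent_bins(pattern, imap, cfg),
                     consistent_bins_oracle(pattern, imap, cfg),
                     info = paste("instance", i))
  }
})

test_that("uncertainty in a non-significant line only grows the bin set", {
  set.seed(55)
  for (i in 1:40) {
    imap <- random_imap(4, 10, p_na = 0)
    pattern <- c(L1 = 1L, L2 = 0L, L3 = 0L, L4 = 1L)
    cfg <- mapping_config(use_leniency = FALSE)
    before <- consistent_bins(pattern, imap, cfg)
    # blank one marker call of a non-significant line: its PS evidence
    # weakens, so the consistent set can only grow
    imap2 <- imap
    ns_line <- sample(c("L2", "L3"), 1)
    imap2$calls[ns_line, sample(10, 1)] <- NA
    after <- consistent_bins(pattern, imap2, cfg)
    expect_true(all(before %in% after), info = paste("instance", i))
  }
})

test_that("mapping is deterministic and the true bin is always recovered on clean patterns", {
  imap <- melon_introgression_map()
  roi <- ethqb35_region(imap)
  states <- bin_states(imap)
  nils <- setdiff(rownames(imap$calls), "PS")
  for (b in seq_len(nrow(imap$bins))) {
    carriers <- nils[states[nils, b] == "SC"]
    if (!length(carriers)) next
    pattern <- setNames(as.integer(nils %in% carriers), nils)
    call1 <- map_single_qtl(pattern, imap, roi)
    call2 <- map_single_qtl(pattern, imap, roi)
    expect_identical(call1, call2)
    expect_equal(call1$status, "MAPPED", info = paste("bin", b))
    # single-QTL soundness: the generating bin lies in the mapped interval
    expect_lte(call1$left_pos, imap$bins$left_pos[b])
    expect_gte(call1$right_pos, imap$bins$right_pos[b])
    expect_true(b %in% consistent_bins(pattern, imap))
  }
})

test_that("panel summaries conserve counts and classify scenarios", {
  rp <- reproduce_paper()
  s <- rp$summary
  expect_equal(s$n_mapped + s$n_not_interpretable + s$n_no_signal, s$n_traits)
  expect_equal(s$n_mapped, s$n_up + s$n_down)
  expect_equal(s$n_mapped, s$n_in_roi + s$n_outside)
  expect_equal(s$n_outside, s$n_outside_left + s$n_outside_right)
  calls <- rp$voc_calls
  expect_error(scenario_class(calls), "NO_SIGNAL")
  mapped <- calls[calls$status == "MAPPED", ]
  expect_true(all(scenario_class(mapped) %in% c("i", "ii")))
  expect_equal(scenario_class(mapped), ifelse(mapped$colocalizes_roi, "i", "ii"))
  # ethylene labels: methyl propanoate (order 1) in ROI, hexanal (64) not
  eth <- classify_ethylene(calls)
  expect_equal(eth[calls$trait == "1"], 1L)
  expect_equal(eth[calls$trait == "64"], -1L)
  expect_true(is.na(eth[calls$trait == "105"]))   # no significant line
  empty <- summarize_qtl_table(calls[0, ])
  expect_equal(empty$n_mapped, 0)
  expect_equal(empty$n_traits, 0)
})
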