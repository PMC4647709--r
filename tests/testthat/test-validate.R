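test_that("misjoin breakpoint regions span the flank overlap and trim
           mismatched tails", {
  sseq <- strrep("A", 3000)
  diff <- data.frame(kind = "MISJOIN", s_left = 1000L, s_right = 1200L)
  # clean pileup: no trimming
  counts <- matrix(0L, 4, 3000, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts["A", ] <- 20L
  pu <- list(counts = counts, depth = colSums(counts))
  reg <- compute_breakpoint_region(diff, pu, sseq)
  expect_equal(c(reg$M_L, reg$M_R), c(1000L, 1200L))

  # majority base disagrees with the scaffold over [990, 1000): M_L moves
  counts2 <- counts
  counts2["A", 991:1000] <- 2L
  counts2["G", 991:1000] <- 18L
  pu2 <- list(counts = counts2, depth = colSums(counts2))
  reg2 <- compute_breakpoint_region(diff, pu2, sseq)
  expect_equal(reg2$M_L, 990L)
  expect_equal(reg2$M_R, 1200L)

  # trimming is capped
  counts3 <- counts
  counts3["A", 1:1000] <- 0L
  counts3["G", 1:1000] <- 18L
  pu3 <- list(counts = counts3, depth = colSums(counts3))
  expect_equal(compute_breakpoint_region(diff, pu3, sseq,
                                         trim_cap = 50L)$M_L, 950L)
})

test_that("indel breakpoint regions come directly from the alignments", {
  sseq <- strrep("A", 3000)
  diff <- data.frame(kind = "INSERTION_MID", s_left = 500L, s_right = 600L)
  reg <- compute_breakpoint_region(diff, NULL, sseq)
  expect_equal(c(reg$M_L, reg$M_R), c(500L, 600L))
  # zero-width junction widened to one base
  d2 <- data.frame(kind = "DELETION", s_left = 700L, s_right = 700L)
  reg2 <- compute_breakpoint_region(d2, NULL, sseq)
  expect_equal(c(reg2$M_L, reg2$M_R), c(700L, 701L))
})

test_that("misjoin validation requires anomaly/disagreements or a high
           multi-align ratio", {
  # more than one disagreement
  v <- validate_misjoin(mk_ev(n_disagreements = 3L))
  expect_equal(v$label, "ERROR_MISJOIN")
  expect_equal(v$correction, "SPLIT")
  # exactly one disagreement is not enough on its own
  expect_null(validate_misjoin(mk_ev(n_disagreements = 1L)))
  # multi-align ratio above 0.1
  expect_equal(validate_misjoin(mk_ev(multi_align_ratio = 0.25))$label,
               "ERROR_MISJOIN")
  # exactly 0.1 does not fire (strict >)
  expect_null(validate_misjoin(mk_ev(multi_align_ratio = 0.1)))
  # abnormal coverage alone validates
  expect_equal(validate_misjoin(mk_ev(has_zero_cov = TRUE))$label,
               "ERROR_MISJOIN")
  # nothing abnormal: passed on to SV analysis
  expect_null(validate_misjoin(mk_ev(multi_align_ratio = 0.05)))
})

test_that("middle insertions combine the fragment-size test with
           two-of-three support", {
  lib <- list(mu = 368, sigma = 61)
  # |(470-368) - 100| = 2 < 122, disagreements + discordant ratio
  ev <- mk_ev(n_disagreements = 1L, discordant_ratio = 0.2,
              span_frag_mean = 470, span_pair_count = 10L)
  d <- data.frame(kind = "INSERTION_MID", est_size = 100L)
  expect_equal(validate_insertion(d, ev, lib)$label, "ERROR_INSERTION")
  # only one supporting feature: not validated
  ev1 <- mk_ev(n_disagreements = 1L, span_frag_mean = 470,
               span_pair_count = 10L)
  expect_null(validate_insertion(d, ev1, lib))
  # fragment-size mismatch at exactly 2 sigma does not count (strict <)
  ev2 <- mk_ev(n_disagreements = 1L, discordant_ratio = 0.2,
               span_frag_mean = 368 + 100 + 2 * 61,
               span_pair_count = 10L)
  expect_null(validate_insertion(d, ev2, lib))
})

test_that("large insertions without a fragment match use the
           disagreement rate", {
  lib <- list(mu = 368, sigma = 61)
  d <- data.frame(kind = "INSERTION_MID", est_size = 2000L)
  expect_null(validate_insertion(d, mk_ev(disagreements_per_kbp = 0.4),
                                 lib))
  v <- validate_insertion(d, mk_ev(disagreements_per_kbp = 3), lib)
  expect_equal(v$label, "ERROR_INSERTION")
  # exactly 1 per kbp does not fire
  expect_null(validate_insertion(d, mk_ev(disagreements_per_kbp = 1), lib))
})

test_that("end insertions validate on disagreements or zero coverage and
           trim the end", {
  lib <- list(mu = 368, sigma = 61)
  d <- data.frame(kind = "INSERTION_END", est_size = 300L)
  v <- validate_insertion(d, mk_ev(has_zero_cov = TRUE), lib)
  expect_equal(v$label, "ERROR_INSERTION")
  expect_equal(v$correction, "TRIM_END")
  expect_equal(validate_insertion(d, mk_ev(n_disagreements = 1L),
                                  lib)$correction, "TRIM_END")
  expect_null(validate_insertion(d, mk_ev(), lib))
})

test_that("deletion validation mirrors the insertion rule", {
  lib <- list(mu = 368, sigma = 61)
  d <- data.frame(kind = "DELETION", est_size = 55L)
  # |(368-310) - 55| = 3 < 122; zero coverage + discordant ratio
  ev <- mk_ev(has_zero_cov = TRUE, discordant_ratio = 0.15,
              span_frag_mean = 310, span_pair_count = 8L)
  expect_equal(validate_deletion(d, ev, lib)$label, "ERROR_DELETION")
  # fragment mean equal to the library mean still "matches" a small
  # deletion (70 < 2 sigma) but clean evidence blocks the call
  d70 <- data.frame(kind = "DELETION", est_size = 70L)
  ev2 <- mk_ev(span_frag_mean = 368, span_pair_count = 8L)
  expect_null(validate_deletion(d70, ev2, lib))
  # no spanning pairs: disagreement-rate fallback
  ev3 <- mk_ev(disagreements_per_kbp = 3)
  expect_equal(validate_deletion(d70, ev3, lib)$label, "ERROR_DELETION")
})

test_that("unvalidated differences split into correct-SV and warnings", {
  expect_equal(classify_sv(mk_ev(discordant_ratio = 0.02))$label,
               "CORRECT_SV")
  expect_equal(classify_sv(mk_ev(has_low_cov = TRUE))$label, "WARNING")
  # boundary: discordant ratio exactly 0.1 is not "very few" (strict <)
  expect_equal(classify_sv(mk_ev(discordant_ratio = 0.1))$label, "WARNING")
  expect_equal(classify_sv(mk_ev(n_disagreements = 1L))$label, "WARNING")
  # almost no reads: low-evidence warning, not correctness
  v <- classify_sv(mk_ev(n_reads = 2L))
  expect_equal(v$label, "WARNING")
  expect_match(v$note, "low evidence")
})

test_that("strengthening evidence never flips an error call back to
           correct-SV", {
  for (kind in c("MISJOIN", "INSERTION_MID", "DELETION")) {
    labels <- matrix(NA_character_, 4, 4)
    for (di in 1:4) {
      for (ri in 1:4) {
        ev <- mk_ev(n_disagreements = c(0L, 1L, 2L, 5L)[di],
                    disagreements_per_kbp = c(0, 0.5, 2, 5)[di],
                    discordant_ratio = c(0, 0.05, 0.15, 0.5)[ri],
                    has_low_cov = ri >= 3,
                    span_frag_mean = 368 + 100, span_pair_count = 5L)
        labels[di, ri] <- dispatch_verdict(kind, ev, est_size = 100L)$label
      }
    }
    for (di in 1:4) for (ri in 1:4) {
      if (grepl("^ERROR_", labels[di, ri])) {
        expect_false(any(labels[di:4, ri:4] == "CORRECT_SV"),
                     info = paste(kind, di, ri))
      }
    }
  }
})

test_that("every difference of a run receives exactly one verdict", {
  res <- small_pipeline_result()
  expect_equal(nrow(res$verdicts), nrow(res$differences))
  expect_true(all(res$verdicts$label %in%
                    c("ERROR_MISJOIN", "ERROR_INSERTION", "ERROR_DELETION",
                      "CORRECT_SV", "WARNING", "GAP_REPORT")))
  # label/correction invariants
  mj <- res$verdicts$label == "ERROR_MISJOIN"
  expect_true(all(res$verdicts$correction[mj] == "SPLIT"))
  rep_only <- res$verdicts$label %in% c("CORRECT_SV", "WARNING",
                                        "GAP_REPORT")
  expect_true(all(res$verdicts$correction[rep_only] == "REPORT_ONLY"))
})
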