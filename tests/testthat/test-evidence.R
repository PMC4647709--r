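scaf20 <- strrep("A", 20)

test_that("pileup counts bases per column", {
  # no reads -> all zero
  pu <- build_pileup(read_row("x", 0, "A")[0, ], scaf20)
  expect_true(all(pu$depth == 0L))

  reads <- do.call(rbind, lapply(1:10, function(i) {
    read_row(paste0("r", i), 3, "AAAAA")
  }))
  pu <- build_pileup(reads, scaf20)
  expect_equal(unname(pu$counts["A", 4]), 10L)
  expect_equal(unname(pu$depth[4:8]), rep(10L, 5))
  expect_equal(unname(pu$depth[3]), 0L)
})

test_that("multi-placed reads are counted per covered column", {
  reads <- rbind(read_row("m", 5, "CCCCC", multi = TRUE),
                 read_row("u", 5, "CCCCC"))
  pu <- build_pileup(reads, scaf20)
  expect_equal(unname(pu$multi[6:10]), rep(1L, 5))
  expect_equal(unname(pu$multi[11]), 0L)
  expect_true(all(pu$multi <= pu$depth))
})

test_that("out-of-bounds reads are rejected with a warning count", {
  reads <- rbind(read_row("ok", 0, "AAAA"),
                 read_row("bad", 18, "AAAA"))
  expect_warning(pu <- build_pileup(reads, scaf20), "rejected")
  expect_equal(pu$n_rejected, 1L)
  expect_equal(sum(pu$depth), 4L)
})

test_that("pileup conserves aligned bases", {
  set.seed(3)
  g <- generate_genome(5000)
  rd <- simulate_reads(g, depth = 15, read_len = 60, insert_mu = 200,
                       insert_sd = 20)
  al <- naive_align_reads(rd$read1, rd$read2, c(s = unname(g)),
                          seed_k = 15)
  pu <- build_pileup(al, unname(g))
  aligned_bases <- sum(nchar(al$seq)) -
    sum(vapply(strsplit(al$seq, ""), function(x) sum(x %in% c("N", "-")),
               numeric(1)))
  expect_equal(sum(pu$depth), aligned_bases)
})

test_that("disagreement calling applies the strict 0.8 majority rule", {
  mk_pu <- function(a, c) {
    counts <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
    counts["A", 2] <- a
    counts["C", 2] <- c
    list(counts = counts, depth = colSums(counts))
  }
  # 7/10 majority -> disagreement
  expect_equal(call_disagreements(mk_pu(7L, 3L)), 1L)
  # exactly 0.8 is not below the threshold
  expect_equal(length(call_disagreements(mk_pu(8L, 2L))), 0L)
  # unanimous column never fires
  expect_equal(length(call_disagreements(mk_pu(10L, 0L))), 0L)
  # below min_depth never fires
  expect_equal(length(call_disagreements(mk_pu(2L, 2L), min_depth = 5L)), 0L)
})

test_that("disagreements match a per-column recount on random pileups", {
  set.seed(13)
  for (rep in 1:5) {
    L <- 40L
    counts <- matrix(rpois(4 * L, 3), 4, L,
                     dimnames = list(c("A", "C", "G", "T"), NULL))
    pu <- list(counts = counts, depth = colSums(counts))
    got <- call_disagreements(pu, 0.8, 5L)
    want <- which(vapply(seq_len(L), function(j) {
      d <- sum(counts[, j])
      d >= 5 && max(counts[, j]) / d < 0.8
    }, logical(1))) - 1L
    expect_equal(got, want)
  }
})

test_that("coverage flags react to windowed anomalies", {
  depth <- rep(50L, 2000L)
  reg <- c(900L, 1100L)
  f <- coverage_flags(depth, reg)
  expect_false(f$has_high_cov || f$has_low_cov || f$has_zero_cov)

  # two 50-bp sub-regions at 80x against a scaffold mean of ~50 (>75)
  d2 <- depth
  d2[951:1050] <- 80L
  f <- coverage_flags(d2, reg)
  expect_true(f$has_high_cov)
  # one anomalous window is not enough ("more than one")
  d3 <- depth
  d3[951:1000] <- 80L
  expect_false(coverage_flags(d3, reg)$has_high_cov)

  # a single zero-coverage base inside the region proper
  d4 <- depth
  d4[1000] <- 0L
  expect_true(coverage_flags(d4, reg)$has_zero_cov)
  # zero coverage outside the region does not count
  d5 <- depth
  d5[1500] <- 0L
  expect_false(coverage_flags(d5, reg)$has_zero_cov)
})

test_that("single-cell mode thresholds use window mean and sd", {
  set.seed(8)
  # uneven baseline: window means sd is large, so 80x is not anomalous
  depth <- rep(rep(c(20L, 90L), length.out = 40L), each = 50L)
  reg <- c(900L, 1100L)
  d2 <- depth
  d2[901:1000] <- 95L
  expect_true(coverage_flags(d2, reg)$has_high_cov)   # standard mode fires
  expect_false(coverage_flags(d2, reg, mode = "single_cell")$has_high_cov)
})

test_that("multi-align ratio is the multi fraction of overlapping reads", {
  reads <- do.call(rbind, lapply(1:10, function(i) {
    read_row(paste0("r", i), i, "AAAAA", multi = i <= 3)
  }))
  expect_equal(multi_align_ratio(reads, c(0L, 20L))$ratio, 0.3)
  expect_equal(multi_align_ratio(reads[4:10, ], c(0L, 20L))$ratio, 0)
  out <- multi_align_ratio(reads, c(100L, 120L))
  expect_equal(out$ratio, 0)
  expect_equal(out$n, 0L)
})

test_that("pair classification applies orientation and the strict 3-sigma rule", {
  lib <- list(mu = 368, sigma = 61)
  p <- rbind(pair_row(0L, 368L),                 # at the mean
             pair_row(0L, 368L + 4L * 61L),      # 4 sigma away
             pair_row(0L, 368L + 3L * 61L),      # exactly 3 sigma
             pair_row(0L, 368L, fr = FALSE))     # wrong orientation
  expect_equal(classify_pairs(p, lib), c(FALSE, TRUE, FALSE, TRUE))
  # inter-scaffold pairs are discordant
  q <- pair_row(0L, 368L)
  q$scaffold_2 <- "other"; q$same_scaffold <- FALSE; q$is_fr <- FALSE
  q$frag <- NA_integer_
  expect_true(classify_pairs(q, lib))
})

test_that("pair geometry derives FR orientation and 5'-end fragment size", {
  reads <- rbind(
    read_row("p1", 100, strrep("A", 100), mate = 1L, scaffold = "s"),
    within(read_row("p1", 368, strrep("A", 100), mate = 2L,
                    scaffold = "s"), strand <- "-"))
  pr <- make_pairs(reads)
  expect_true(pr$is_fr)
  expect_equal(pr$frag, 368L)   # five' ends at 100 and 467
  # outward-facing pair is not FR
  reads2 <- rbind(
    within(read_row("p2", 100, strrep("A", 100), mate = 1L), strand <- "-"),
    read_row("p2", 368, strrep("A", 100), mate = 2L))
  expect_false(make_pairs(reads2)$is_fr)
})

test_that("discordant ratio uses fragment-interval overlap and sub-regions", {
  ev <- function(lo, hi, disc) data.frame(scaffold_id = "s", lo = lo,
                                          hi = hi, discordant = disc)
  # 20 pairs, 4 discordant, short region
  e <- ev(seq(0, 190, by = 10), seq(300, 490, by = 10),
          rep(c(TRUE, FALSE), c(4, 16)))
  expect_equal(discordant_ratio(e, c(100L, 400L))$ratio, 0.2)
  expect_equal(discordant_ratio(e[0, ], c(100L, 400L))$ratio, 0)
  # long region: maximum over consecutive 500-bp sub-regions
  e2 <- rbind(ev(rep(0, 20), rep(400, 20), rep(c(TRUE, FALSE), c(1, 19))),
              ev(rep(520, 10), rep(900, 10), rep(c(TRUE, FALSE), c(3, 7))),
              ev(rep(1010, 5), rep(1190, 5), rep(FALSE, 5)))
  out <- discordant_ratio(e2, c(0L, 1200L))
  expect_equal(out$ratio, 0.3)
})

test_that("discordant ratio is monotone in the discordant count", {
  set.seed(41)
  lo <- sample(0:200, 30, replace = TRUE)
  e <- data.frame(scaffold_id = "s", lo = lo, hi = lo + 300,
                  discordant = rep(FALSE, 30))
  prev <- 0
  for (k in 0:30) {
    e$discordant <- seq_len(30) <= k
    r <- discordant_ratio(e, c(0L, 500L))$ratio
    expect_gte(r, prev)
    expect_true(r >= 0 && r <= 1)
    prev <- r
  }
})

test_that("spanning fragments require mates clear of both margins", {
  reg <- c(890L, 990L)
  frs <- c(400L, 410L, 390L, 405L, 395L)
  # left mates [700,800) end before M_L; right-mate starts are 600+frag,
  # all at or beyond M_R = 990
  p <- do.call(rbind, lapply(frs, function(f) pair_row(700L, f)))
  out <- spanning_fragments(p, reg)
  expect_equal(out$mean, 400)
  expect_equal(out$n, 5L)
  # a mate overlapping the region is excluded
  inside <- pair_row(820L, 400L)   # left mate [820,920) overlaps M_L=890
  expect_equal(spanning_fragments(rbind(p, inside), reg)$n, 5L)
  # no spanning pairs -> absent
  out0 <- spanning_fragments(p[0, ], reg)
  expect_equal(out0$n, 0L)
  expect_true(is.na(out0$mean))
  # below min_span the mean is withheld
  expect_true(is.na(spanning_fragments(p[1:2, ], reg)$mean))
})

test_that("library estimation recovers simulated insert parameters", {
  set.seed(19)
  frag <- as.integer(round(rnorm(10000, 368, 61)))
  p <- do.call(rbind, lapply(frag, function(f) pair_row(0L, f)))
  lib <- estimate_library(p)
  expect_equal(lib$source, "estimated")
  expect_lt(abs(lib$mu - 368) / 368, 0.02)
  expect_lt(abs(lib$sigma - 61) / 61, 0.05)
  # user-supplied values pass through verbatim
  given <- estimate_library(NULL, mu = 368, sigma = 61)
  expect_equal(given[c("mu", "sigma", "source")],
               list(mu = 368, sigma = 61, source = "given"))
  # too few pairs and nothing given is an error
  expect_error(estimate_library(p[1:10, ]), "too few")
})
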