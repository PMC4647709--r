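test_that("genome generation is seeded and respects length and GC", {
  g1 <- generate_genome(1000, seed = 1)
  g2 <- generate_genome(1000, seed = 1)
  expect_identical(g1, g2)
  expect_equal(nchar(g1[[1]]), 1000L)
  g3 <- generate_genome(200000, gc = 0.5, seed = 2)
  gc <- sum(strsplit(g3[[1]], "")[[1]] %in% c("G", "C")) / 200000
  expect_lt(abs(gc - 0.5), 0.01)
  g4 <- generate_genome(200000, gc = 0.3, seed = 2)
  gc4 <- sum(strsplit(g4[[1]], "")[[1]] %in% c("G", "C")) / 200000
  expect_lt(abs(gc4 - 0.3), 0.01)
  expect_error(generate_genome(0), ">= 1")
})

test_that("read simulation follows the coverage arithmetic and is seeded", {
  g <- generate_genome(100000, seed = 3)
  rd <- simulate_reads(g, depth = 50, read_len = 100, seed = 4)
  expect_equal(length(rd$read1), 25000L)   # 50 * 1e5 / (2 * 100)
  expect_equal(length(rd$read2), 25000L)
  rd2 <- simulate_reads(g, depth = 50, read_len = 100, seed = 4)
  expect_identical(rd, rd2)
  rd3 <- simulate_reads(g, depth = 50, read_len = 100, seed = 5)
  expect_false(identical(rd$read1, rd3$read1))
})

test_that("error-free reads are exact genome substrings in FR geometry", {
  g <- generate_genome(20000, seed = 6)
  rd <- simulate_reads(g, depth = 3, read_len = 80, base_error = 0,
                       seed = 7)
  gs <- g[[1]]
  for (i in seq(1, length(rd$read1), by = 25)) {
    expect_true(grepl(rd$read1[[i]], gs, fixed = TRUE))
    expect_true(grepl(misasm:::revcomp(rd$read2[[i]]), gs, fixed = TRUE))
  }
  # with base errors, most reads still anchor at their true origin
  lens <- nchar(c(rd$read1, rd$read2))
  expect_true(all(lens == 80L))
})

test_that("the six-modification preset yields eight expected loci", {
  g <- generate_genome(300000, seed = 8)
  svs <- sv_preset_six(relocation_len = 20000L)
  svs$pos <- c(50000L, 100000L, 160000L, 170000L, 180000L, 190000L)
  svs$pos2 <- c(NA, 150000L, NA, NA, NA, NA)
  out <- inject_svs(g, svs)
  expect_equal(nrow(out$truth), 8L)
  expect_equal(sum(out$truth$kind == "misjoin"), 3L)   # relocation
  expect_equal(sum(out$truth$kind == "deletion"), 3L)  # dup + 2 ref ins
  expect_equal(sum(out$truth$kind == "insertion"), 2L) # 2 ref del
  # length bookkeeping: dup +1000, ins +100, del -100, reloc +-0
  expect_equal(nchar(out$reference[[1]]), 300000L + 1000L)
})

test_that("single SVs produce one expected difference; none leave the
           genome untouched", {
  g <- generate_genome(50000, seed = 9)
  one <- data.frame(kind = "deletion", size = 70L, pos = 20000L,
                    pos2 = NA_integer_)
  out <- inject_svs(g, one)
  expect_equal(nrow(out$truth), 1L)
  expect_equal(out$truth$kind, "insertion")
  expect_equal(nchar(out$reference[[1]]), 49930L)
  expect_error(inject_svs(g, rbind(one, within(one, pos <- 20030L))),
               "overlap")
})

test_that("error injection keeps exact length bookkeeping", {
  g <- generate_genome(500000, seed = 10)
  errors <- data.frame(kind = c("insertion_mid", "deletion",
                                "insertion_end"),
                       size = c(300L, 55L, 200L))
  inj <- inject_assembly_errors(g, errors)
  tr <- inj$truth
  expect_equal(nrow(tr), 3L)
  # per-scaffold length change equals the signed sum of its edits
  win <- inj$normal_windows
  for (w in seq_len(nrow(win))) {
    sid <- sprintf("scf%02d", w)
    rows <- tr[tr$scaffold_id == sid, , drop = FALSE]
    delta <- sum(ifelse(rows$kind == "insertion", rows$size, -rows$size))
    expect_equal(nchar(inj$scaffolds[[sid]]) - (win$end[w] - win$start[w]),
                 delta, info = sid)
  }
  # the deletion makes its scaffold 55 bp shorter than the source window
  del <- tr[tr$kind == "deletion", ]
  expect_equal(del$size, 55L)
  # no errors: scaffolds are exact genome windows
  inj0 <- inject_assembly_errors(g, errors[0, ])
  for (w in seq_len(nrow(inj0$normal_windows))) {
    expect_identical(inj0$scaffolds[[sprintf("scf%02d", w)]],
                     substr(inj0$genome[[1]], inj0$normal_windows$start[w] + 1,
                            inj0$normal_windows$end[w]))
  }
})

test_that("misjoin injection plants an overlapping repeat shared by two
           scaffolds", {
  g <- generate_genome(400000, seed = 11)
  inj <- inject_assembly_errors(g, data.frame(kind = "misjoin", size = 0L))
  mj <- inj$scaffolds[["mis01"]]
  cp <- inj$scaffolds[["cmp01"]]
  jrep <- substr(mj, 40001, 40500)
  expect_identical(substr(cp, nchar(cp) - 499, nchar(cp)), jrep)
  tr <- inj$truth[inj$truth$kind == "misjoin", ]
  expect_equal(c(tr$s_left, tr$s_right), c(40000L, 40500L))
  # the two joined source windows are distant on the genome
  expect_gte(70000L - 40500L, 10000L)
})

test_that("the anchor aligner recovers whole-window, split and
           reverse-strand alignments", {
  g <- generate_genome(60000, seed = 12)
  gs <- g[[1]]
  ref <- c(ref = gs)
  # scaffold equal to a window: one full-length segment
  sc <- c(w = substr(gs, 10001, 30000))
  segs <- naive_align_long(sc, ref)
  expect_equal(nrow(segs), 1L)
  expect_equal(c(segs$s_start, segs$s_end), c(0L, 20000L))
  expect_equal(c(segs$r_start, segs$r_end), c(10000L, 30000L))
  # a 100-bp novel insertion splits the alignment around it
  sc2 <- c(w = paste0(substr(gs, 10001, 20000), random_seq_for_test(100),
                      substr(gs, 20001, 30000)))
  segs2 <- naive_align_long(sc2, ref)
  segs2 <- segs2[order(segs2$s_start), ]
  expect_equal(nrow(segs2), 2L)
  expect_equal(segs2$s_end[1], 10000L)
  expect_equal(segs2$s_start[2], 10100L)
  # reverse-complemented scaffold: single minus-strand segment
  sc3 <- c(w = misasm:::revcomp(substr(gs, 10001, 30000)))
  segs3 <- naive_align_long(sc3, ref)
  expect_equal(nrow(segs3), 1L)
  expect_equal(segs3$strand, "-")
  expect_equal(c(segs3$r_start, segs3$r_end), c(10000L, 30000L))
})

test_that("the read aligner marks repeat reads as multi and is seeded", {
  set.seed(13)
  rep_seq <- random_seq_for_test(400)
  sc <- c(s = paste0(random_seq_for_test(3000), rep_seq,
                     random_seq_for_test(2000), rep_seq,
                     random_seq_for_test(3000)))
  unique_read <- substr(sc[[1]], 1001, 1100)
  repeat_read <- substr(rep_seq, 101, 200)
  al <- naive_align_reads(setNames(c(unique_read, repeat_read),
                                   c("u", "r")), NULL, sc)
  expect_equal(al$is_multi[al$read_id == "u"], FALSE)
  expect_equal(al$n_best[al$read_id == "u"], 1L)
  expect_equal(al$is_multi[al$read_id == "r"], TRUE)
  expect_equal(al$n_best[al$read_id == "r"], 2L)
  # placements are reproducible under a fixed seed
  reads <- setNames(rep(repeat_read, 50), paste0("m", 1:50))
  set.seed(99); a1 <- naive_align_reads(reads, NULL, sc)
  set.seed(99); a2 <- naive_align_reads(reads, NULL, sc)
  expect_identical(a1, a2)
  # multi-placement choices split between the two copies
  expect_gt(length(unique(a1$pos)), 1L)
})

test_that("reads with excess mismatches or no seed match are dropped", {
  sc <- c(s = random_seq_for_test(2000))
  good <- substr(sc[[1]], 501, 600)
  mut <- good
  for (p in c(10, 30, 50, 70, 90)) substr(mut, p, p) <- "N"
  al <- naive_align_reads(setNames(c(good, mut, random_seq_for_test(100)),
                                   c("g", "m", "x")), NULL, sc)
  expect_identical(sort(al$read_id), "g")
})

test_that("scenario generation is reproducible and internally consistent", {
  sc1 <- simulate_scenario(seed = 5, genome_len = 120000L, n_misjoin = 0L,
                           n_ins_mid = 2L, n_ins_end = 1L, n_del = 1L,
                           svs = NULL, depth = 5)
  sc2 <- simulate_scenario(seed = 5, genome_len = 120000L, n_misjoin = 0L,
                           n_ins_mid = 2L, n_ins_end = 1L, n_del = 1L,
                           svs = NULL, depth = 5)
  expect_identical(sc1$scaffolds, sc2$scaffolds)
  expect_identical(sc1$read1, sc2$read1)
  expect_identical(sc1$truth, sc2$truth)
  # truth coordinates are consistent with the emitted sequences
  expect_equal(nrow(sc1$truth), 4L)
  for (i in seq_len(nrow(sc1$truth))) {
    L <- nchar(sc1$scaffolds[[sc1$truth$scaffold_id[i]]])
    expect_lte(sc1$truth$s_right[i], L)
  }
})
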