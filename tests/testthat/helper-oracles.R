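# Independent oracles and small fixture builders used across the suite.

# Plain-loop implementation of the chain-selection rule, kept deliberately
# close to its verbal statement: start from the best-scoring segment,
# extend to the 3' end choosing the adjacent candidate (overlap/gap <=
# max_adjacency) with the smallest overlap/gap, falling back to the
# globally smallest when none is adjacent; then extend to the 5' end the
# same way. Assumes distinct scores and no contained intervals among the
# inputs (the random generator below guarantees both).
oracle_chain <- function(segs, scaffold_len, max_adjacency = 1000) {
  n <- nrow(segs)
  if (n <= 1) return(segs[order(segs$s_start), , drop = FALSE])
  contained <- vapply(seq_len(n), function(i) {
    any(vapply(seq_len(n), function(j) {
      j != i && segs$s_start[j] <= segs$s_start[i] &&
        segs$s_end[i] <= segs$s_end[j] &&
        !(segs$s_start[j] == segs$s_start[i] &&
            segs$s_end[j] == segs$s_end[i])
    }, logical(1)))
  }, logical(1))
  segs <- segs[!contained, , drop = FALSE]
  n <- nrow(segs)
  used <- rep(FALSE, n)
  cur <- which.max(segs$score)
  used[cur] <- TRUE
  chain <- cur
  cur_end <- segs$s_end[cur]
  repeat {
    cand <- which(!used & segs$s_end > cur_end)
    if (length(cand) == 0 || cur_end >= scaffold_len) break
    size <- abs(segs$s_start[cand] - cur_end)
    near <- cand[size <= max_adjacency]
    pick <- if (length(near)) {
      near[which.min(abs(segs$s_start[near] - cur_end))]
    } else {
      cand[which.min(size)]
    }
    used[pick] <- TRUE
    chain <- c(chain, pick)
    cur_end <- segs$s_end[pick]
  }
  cur_start <- segs$s_start[which.max(segs$score)]
  repeat {
    cand <- which(!used & segs$s_start < cur_start)
    if (length(cand) == 0 || cur_start <= 0) break
    size <- abs(cur_start - segs$s_end[cand])
    near <- cand[size <= max_adjacency]
    pick <- if (length(near)) {
      near[which.min(abs(cur_start - segs$s_end[near]))]
    } else {
      cand[which.min(size)]
    }
    used[pick] <- TRUE
    chain <- c(chain, pick)
    cur_start <- segs$s_start[pick]
  }
  out <- segs[sort(chain), , drop = FALSE]
  out[order(out$s_start), , drop = FALSE]
}

# brute-force N50: try every candidate length, keep the largest that
# satisfies the defining property
oracle_n50 <- function(lengths) {
  ok <- vapply(sort(unique(lengths), decreasing = TRUE), function(L) {
    sum(lengths[lengths >= L]) >= sum(lengths) / 2
  }, logical(1))
  sort(unique(lengths), decreasing = TRUE)[which(ok)[1]]
}

# random alignment-segment set on one scaffold, built to avoid score ties
# and duplicate intervals
random_segments <- function(n, scaffold_len = 10000) {
  repeat {
    s_start <- sample.int(scaffold_len - 500, n)
    width <- sample(200:3000, n, replace = TRUE)
    s_end <- pmin(s_start + width, scaffold_len)
    if (anyDuplicated(cbind(s_start, s_end))) next
    break
  }
  data.frame(scaffold_id = "s", ref_id = "r",
             s_start = s_start, s_end = s_end,
             r_start = s_start, r_end = s_end,
             strand = "+",
             score = sample(seq(10, 1000, by = 1), n),
             identity_pct = 100, n_mismatch = 0L, n_gap = 0L,
             stringsAsFactors = FALSE)
}

# minimal alignment-segment row
seg <- function(s_start, s_end, r_start = s_start, r_end = s_end,
                score = s_end - s_start, strand = "+", ref_id = "ref",
                scaffold_id = "scf") {
  data.frame(scaffold_id = scaffold_id, ref_id = ref_id,
             s_start = s_start, s_end = s_end,
             r_start = r_start, r_end = r_end, strand = strand,
             score = score, identity_pct = 100, n_mismatch = 0L,
             n_gap = 0L, stringsAsFactors = FALSE)
}

# minimal read-alignment rows (ungapped, plus-strand unless stated)
read_row <- function(id, pos, seq, mate = 1L, scaffold = "scf",
                     strand = "+", multi = FALSE) {
  data.frame(read_id = id, mate = mate, scaffold_id = scaffold,
             pos = pos, end = pos + nchar(seq), strand = strand,
             is_multi = multi, n_best = if (multi) 2L else 1L, seq = seq,
             mate_scaffold = NA_character_, mate_pos = NA_integer_,
             mate_strand = NA_character_, stringsAsFactors = FALSE)
}

# pair-table row in the geometry make_pairs() would produce for an
# FR pair of read length rl with 5' ends at p1 (fwd) and p2 (rev)
pair_row <- function(p1, frag, rl = 100L, scaffold = "s",
                     fr = TRUE) {
  five2 <- p1 + frag - 1L
  data.frame(read_id = "p", scaffold_1 = scaffold, pos_1 = p1,
             end_1 = p1 + rl, strand_1 = "+",
             scaffold_2 = scaffold, pos_2 = five2 - rl + 1L,
             end_2 = five2 + 1L, strand_2 = "-",
             same_scaffold = TRUE, is_fr = fr, frag = frag,
             frag_lo = p1, frag_hi = five2 + 1L,
             stringsAsFactors = FALSE)
}

# evidence bundle with benign defaults, overridable per test
mk_ev <- function(n_disagreements = 0L, disagreements_per_kbp = 0,
                  has_high_cov = FALSE, has_low_cov = FALSE,
                  has_zero_cov = FALSE, multi_align_ratio = 0,
                  n_reads = 50L, discordant_ratio = 0,
                  span_frag_mean = NA_real_, span_pair_count = 0L) {
  list(n_disagreements = n_disagreements,
       disagreements_per_kbp = disagreements_per_kbp,
       has_high_cov = has_high_cov, has_low_cov = has_low_cov,
       has_zero_cov = has_zero_cov,
       multi_align_ratio = multi_align_ratio, n_reads = n_reads,
       discordant_ratio = discordant_ratio,
       span_frag_mean = span_frag_mean,
       span_pair_count = span_pair_count,
       end_paired_support = FALSE)
}

# full verdict for one difference kind given an evidence bundle,
# mirroring the dispatch order of validate_differences()
dispatch_verdict <- function(kind, ev, est_size = 100L,
                             lib = list(mu = 368, sigma = 61),
                             cfg = misasm_config()) {
  diff <- data.frame(kind = kind, est_size = est_size)
  v <- if (kind == "MISJOIN") {
    validate_misjoin(ev, cfg)
  } else if (kind == "DELETION") {
    validate_deletion(diff, ev, lib, cfg)
  } else {
    validate_insertion(diff, ev, lib, cfg)
  }
  if (is.null(v)) v <- classify_sv(ev, cfg)
  v
}

random_seq_for_test <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
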