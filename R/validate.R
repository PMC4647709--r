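#' Compute the breakpoint region of a difference
#'
#' Misjoins span the overlap (or junction) of the two flanking segments
#' on the scaffold; each margin is then pushed outward past contiguous
#' columns whose pileup majority base disagrees with the scaffold base
#' (mismatched segment tails), up to `trim_cap` bp per side. Middle
#' insertions and deletions take the inner scaffold endpoints of the
#' flanking segments directly; end insertions run from the last aligned
#' position to the scaffold end; an unaligned scaffold is its own region.
#' Zero-width junctions are widened to 1 bp so evidence can be evaluated.
#'
#' @param diff one-row difference data frame.
#' @param pileup pileup list for the scaffold (used for misjoin margin
#'   trimming; may be NULL to skip trimming).
#' @param scaffold_seq scaffold sequence string.
#' @param trim_cap maximum trimming per side in bp (default 200).
#' @param majority_frac majority threshold used during trimming.
#' @return List with `M_L`, `M_R` (0-based half-open) and `origin_kind`.
#' @export
compute_breakpoint_region <- function(diff, pileup = NULL,
                                      scaffold_seq = NULL, trim_cap = 200L,
                                      majority_frac = 0.8) {
  L <- nchar(scaffold_seq)
  ml <- diff$s_left
  mr <- diff$s_right
  if (diff$kind == "MISJOIN" && !is.null(pileup) && !is.null(scaffold_seq)) {
    counts <- pileup$counts
    depth <- pileup$depth
    mismatch_col <- function(p) {
      # 0-based p; TRUE when covered and the majority base differs from
      # the scaffold base
      if (p < 0L || p >= L || depth[p + 1L] == 0L) return(FALSE)
      col <- counts[, p + 1L]
      b <- c("A", "C", "G", "T")[which.max(col)]
      b != substr(scaffold_seq, p + 1L, p + 1L)
    }
    moved <- 0L
    while (moved < trim_cap && mismatch_col(ml - 1L)) {
      ml <- ml - 1L
      moved <- moved + 1L
    }
    moved <- 0L
    while (moved < trim_cap && mismatch_col(mr)) {
      mr <- mr + 1L
      moved <- moved + 1L
    }
  }
  if (mr <= ml) {
    mr <- min(L, ml + 1L)
    ml <- mr - 1L
  }
  list(M_L = as.integer(ml), M_R = as.integer(mr), origin_kind = diff$kind)
}

new_verdict <- function(label, correction, note = "") {
  list(label = label, correction = correction, note = note)
}

#' Validate a putative misjoin against read evidence
#'
#' A misjoin is a validated assembly error when it shows abnormal
#' coverage (high, low or zero) or more than one disagreement, or when
#' its multi-align ratio exceeds the threshold (repeat-driven joins).
#' Otherwise it is passed on to structural-variation analysis.
#'
#' @param ev evidence bundle list for the region.
#' @param cfg configuration list.
#' @return Verdict list (`label`, `correction`, `note`) or NULL when not
#'   validated.
#' @export
validate_misjoin <- function(ev, cfg = misasm_config()) {
  cond1 <- ev$has_high_cov || ev$has_low_cov || ev$has_zero_cov ||
    ev$n_disagreements > 1L
  cond2 <- ev$multi_align_ratio > cfg$multi_ratio_thresh
  if (cond1 || cond2) {
    return(new_verdict("ERROR_MISJOIN", "SPLIT"))
  }
  NULL
}

#' Validate a putative insertion against read evidence
#'
#' Middle insertions with enough spanning pairs use the fragment-size
#' test: the excess of the spanning-pair fragment mean over the library
#' insert size must be within `sd_mult_indel` standard deviations of the
#' estimated insertion size, and at least two of disagreements present,
#' low coverage, and discordant ratio above threshold must hold. Without
#' a fragment-size match (typically insertions longer than the read
#' length) the fallback is more than `disag_per_kbp` disagreements per
#' kbp. End insertions and unaligned scaffolds are errors when the
#' region shows any disagreement or zero-coverage base; their correction
#' is an end trim.
#'
#' @param diff one-row difference data frame.
#' @param ev evidence bundle list.
#' @param lib library model (`mu`, `sigma`).
#' @param cfg configuration list.
#' @return Verdict list or NULL when not validated.
#' @export
validate_insertion <- function(diff, ev, lib, cfg = misasm_config()) {
  if (diff$kind %in% c("INSERTION_END", "UNALIGNED_SCAFFOLD")) {
    if (ev$n_disagreements >= 1L || ev$has_zero_cov) {
      return(new_verdict("ERROR_INSERTION", "TRIM_END"))
    }
    return(NULL)
  }
  frag_match <- FALSE
  if (!is.na(ev$span_frag_mean)) {
    frag_match <- abs((ev$span_frag_mean - lib$mu) - diff$est_size) <
      cfg$sd_mult_indel * lib$sigma
  }
  if (frag_match) {
    support <- (ev$n_disagreements >= 1L) + ev$has_low_cov +
      (ev$discordant_ratio > cfg$disc_ratio_thresh)
    if (support >= 2L) {
      return(new_verdict("ERROR_INSERTION", "REPORT_ONLY"))
    }
    return(NULL)
  }
  if (ev$disagreements_per_kbp > cfg$disag_per_kbp) {
    return(new_verdict("ERROR_INSERTION", "REPORT_ONLY",
                       "validated by disagreement rate"))
  }
  NULL
}

#' Validate a putative deletion against read evidence
#'
#' Mirror image of the insertion rule: the shortfall of the
#' spanning-pair fragment mean below the library insert size must be
#' within `sd_mult_indel` standard deviations of the estimated deleted
#' size, with at least two of disagreements present, abnormal (high, low
#' or zero) coverage, and discordant ratio above threshold. The fallback
#' for large deletions without a fragment match is the disagreement
#' rate.
#'
#' @inheritParams validate_insertion
#' @return Verdict list or NULL when not validated.
#' @export
validate_deletion <- function(diff, ev, lib, cfg = misasm_config()) {
  frag_match <- FALSE
  if (!is.na(ev$span_frag_mean)) {
    frag_match <- abs((lib$mu - ev$span_frag_mean) - diff$est_size) <
      cfg$sd_mult_indel * lib$sigma
  }
  if (frag_match) {
    support <- (ev$n_disagreements >= 1L) +
      (ev$has_high_cov || ev$has_low_cov || ev$has_zero_cov) +
      (ev$discordant_ratio > cfg$disc_ratio_thresh)
    if (support >= 2L) {
      return(new_verdict("ERROR_DELETION", "REPORT_ONLY"))
    }
    return(NULL)
  }
  if (ev$disagreements_per_kbp > cfg$disag_per_kbp) {
    return(new_verdict("ERROR_DELETION", "REPORT_ONLY",
                       "validated by disagreement rate"))
  }
  NULL
}

#' Classify an unvalidated difference as structural variation or warning
#'
#' A difference not validated as an assembly error is a correct assembly
#' reflecting structural variation when its breakpoint region looks like
#' a normal region: no coverage anomaly (high, low or zero), no
#' disagreements, and a discordant ratio strictly below the threshold.
#' Otherwise it is output as a warning. Regions with almost no read
#' evidence (fewer than `min_region_reads` reads and fewer than
#' `min_span_pairs` spanning pairs) are warnings as well, since absence
#' of reads is not evidence of correctness.
#'
#' @param ev evidence bundle list.
#' @param cfg configuration list.
#' @return Verdict list (always non-NULL).
#' @export
classify_sv <- function(ev, cfg = misasm_config()) {
  if (ev$n_reads < cfg$min_region_reads && ev$span_pair_count <
      cfg$min_span_pairs) {
    return(new_verdict("WARNING", "REPORT_ONLY", "low evidence"))
  }
  clean <- !ev$has_high_cov && !ev$has_low_cov && !ev$has_zero_cov &&
    ev$n_disagreements == 0L &&
    ev$discordant_ratio < cfg$disc_ratio_thresh
  if (clean) new_verdict("CORRECT_SV", "REPORT_ONLY")
  else new_verdict("WARNING", "REPORT_ONLY")
}

# assemble the evidence bundle for one region from per-scaffold context
region_evidence <- function(region, sc, cfg) {
  reg <- c(region$M_L, region$M_R)
  flags <- coverage_flags(sc$depth, reg, mode = cfg$mode,
                          window = cfg$window_cov,
                          anomaly_windows = cfg$anomaly_windows,
                          extend = sc$read_len, profile = sc$profile)
  nd <- sum(sc$disag >= reg[1] & sc$disag < reg[2])
  width <- reg[2] - reg[1]
  mar <- multi_align_ratio(sc$reads, reg)
  dr <- discordant_ratio(sc$events, reg, window = cfg$window_disc)
  sp <- spanning_fragments(sc$pairs, reg, min_span = cfg$min_span_pairs)
  ends <- sc$pairs$is_fr & !is.na(sc$pairs$frag_lo) &
    (sc$pairs$frag_lo < sc$read_len |
       sc$pairs$frag_hi > length(sc$depth) - sc$read_len)
  list(n_disagreements = nd,
       disagreements_per_kbp = nd / (width / 1000),
       has_high_cov = flags$has_high_cov,
       has_low_cov = flags$has_low_cov,
       has_zero_cov = flags$has_zero_cov,
       multi_align_ratio = mar$ratio,
       n_reads = mar$n,
       discordant_ratio = dr$ratio,
       n_region_pairs = dr$n,
       span_frag_mean = sp$mean,
       span_pair_count = sp$n,
       end_paired_support = any(ends))
}

#' Validate all differences of a run against read evidence
#'
#' Computes the breakpoint region and evidence bundle of every
#' difference, applies the per-type validation rule, and classifies
#' unvalidated differences as structural-variation correct assemblies or
#' warnings. Differences intersecting scaffold N-runs are gap reports
#' regardless of evidence.
#'
#' @param diffs difference data frame from [classify_differences()].
#' @param scaffolds named character vector of scaffold sequences.
#' @param reads read alignment data frame.
#' @param pairs pair data frame from [make_pairs()].
#' @param lib library model list.
#' @param cfg configuration list.
#' @return Verdict data frame: one row per difference with the
#'   breakpoint region, label, correction directive and all evidence
#'   values.
#' @export
validate_differences <- function(diffs, scaffolds, reads, pairs, lib,
                                 cfg = misasm_config()) {
  discordant <- classify_pairs(pairs, lib, cfg$sd_mult_discordant)
  events <- pair_events(pairs, discordant)
  read_len <- cfg$read_len
  if (is.null(read_len)) {
    read_len <- if (nrow(reads)) {
      as.integer(round(median(reads$end - reads$pos)))
    } else 100L
  }
  rows <- vector("list", nrow(diffs))
  for (sid in unique(diffs$scaffold_id)) {
    sreads <- reads[reads$scaffold_id == sid, , drop = FALSE]
    pu <- build_pileup(sreads, scaffolds[[sid]])
    sc <- list(
      depth = pu$depth,
      disag = call_disagreements(pu, cfg$majority_frac, cfg$min_depth),
      profile = coverage_profile(pu$depth, scaffolds[[sid]],
                                 cfg$window_cov, cfg$gap_run_min),
      reads = sreads,
      events = events[events$scaffold_id == sid, , drop = FALSE],
      pairs = pairs[pairs$same_scaffold & pairs$scaffold_1 == sid, ,
                    drop = FALSE],
      read_len = read_len)
    for (i in which(diffs$scaffold_id == sid)) {
      diff <- diffs[i, , drop = FALSE]
      region <- compute_breakpoint_region(diff, pu, scaffolds[[sid]],
                                          cfg$trim_cap, cfg$majority_frac)
      ev <- region_evidence(region, sc, cfg)
      v <- if (diff$is_gap) {
        new_verdict("GAP_REPORT", "REPORT_ONLY", "scaffold N gap")
      } else if (diff$kind == "MISJOIN") {
        validate_misjoin(ev, cfg)
      } else if (diff$kind %in% c("INSERTION_MID", "INSERTION_END",
                                  "UNALIGNED_SCAFFOLD")) {
        validate_insertion(diff, ev, lib, cfg)
      } else {
        validate_deletion(diff, ev, lib, cfg)
      }
      if (is.null(v)) v <- classify_sv(ev, cfg)
      rows[[i]] <- data.frame(
        scaffold_id = diff$scaffold_id, kind = diff$kind,
        s_left = diff$s_left, s_right = diff$s_right,
        est_size = diff$est_size,
        M_L = region$M_L, M_R = region$M_R,
        label = v$label, correction = v$correction, note = v$note,
        n_disagreements = ev$n_disagreements,
        disagreements_per_kbp = round(ev$disagreements_per_kbp, 3),
        has_high_cov = ev$has_high_cov, has_low_cov = ev$has_low_cov,
        has_zero_cov = ev$has_zero_cov,
        multi_align_ratio = round(ev$multi_align_ratio, 4),
        n_reads = ev$n_reads,
        discordant_ratio = round(ev$discordant_ratio, 4),
        span_frag_mean = ev$span_frag_mean,
        span_pair_count = ev$span_pair_count,
        stringsAsFactors = FALSE)
    }
  }
  if (!length(rows)) return(empty_verdicts())
  do.call(rbind, rows)
}

empty_verdicts <- function() {
  data.frame(scaffold_id = character(), kind = character(),
             s_left = integer(), s_right = integer(), est_size = integer(),
             M_L = integer(), M_R = integer(), label = character(),
             correction = character(), note = character(),
             n_disagreements = integer(), disagreements_per_kbp = numeric(),
             has_high_cov = logical(), has_low_cov = logical(),
             has_zero_cov = logical(), multi_align_ratio = numeric(),
             n_reads = integer(), discordant_ratio = numeric(),
             span_frag_mean = numeric(), span_pair_count = integer(),
             stringsAsFactors = FALSE)
}
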