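#' Build a base-count pileup for one scaffold
#'
#' One column per scaffold base holding counts of A, C, G and T from the
#' aligned read bases (soft-clipped bases are excluded upstream; N read
#' bases are ignored), plus the per-base count of covering multi-placed
#' reads. Reads whose interval falls outside the scaffold are rejected
#' and counted.
#'
#' @param reads read alignment data frame restricted to one scaffold.
#' @param scaffold the scaffold sequence (a single character string).
#' @return List with `counts` (4 x L integer matrix, rows A,C,G,T),
#'   `depth` (integer vector), `multi` (integer vector) and `n_rejected`.
#' @export
build_pileup <- function(reads, scaffold) {
  L <- nchar(scaffold)
  res <- cpp_pileup(L, as.integer(reads$pos), as.character(reads$seq),
                    as.logical(reads$is_multi))
  counts <- res$counts
  rownames(counts) <- c("A", "C", "G", "T")
  if (res$rejected > 0) {
    warning(res$rejected, " read(s) outside scaffold bounds rejected")
  }
  list(counts = counts,
       depth = colSums(counts),
       multi = res$multi,
       n_rejected = res$rejected)
}

pileup_majority <- function(counts) {
  maxc <- pmax(counts[1, ], counts[2, ], counts[3, ], counts[4, ])
  base <- c("A", "C", "G", "T")[max.col(t(counts), ties.method = "first")]
  list(count = maxc, base = base)
}

#' Call pileup disagreements
#'
#' A scaffold position is a disagreement when its depth is at least
#' `min_depth` and the majority base accounts for strictly less than
#' `majority_frac` of the covering read bases.
#'
#' @param pileup pileup list from [build_pileup()].
#' @param majority_frac majority threshold (default 0.8, strict `<`).
#' @param min_depth minimum depth for calling (default 5).
#' @return Integer vector of 0-based disagreement positions.
#' @export
call_disagreements <- function(pileup, majority_frac = 0.8, min_depth = 5L) {
  depth <- pileup$depth
  maxc <- pmax(pileup$counts[1, ], pileup$counts[2, ],
               pileup$counts[3, ], pileup$counts[4, ])
  which(depth >= min_depth & maxc < majority_frac * depth) - 1L
}

# per-scaffold coverage summary: consecutive window means plus scaffold
# mean coverage excluding N-run bases
coverage_profile <- function(depth, scaffold_seq = NULL, window = 50L,
                             gap_run_min = 10L) {
  L <- length(depth)
  win_start <- seq.int(0L, L - 1L, by = window)
  win_end <- pmin(win_start + window, L)
  idx <- findInterval(seq_len(L) - 1L, win_start)
  win_mean <- as.numeric(tapply(depth, idx, mean))
  non_gap <- rep(TRUE, L)
  if (!is.null(scaffold_seq)) {
    runs <- find_n_runs(scaffold_seq, gap_run_min)
    if (nrow(runs)) {
      for (i in seq_len(nrow(runs))) {
        non_gap[(runs[i, 1] + 1L):runs[i, 2]] <- FALSE
      }
    }
  }
  list(win_start = win_start, win_end = win_end, win_mean = win_mean,
       scaffold_mean = mean(depth[non_gap]),
       win_mm = mean(win_mean), win_sd = stats::sd(win_mean))
}

#' Coverage anomaly flags for a breakpoint region
#'
#' The breakpoint region, extended by one read length on each side so
#' that coverage ramps around a junction are captured, is cut into
#' consecutive sub-windows (50 bp by default) and per-window mean
#' coverage computed. In standard mode the region is flagged high (low)
#' when at least `anomaly_windows` sub-windows exceed 1.5x (fall below
#' 0.5x) the scaffold mean coverage. In single-cell mode, for highly
#' uneven depth, the thresholds are instead the scaffold's mean 50-bp
#' window coverage plus/minus 1.5 standard deviations of those window
#' coverages. Zero coverage is flagged when any base inside the region
#' proper has depth 0.
#'
#' @param depth per-base depth vector for the scaffold.
#' @param region integer c(M_L, M_R), 0-based half-open.
#' @param mode `"standard"` or `"single_cell"`.
#' @param window window size in bp (default 50).
#' @param anomaly_windows windows required to flag (default 2).
#' @param extend region extension per side in bp (one read length).
#' @param scaffold_seq optional scaffold sequence; N-runs are excluded
#'   from the scaffold mean.
#' @param profile optional precomputed profile (internal reuse).
#' @return List of logicals `has_high_cov`, `has_low_cov`, `has_zero_cov`.
#' @export
coverage_flags <- function(depth, region, mode = c("standard", "single_cell"),
                           window = 50L, anomaly_windows = 2L, extend = 100L,
                           scaffold_seq = NULL, profile = NULL) {
  mode <- match.arg(mode)
  if (region[2] <= region[1]) stop("region must span at least 1 bp")
  if (is.null(profile)) {
    profile <- coverage_profile(depth, scaffold_seq, window)
  }
  a <- max(0L, region[1] - extend)
  b <- min(length(depth), region[2] + extend)
  # consecutive sub-windows of the (extended) breakpoint region
  starts <- seq.int(a, b - 1L, by = window)
  wm <- vapply(starts, function(s) {
    mean(depth[(s + 1L):min(s + window, b)])
  }, numeric(1))
  if (mode == "standard") {
    hi <- sum(wm > 1.5 * profile$scaffold_mean)
    lo <- sum(wm < 0.5 * profile$scaffold_mean)
  } else {
    hi <- sum(wm >= profile$win_mm + 1.5 * profile$win_sd)
    lo <- sum(wm <= profile$win_mm - 1.5 * profile$win_sd)
  }
  zr <- depth[(region[1] + 1L):region[2]]
  list(has_high_cov = hi >= anomaly_windows,
       has_low_cov = lo >= anomaly_windows,
       has_zero_cov = any(zr == 0L))
}

#' Multi-align ratio of a region
#'
#' Fraction of reads overlapping the region that have multiple equal-best
#' placements. Zero (with `n = 0`) when no read overlaps.
#'
#' @param reads read alignment data frame for the scaffold.
#' @param region integer c(M_L, M_R), 0-based half-open.
#' @return List with `ratio` and `n` (overlapping read count).
#' @export
multi_align_ratio <- function(reads, region) {
  sel <- reads$pos < region[2] & reads$end > region[1]
  n <- sum(sel)
  list(ratio = if (n == 0) 0 else mean(reads$is_multi[sel]), n = n)
}

#' Pair mated read alignments
#'
#' Joins mate 1 and mate 2 primary alignments by read id and derives the
#' pair geometry: orientation (inward-facing FR or not) and fragment
#' size, defined as the distance between the two 5' read ends (the 5' end
#' of a forward read is its start, of a reverse read its last base).
#'
#' @param reads read alignment data frame.
#' @return Data frame with one row per pair that has both mates aligned:
#'   mate coordinates, `same_scaffold`, `is_fr`, `frag` (NA for
#'   inter-scaffold pairs) and the fragment interval `frag_lo`/`frag_hi`.
#' @export
make_pairs <- function(reads) {
  m1 <- reads[reads$mate == 1L, , drop = FALSE]
  m2 <- reads[reads$mate == 2L, , drop = FALSE]
  i <- match(m1$read_id, m2$read_id)
  keep <- !is.na(i)
  m1 <- m1[keep, , drop = FALSE]
  m2 <- m2[i[keep], , drop = FALSE]
  same <- m1$scaffold_id == m2$scaffold_id
  # 5' ends: start of the forward mate, last base of the reverse mate
  five1 <- ifelse(m1$strand == "+", m1$pos, m1$end - 1L)
  five2 <- ifelse(m2$strand == "+", m2$pos, m2$end - 1L)
  opposite <- m1$strand != m2$strand
  fwd5 <- ifelse(m1$strand == "+", five1, five2)
  rev5 <- ifelse(m1$strand == "+", five2, five1)
  is_fr <- same & opposite & fwd5 <= rev5
  frag <- ifelse(same & opposite, abs(five2 - five1) + 1L, NA_integer_)
  data.frame(read_id = m1$read_id,
             scaffold_1 = m1$scaffold_id, pos_1 = m1$pos, end_1 = m1$end,
             strand_1 = m1$strand,
             scaffold_2 = m2$scaffold_id, pos_2 = m2$pos, end_2 = m2$end,
             strand_2 = m2$strand,
             same_scaffold = same, is_fr = is_fr,
             frag = as.integer(frag),
             frag_lo = ifelse(same, pmin(five1, five2), NA_integer_),
             frag_hi = ifelse(same, pmax(five1, five2) + 1L, NA_integer_),
             stringsAsFactors = FALSE)
}

#' Classify read pairs as concordant or discordant
#'
#' A pair is discordant when its mates land on different scaffolds, when
#' the orientation is not inward-facing FR, or when its fragment size
#' deviates from the library mean by strictly more than `sd_mult`
#' standard deviations.
#'
#' @param pairs pair data frame from [make_pairs()].
#' @param lib library model list with `mu` and `sigma`.
#' @param sd_mult deviation multiplier (default 3).
#' @return Logical vector, TRUE = discordant.
#' @export
classify_pairs <- function(pairs, lib, sd_mult = 3) {
  disc <- !pairs$same_scaffold | !pairs$is_fr
  sized <- !disc & abs(pairs$frag - lib$mu) > sd_mult * lib$sigma
  disc | sized
}

# region membership events for discordant-ratio computation: one interval
# per same-scaffold pair (its fragment interval) and one per mapped mate
# of an inter-scaffold pair (its read interval, always discordant)
pair_events <- function(pairs, discordant) {
  same <- pairs$same_scaffold
  ev <- data.frame(scaffold_id = pairs$scaffold_1[same],
                   lo = pairs$frag_lo[same], hi = pairs$frag_hi[same],
                   discordant = discordant[same], stringsAsFactors = FALSE)
  if (any(!same)) {
    inter <- pairs[!same, , drop = FALSE]
    ev2 <- data.frame(
      scaffold_id = c(inter$scaffold_1, inter$scaffold_2),
      lo = c(inter$pos_1, inter$pos_2),
      hi = c(inter$end_1, inter$end_2),
      discordant = TRUE, stringsAsFactors = FALSE)
    ev <- rbind(ev, ev2)
  }
  ev
}

#' Discordant-pair ratio of a region
#'
#' Ratio of discordant pairs to all pairs whose fragment interval
#' overlaps the region. Regions wider than `window` bp are cut into
#' consecutive `window`-bp sub-regions and the maximum sub-region ratio
#' returned.
#'
#' @param events pair membership events for the scaffold (internal form:
#'   columns `lo`, `hi`, `discordant`), as produced within the pipeline.
#' @param region integer c(M_L, M_R), 0-based half-open.
#' @param window sub-region size (default 500).
#' @return List with `ratio` and `n` (pairs overlapping the region).
#' @export
discordant_ratio <- function(events, region, window = 500L) {
  width <- region[2] - region[1]
  sub_ratio <- function(a, b) {
    sel <- events$lo < b & events$hi > a
    if (!any(sel)) 0 else mean(events$discordant[sel])
  }
  n <- sum(events$lo < region[2] & events$hi > region[1])
  if (width <= window) {
    return(list(ratio = sub_ratio(region[1], region[2]), n = n))
  }
  starts <- seq.int(region[1], region[2] - 1L, by = window)
  ratios <- vapply(starts, function(a) {
    sub_ratio(a, min(a + window, region[2]))
  }, numeric(1))
  list(ratio = max(ratios), n = n)
}

#' Fragment statistics of pairs spanning a breakpoint region
#'
#' Selects inward-facing FR pairs with one mate entirely left of M_L and
#' the other entirely right of M_R and returns the mean fragment size and
#' count. The mean is reported as NA when fewer than `min_span` pairs
#' span the region.
#'
#' @param pairs pair data frame (same-scaffold rows are considered).
#' @param region integer c(M_L, M_R).
#' @param min_span minimum pair count for a usable mean (default 3).
#' @return List with `mean` (NA if unsupported) and `n`.
#' @export
spanning_fragments <- function(pairs, region, min_span = 3L) {
  p <- pairs[pairs$same_scaffold & pairs$is_fr, , drop = FALSE]
  # mate order by position
  ord <- p$pos_1 <= p$pos_2
  lend <- ifelse(ord, p$end_1, p$end_2)
  rpos <- ifelse(ord, p$pos_2, p$pos_1)
  sel <- lend <= region[1] & rpos >= region[2]
  n <- sum(sel)
  list(mean = if (n >= min_span) mean(p$frag[sel]) else NA_real_, n = n)
}

#' Estimate or accept the library insert-size model
#'
#' With `mu` and `sigma` supplied they are returned verbatim
#' (`source = "given"`). Otherwise the insert-size distribution is
#' estimated from inward-facing FR pairs after discarding fragments
#' outside [1, 5 x median] (`source = "estimated"`).
#'
#' @param pairs pair data frame from [make_pairs()] (may be NULL when
#'   `mu`/`sigma` are given).
#' @param mu,sigma user-supplied insert-size mean/sd in bp, or NULL.
#' @param min_pairs minimum FR pairs required to estimate (default 1000).
#' @return List with `mu`, `sigma`, `source`.
#' @export
estimate_library <- function(pairs = NULL, mu = NULL, sigma = NULL,
                             min_pairs = 1000L) {
  if (!is.null(mu) && !is.null(sigma)) {
    stopifnot(mu > 0, sigma > 0)
    return(list(mu = mu, sigma = sigma, source = "given"))
  }
  if (is.null(pairs)) {
    stop("no insert-size values supplied and no pairs to estimate from")
  }
  frag <- pairs$frag[pairs$is_fr]
  frag <- frag[!is.na(frag)]
  med <- median(frag)
  frag <- frag[frag >= 1 & frag <= 5 * med]
  if (length(frag) < min_pairs) {
    stop("too few proper pairs (", length(frag),
         ") to estimate the insert-size distribution; supply mu and sigma")
  }
  list(mu = mean(frag), sigma = sd(frag), source = "estimated")
}
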