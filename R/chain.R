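#' Select a non-redundant chain of alignment segments for one scaffold
#'
#' A scaffold aligned by a single segment keeps that segment unchanged.
#' Otherwise segments whose scaffold interval is contained in another
#' segment's interval are removed, and a chain is grown greedily: starting
#' from the highest-scoring segment it is extended towards the scaffold
#' 3' end by repeatedly choosing, among candidates whose scaffold overlap
#' or gap with the current chain end is at most `max_adjacency`, the
#' candidate with the smallest overlap/gap; when no candidate is that
#' close, the remaining candidate with the globally smallest overlap/gap
#' is admitted. The 5' side is then extended symmetrically. Ties on score
#' prefer the longer scaffold interval, then the smaller start; ties on
#' overlap/gap size prefer the higher score.
#'
#' @param segments alignment segment data frame (one scaffold).
#' @param scaffold_len scaffold length in bp.
#' @param max_adjacency maximum overlap or gap in bp for adjacency
#'   (default 1000).
#' @return A `segment_chain`: list with `scaffold_id`, `scaffold_len` and
#'   `segments` (data frame sorted by `s_start`).
#' @export
select_nonredundant <- function(segments, scaffold_len,
                                max_adjacency = 1000L) {
  sid <- if (nrow(segments)) segments$scaffold_id[1] else NA_character_
  if (nrow(segments) > 1 &&
      length(unique(segments$scaffold_id)) != 1) {
    stop("segments must all belong to one scaffold")
  }
  chain <- function(segs) {
    structure(list(scaffold_id = sid, scaffold_len = scaffold_len,
                   segments = segs[order(segs$s_start, segs$s_end), ,
                                   drop = FALSE]),
              class = "segment_chain")
  }
  if (nrow(segments) <= 1) return(chain(segments))

  segs <- remove_contained(segments)
  if (nrow(segs) == 1) return(chain(segs))

  # deterministic ordering used for every tie-break
  pref <- order(-segs$score, -(segs$s_end - segs$s_start), segs$s_start)
  segs <- segs[pref, , drop = FALSE]
  used <- rep(FALSE, nrow(segs))
  start <- 1L
  used[start] <- TRUE
  picked <- start

  pick_next <- function(dist) {
    # dist: signed overlap(-)/gap(+) per segment, NA = not a candidate
    ok <- !used & !is.na(dist)
    if (!any(ok)) return(NA_integer_)
    size <- abs(dist)
    near <- ok & size <= max_adjacency
    pool <- if (any(near)) which(near) else which(ok)
    pool[order(size[pool])][1]  # rows already in score-preference order
  }

  # extend towards the 3' end
  cur_end <- segs$s_end[start]
  repeat {
    if (cur_end >= scaffold_len) break
    d <- ifelse(segs$s_end > cur_end, segs$s_start - cur_end, NA_real_)
    nxt <- pick_next(d)
    if (is.na(nxt)) break
    used[nxt] <- TRUE
    picked <- c(picked, nxt)
    cur_end <- segs$s_end[nxt]
  }
  # extend towards the 5' end
  cur_start <- segs$s_start[start]
  repeat {
    if (cur_start <= 0) break
    d <- ifelse(segs$s_start < cur_start, cur_start - segs$s_end, NA_real_)
    nxt <- pick_next(d)
    if (is.na(nxt)) break
    used[nxt] <- TRUE
    picked <- c(picked, nxt)
    cur_start <- segs$s_start[nxt]
  }
  chain(segs[sort(picked), , drop = FALSE])
}

# drop segments whose scaffold interval lies inside another segment's
# interval; of identical intervals the higher-scoring one survives
remove_contained <- function(segs) {
  ord <- order(segs$s_start, -segs$s_end, -segs$score)
  s <- segs[ord, , drop = FALSE]
  keep <- rep(TRUE, nrow(s))
  max_end <- -Inf
  for (i in seq_len(nrow(s))) {
    if (s$s_end[i] <= max_end) keep[i] <- FALSE else max_end <- s$s_end[i]
  }
  s[keep, , drop = FALSE]
}

#' @export
print.segment_chain <- function(x, ...) {
  cat("segment chain for", x$scaffold_id, "(", x$scaffold_len, "bp ):",
      nrow(x$segments), "segments\n")
  invisible(x)
}

empty_differences <- function() {
  data.frame(scaffold_id = character(), kind = character(),
             s_left = integer(), s_right = integer(), est_size = integer(),
             s_gap = integer(), r_gap = integer(),
             ref_id_l = character(), ref_id_r = character(),
             strand_l = character(), strand_r = character(),
             left_end = integer(), right_start = integer(),
             is_gap = logical(), stringsAsFactors = FALSE)
}

# 0-based half-open intervals of runs of >= min_run Ns
find_n_runs <- function(seq, min_run = 10L) {
  m <- gregexpr(sprintf("N{%d,}", min_run), seq)[[1]]
  if (m[1] == -1) return(matrix(integer(0), ncol = 2))
  cbind(m - 1L, m - 1L + attr(m, "match.length"))
}

#' Classify the differences implied by a segment chain
#'
#' Junctions between adjacent chained segments are classified into
#' putative mis-assemblies: adjacent segments on different reference
#' sequences, on opposite strands, at reference distance beyond
#' `misjoin_distance`, or in reference order inconsistent with their
#' strand are misjoins; otherwise a scaffold/reference gap discrepancy
#' larger than `indel_min` is a middle insertion (scaffold gap larger) or
#' a deletion (reference gap larger). Unaligned scaffold ends longer than
#' `end_min` are end insertions, and a scaffold with no alignments at all
#' is an unaligned scaffold, treated as insertion. Differences
#' intersecting a run of `gap_run_min` or more Ns are flagged as scaffold
#' gaps (`is_gap`), to be reported rather than treated as errors.
#'
#' @param chain a `segment_chain` from [select_nonredundant()].
#' @param scaffold_seq the scaffold sequence (for N-run detection); may be
#'   NULL to skip gap flagging.
#' @param cfg configuration list from [misasm_config()].
#' @return Data frame of differences (possibly zero rows) with scaffold
#'   and reference context and the estimated inserted/deleted size.
#' @export
classify_differences <- function(chain, scaffold_seq = NULL,
                                 cfg = misasm_config()) {
  segs <- chain$segments
  L <- chain$scaffold_len
  out <- list()
  add <- function(kind, s_left, s_right, est, p = NULL, n = NULL,
                  s_gap = NA_integer_, r_gap = NA_integer_) {
    out[[length(out) + 1L]] <<- data.frame(
      scaffold_id = chain$scaffold_id, kind = kind,
      s_left = as.integer(s_left), s_right = as.integer(s_right),
      est_size = as.integer(est),
      s_gap = as.integer(s_gap), r_gap = as.integer(r_gap),
      ref_id_l = if (is.null(p)) NA_character_ else p$ref_id,
      ref_id_r = if (is.null(n)) NA_character_ else n$ref_id,
      strand_l = if (is.null(p)) NA_character_ else p$strand,
      strand_r = if (is.null(n)) NA_character_ else n$strand,
      left_end = if (is.null(p)) NA_integer_ else as.integer(p$s_end),
      right_start = if (is.null(n)) NA_integer_ else as.integer(n$s_start),
      is_gap = FALSE, stringsAsFactors = FALSE)
  }

  if (nrow(segs) == 0) {
    if (L > 0) add("UNALIGNED_SCAFFOLD", 0L, L, L)
  } else {
    first <- segs[1, ]
    last <- segs[nrow(segs), ]
    if (first$s_start > cfg$end_min) {
      add("INSERTION_END", 0L, first$s_start, first$s_start, n = first)
    }
    if (nrow(segs) >= 2) {
      for (i in seq_len(nrow(segs) - 1L)) {
        p <- segs[i, ]
        n <- segs[i + 1L, ]
        g_s <- n$s_start - p$s_end
        jl <- min(p$s_end, n$s_start)
        jr <- max(p$s_end, n$s_start)
        if (p$ref_id != n$ref_id || p$strand != n$strand) {
          add("MISJOIN", jl, jr, 0L, p, n, g_s)
          next
        }
        g_r <- if (p$strand == "+") n$r_start - p$r_end
               else p$r_start - n$r_end
        if (g_r > cfg$misjoin_distance || g_r < -cfg$max_adjacency) {
          add("MISJOIN", jl, jr, 0L, p, n, g_s, g_r)
          next
        }
        d <- g_s - g_r
        if (d > cfg$indel_min) {
          add("INSERTION_MID", jl, jr, d, p, n, g_s, g_r)
        } else if (-d > cfg$indel_min) {
          add("DELETION", jl, jr, -d, p, n, g_s, g_r)
        }
      }
    }
    if (last$s_end < L - cfg$end_min) {
      add("INSERTION_END", last$s_end, L, L - last$s_end, p = last)
    }
  }
  if (length(out) == 0) return(empty_differences())
  diffs <- do.call(rbind, out)
  if (!is.null(scaffold_seq)) {
    runs <- find_n_runs(scaffold_seq, cfg$gap_run_min)
    if (nrow(runs)) {
      for (i in seq_len(nrow(diffs))) {
        a <- diffs$s_left[i]
        b <- max(diffs$s_right[i], a + 1L)
        diffs$is_gap[i] <- any(runs[, 1] < b & runs[, 2] > a)
      }
    }
  }
  diffs
}
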