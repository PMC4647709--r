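#' Apply corrections implied by validated errors
#'
#' Every validated misjoin splits its scaffold at the breakpoint region,
#' removing the interval [M_L, M_R) from both resulting pieces (the two
#' copies of the mis-collapsed repeat tail are trimmed). End-insertion
#' errors trim the erroneous scaffold end. Middle insertion/deletion
#' errors are reported but not edited. Multiple corrections on one
#' scaffold are applied right to left; corrected fragments shorter than
#' `min_out_len` are dropped.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param verdicts verdict data frame from [validate_differences()].
#' @param min_out_len minimum emitted fragment length (default 200).
#' @return Named character vector of corrected scaffold sequences; split
#'   pieces are suffixed `_1`, `_2`, ...
#' @export
apply_corrections <- function(scaffolds, verdicts, min_out_len = 200L) {
  out <- list()
  for (sid in names(scaffolds)) {
    seq <- scaffolds[[sid]]
    L <- nchar(seq)
    v <- verdicts[verdicts$scaffold_id == sid &
                    verdicts$correction %in% c("SPLIT", "TRIM_END"), ,
                  drop = FALSE]
    if (nrow(v) == 0) {
      out[[sid]] <- seq
      next
    }
    # removal intervals; SPLIT takes precedence over an overlapping trim
    splits <- v[v$correction == "SPLIT", , drop = FALSE]
    trims <- v[v$correction == "TRIM_END", , drop = FALSE]
    rem <- list()
    for (i in seq_len(nrow(splits))) {
      rem[[length(rem) + 1L]] <- c(splits$M_L[i], splits$M_R[i])
    }
    for (i in seq_len(nrow(trims))) {
      iv <- if (trims$M_L[i] <= 0L) c(0L, trims$M_R[i])
            else c(trims$M_L[i], L)
      overlaps <- any(vapply(rem, function(r) iv[1] < r[2] && iv[2] > r[1],
                             logical(1)))
      if (overlaps) {
        message("trim on ", sid, " overlaps a split; split takes precedence")
      } else {
        rem[[length(rem) + 1L]] <- iv
      }
    }
    rem <- rem[order(vapply(rem, `[`, numeric(1), 1))]
    pieces <- character(0)
    at <- 0L
    for (r in rem) {
      if (r[1] > at) pieces <- c(pieces, substr(seq, at + 1L, r[1]))
      at <- max(at, r[2])
    }
    if (at < L) pieces <- c(pieces, substr(seq, at + 1L, L))
    pieces <- pieces[nchar(pieces) >= min_out_len]
    if (length(pieces) == 0) {
      message("scaffold ", sid, " fully removed by corrections")
    } else if (length(pieces) == 1) {
      out[[sid]] <- pieces
    } else {
      for (k in seq_along(pieces)) {
        out[[paste0(sid, "_", k)]] <- pieces[k]
      }
    }
  }
  unlist(out)
}

#' N50 of a set of sequence lengths
#'
#' The largest length L such that sequences of length at least L together
#' cover at least half the total length.
#'
#' @param lengths positive integer vector of sequence lengths.
#' @return N50 in bp.
#' @export
n50 <- function(lengths) {
  if (length(lengths) == 0) stop("n50 of an empty assembly is undefined")
  stopifnot(all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  unname(s[which(cumsum(s) >= sum(s) / 2)[1]])
}

#' Assembly summary statistics
#'
#' @param seqs named character vector of sequences.
#' @return List with `n_scaffolds`, `total_len`, `n50`.
#' @export
assembly_stats <- function(seqs) {
  lens <- nchar(seqs)
  list(n_scaffolds = length(seqs), total_len = sum(lens),
       n50 = if (length(lens)) n50(lens) else 0L)
}

kind_class <- function(kind) {
  c(MISJOIN = "misjoin", INSERTION_MID = "insertion",
    INSERTION_END = "insertion", UNALIGNED_SCAFFOLD = "insertion",
    DELETION = "deletion", ERROR_MISJOIN = "misjoin",
    ERROR_INSERTION = "insertion", ERROR_DELETION = "deletion",
    misjoin = "misjoin", insertion = "insertion",
    deletion = "deletion")[kind]
}

#' Evaluate verdicts against a truth table
#'
#' A call matches a truth record when it lies on the same scaffold, has
#' the same kind class (misjoin vs insertion vs deletion), and its
#' breakpoint region overlaps the truth interval within `match_slop` bp.
#' Error truth records are matched against validated-error verdicts;
#' structural-variation truth records against CORRECT_SV verdicts. For
#' each class, precision = TP / (TP + FP) and the true positive rate
#' TPR = TP / (TP + FN) are reported.
#'
#' @param verdicts verdict data frame.
#' @param truth truth data frame with columns `scaffold_id`, `kind`
#'   (misjoin/insertion/deletion), `s_left`, `s_right`,
#'   `class` (error/sv).
#' @param match_slop breakpoint tolerance in bp (default 100).
#' @return Data frame with one row per class: `tp`, `fp`, `fn`,
#'   `precision`, `tpr`.
#' @export
evaluate_against_truth <- function(verdicts, truth, match_slop = 100L) {
  if (is.null(verdicts) || nrow(verdicts) == 0) verdicts <- empty_verdicts()
  eval_class <- function(cl) {
    tr <- truth[truth$class == cl, , drop = FALSE]
    if (cl == "error") {
      vv <- verdicts[grepl("^ERROR_", verdicts$label), , drop = FALSE]
    } else {
      vv <- verdicts[verdicts$label == "CORRECT_SV", , drop = FALSE]
    }
    v_class <- if (nrow(vv)) {
      if (cl == "error") unname(kind_class(vv$label))
      else unname(kind_class(vv$kind))
    } else character(0)
    matched_v <- rep(FALSE, nrow(vv))
    tp <- 0L
    for (i in seq_len(nrow(tr))) {
      cand <- which(!matched_v &
                      vv$scaffold_id == tr$scaffold_id[i] &
                      v_class == kind_class(tr$kind[i]) &
                      vv$M_L - match_slop < tr$s_right[i] &
                      vv$M_R + match_slop > tr$s_left[i])
      if (length(cand)) {
        matched_v[cand[1]] <- TRUE
        tp <- tp + 1L
      }
    }
    fp <- sum(!matched_v)
    fn <- nrow(tr) - tp
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
               tpr = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
               stringsAsFactors = FALSE)
  }
  do.call(rbind, lapply(intersect(c("error", "sv"), unique(truth$class)),
                        eval_class))
}

#' Summarize a validation run
#'
#' @param verdicts verdict data frame.
#' @param stats_before,stats_after assembly statistics lists from
#'   [assembly_stats()].
#' @return Long-format data frame of summary metrics (counts per label
#'   and per error kind, scaffold counts and N50 before/after).
#' @export
summarize_run <- function(verdicts, stats_before, stats_after) {
  lab <- table(factor(verdicts$label,
                      levels = c("ERROR_MISJOIN", "ERROR_INSERTION",
                                 "ERROR_DELETION", "CORRECT_SV", "WARNING",
                                 "GAP_REPORT")))
  data.frame(
    metric = c("n_differences", "n_errors",
               paste0("n_", tolower(names(lab))),
               "n_scaffolds_before", "n_scaffolds_after",
               "total_len_before", "total_len_after",
               "n50_before", "n50_after"),
    value = c(nrow(verdicts), sum(grepl("^ERROR_", verdicts$label)),
              as.integer(lab),
              stats_before$n_scaffolds, stats_after$n_scaffolds,
              stats_before$total_len, stats_after$total_len,
              stats_before$n50, stats_after$n50),
    stringsAsFactors = FALSE)
}
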