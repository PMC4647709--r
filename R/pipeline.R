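resolve_seqs <- function(x) {
  if (is.character(x) && length(x) == 1 && is.null(names(x)) &&
      file.exists(x)) {
    read_fasta(x)
  } else {
    x
  }
}

#' Run the full mis-assembly detection pipeline
#'
#' Chains scaffold-to-reference alignments into non-redundant chains,
#' classifies differences, validates each difference against paired-end
#' read evidence, distinguishes correct assemblies reflecting structural
#' variation, applies corrections (scaffold splits at validated
#' misjoins, end trims at validated end insertions), and reports
#' assembly statistics before and after. When a truth table is supplied
#' the calls are additionally evaluated (TP/FP/FN, precision, TPR).
#'
#' @param scaffolds named character vector of scaffold sequences, or a
#'   FASTA path.
#' @param reference named character vector of reference sequences, or a
#'   FASTA path; may be NULL when `segments` are supplied.
#' @param segments scaffold-to-reference alignment segments: a data
#'   frame in the internal convention (see
#'   [read_alignments_tabular()]), or a path to a blast6/PAF file, or
#'   NULL to align with the built-in anchor aligner.
#' @param reads paired-end read evidence: a read alignment data frame,
#'   a SAM/BAM path, or a list with elements `read1`/`read2` of named
#'   read sequences to be placed by the built-in read aligner.
#' @param insert_mu,insert_sd library insert-size mean/sd in bp; NULL to
#'   estimate from proper pairs.
#' @param truth optional truth table (see [evaluate_against_truth()]).
#' @param segments_dialect dialect when `segments` is a path.
#' @param cfg configuration list from [misasm_config()].
#' @return A `misasm_result` list: `chains`, `differences`, `verdicts`,
#'   `lib`, `corrected`, `stats_before`, `stats_after`, `summary`,
#'   `evaluation` (or NULL), `tracks` (bedGraph-ready evidence tracks).
#' @export
run_misasm <- function(scaffolds, reference = NULL, segments = NULL,
                       reads = NULL, insert_mu = NULL, insert_sd = NULL,
                       truth = NULL, segments_dialect = "blast6",
                       cfg = misasm_config()) {
  scaffolds <- resolve_seqs(scaffolds)
  if (!is.null(reference)) reference <- resolve_seqs(reference)
  if (is.null(segments)) {
    if (is.null(reference)) stop("supply either alignments or a reference")
    segments <- naive_align_long(scaffolds, reference, k = cfg$anchor_k)
  } else if (is.character(segments)) {
    segments <- read_alignments_tabular(segments, segments_dialect)
  }

  chains <- lapply(names(scaffolds), function(sid) {
    select_nonredundant(segments[segments$scaffold_id == sid, ,
                                 drop = FALSE],
                        nchar(scaffolds[[sid]]), cfg$max_adjacency)
  })
  names(chains) <- names(scaffolds)
  # carry scaffold ids for chains of scaffolds without any alignment
  for (sid in names(chains)) {
    if (is.na(chains[[sid]]$scaffold_id)) chains[[sid]]$scaffold_id <- sid
  }
  diffs <- do.call(rbind, lapply(chains, function(ch) {
    classify_differences(ch, scaffolds[[ch$scaffold_id]], cfg)
  }))
  if (is.null(diffs)) diffs <- empty_differences()
  rownames(diffs) <- NULL

  if (is.null(reads)) stop("paired-end read evidence is required")
  if (is.character(reads)) {
    reads <- load_read_alignments(reads)
  } else if (is.list(reads) && !is.data.frame(reads)) {
    reads <- naive_align_reads(reads$read1, reads$read2, scaffolds,
                               seed_k = cfg$read_seed_k,
                               max_mismatch = cfg$max_mismatch)
  }
  pairs <- make_pairs(reads)
  lib <- estimate_library(pairs, insert_mu, insert_sd,
                          min_pairs = cfg$min_lib_pairs)

  verdicts <- validate_differences(diffs, scaffolds, reads, pairs, lib, cfg)
  corrected <- apply_corrections(scaffolds, verdicts, cfg$min_out_len)
  stats_before <- assembly_stats(scaffolds)
  stats_after <- assembly_stats(corrected)
  evaluation <- if (!is.null(truth)) {
    evaluate_against_truth(verdicts, truth, cfg$match_slop)
  } else NULL

  tracks <- build_tracks(scaffolds, reads, pairs, lib, verdicts, cfg)

  structure(list(chains = chains, differences = diffs, verdicts = verdicts,
                 lib = lib, corrected = corrected,
                 stats_before = stats_before, stats_after = stats_after,
                 summary = summarize_run(verdicts, stats_before,
                                         stats_after),
                 evaluation = evaluation, tracks = tracks),
            class = "misasm_result")
}

# the five per-scaffold evidence tracks: coverage, disagreement mask,
# zero-coverage mask, and windowed multi-align / discordant ratios
build_tracks <- function(scaffolds, reads, pairs, lib, verdicts, cfg) {
  discordant <- classify_pairs(pairs, lib, cfg$sd_mult_discordant)
  events <- pair_events(pairs, discordant)
  cov <- list(); dis <- list(); zero <- list(); mult <- list(); disc <- list()
  for (sid in names(scaffolds)) {
    sreads <- reads[reads$scaffold_id == sid, , drop = FALSE]
    pu <- build_pileup(sreads, scaffolds[[sid]])
    L <- length(pu$depth)
    cov[[sid]] <- rle_to_bedgraph(pu$depth, sid)
    dmask <- integer(L)
    dpos <- call_disagreements(pu, cfg$majority_frac, cfg$min_depth)
    dmask[dpos + 1L] <- 1L
    dis[[sid]] <- rle_to_bedgraph(dmask, sid)
    zero[[sid]] <- rle_to_bedgraph(as.integer(pu$depth == 0L), sid)
    w <- cfg$window_disc
    starts <- seq.int(0L, max(0L, L - 1L), by = w)
    ev <- events[events$scaffold_id == sid, , drop = FALSE]
    mrat <- vapply(starts, function(a) {
      multi_align_ratio(sreads, c(a, min(a + w, L)))$ratio
    }, numeric(1))
    drat <- vapply(starts, function(a) {
      b <- min(a + w, L)
      sel <- ev$lo < b & ev$hi > a
      if (!any(sel)) 0 else mean(ev$discordant[sel])
    }, numeric(1))
    mult[[sid]] <- data.frame(chrom = sid, start = starts,
                              end = pmin(starts + w, L), value = mrat,
                              stringsAsFactors = FALSE)
    disc[[sid]] <- data.frame(chrom = sid, start = starts,
                              end = pmin(starts + w, L), value = drat,
                              stringsAsFactors = FALSE)
  }
  list(coverage = do.call(rbind, cov),
       disagreements = do.call(rbind, dis),
       zero_coverage = do.call(rbind, zero),
       multi_align_ratio = do.call(rbind, mult),
       discordant_ratio = do.call(rbind, disc))
}

#' @export
print.misasm_result <- function(x, ...) {
  v <- x$verdicts
  n_err <- sum(grepl("^ERROR_", v$label))
  cat("mis-assembly validation result\n")
  cat(sprintf("  differences: %d (errors %d, correct SV %d, warnings %d, gap reports %d)\n",
              nrow(v), n_err, sum(v$label == "CORRECT_SV"),
              sum(v$label == "WARNING"), sum(v$label == "GAP_REPORT")))
  cat(sprintf("  insert size: mu=%.1f sd=%.1f (%s)\n", x$lib$mu,
              x$lib$sigma, x$lib$source))
  cat(sprintf("  scaffolds: %d -> %d, N50 %d -> %d bp\n",
              x$stats_before$n_scaffolds, x$stats_after$n_scaffolds,
              x$stats_before$n50, x$stats_after$n50))
  if (!is.null(x$evaluation)) {
    e <- x$evaluation
    for (i in seq_len(nrow(e))) {
      cat(sprintf("  %s calls: TP=%d FP=%d FN=%d precision=%s TPR=%s\n",
                  e$class[i], e$tp[i], e$fp[i], e$fn[i],
                  format(e$precision[i], digits = 4),
                  format(e$tpr[i], digits = 4)))
    }
  }
  invisible(x)
}
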