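#' Read a FASTA file of DNA sequences
#'
#' Sequences are uppercased, U is converted to T, and any other character
#' outside A, C, G, T, N becomes N. Sequences are returned as a named
#' character vector, the in-memory representation used throughout the
#' package.
#'
#' @param path path to a FASTA file.
#' @return Named character vector of uppercase DNA sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) stop("FASTA file '", path, "' contains no records")
  ids <- sub("\\s.*$", "", names(set))
  if (any(ids == "")) stop("FASTA file '", path, "' has an empty record id")
  if (anyDuplicated(ids)) {
    stop("duplicate sequence id in '", path, "': ",
         ids[duplicated(ids)][1])
  }
  seqs <- toupper(as.character(set))
  seqs <- chartr("U", "T", seqs)
  seqs <- gsub("[^ACGTN]", "N", seqs)
  if (any(nchar(seqs) == 0)) stop("FASTA file '", path, "' has an empty sequence")
  names(seqs) <- ids
  seqs
}

#' Write sequences to a FASTA file
#'
#' @param seqs named character vector of DNA sequences.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

empty_segments <- function() {
  data.frame(scaffold_id = character(), ref_id = character(),
             s_start = integer(), s_end = integer(),
             r_start = integer(), r_end = integer(),
             strand = character(), score = numeric(),
             identity_pct = numeric(), n_mismatch = integer(),
             n_gap = integer(), stringsAsFactors = FALSE)
}

#' Read scaffold-to-reference alignments from a tabular file
#'
#' Supports BLAST tabular output format 6 (12 standard columns) and PAF.
#' Coordinates are normalized to the internal convention: 0-based,
#' half-open, on the forward strand of both sequences. blast6 rows whose
#' subject interval is reversed (sstart > send) become strand "-" with the
#' reference interval swapped and converted.
#'
#' @param path path to the alignment file.
#' @param dialect `"blast6"` or `"paf"`.
#' @return Data frame of alignment segments with columns `scaffold_id`,
#'   `ref_id`, `s_start`, `s_end`, `r_start`, `r_end`, `strand`, `score`,
#'   `identity_pct`, `n_mismatch`, `n_gap`.
#' @export
read_alignments_tabular <- function(path, dialect = c("blast6", "paf")) {
  dialect <- match.arg(dialect)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_segments())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  need <- if (dialect == "blast6") 12L else 12L
  rows <- lapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) < need) {
      stop("malformed ", dialect, " row at line ", i, " of '", path,
           "': expected >= ", need, " fields, got ", length(f))
    }
    if (dialect == "blast6") {
      num <- suppressWarnings(as.numeric(f[3:12]))
      if (anyNA(num)) stop("malformed blast6 row at line ", i, " of '", path,
                           "': non-numeric field")
      qs <- num[5]; qe <- num[6]; ss <- num[7]; se <- num[8]
      strand <- if (ss <= se) "+" else "-"
      data.frame(scaffold_id = f[1], ref_id = f[2],
                 s_start = as.integer(qs - 1), s_end = as.integer(qe),
                 r_start = as.integer(min(ss, se) - 1),
                 r_end = as.integer(max(ss, se)),
                 strand = strand, score = num[10],
                 identity_pct = num[1],
                 n_mismatch = as.integer(num[3]),
                 n_gap = as.integer(num[4]), stringsAsFactors = FALSE)
    } else {
      num <- suppressWarnings(as.numeric(f[c(2:4, 7:12)]))
      if (anyNA(num) || !(f[5] %in% c("+", "-"))) {
        stop("malformed PAF row at line ", i, " of '", path, "'")
      }
      alen <- num[8]
      data.frame(scaffold_id = f[1], ref_id = f[6],
                 s_start = as.integer(num[2]), s_end = as.integer(num[3]),
                 r_start = as.integer(num[5]), r_end = as.integer(num[6]),
                 strand = f[5], score = num[7],
                 identity_pct = if (alen > 0) 100 * num[7] / alen else 0,
                 n_mismatch = as.integer(alen - num[7]),
                 n_gap = 0L, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  bad <- out$s_start >= out$s_end | out$r_start >= out$r_end
  if (any(bad)) stop("malformed row at line ", which(bad)[1], " of '", path,
                     "': empty interval")
  out
}

#' Write alignment segments as BLAST tabular (outfmt 6)
#'
#' Inverse of [read_alignments_tabular()] for the blast6 dialect:
#' converting a segment to text and re-parsing yields the identical
#' segment.
#'
#' @param segments alignment segment data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_alignments_blast6 <- function(segments, path) {
  con <- file(path, "w")
  on.exit(close(con))
  if (nrow(segments)) {
    alen <- segments$s_end - segments$s_start
    ss <- ifelse(segments$strand == "+", segments$r_start + 1L, segments$r_end)
    se <- ifelse(segments$strand == "+", segments$r_end, segments$r_start + 1L)
    lines <- sprintf("%s\t%s\t%.2f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%g\t%g",
                     segments$scaffold_id, segments$ref_id,
                     segments$identity_pct, alen,
                     segments$n_mismatch, segments$n_gap,
                     segments$s_start + 1L, segments$s_end, ss, se,
                     0, segments$score)
    writeLines(lines, con)
  }
  invisible(path)
}

empty_read_alignments <- function() {
  data.frame(read_id = character(), mate = integer(),
             scaffold_id = character(), pos = integer(), end = integer(),
             strand = character(), is_multi = logical(), n_best = integer(),
             seq = character(), mate_scaffold = character(),
             mate_pos = integer(), mate_strand = character(),
             stringsAsFactors = FALSE)
}

# expand a SAM record to the bases it aligns to consecutive reference
# positions; soft clips and insertions are dropped, deletions/skips yield '-'
cigar_aligned_seq <- function(cigar, seq) {
  if (grepl("^[0-9]+M$", cigar)) return(seq)
  ops <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^[0-9]+", "", ops)
  out <- character(0)
  qi <- 1L
  for (i in seq_along(op)) {
    if (op[i] %in% c("M", "=", "X")) {
      out <- c(out, substr(seq, qi, qi + n[i] - 1L))
      qi <- qi + n[i]
    } else if (op[i] %in% c("I", "S")) {
      qi <- qi + n[i]
    } else if (op[i] %in% c("D", "N")) {
      out <- c(out, strrep("-", n[i]))
    }
  }
  paste(out, collapse = "")
}

#' Load paired-end read alignments from a SAM or BAM file
#'
#' Unmapped and supplementary records are dropped. A read is marked
#' `is_multi` when the file carries secondary alignments for it or an
#' `NH` tag of 2 or more. Mate fields are resolved from the pairing flags
#' when the mate is mapped. Positions are converted to the internal
#' 0-based half-open convention, and each record carries the read bases
#' aligned to consecutive reference positions (for pileup).
#'
#' @param path path to a coordinate-sortable SAM or BAM file.
#' @return Read alignment data frame (one row per mapped primary record).
#' @export
load_read_alignments <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- Rsamtools::asBam(path, destination = dest,
                            overwrite = TRUE, indexDestination = FALSE)
  } else {
    bam <- path
  }
  hdr <- Rsamtools::scanBamHeader(bam)[[1]]$targets
  if (is.null(hdr) || length(hdr) == 0) {
    stop("SAM/BAM file '", path, "' has no sequence dictionary in its header")
  }
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "rname", "pos", "cigar", "seq", "mrnm", "mpos"),
    tag = "NH")
  res <- Rsamtools::scanBam(bam, param = param)[[1]]
  flag <- res$flag
  mapped <- bitwAnd(flag, 4L) == 0L
  suppl <- bitwAnd(flag, 2048L) != 0L
  second <- bitwAnd(flag, 256L) != 0L
  mate_idx <- ifelse(bitwAnd(flag, 128L) != 0L, 2L, 1L)
  key <- paste(res$qname, mate_idx, sep = "/")
  multi_keys <- unique(key[mapped & second])
  keep <- mapped & !suppl & !second
  if (!any(keep)) return(empty_read_alignments())
  nh <- res$tag$NH
  if (is.null(nh)) nh <- rep(NA_integer_, length(flag))
  seqs <- as.character(res$seq)[keep]
  cig <- res$cigar[keep]
  aligned <- vapply(seq_along(cig), function(i) {
    cigar_aligned_seq(cig[i], seqs[i])
  }, character(1))
  pos <- res$pos[keep] - 1L
  out <- data.frame(
    read_id = res$qname[keep],
    mate = mate_idx[keep],
    scaffold_id = as.character(res$rname[keep]),
    pos = pos,
    end = pos + nchar(aligned),
    strand = ifelse(bitwAnd(flag[keep], 16L) != 0L, "-", "+"),
    is_multi = (key[keep] %in% multi_keys) |
      (!is.na(nh[keep]) & nh[keep] >= 2L),
    n_best = ifelse(is.na(nh[keep]), 1L, as.integer(nh[keep])),
    seq = aligned,
    stringsAsFactors = FALSE)
  mate_mapped <- bitwAnd(flag[keep], 8L) == 0L &
    bitwAnd(flag[keep], 1L) != 0L & !is.na(res$mpos[keep])
  out$mate_scaffold <- ifelse(mate_mapped, as.character(res$mrnm[keep]),
                              NA_character_)
  out$mate_pos <- ifelse(mate_mapped, res$mpos[keep] - 1L, NA_integer_)
  out$mate_strand <- ifelse(mate_mapped,
                            ifelse(bitwAnd(flag[keep], 32L) != 0L, "-", "+"),
                            NA_character_)
  out
}

#' Write read alignments as SAM
#'
#' Emits one primary record per alignment row with proper-pair flags
#' derived from FR geometry and an `NH` tag carrying the number of
#' equal-best placements, so multi-placement marks survive a round trip
#' through [load_read_alignments()].
#'
#' @param alignments read alignment data frame.
#' @param scaffolds named character vector of scaffold sequences (for the
#'   header sequence dictionary).
#' @param path output path (conventionally `.sam`).
#' @return `path`, invisibly.
#' @export
write_sam <- function(alignments, scaffolds, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("@HD\tVN:1.6\tSO:unsorted", con)
  writeLines(sprintf("@SQ\tSN:%s\tLN:%d", names(scaffolds),
                     nchar(scaffolds)), con)
  a <- alignments
  if (nrow(a)) {
    has_mate <- !is.na(a$mate_scaffold)
    flag <- 0L +
      ifelse(has_mate, 1L + 2L, 0L) +
      ifelse(a$strand == "-", 16L, 0L) +
      ifelse(has_mate & a$mate_strand == "-", 32L, 0L) +
      ifelse(a$mate == 1L, 64L, 128L)
    rnext <- ifelse(has_mate,
                    ifelse(a$mate_scaffold == a$scaffold_id, "=",
                           a$mate_scaffold), "*")
    pnext <- ifelse(has_mate, a$mate_pos + 1L, 0L)
    lines <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t%s\t%d\t%d\t%s\t*\tNH:i:%d",
                     a$read_id, flag, a$scaffold_id, a$pos + 1L,
                     ifelse(a$is_multi, 0L, 60L),
                     nchar(a$seq), rnext, pnext, 0L, a$seq,
                     if (is.null(a$n_best)) 1L else a$n_best)
    writeLines(lines, con)
  }
  invisible(path)
}

write_bedgraph <- function(df, path, name) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf('track type=bedGraph name="%s"', name), con)
  if (nrow(df)) {
    writeLines(sprintf("%s\t%d\t%d\t%g", df$chrom, df$start, df$end,
                       df$value), con)
  }
  invisible(path)
}

rle_to_bedgraph <- function(values, chrom) {
  r <- rle(values)
  ends <- cumsum(r$lengths)
  data.frame(chrom = chrom, start = c(0L, ends[-length(ends)]),
             end = ends, value = r$values, stringsAsFactors = FALSE)
}

#' Write all pipeline outputs to a directory
#'
#' Writes a per-difference TSV report, the corrected scaffolds as FASTA,
#' a run summary TSV, an evaluation TSV when a truth table was supplied,
#' and bedGraph evidence tracks (coverage, disagreement mask,
#' zero-coverage mask, and per-500-bp multi-align and discordant ratios).
#'
#' @param result a `misasm_result` from [run_misasm()].
#' @param out_dir output directory, created if needed.
#' @return Character vector of written paths, invisibly.
#' @export
write_outputs <- function(result, out_dir) {
  ok <- dir.exists(out_dir) || dir.create(out_dir, recursive = TRUE)
  if (!ok || file.access(out_dir, 2) != 0) {
    stop("cannot write to output directory '", out_dir, "'")
  }
  paths <- character(0)
  p <- file.path(out_dir, "report.tsv")
  write.table(result$verdicts, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(out_dir, "corrected.fasta")
  write_fasta(result$corrected, p)
  paths <- c(paths, p)
  p <- file.path(out_dir, "summary.tsv")
  write.table(result$summary, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(result$evaluation)) {
    p <- file.path(out_dir, "evaluation.tsv")
    write.table(result$evaluation, p, sep = "\t", quote = FALSE,
                row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(result$tracks)) {
    tdir <- file.path(out_dir, "tracks")
    dir.create(tdir, showWarnings = FALSE)
    tr <- result$tracks
    for (nm in names(tr)) {
      p <- file.path(tdir, paste0(nm, ".bedGraph"))
      write_bedgraph(tr[[nm]], p, nm)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
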