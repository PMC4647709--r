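BASES <- c("A", "C", "G", "T")

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_seq <- function(len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(BASES, len, replace = TRUE, prob = p), collapse = "")
}

#' Generate a random genome sequence
#'
#' Bases are drawn i.i.d. at the requested GC fraction. Fully
#' reproducible for a fixed seed.
#'
#' @param len genome length in bp (>= 1).
#' @param gc GC fraction (default 0.5).
#' @param seed optional integer seed; NULL uses the current RNG state.
#' @return Named character vector of length 1 (name `"genome"`).
#' @export
generate_genome <- function(len, gc = 0.5, seed = NULL) {
  if (len < 1) stop("genome length must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  c(genome = random_seq(len, gc))
}

# apply middle-of-scaffold edits (0-based positions on the source window)
# and translate marker points through the coordinate shifts.
# edits: data.frame(pos, kind in c("ins","del"), size, ins_seq)
# markers: data.frame(pos, width) in source coordinates
apply_edits <- function(seq, edits, markers = NULL) {
  if (is.null(edits) || nrow(edits) == 0) {
    return(list(seq = seq, edits = edits,
                marker_pos = if (is.null(markers)) integer(0)
                             else markers$pos))
  }
  edits <- edits[order(edits$pos), , drop = FALSE]
  pieces <- character(0)
  at <- 0L
  offset <- 0L
  final_left <- integer(nrow(edits))
  final_right <- integer(nrow(edits))
  for (i in seq_len(nrow(edits))) {
    p <- edits$pos[i]
    pieces <- c(pieces, substr(seq, at + 1L, p))
    if (edits$kind[i] == "ins") {
      pieces <- c(pieces, edits$ins_seq[i])
      final_left[i] <- p + offset
      final_right[i] <- p + offset + edits$size[i]
      offset <- offset + edits$size[i]
      at <- p
    } else {
      final_left[i] <- p + offset
      final_right[i] <- p + offset + 1L
      offset <- offset - edits$size[i]
      at <- p + edits$size[i]
    }
  }
  pieces <- c(pieces, substr(seq, at + 1L, nchar(seq)))
  edits$final_left <- final_left
  edits$final_right <- final_right
  marker_pos <- integer(0)
  if (!is.null(markers) && nrow(markers)) {
    marker_pos <- vapply(markers$pos, function(m) {
      sh <- 0L
      for (i in seq_len(nrow(edits))) {
        if (edits$pos[i] < m) {
          sh <- sh + if (edits$kind[i] == "ins") edits$size[i] else
            -edits$size[i]
        }
      }
      as.integer(m + sh)
    }, integer(1))
  }
  list(seq = paste(pieces, collapse = ""), edits = edits,
       marker_pos = marker_pos)
}

#' The six-modification structural-variation preset
#'
#' One duplication (1 kbp), one large relocation, two insertions (70 and
#' 30 bp) and two deletions (70 and 30 bp) applied to the reference,
#' which together produce eight expected differences against correctly
#' assembled scaffolds (the relocation contributes three junction
#' differences, each other modification one).
#'
#' @param relocation_len relocated segment size in bp (default 20000 at
#'   the 1-Mbp scale of the bundled scenarios).
#' @return Data frame of SV specs with columns `kind` and `size`.
#' @export
sv_preset_six <- function(relocation_len = 20000L) {
  data.frame(
    kind = c("duplication", "relocation", "insertion", "insertion",
             "deletion", "deletion"),
    size = c(1000L, as.integer(relocation_len), 70L, 30L, 70L, 30L),
    stringsAsFactors = FALSE)
}

#' Apply structural variations to a genome to build a mutated reference
#'
#' Duplications copy a segment adjacently; relocations move a segment to
#' a downstream position; insertions add random sequence; deletions
#' remove sequence. Positions are taken from the `pos` column (and `pos2`
#' for the relocation target) of `svs`, all 0-based genome coordinates;
#' intervals must not overlap.
#'
#' @param genome genome sequence (length-1 character).
#' @param svs data frame with columns `kind`
#'   (duplication/relocation/insertion/deletion), `size`, `pos`, and
#'   `pos2` (relocation insertion point, NA otherwise).
#' @return List with `reference` (named character, `"ref"`) and `truth`:
#'   the expected difference loci in target-genome coordinates, with the
#'   difference kind each SV induces in a correctly assembled scaffold
#'   (duplication and reference insertions appear as deletions, reference
#'   deletions as insertions, relocations as three misjoin junctions).
#' @export
inject_svs <- function(genome, svs) {
  g <- unname(genome[1])
  iv <- cbind(svs$pos, svs$pos + ifelse(svs$kind == "insertion", 1L,
                                        svs$size))
  ord <- order(iv[, 1])
  if (any(iv[ord[-1], 1] < iv[ord[-length(ord)], 2])) {
    stop("SV intervals overlap")
  }
  truth <- list()
  ops <- list()
  for (i in seq_len(nrow(svs))) {
    kind <- svs$kind[i]
    p <- svs$pos[i]
    s <- svs$size[i]
    if (kind == "duplication") {
      ops[[length(ops) + 1L]] <- list(pos = p + s, what = "ins",
                                      seq = substr(g, p + 1L, p + s))
      truth[[length(truth) + 1L]] <- data.frame(
        genome_left = p, genome_right = p + s, kind = "deletion",
        size = s, stringsAsFactors = FALSE)
    } else if (kind == "insertion") {
      ops[[length(ops) + 1L]] <- list(pos = p, what = "ins",
                                      seq = random_seq(s))
      truth[[length(truth) + 1L]] <- data.frame(
        genome_left = p, genome_right = p + 1L, kind = "deletion",
        size = s, stringsAsFactors = FALSE)
    } else if (kind == "deletion") {
      ops[[length(ops) + 1L]] <- list(pos = p, what = "del", size = s)
      truth[[length(truth) + 1L]] <- data.frame(
        genome_left = p, genome_right = p + s, kind = "insertion",
        size = s, stringsAsFactors = FALSE)
    } else if (kind == "relocation") {
      q <- svs$pos2[i]
      if (is.na(q) || q < p + s) stop("relocation target must follow the segment")
      seg <- substr(g, p + 1L, p + s)
      ops[[length(ops) + 1L]] <- list(pos = q, what = "ins", seq = seg)
      ops[[length(ops) + 1L]] <- list(pos = p, what = "del", size = s)
      truth[[length(truth) + 1L]] <- data.frame(
        genome_left = c(p, p + s, q), genome_right = c(p, p + s, q) + 1L,
        kind = "misjoin", size = 0L, stringsAsFactors = FALSE)
    } else {
      stop("unknown SV kind: ", kind)
    }
  }
  ops <- ops[order(-vapply(ops, `[[`, numeric(1), "pos"))]
  for (op in ops) {
    if (op$what == "ins") {
      g <- paste0(substr(g, 1L, op$pos), op$seq,
                  substr(g, op$pos + 1L, nchar(g)))
    } else {
      g <- paste0(substr(g, 1L, op$pos),
                  substr(g, op$pos + op$size + 1L, nchar(g)))
    }
  }
  list(reference = c(ref = g), truth = do.call(rbind, truth))
}

#' Simulate paired-end reads from a genome
#'
#' Fragments are placed uniformly with Gaussian insert sizes (rounded,
#' floored at the read length); mate 1 is the forward strand prefix and
#' mate 2 the reverse-complemented suffix of each fragment (inward FR
#' orientation). Base-call errors are symmetric substitutions at
#' `base_error` per base. Reads are drawn from the true target genome so
#' that scaffold errors show up as discordance and disagreements.
#'
#' @param genome genome sequence (length-1 character).
#' @param depth target sequencing depth; the pair count is
#'   `round(depth * L / (2 * read_len))`.
#' @param read_len read length in bp.
#' @param insert_mu,insert_sd insert-size (fragment length) mean and sd.
#' @param base_error per-base substitution probability.
#' @param seed optional integer seed.
#' @param n_pairs override for the pair count.
#' @return List with named character vectors `read1`, `read2` and the
#'   true `frag_start` (0-based) and `frag_len`.
#' @export
simulate_reads <- function(genome, depth = 50, read_len = 100L,
                           insert_mu = 368, insert_sd = 61,
                           base_error = 0.005, seed = NULL,
                           n_pairs = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- unname(genome[1])
  L <- nchar(g)
  if (insert_mu <= 2 * read_len) {
    warning("insert mean not larger than twice the read length; ",
            "mates will overlap heavily")
  }
  if (is.null(n_pairs)) n_pairs <- round(depth * L / (2 * read_len))
  if (n_pairs < 1) stop("simulation parameters yield zero read pairs")
  frag <- pmin(pmax(as.integer(round(rnorm(n_pairs, insert_mu,
                                           insert_sd))), read_len), L)
  start <- as.integer(floor(runif(n_pairs, 0, L - frag + 1)))
  r1 <- substring(g, start + 1L, start + read_len)
  r2 <- revcomp(substring(g, start + frag - read_len + 1L, start + frag))
  inject <- function(reads) {
    k <- rbinom(length(reads), read_len, base_error)
    total <- sum(k)
    if (total == 0) return(reads)
    idx <- rep(which(k > 0), k[k > 0])
    pos <- sample.int(read_len, total, replace = TRUE)
    cur <- substring(reads[idx], pos, pos)
    ci <- match(cur, BASES)
    ci[is.na(ci)] <- sample.int(4L, sum(is.na(ci)), replace = TRUE)
    new <- BASES[(ci - 1L + sample.int(3L, total, replace = TRUE)) %% 4L + 1L]
    cpp_inject_errors(reads, idx, pos, new)
  }
  ids <- sprintf("frag%07d", seq_len(n_pairs))
  list(read1 = setNames(inject(r1), ids),
       read2 = setNames(inject(r2), ids),
       frag_start = start, frag_len = frag)
}

#' Naive long-sequence aligner (exact k-mer anchor chaining)
#'
#' Exact-match k-mer anchors between each scaffold and each reference
#' sequence are merged into maximal collinear runs per diagonal and
#' strand; each run becomes an alignment segment scored by its length.
#' Designed for synthetic data, where sequences share exact k-mers
#' everywhere outside engineered difference loci, so segment breaks land
#' exactly at every difference of at least `indel_min` bp.
#'
#' @param scaffolds named character vector of scaffold sequences.
#' @param reference named character vector of reference sequences.
#' @param k anchor length (default 31).
#' @param min_seg minimum emitted segment length (default `3 * k`).
#' @param max_hits skip k-mers occurring more than this many times in
#'   the reference (default 8).
#' @return Alignment segment data frame in the internal 0-based
#'   half-open convention.
#' @export
naive_align_long <- function(scaffolds, reference, k = 31L,
                             min_seg = 3L * k, max_hits = 8L) {
  out <- list()
  for (si in seq_along(scaffolds)) {
    scaf <- unname(scaffolds[si])
    L <- nchar(scaf)
    rc <- revcomp(scaf)
    for (ri in seq_along(reference)) {
      ref <- unname(reference[ri])
      fwd <- cpp_anchor_runs(scaf, ref, k, k, min_seg, max_hits)
      if (nrow(fwd)) {
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = names(scaffolds)[si], ref_id = names(reference)[ri],
          s_start = fwd$q_start, s_end = fwd$q_end,
          r_start = fwd$r_start, r_end = fwd$r_end,
          strand = "+", score = as.numeric(fwd$q_end - fwd$q_start),
          identity_pct = 100, n_mismatch = 0L, n_gap = 0L,
          stringsAsFactors = FALSE)
      }
      rev <- cpp_anchor_runs(rc, ref, k, k, min_seg, max_hits)
      if (nrow(rev)) {
        out[[length(out) + 1L]] <- data.frame(
          scaffold_id = names(scaffolds)[si], ref_id = names(reference)[ri],
          s_start = L - rev$q_end, s_end = L - rev$q_start,
          r_start = rev$r_start, r_end = rev$r_end,
          strand = "-", score = as.numeric(rev$q_end - rev$q_start),
          identity_pct = 100, n_mismatch = 0L, n_gap = 0L,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(empty_segments())
  do.call(rbind, out)
}

#' Naive short-read aligner (seed and extend, mismatch-bounded)
#'
#' Seeds of length `seed_k` at three offsets propose candidate
#' placements on both strands; candidates are verified by full-length
#' comparison and placements with at most `max_mismatch` mismatches
#' kept. Among equal-best placements one is selected uniformly at random
#' (seeded through the R RNG) so that repeat regions keep read coverage,
#' and such reads are marked as multi-placed. Reads without a valid
#' placement are dropped.
#'
#' @param reads1,reads2 named character vectors of mate sequences (names
#'   are read ids; `reads2` may be NULL for single-end input).
#' @param scaffolds named character vector of scaffold sequences.
#' @param seed_k seed length (default 20).
#' @param max_mismatch mismatch cap (default 3).
#' @return Read alignment data frame with mate fields resolved.
#' @export
naive_align_reads <- function(reads1, reads2 = NULL, scaffolds,
                              seed_k = 20L, max_mismatch = 3L) {
  all_reads <- c(reads1, reads2)
  mate_of <- rep(c(1L, 2L), c(length(reads1), length(reads2)))
  ids <- c(names(reads1), names(reads2))
  rl <- as.integer(median(nchar(all_reads)))
  offsets <- unique(pmax(0L, c(0L, (rl - seed_k) %/% 2L, rl - seed_k)))
  res <- cpp_align_reads(unname(all_reads), unname(scaffolds), seed_k,
                         offsets, max_mismatch)
  if (!length(res$read)) return(empty_read_alignments())
  seqs <- unname(all_reads[res$read])
  minus <- res$strand < 0
  if (any(minus)) seqs[minus] <- revcomp(seqs[minus])
  out <- data.frame(
    read_id = ids[res$read], mate = mate_of[res$read],
    scaffold_id = names(scaffolds)[res$scaffold],
    pos = res$pos, end = res$pos + nchar(seqs),
    strand = ifelse(minus, "-", "+"),
    is_multi = res$n_best >= 2L, n_best = res$n_best,
    seq = seqs, stringsAsFactors = FALSE)
  # resolve mate fields
  key <- paste(out$read_id, 3L - out$mate)
  i <- match(paste(out$read_id, out$mate), paste(out$read_id, out$mate))
  j <- match(key, paste(out$read_id, out$mate))
  out$mate_scaffold <- ifelse(is.na(j), NA_character_, out$scaffold_id[j])
  out$mate_pos <- ifelse(is.na(j), NA_integer_, out$pos[j])
  out$mate_strand <- ifelse(is.na(j), NA_character_, out$strand[j])
  out
}

#' Inject assembly errors into scaffolds drawn from a genome
#'
#' Lays the genome out into scaffold source windows and injects the
#' requested errors. Misjoins are built the way real ones arise: a
#' repeat of `repeat_len` bp is planted at two distant genome loci and
#' the mis-joined scaffold concatenates the sequence up to the end of
#' the first copy with the sequence after the second copy, so the two
#' flanking alignment segments overlap by the repeat and multi-placed
#' reads genuinely accumulate at the junction (the intervening sequence,
#' ending in the second repeat copy, becomes a separate companion
#' scaffold). Middle insertions add random sequence, deletions remove
#' genome sequence, end insertions append random sequence to a scaffold
#' 3' end.
#'
#' Because the genome is modified (planted repeats), the returned genome
#' must be used for read simulation.
#'
#' @param genome genome sequence (length-1 named character).
#' @param errors data frame with columns `kind`
#'   (misjoin/insertion_mid/insertion_end/deletion) and `size` (ignored
#'   for misjoins).
#' @param repeat_len misjoin repeat length (default 500).
#' @param reserve optional data frame of genome intervals
#'   (`start`,`end`) that error edits must avoid (e.g. SV loci).
#' @return List with `genome` (with planted repeats), `scaffolds`,
#'   `truth` (error records in final scaffold coordinates), and
#'   `layout` (scaffold source windows in genome coordinates).
#' @export
inject_assembly_errors <- function(genome, errors, repeat_len = 500L,
                                   reserve = NULL) {
  g <- unname(genome[1])
  L <- nchar(g)
  n_mj <- sum(errors$kind == "misjoin")
  mids <- errors[errors$kind == "insertion_mid", , drop = FALSE]
  ends <- errors[errors$kind == "insertion_end", , drop = FALSE]
  dels <- errors[errors$kind == "deletion", , drop = FALSE]

  mb <- 95000L
  if (L - n_mj * mb < 100000L) {
    stop("genome too short for this error layout")
  }
  normal_base <- n_mj * mb
  n_normal <- max(4L, (L - normal_base) %/% 102000L)
  norm_len <- (L - normal_base) %/% n_normal

  truth <- list()
  scaffolds <- list()
  layout <- list()

  # misjoin blocks: A(40 kbp) R M(29.5 kbp) R D(24.5 kbp)
  for (i in seq_len(n_mj)) {
    p <- (i - 1L) * mb
    rep_seq <- random_seq(repeat_len)
    substr(g, p + 40001L, p + 40000L + repeat_len) <- rep_seq
    substr(g, p + 70001L, p + 70000L + repeat_len) <- rep_seq
    mj <- paste0(substr(g, p + 1L, p + 40000L + repeat_len),
                 substr(g, p + 70001L + repeat_len, p + mb))
    cp <- substr(g, p + 40001L + repeat_len, p + 70000L + repeat_len)
    mj_id <- sprintf("mis%02d", i)
    cp_id <- sprintf("cmp%02d", i)
    scaffolds[[mj_id]] <- mj
    scaffolds[[cp_id]] <- cp
    layout[[mj_id]] <- data.frame(start = c(p, p + 70000L + repeat_len),
                                  end = c(p + 40000L + repeat_len, p + mb))
    layout[[cp_id]] <- data.frame(start = p + 40000L + repeat_len,
                                  end = p + 70000L + repeat_len)
    truth[[length(truth) + 1L]] <- data.frame(
      scaffold_id = mj_id, kind = "misjoin", s_left = 40000L,
      s_right = 40000L + repeat_len, size = 0L, class = "error",
      stringsAsFactors = FALSE)
  }

  # normal windows with indel edits
  win_start <- normal_base + (seq_len(n_normal) - 1L) * norm_len
  win_end <- win_start + norm_len
  margin <- 8000L
  spacing <- 6000L
  reserved_ok <- function(gpos) {
    is.null(reserve) || !any(reserve$start - 3000L < gpos &
                               reserve$end + 3000L > gpos)
  }
  # candidate slots ordered so consecutive edits land on different windows
  slots <- list()
  for (off in seq(margin, norm_len - margin, by = spacing)) {
    for (w in seq_len(n_normal)[-1]) {   # window 1 kept edit-free
      gpos <- win_start[w] + off
      if (reserved_ok(gpos)) {
        slots[[length(slots) + 1L]] <- c(w, off)
      }
    }
  }
  need <- nrow(mids) + nrow(dels)
  if (need > length(slots)) stop("not enough room to place all errors")
  kinds <- c(rep("ins", nrow(mids)), rep("del", nrow(dels)))
  sizes <- c(mids$size, dels$size)
  edit_tab <- do.call(rbind, lapply(seq_len(need), function(e) {
    data.frame(w = slots[[e]][1], pos = slots[[e]][2], kind = kinds[e],
               size = sizes[e], stringsAsFactors = FALSE)
  }))
  end_ws <- if (nrow(ends)) {
    (seq_len(nrow(ends)) - 1L) %% (n_normal - 1L) + 2L
  } else integer(0)

  for (w in seq_len(n_normal)) {
    sid <- sprintf("scf%02d", w)
    seq_w <- substr(g, win_start[w] + 1L, win_end[w])
    ed <- if (is.null(edit_tab)) NULL else
      edit_tab[edit_tab$w == w, , drop = FALSE]
    if (!is.null(ed) && nrow(ed)) {
      ed$ins_seq <- ifelse(ed$kind == "ins",
                           vapply(ed$size, random_seq, character(1)), "")
      res <- apply_edits(seq_w, ed)
      seq_w <- res$seq
      for (i in seq_len(nrow(res$edits))) {
        truth[[length(truth) + 1L]] <- data.frame(
          scaffold_id = sid,
          kind = if (res$edits$kind[i] == "ins") "insertion" else "deletion",
          s_left = res$edits$final_left[i],
          s_right = res$edits$final_right[i],
          size = res$edits$size[i], class = "error",
          stringsAsFactors = FALSE)
      }
    }
    ei <- which(end_ws == w)
    for (e in ei) {
      sz <- ends$size[e]
      truth[[length(truth) + 1L]] <- data.frame(
        scaffold_id = sid, kind = "insertion", s_left = nchar(seq_w),
        s_right = nchar(seq_w) + sz, size = sz, class = "error",
        stringsAsFactors = FALSE)
      seq_w <- paste0(seq_w, random_seq(sz))
    }
    scaffolds[[sid]] <- seq_w
    layout[[sid]] <- data.frame(start = win_start[w], end = win_end[w])
  }
  list(genome = c(genome = g),
       scaffolds = unlist(scaffolds),
       truth = if (length(truth)) do.call(rbind, truth) else NULL,
       layout = layout,
       normal_windows = data.frame(start = win_start, end = win_end),
       edit_tab = edit_tab)
}

#' Build a complete synthetic evaluation scenario
#'
#' Generates a random genome, scaffolds carrying the requested injected
#' assembly errors, a reference mutated with the requested structural
#' variations, paired-end reads drawn from the true genome, and a truth
#' table covering both error loci (class `"error"`) and expected
#' SV-induced difference loci (class `"sv"`), all in final scaffold
#' coordinates. The defaults reproduce the scaled-down evaluation
#' design: a 1-Mbp genome, 27 errors (3 misjoins, 16 middle + 4 end
#' insertions, 4 deletions), the six-modification SV preset with the
#' relocation scaled to 20 kbp, and 50x paired-end reads with insert
#' mean 368 bp and sd 61 bp.
#'
#' @param seed integer seed (fixes every random choice).
#' @param genome_len genome length in bp.
#' @param n_misjoin,n_ins_mid,n_ins_end,n_del injected error counts.
#' @param ins_mid_range,ins_end_range,del_range size ranges (bp) from
#'   which error sizes are drawn uniformly.
#' @param svs SV spec data frame (kind, size) or NULL for none.
#' @param repeat_len misjoin repeat length (default 500).
#' @param depth,read_len,insert_mu,insert_sd,base_error read-simulation
#'   parameters.
#' @param reads logical; simulate reads (default TRUE)?
#' @return List with `genome`, `scaffolds`, `reference`, `truth`,
#'   `read1`, `read2`, and the library parameters used.
#' @export
simulate_scenario <- function(seed = NULL, genome_len = 1000000L,
                              n_misjoin = 3L, n_ins_mid = 16L,
                              n_ins_end = 4L, n_del = 4L,
                              ins_mid_range = c(250L, 450L),
                              ins_end_range = c(200L, 500L),
                              del_range = c(110L, 180L),
                              svs = sv_preset_six(),
                              repeat_len = 500L, depth = 50,
                              read_len = 100L, insert_mu = 368,
                              insert_sd = 61, base_error = 0.005,
                              reads = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  genome <- generate_genome(genome_len)

  draw <- function(n, range) {
    if (n == 0) integer(0) else
      as.integer(sample(seq(range[1], range[2]), n, replace = TRUE))
  }
  errors <- data.frame(
    kind = c(rep("misjoin", n_misjoin), rep("insertion_mid", n_ins_mid),
             rep("insertion_end", n_ins_end), rep("deletion", n_del)),
    size = c(rep(0L, n_misjoin), draw(n_ins_mid, ins_mid_range),
             draw(n_ins_end, ins_end_range), draw(n_del, del_range)),
    stringsAsFactors = FALSE)

  # SV genome positions: relocation in normal window 1, others on later
  # windows at fixed offsets; computed with the same layout arithmetic
  # used by inject_assembly_errors
  mb <- 95000L
  normal_base <- n_misjoin * mb
  n_normal <- max(4L, (genome_len - normal_base) %/% 102000L)
  norm_len <- (genome_len - normal_base) %/% n_normal
  sv_tab <- NULL
  reserve <- NULL
  if (!is.null(svs) && nrow(svs)) {
    sv_tab <- svs
    sv_tab$pos <- NA_integer_
    sv_tab$pos2 <- NA_integer_
    slot_w <- 2L
    slot_off <- 20000L
    for (i in seq_len(nrow(sv_tab))) {
      if (sv_tab$kind[i] == "relocation") {
        if (norm_len < sv_tab$size[i] + 48000L) {
          stop("normal windows too short for the relocation")
        }
        sv_tab$pos[i] <- normal_base + 10000L
        sv_tab$pos2[i] <- normal_base + 10000L + sv_tab$size[i] + 30000L
      } else {
        if (slot_w > n_normal) stop("not enough windows for the SV specs")
        sv_tab$pos[i] <- normal_base + (slot_w - 1L) * norm_len + slot_off
        slot_off <- slot_off + 30000L
        if (slot_off > norm_len - 10000L) {
          slot_off <- 20000L
          slot_w <- slot_w + 1L
        }
      }
    }
    reserve <- data.frame(
      start = sv_tab$pos,
      end = ifelse(sv_tab$kind == "relocation", sv_tab$pos2 + 1L,
                   sv_tab$pos + pmax(sv_tab$size, 1L)))
  }

  inj <- inject_assembly_errors(genome, errors, repeat_len = repeat_len,
                                reserve = reserve)
  truth <- inj$truth

  if (!is.null(sv_tab)) {
    sv_res <- inject_svs(inj$genome, sv_tab)
    reference <- sv_res$reference
    # translate SV truth loci from genome to final scaffold coordinates
    wins <- inj$normal_windows
    for (i in seq_len(nrow(sv_res$truth))) {
      gl <- sv_res$truth$genome_left[i]
      gr <- sv_res$truth$genome_right[i]
      w <- which(wins$start <= gl & gl < wins$end)
      sid <- sprintf("scf%02d", w)
      rel <- c(gl, gr) - wins$start[w]
      ed <- inj$edit_tab
      sh <- 0L
      if (!is.null(ed)) {
        ed <- ed[ed$w == w & ed$pos < rel[1], , drop = FALSE]
        if (nrow(ed)) {
          sh <- sum(ifelse(ed$kind == "ins", ed$size, -ed$size))
        }
      }
      truth <- rbind(truth, data.frame(
        scaffold_id = sid, kind = sv_res$truth$kind[i],
        s_left = rel[1] + sh, s_right = rel[2] + sh,
        size = sv_res$truth$size[i], class = "sv",
        stringsAsFactors = FALSE))
    }
  } else {
    reference <- c(ref = unname(inj$genome[1]))
  }

  rd <- if (reads) {
    simulate_reads(inj$genome, depth = depth, read_len = read_len,
                   insert_mu = insert_mu, insert_sd = insert_sd,
                   base_error = base_error)
  } else NULL
  list(genome = inj$genome, scaffolds = inj$scaffolds,
       reference = reference, truth = truth,
       read1 = rd$read1, read2 = rd$read2,
       insert_mu = insert_mu, insert_sd = insert_sd,
       read_len = read_len)
}
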