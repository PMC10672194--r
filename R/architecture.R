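# Gene-junction analysis (overlaps, abutments, unassigned regions), control
# region identification with repeat content, and a heuristic tRNA cloverleaf
# consistency check. The cloverleaf checker is a pairing heuristic, not a
# thermodynamic folding algorithm.

#' Junction table of a mitogenome
#'
#' Consecutive features in genomic order are compared; each junction is an
#' overlap (negative gap), an abutment (zero gap) or an unassigned region
#' (UR; positive gap). On complete circular genomes the wrap between the last
#' and first feature is included. Overlap/UR sequences are reported on the
#' J strand.
#'
#' @param genome A [mitogenome()].
#' @return data.frame: upstream, downstream, relation, length, sequence.
#' @export
junction_table <- function(genome) {
  fts <- genome$features
  if (nrow(fts) < 2) stop("need at least two features", call. = FALSE)
  n <- genome_length(genome)
  # containment of one feature inside another of the same kind is an
  # annotation error, not a junction
  for (i in seq_len(nrow(fts) - 1)) {
    for (j in seq(i + 1, nrow(fts))) {
      if (fts$kind[i] == fts$kind[j] &&
          fts$start[j] >= fts$start[i] && fts$end[j] <= fts$end[i]) {
        stop(sprintf("annotation error: %s fully contains %s",
                     fts$name[i], fts$name[j]), call. = FALSE)
      }
    }
  }
  rows <- list()
  npairs <- if (genome$circular && genome$complete) nrow(fts) else nrow(fts) - 1L
  for (k in seq_len(npairs)) {
    i <- k
    j <- if (k == nrow(fts)) 1L else k + 1L
    up_end <- fts$end[i]
    down_start <- if (j == 1L) fts$start[j] + n else fts$start[j]
    gap <- down_start - up_end
    if (gap > 0) {
      relation <- "UR"
      seq <- slice_seq(genome$sequence, up_end %% n,
                       (up_end %% n) + gap, circular = genome$circular)
      len <- gap
    } else if (gap == 0) {
      relation <- "abut"; seq <- ""; len <- 0L
    } else {
      relation <- "overlap"
      len <- -gap
      seq <- slice_seq(genome$sequence, down_start %% n,
                       (down_start %% n) + len, circular = genome$circular)
    }
    rows[[k]] <- data.frame(upstream = fts$name[i], downstream = fts$name[j],
                            relation = relation, length = as.integer(len),
                            sequence = seq, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

# smallest-period check: motif is primitive if no proper divisor period repeats
is_primitive_motif <- function(motif) {
  m <- nchar(motif)
  if (m == 1) return(TRUE)
  for (p in seq_len(m - 1)) {
    if (m %% p == 0) {
      unit <- substr(motif, 1, p)
      if (paste(rep(unit, m / p), collapse = "") == motif) return(FALSE)
    }
  }
  TRUE
}

canonical_rotation <- function(motif) {
  m <- nchar(motif)
  if (m == 1) return(motif)
  rots <- vapply(seq_len(m), function(i) {
    paste0(substr(motif, i, m), substr(motif, 1, i - 1))
  }, "")
  min(rots)
}

#' Find perfect microsatellite-like tandem repeats
#'
#' Maximal perfect tandem runs of primitive motifs of 1-6 bp with total run
#' length >= `min_length` and at least two full copies. Runs are truncated to
#' whole copies; the motif is reported in canonical rotation
#' (lexicographically smallest rotation of the earliest phase). Nested
#' reports are suppressed by the primitive-motif rule: an (AT)n run is never
#' also reported as (ATAT)n/2.
#'
#' @param seq DNA string.
#' @param min_motif,max_motif Motif length bounds (bp).
#' @param min_length Minimum total run length (bp).
#' @return data.frame: kind, motif, start, end (0-based half-open), copies,
#'   identity.
#' @export
find_microsatellites <- function(seq, min_motif = 1, max_motif = 6, min_length = 10) {
  seq <- toupper(seq)
  chars <- s2c(seq)
  L <- length(chars)
  hits <- list()
  for (m in seq(min_motif, max_motif)) {
    if (L < 2 * m) next
    match_vec <- chars[seq_len(L - m)] == chars[seq(m + 1, L)]
    r <- rle(match_vec)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      run_len <- r$lengths[k] + m        # total periodic span
      start0 <- starts[k] - 1L           # 0-based
      copies <- run_len %/% m
      span <- copies * m
      if (span < min_length || copies < 2) next
      motif <- substr(seq, start0 + 1L, start0 + m)
      if (!is_primitive_motif(motif)) next
      hits[[length(hits) + 1L]] <- data.frame(
        kind = "microsatellite", motif = canonical_rotation(motif),
        start = start0, end = start0 + span, copies = as.integer(copies),
        identity = 1, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(kind = character(0), motif = character(0),
                      start = integer(0), end = integer(0),
                      copies = integer(0), identity = numeric(0)))
  }
  out <- do.call(rbind, hits)
  # drop hits fully contained in a longer hit (e.g. a homopolymer stretch
  # inside a longer dinucleotide run)
  keep <- rep(TRUE, nrow(out))
  ord <- order(out$end - out$start, decreasing = TRUE)
  for (i in seq_along(ord)) {
    a <- ord[i]
    if (!keep[a]) next
    inside <- out$start >= out$start[a] & out$end <= out$end[a]
    inside[a] <- FALSE
    keep[inside & (out$end - out$start) < (out$end[a] - out$start[a])] <- FALSE
  }
  out <- out[keep, , drop = FALSE]
  out[order(out$start, out$end), , drop = FALSE]
}

#' Find long direct (same-strand) repeats
#'
#' Exact 15-mer seeds are chained by diagonal (offset) and extended without
#' gaps while the running identity stays at or above `min_identity`;
#' candidate copy pairs shorter than `min_copy_len` are dropped and the
#' survivors are selected greedily by descending copy length, without overlap.
#' Only direct repeats are reported (inverted repeats are out of scope).
#'
#' @param seq DNA string of length >= 2 * `min_copy_len`.
#' @param min_copy_len Minimum length of one copy (bp).
#' @param min_identity Minimum fraction of matching positions.
#' @param k Seed length.
#' @return data.frame: kind, copy_length, start, end (span from the start of
#'   the first copy to the end of the second), copies, identity.
#' @export
find_long_repeats <- function(seq, min_copy_len = 200, min_identity = 0.9, k = 15) {
  seq <- toupper(seq)
  L <- nchar(seq)
  empty <- data.frame(kind = character(0), copy_length = integer(0),
                      start = integer(0), end = integer(0),
                      copies = integer(0), identity = numeric(0))
  if (L < 2 * min_copy_len) return(empty)
  chars <- s2c(seq)
  kmers <- substring(seq, seq_len(L - k + 1L), seq(k, L))
  occ <- split(seq_along(kmers), kmers)
  occ <- occ[lengths(occ) > 1]
  offsets <- unique(unlist(lapply(occ, function(pos) {
    if (length(pos) > 8) pos <- pos[seq_len(8)]  # cap degenerate seeds
    d <- as.vector(outer(pos, pos, "-"))
    d[d >= min_copy_len]
  })))
  cand <- list()
  for (d in offsets) {
    nn <- L - d
    if (nn < min_copy_len) next
    mv <- chars[seq_len(nn)] == chars[seq(d + 1L, L)]
    # start from the longest exact run on this diagonal and extend with
    # X-drop scoring (+1 match, -4 mismatch, drop-off 12), so extension stops
    # at the repeat boundary instead of diluting identity into background
    r <- rle(mv)
    if (!any(r$values)) next
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    runs <- which(r$values)
    best <- runs[which.max(r$lengths[runs])]
    lo <- starts[best]; hi <- ends[best]
    xdrop_extend <- function(from, step) {
      s <- 0; best_s <- 0; best_pos <- from
      t <- from + step
      while (t >= 1L && t <= nn) {
        s <- s + if (mv[t]) 1 else -4
        if (s > best_s) { best_s <- s; best_pos <- t }
        if (s < best_s - 12) break
        t <- t + step
      }
      best_pos
    }
    hi <- xdrop_extend(hi, 1L)
    lo <- xdrop_extend(lo, -1L)
    # copies must not overlap: copy length cannot exceed the offset
    len <- min(hi - lo + 1L, d)
    hi <- lo + len - 1L
    # trim mismatched ends left by the cap
    while (hi > lo && !mv[hi]) hi <- hi - 1L
    while (lo < hi && !mv[lo]) lo <- lo + 1L
    len <- hi - lo + 1L
    ident <- sum(mv[lo:hi]) / len
    if (len >= min_copy_len && ident >= min_identity) {
      cand[[length(cand) + 1L]] <- data.frame(
        kind = "longRepeat", copy_length = as.integer(len),
        start = lo - 1L, end = lo - 1L + d + len, copies = 2L,
        identity = ident, stringsAsFactors = FALSE)
    }
  }
  if (length(cand) == 0) return(empty)
  out <- do.call(rbind, cand)
  out <- out[order(-out$copy_length), , drop = FALSE]
  chosen <- list()
  taken <- rep(FALSE, L)
  for (i in seq_len(nrow(out))) {
    span <- seq(out$start[i] + 1L, out$end[i])
    if (any(taken[span])) next
    taken[span] <- TRUE
    chosen[[length(chosen) + 1L]] <- out[i, ]
  }
  out <- do.call(rbind, chosen)
  rownames(out) <- NULL
  out
}

find_t_runs <- function(seq, min_len = 8) {
  r <- rle(s2c(toupper(seq)) == "T")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  idx <- which(r$values & r$lengths >= min_len)
  data.frame(start = starts[idx] - 1L, length = r$lengths[idx])
}

#' Control region report
#'
#' Locates the control region (the annotated `control_region` feature, else
#' the longest unassigned region) and characterizes it: A+T content,
#' microsatellites, long repeats, and T-runs (>= 8 nt). The four
#' identification criteria are emitted as booleans: longest UR status,
#' T-rich runs present, A+T above the whole-genome value, and repetitive
#' elements present.
#'
#' @param genome A [mitogenome()].
#' @param microsat_min_len Minimum microsatellite run length (bp).
#' @param long_repeat_min_len Minimum long-repeat copy length (bp).
#' @return A `control_region_report` list.
#' @export
control_region_report <- function(genome, microsat_min_len = 10,
                                  long_repeat_min_len = 200) {
  fts <- genome$features
  jt <- tryCatch(junction_table(genome), error = function(e) NULL)
  urs <- if (!is.null(jt)) jt[jt$relation == "UR", , drop = FALSE] else NULL
  if ("control_region" %in% fts$name) {
    f <- get_feature(genome, "control_region")
    cr_seq <- extract_gene_sequence(genome, f)
    location <- sprintf("annotated [%d,%d)", f$start, f$end)
    is_longest_ur <- is.null(urs) || nrow(urs) == 0 ||
      nchar(cr_seq) > max(urs$length)
  } else {
    if (is.null(urs) || nrow(urs) == 0) {
      stop("control region unresolved: no annotation and no UR", call. = FALSE)
    }
    best <- which.max(urs$length)
    cr_seq <- urs$sequence[best]
    location <- sprintf("longest UR between %s and %s",
                        urs$upstream[best], urs$downstream[best])
    is_longest_ur <- TRUE
  }
  len <- nchar(cr_seq)
  warn <- character(0)
  if (len < 200) warn <- c(warn, "short CR candidate")
  cr_at <- skew(base_composition(cr_seq, "control region"))$at_content
  genome_at <- skew(base_composition(genome$sequence, "whole genome"))$at_content
  ms <- find_microsatellites(cr_seq, min_length = microsat_min_len)
  lr <- if (len >= 2 * long_repeat_min_len) {
    find_long_repeats(cr_seq, min_copy_len = long_repeat_min_len)
  } else {
    find_long_repeats("A", min_copy_len = 1)[0, ]
  }
  tr <- find_t_runs(cr_seq)
  structure(list(
    genome = genome$id, location = location, length = len,
    at_content = cr_at, genome_at_content = genome_at,
    microsatellites = ms, long_repeats = lr, t_rich_runs = tr,
    criteria = c(unassigned_region = is_longest_ur,
                 t_rich_runs = nrow(tr) > 0,
                 high_at = !is.na(cr_at) && cr_at > genome_at,
                 repeats = nrow(ms) > 0 || nrow(lr) > 0),
    warnings = warn), class = "control_region_report")
}

#' @export
print.control_region_report <- function(x, ...) {
  cat(sprintf("<control region: %s> %s, %d bp, AT %.2f%% (genome %.2f%%)\n",
              x$genome, x$location, x$length, x$at_content, x$genome_at_content))
  cat(sprintf("  microsatellites: %d, long repeats: %d, T-runs: %d\n",
              nrow(x$microsatellites), nrow(x$long_repeats), nrow(x$t_rich_runs)))
  cat("  criteria:", paste(sprintf("%s=%s", names(x$criteria), x$criteria),
                           collapse = ", "), "\n")
  if (length(x$warnings)) cat("  warnings:", paste(x$warnings, collapse = "; "), "\n")
  invisible(x)
}

# ---- cloverleaf heuristic ---------------------------------------------------

can_pair <- function(x, y) {
  (x == "A" & y == "T") | (x == "T" & y == "A") |
    (x == "G" & y == "C") | (x == "C" & y == "G") |
    (x == "G" & y == "T") | (x == "T" & y == "G")
}

# count pairs between stem halves s5 and s3 (s3 given 5'->3'; pairing is
# antiparallel, so s5[i] pairs s3[len - i + 1])
stem_pairs <- function(chars, i5, i3, len) {
  x <- chars[seq(i5, i5 + len - 1L)]
  y <- chars[seq(i3 + len - 1L, i3)]
  sum(can_pair(x, y))
}

# search a region for a stem-loop; returns best candidate or NULL
find_stem_loop <- function(chars, from, to, stem_lens, loop_lens, max_mismatch) {
  best <- NULL
  for (sl in stem_lens) {
    for (ll in loop_lens) {
      total <- 2L * sl + ll
      if (to - from + 1L < total) next
      for (p in seq(from, to - total + 1L)) {
        pr <- stem_pairs(chars, p, p + sl + ll, sl)
        mm <- sl - pr
        if (mm <= max_mismatch) {
          cand <- list(start = p, stem_len = sl, loop_len = ll,
                       pairs = pr, mismatches = mm,
                       loop_start = p + sl)
          if (is.null(best) || cand$mismatches < best$mismatches ||
              (cand$mismatches == best$mismatches && cand$pairs > best$pairs)) {
            best <- cand
          }
        }
      }
    }
  }
  best
}

#' Heuristic tRNA cloverleaf consistency check
#'
#' Searches a tRNA gene sequence for the four canonical arms using
#' Watson-Crick plus G-U wobble pairing: a 7-bp acceptor stem between the 5'
#' and 3' ends (<= 1 mismatch), an anticodon arm (5-bp stem, 7-nt loop whose
#' central triplet must equal the anticodon for `anticodon_matches`), a D-arm
#' (3-4 bp stem, no mismatches) between the acceptor and anticodon arms, and
#' a T-arm (4-5 bp stem, <= 1 mismatch) between the anticodon arm and the 3'
#' acceptor half. Metazoan mitochondrial trnS2 typically lacks the D-arm
#' stem, and an all-negative report is valid output: this is a consistency
#' heuristic, not a folding algorithm.
#'
#' @param trna_seq tRNA gene sequence (50-100 nt, coding orientation).
#' @param anticodon Anticodon 3-mer (DNA or RNA alphabet).
#' @return A `cloverleaf_report` list with per-arm found/pairs/mismatches and
#'   `anticodon_matches`.
#' @export
check_cloverleaf <- function(trna_seq, anticodon) {
  seq <- toupper(trna_seq)
  L <- nchar(seq)
  if (L < 50 || L > 100) {
    warning(sprintf("tRNA length %d outside 50-100 nt", L), call. = FALSE)
  }
  anticodon <- rna_to_dna(toupper(anticodon))
  chars <- s2c(seq)

  acc_pairs <- stem_pairs(chars, 1L, L - 6L, 7L)
  acceptor <- list(found = (7L - acc_pairs) <= 1L, pairs = acc_pairs,
                   mismatches = 7L - acc_pairs)

  # anticodon arm: 5-bp stem + 7-nt loop, scanned over the interior;
  # prefer candidates whose loop centre equals the anticodon
  ac_best <- NULL
  for (p in seq(10L, max(10L, L - 24L))) {
    if (p + 16L > L - 7L) break
    pr <- stem_pairs(chars, p, p + 12L, 5L)
    mm <- 5L - pr
    if (mm > 1L) next
    loop <- c2s(chars[seq(p + 5L, p + 11L)])
    matches <- substr(loop, 3, 5) == anticodon
    cand <- list(start = p, pairs = pr, mismatches = mm, matches = matches)
    if (is.null(ac_best) ||
        (matches && !ac_best$matches) ||
        (matches == ac_best$matches && mm < ac_best$mismatches)) {
      ac_best <- cand
    }
  }
  anticodon_arm <- if (is.null(ac_best)) {
    list(found = FALSE, pairs = 0L, mismatches = NA_integer_)
  } else {
    list(found = TRUE, pairs = ac_best$pairs, mismatches = ac_best$mismatches)
  }
  anticodon_matches <- if (is.null(ac_best)) NA else ac_best$matches

  # D-arm between acceptor 5' half and the anticodon arm
  d_to <- if (!is.null(ac_best)) ac_best$start - 1L else L - 25L
  d_best <- if (d_to >= 17L) {
    find_stem_loop(chars, 9L, d_to, stem_lens = c(4L, 3L),
                   loop_lens = 3:10, max_mismatch = 0L)
  } else NULL
  d_arm <- if (is.null(d_best)) list(found = FALSE, pairs = 0L, mismatches = NA_integer_)
  else list(found = TRUE, pairs = d_best$pairs, mismatches = d_best$mismatches)

  # T-arm between the anticodon arm and the 3' acceptor half
  t_from <- if (!is.null(ac_best)) ac_best$start + 17L else 27L
  t_best <- if (L - 7L - t_from + 1L >= 11L) {
    find_stem_loop(chars, t_from, L - 7L, stem_lens = c(5L, 4L),
                   loop_lens = 3:9, max_mismatch = 1L)
  } else NULL
  t_arm <- if (is.null(t_best)) list(found = FALSE, pairs = 0L, mismatches = NA_integer_)
  else list(found = TRUE, pairs = t_best$pairs, mismatches = t_best$mismatches)

  structure(list(acceptor_stem = acceptor, d_arm = d_arm,
                 anticodon_arm = anticodon_arm, t_arm = t_arm,
                 anticodon_matches = anticodon_matches),
            class = "cloverleaf_report")
}

#' Cloverleaf reports for all tRNAs of a genome
#'
#' @param genome A [mitogenome()].
#' @return data.frame, one row per tRNA with arm flags.
#' @export
cloverleaf_table <- function(genome) {
  trnas <- genome$features[genome$features$kind == "tRNA", ]
  do.call(rbind, lapply(seq_len(nrow(trnas)), function(i) {
    f <- trnas[i, ]
    rep <- check_cloverleaf(extract_gene_sequence(genome, f),
                            if (is.na(f$anticodon)) "NNN" else f$anticodon)
    data.frame(genome = genome$id, trna = f$name,
               acceptor = rep$acceptor_stem$found, d_arm = rep$d_arm$found,
               anticodon_arm = rep$anticodon_arm$found, t_arm = rep$t_arm$found,
               anticodon_matches = rep$anticodon_matches,
               stringsAsFactors = FALSE)
  }))
}
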