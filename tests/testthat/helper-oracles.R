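# Independent oracles used by the test suite. These deliberately share no
# code with the package implementations they check: naive loops and explicit
# enumeration throughout.

ORACLE_BASES <- c("A", "C", "G", "T")

oracle_code5 <- function() {
  # written out independently of the package constant
  ref <- mitocomp::mt_genetic_code()
  if (requireNamespace("Biostrings", quietly = TRUE)) {
    bs <- Biostrings::getGeneticCode("5")
    stopifnot(identical(unname(bs[names(ref)]), unname(ref)))
  }
  ref
}

# per-codon synonymous site count by explicit looping
oracle_syn_sites <- function(codon, code = oracle_code5()) {
  s <- 0
  for (pos in 1:3) {
    syn <- 0; valid <- 0
    for (b in ORACLE_BASES) {
      if (b == substr(codon, pos, pos)) next
      mut <- codon
      substr(mut, pos, pos) <- b
      if (code[[mut]] == "*") next
      valid <- valid + 1
      if (code[[mut]] == code[[codon]]) syn <- syn + 1
    }
    if (valid > 0) s <- s + syn / valid
  }
  s
}

# all mutational pathways between two codons, as lists of (from, to) steps
oracle_paths <- function(a, b) {
  if (a == b) return(list(list()))
  out <- list()
  for (pos in which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])) {
    mid <- a
    substr(mid, pos, pos) <- substr(b, pos, pos)
    for (tail_path in oracle_paths(mid, b)) {
      out[[length(out) + 1L]] <- c(list(c(a, mid)), tail_path)
    }
  }
  out
}

# pathway-averaged synonymous/nonsynonymous difference counts, skipping
# pathways through stop codons (falling back to all pathways)
oracle_diff_counts <- function(a, b, code = oracle_code5()) {
  paths <- oracle_paths(a, b)
  score <- function(path) {
    sd <- 0; nd <- 0; through_stop <- FALSE
    for (k in seq_along(path)) {
      from <- path[[k]][1]; to <- path[[k]][2]
      if (code[[to]] == "*" && k < length(path)) through_stop <- TRUE
      if (code[[to]] != "*" && code[[to]] == code[[from]]) sd <- sd + 1 else nd <- nd + 1
    }
    c(sd = sd, nd = nd, stop = as.numeric(through_stop))
  }
  scores <- vapply(paths, score, numeric(3))
  ok <- scores["stop", ] == 0
  use <- if (any(ok)) scores[, ok, drop = FALSE] else scores
  c(Sd = mean(use["sd", ]), Nd = mean(use["nd", ]))
}

random_sense_codon <- function(code = oracle_code5()) {
  repeat {
    cd <- paste(sample(ORACLE_BASES, 3, replace = TRUE), collapse = "")
    if (code[[cd]] != "*") return(cd)
  }
}

# exhaustive perfect-tandem-repeat scan (no cleverness): every start, every
# motif length, count full copies
oracle_microsat_spans <- function(seq, min_motif = 1, max_motif = 6, min_length = 10) {
  n <- nchar(seq)
  spans <- list()
  for (m in seq(min_motif, max_motif)) {
    for (s in seq_len(n - 2 * m + 1)) {
      motif <- substr(seq, s, s + m - 1)
      copies <- 1
      while (s + (copies + 1) * m - 1 <= n &&
             substr(seq, s + copies * m, s + (copies + 1) * m - 1) == motif) {
        copies <- copies + 1
      }
      if (copies >= 2 && copies * m >= min_length) {
        spans[[length(spans) + 1L]] <- c(start = s - 1, end = s - 1 + copies * m,
                                         m = m)
      }
    }
  }
  spans
}

# reduce raw oracle spans to maximal distinct runs: within a period, spans
# sharing at least one full period are phases of the same run (keep the
# earliest start); across periods, drop spans contained in a longer span
oracle_microsat_maximal <- function(spans) {
  if (length(spans) == 0) {
    return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("start", "end"))))
  }
  tab <- unique(do.call(rbind, spans))
  kept <- list()
  for (m in sort(unique(tab[, "m"]))) {
    sub <- tab[tab[, "m"] == m, , drop = FALSE]
    sub <- sub[order(sub[, "start"]), , drop = FALSE]
    grp_start <- sub[1, ]
    grp_end <- sub[1, "end"]
    for (i in seq_len(nrow(sub))[-1]) {
      overlap <- min(grp_end, sub[i, "end"]) - sub[i, "start"]
      if (overlap >= m) {
        grp_end <- max(grp_end, sub[i, "end"])
      } else {
        kept[[length(kept) + 1L]] <- grp_start
        grp_start <- sub[i, ]
        grp_end <- sub[i, "end"]
      }
    }
    kept[[length(kept) + 1L]] <- grp_start
  }
  tab <- do.call(rbind, kept)
  contained <- vapply(seq_len(nrow(tab)), function(i) {
    any(tab[, "start"] <= tab[i, "start"] & tab[, "end"] >= tab[i, "end"] &
          (tab[, "end"] - tab[, "start"]) > (tab[i, "end"] - tab[i, "start"]))
  }, logical(1))
  tab <- unique(tab[!contained, c("start", "end"), drop = FALSE])
  tab[order(tab[, "start"], tab[, "end"]), , drop = FALSE]
}

# all-pairs direct-repeat scan at small scale: is there any pair of
# non-overlapping windows of length len with identity >= min_identity?
oracle_has_long_repeat <- function(seq, len, min_identity = 0.9) {
  n <- nchar(seq)
  chars <- strsplit(seq, "")[[1]]
  if (n < 2 * len) return(FALSE)
  for (i in seq_len(n - 2 * len + 1)) {
    for (j in seq(i + len, n - len + 1)) {
      a <- chars[i:(i + len - 1)]
      b <- chars[j:(j + len - 1)]
      if (mean(a == b) >= min_identity) return(TRUE)
    }
  }
  FALSE
}

# rule-for-rule reimplementation of the conserved-block filter, as an
# independent reference (plain loops, no rle)
oracle_filter_kept <- function(seqs, conserved = 0.5, max_nonconserved = 8,
                               min_block = 10) {
  m <- do.call(rbind, strsplit(toupper(seqs), ""))
  n <- nrow(m); L <- ncol(m)
  cons <- logical(L)
  for (j in seq_len(L)) {
    col <- m[, j]
    if (sum(col %in% c("-", "?")) >= n / 2) { cons[j] <- FALSE; next }
    res <- col[!col %in% c("-", "?")]
    cons[j] <- max(table(res)) / n > conserved
  }
  keep <- rep(TRUE, L)
  j <- 1
  while (j <= L) {
    if (!cons[j]) {
      k <- j
      while (k <= L && !cons[k]) k <- k + 1
      if (k - j > max_nonconserved) keep[j:(k - 1)] <- FALSE
      j <- k
    } else j <- j + 1
  }
  j <- 1
  while (j <= L) {
    if (keep[j]) {
      k <- j
      while (k <= L && keep[k]) k <- k + 1
      if (k - j < min_block) keep[j:(k - 1)] <- FALSE
      j <- k
    } else j <- j + 1
  }
  which(keep) - 1L
}

# small hand-rolled mitogenome for I/O and junction tests
toy_genome <- function() {
  set.seed(404)
  seq <- paste(sample(ORACLE_BASES, 400, replace = TRUE, prob = c(.35, .15, .1, .4)),
               collapse = "")
  # cox1 [0,90) J; trnM [95,158) J; nad1 [150,300) N (overlap 8 with trnM);
  # UR [300,380); rrnS [380,400+20) spanning the origin
  feats <- rbind(
    mitocomp::gene_feature("cox1", "PCG", 0, 90, "J"),
    mitocomp::gene_feature("trnM", "tRNA", 95, 158, "J", "CAT"),
    mitocomp::gene_feature("nad1", "PCG", 150, 300, "N"),
    mitocomp::gene_feature("rrnS", "rRNA", 380, 420, "N"))
  mitocomp::mitogenome("TOY1", "Toy insect", seq, circular = TRUE,
                       complete = TRUE, features = feats)
}

default_sim_genes_omega0 <- function() {
  g <- mitocomp:::default_gene_table()
  g$omega[!is.na(g$omega)] <- 0
  g
}

fixture_genome_cached <- local({
  g <- NULL
  function() {
    if (is.null(g)) g <<- mitocomp::make_fixture_genome(1)
    g
  }
})
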