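# Per-gene divergence statistics across aligned mitogenomes: nucleotide
# diversity (pi), Nei-Gojobori (1986) Ka/Ks with Jukes-Cantor correction,
# Tamura-Nei (1993) distances, and transition/transversion saturation
# profiles by codon position.

#' Construct a gene alignment
#'
#' @param gene Gene name.
#' @param taxa Character vector of taxon labels.
#' @param seqs Character vector of equal-length aligned sequences (gap `-`).
#' @param is_codon TRUE for protein-coding alignments (length divisible by 3;
#'   frame-breaking gap runs raise a warning and the affected codons are
#'   masked downstream).
#' @return A `gene_alignment` object.
#' @export
gene_alignment <- function(gene, taxa, seqs, is_codon = FALSE) {
  stopifnot(length(taxa) == length(seqs), length(seqs) >= 2)
  seqs <- toupper(seqs)
  lens <- nchar(seqs)
  if (length(unique(lens)) != 1) stop("aligned rows differ in length", call. = FALSE)
  if (is_codon) {
    if (lens[1] %% 3 != 0) stop(sprintf("codon alignment '%s' length not divisible by 3", gene),
                                call. = FALSE)
    for (s in seqs) {
      runs <- rle(s2c(s) == "-")
      if (any(runs$values & runs$lengths %% 3 != 0)) {
        warning(sprintf("%s: frame-breaking gap run; affected codons will be masked", gene),
                call. = FALSE)
        break
      }
    }
  }
  structure(list(gene = gene, taxa = taxa, seqs = stats::setNames(seqs, taxa),
                 is_codon = is_codon, length = lens[1]),
            class = "gene_alignment")
}

aln_matrix <- function(aln) {
  do.call(rbind, lapply(aln$seqs, s2c))
}

#' Nucleotide diversity (pi) of an alignment
#'
#' pi = (2 / (n(n-1))) * sum over pairs of d_ij, where d_ij is the proportion
#' of differing sites among sites comparable for that pair. Gap handling:
#' `"pairwise"` deletion (default) drops a site only for pairs where either
#' member has a gap/ambiguity; `"complete"` drops it for all pairs.
#'
#' @param aln A [gene_alignment()].
#' @param deletion `"pairwise"` or `"complete"`.
#' @return A `diversity_result` list: `gene`, `pi`, `n_sequences`, `sites`
#'   (mean comparable sites per pair).
#' @export
nucleotide_diversity <- function(aln, deletion = c("pairwise", "complete")) {
  deletion <- match.arg(deletion)
  m <- aln_matrix(aln)
  valid <- matrix(m %in% c("A", "C", "G", "T"), nrow = nrow(m))
  if (deletion == "complete") {
    keep <- apply(valid, 2, all)
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  n <- nrow(m)
  dsum <- 0; npairs <- 0L; site_sum <- 0; any_sites <- FALSE
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      comp <- valid[i, ] & valid[j, ]
      nc <- sum(comp)
      npairs <- npairs + 1L
      site_sum <- site_sum + nc
      if (nc == 0) next
      any_sites <- TRUE
      dsum <- dsum + sum(m[i, comp] != m[j, comp]) / nc
    }
  }
  pi <- if (any_sites) dsum / npairs else NA_real_
  structure(list(gene = aln$gene, pi = pi, n_sequences = n,
                 sites = site_sum / npairs),
            class = "diversity_result")
}

# ---- NG86 -------------------------------------------------------------------

# Precomputed tables: per-codon synonymous site counts and pathway-averaged
# synonymous/nonsynonymous difference counts for every codon pair. Built once
# per session (a few thousand small enumerations).
ng86_tables <- function() {
  if (!is.null(.mc_env$ng86)) return(.mc_env$ng86)
  code <- gc5()
  codons <- names(code)
  bases <- c("A", "C", "G", "T")

  syn_sites <- stats::setNames(numeric(64), codons)
  for (cd in codons) {
    if (code[[cd]] == "*") { syn_sites[cd] <- NA_real_; next }
    s <- 0
    for (pos in 1:3) {
      ref <- substr(cd, pos, pos)
      alts <- setdiff(bases, ref)
      muts <- vapply(alts, function(b) { x <- cd; substr(x, pos, pos) <- b; x }, "")
      aas <- code[muts]
      nonstop <- aas != "*"
      if (any(nonstop)) s <- s + sum(aas[nonstop] == code[[cd]]) / sum(nonstop)
    }
    syn_sites[cd] <- s
  }

  perms <- list(`1` = list(1L), `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  sd_tab <- matrix(NA_real_, 64, 64, dimnames = list(codons, codons))
  nd_tab <- sd_tab
  sense <- codons[code != "*"]
  for (a in sense) {
    for (b in sense) {
      if (a == b) { sd_tab[a, b] <- 0; nd_tab[a, b] <- 0; next }
      if (!is.na(sd_tab[b, a])) {
        sd_tab[a, b] <- sd_tab[b, a]; nd_tab[a, b] <- nd_tab[b, a]; next
      }
      diff_pos <- which(s2c(a) != s2c(b))
      paths <- perms[[as.character(length(diff_pos))]]
      stats_per_path <- vapply(paths, function(ord) {
        cur <- a; sd <- 0; nd <- 0; hit_stop <- FALSE
        for (pos in diff_pos[ord]) {
          nxt <- cur
          substr(nxt, pos, pos) <- substr(b, pos, pos)
          if (code[[nxt]] == "*" && nxt != b) hit_stop <- TRUE
          if (code[[nxt]] == code[[cur]] && code[[nxt]] != "*") sd <- sd + 1
          else nd <- nd + 1
          cur <- nxt
        }
        c(sd, nd, as.numeric(hit_stop))
      }, numeric(3))
      ok <- stats_per_path[3, ] == 0
      use <- if (any(ok)) stats_per_path[, ok, drop = FALSE] else stats_per_path
      sd_tab[a, b] <- mean(use[1, ])
      nd_tab[a, b] <- mean(use[2, ])
    }
  }
  .mc_env$ng86 <- list(syn_sites = syn_sites, sd = sd_tab, nd = nd_tab)
  .mc_env$ng86
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 0.75) {
    warning("proportion of differences >= 3/4; Jukes-Cantor correction undefined",
            call. = FALSE)
    return(NA_real_)
  }
  -0.75 * log(1 - 4 * p / 3)
}

ng86_pair <- function(c1, c2) {
  tabs <- ng86_tables()
  code <- gc5()
  usable <- c1 %in% names(code) & c2 %in% names(code) &
    !grepl("[^ACGT]", c1) & !grepl("[^ACGT]", c2)
  usable[usable] <- code[c1[usable]] != "*" & code[c2[usable]] != "*"
  c1 <- c1[usable]; c2 <- c2[usable]
  if (length(c1) == 0) {
    return(list(N = NA_real_, S = NA_real_, Nd = NA_real_, Sd = NA_real_, codons = 0L))
  }
  S <- (sum(tabs$syn_sites[c1]) + sum(tabs$syn_sites[c2])) / 2
  N <- 3 * length(c1) - S
  Sd <- sum(tabs$sd[cbind(c1, c2)])
  Nd <- sum(tabs$nd[cbind(c1, c2)])
  list(N = N, S = S, Nd = Nd, Sd = Sd, codons = length(c1))
}

#' Nei-Gojobori (1986) Ka/Ks for a codon alignment
#'
#' Synonymous/nonsynonymous site counts per codon average the synonymy of
#' each position over single-base mutations under the invertebrate
#' mitochondrial code, with mutations to stop codons excluded from the
#' denominator. Between-codon differences are resolved by equal-weight
#' averaging over all mutational pathway orderings that avoid stop codons
#' (falling back to all orderings when every one passes through a stop).
#' Proportions pN = Nd/N and pS = Sd/S receive the Jukes-Cantor correction
#' d = -(3/4) ln(1 - 4p/3). With more than two sequences the result is the
#' unweighted mean of the per-pair quantities and the ratio is mean Ka over
#' mean Ks.
#'
#' Codons containing a gap, an ambiguity code, or a stop in either member of
#' a pair are skipped for that pair.
#'
#' @param aln A codon [gene_alignment()].
#' @param pair Optional length-2 vector of taxon labels restricting the
#'   computation to one pair.
#' @return A `kaks_result` list: `Ka`, `Ks`, `ratio` (NA when Ks = 0), `N`,
#'   `S`, `Nd`, `Sd`, `n_pairs`, `gene`.
#' @export
ng86_kaks <- function(aln, pair = NULL) {
  stopifnot(inherits(aln, "gene_alignment"))
  if (!aln$is_codon) stop("ng86_kaks needs a codon alignment", call. = FALSE)
  seqs <- aln$seqs
  if (!is.null(pair)) {
    stopifnot(length(pair) == 2, all(pair %in% aln$taxa))
    seqs <- seqs[pair]
  }
  codon_rows <- lapply(seqs, split_codons)
  n <- length(codon_rows)
  acc <- list(Ka = c(), Ks = c(), N = c(), S = c(), Nd = c(), Sd = c())
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      pc <- ng86_pair(codon_rows[[i]], codon_rows[[j]])
      if (pc$codons == 0L) next
      ka <- jc_correct(pc$Nd / pc$N)
      ks <- jc_correct(pc$Sd / pc$S)
      acc$Ka <- c(acc$Ka, ka); acc$Ks <- c(acc$Ks, ks)
      acc$N <- c(acc$N, pc$N); acc$S <- c(acc$S, pc$S)
      acc$Nd <- c(acc$Nd, pc$Nd); acc$Sd <- c(acc$Sd, pc$Sd)
    }
  }
  if (length(acc$N) == 0) stop("no comparable codons in any pair", call. = FALSE)
  Ka <- mean(acc$Ka); Ks <- mean(acc$Ks)
  ratio <- if (is.na(Ks) || is.na(Ka) || Ks == 0) NA_real_ else Ka / Ks
  structure(list(gene = aln$gene, Ka = Ka, Ks = Ks, ratio = ratio,
                 N = mean(acc$N), S = mean(acc$S),
                 Nd = mean(acc$Nd), Sd = mean(acc$Sd),
                 n_pairs = length(acc$N)),
            class = "kaks_result")
}

#' @export
print.kaks_result <- function(x, ...) {
  cat(sprintf("<NG86 %s> Ka = %.4f, Ks = %.4f, Ka/Ks = %s (%d pair%s)\n",
              x$gene, x$Ka, x$Ks,
              if (is.na(x$ratio)) "NA" else sprintf("%.3f", x$ratio),
              x$n_pairs, if (x$n_pairs == 1) "" else "s"))
  invisible(x)
}

# ---- TN93 -------------------------------------------------------------------

#' Tamura-Nei (1993) distance between two aligned sequences
#'
#' Uses base frequencies pooled over the two sequences at comparable sites,
#' with the two transition classes (A<->G, C<->T) separated from
#' transversions. Saturated comparisons (logarithm argument <= 0) return `NA`
#' with attribute `saturated = TRUE`.
#'
#' @param a,b Aligned DNA strings of equal length.
#' @return The TN93 distance (substitutions/site), or `NA` when undefined.
#' @export
tn93_distance <- function(a, b) {
  ca <- s2c(toupper(a)); cb <- s2c(toupper(b))
  if (length(ca) != length(cb)) stop("sequences differ in length", call. = FALSE)
  comp <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
  if (!any(comp)) stop("no comparable sites", call. = FALSE)
  ca <- ca[comp]; cb <- cb[comp]
  nsite <- length(ca)
  freq <- (table(factor(ca, levels = c("A", "C", "G", "T"))) +
             table(factor(cb, levels = c("A", "C", "G", "T")))) / (2 * nsite)
  gA <- freq[["A"]]; gC <- freq[["C"]]; gG <- freq[["G"]]; gT <- freq[["T"]]
  gR <- gA + gG; gY <- gC + gT
  diff <- ca != cb
  P1 <- sum(diff & ((ca == "A" & cb == "G") | (ca == "G" & cb == "A"))) / nsite
  P2 <- sum(diff & ((ca == "C" & cb == "T") | (ca == "T" & cb == "C"))) / nsite
  Q <- sum(diff & is_transition(ca, cb) == FALSE) / nsite

  k1 <- if (gR > 0) 2 * gA * gG / gR else 0
  k2 <- if (gY > 0) 2 * gT * gC / gY else 0
  k3 <- 2 * (gR * gY - (if (gR > 0) gA * gG * gY / gR else 0) -
               (if (gY > 0) gT * gC * gR / gY else 0))
  term <- function(k, w) {
    if (k == 0) return(0)
    if (w <= 0) return(NA_real_)
    -k * log(w)
  }
  w1 <- if (k1 > 0) 1 - P1 / k1 - Q / (2 * gR) else 1
  w2 <- if (k2 > 0) 1 - P2 / k2 - Q / (2 * gY) else 1
  w3 <- if (gR * gY > 0) 1 - Q / (2 * gR * gY) else 1
  d <- term(k1, w1) + term(k2, w2) + term(k3, w3)
  if (is.na(d)) {
    d <- NA_real_
    attr(d, "saturated") <- TRUE
  }
  d
}

#' TN93 distance matrix of an alignment
#'
#' @param aln A [gene_alignment()] (or list of sequences sharing taxa).
#' @return A `distance_matrix`: symmetric matrix with taxa as dimnames and a
#'   `metric` attribute; saturated entries are `NA`.
#' @export
tn93_matrix <- function(aln) {
  seqs <- aln$seqs
  n <- length(seqs)
  m <- matrix(0, n, n, dimnames = list(aln$taxa, aln$taxa))
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      d <- tn93_distance(seqs[[i]], seqs[[j]])
      m[i, j] <- m[j, i] <- as.numeric(d)
    }
  }
  attr(m, "metric") <- "TN93"
  m
}

# ---- saturation -------------------------------------------------------------

#' Transition/transversion saturation profile of a codon alignment
#'
#' For every unordered taxon pair, reports the observed transition and
#' transversion proportions against the TN93 distance, at one codon position
#' or over all sites. Summary slopes of S and V against distance come from
#' ordinary least squares through the origin (d = 0 implies S = V = 0 by
#' construction).
#'
#' @param aln A codon [gene_alignment()] (e.g. a concatenated PCG alignment).
#' @param position `1`, `2`, `3` or `"all"`.
#' @return List with `points` (data.frame: taxon pair, tn93, s_prop, v_prop,
#'   position) and `s_slope`, `v_slope`.
#' @export
saturation_profile <- function(aln, position = "all") {
  stopifnot(inherits(aln, "gene_alignment"))
  if (length(aln$taxa) < 3) stop("saturation profile needs >= 3 taxa", call. = FALSE)
  position <- as.character(position)
  idx <- if (position == "all") seq_len(aln$length) else
    seq(as.integer(position), aln$length, by = 3L)
  sub <- vapply(aln$seqs, function(s) c2s(s2c(s)[idx]), "")
  n <- length(sub)
  rows <- list()
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      ca <- s2c(sub[[i]]); cb <- s2c(sub[[j]])
      comp <- ca %in% c("A", "C", "G", "T") & cb %in% c("A", "C", "G", "T")
      nc <- sum(comp)
      if (nc == 0) next
      diff <- comp & ca != cb
      s <- sum(diff & is_transition(ca, cb))
      v <- sum(diff) - s
      d <- tryCatch(tn93_distance(sub[[i]], sub[[j]]), error = function(e) NA_real_)
      rows[[length(rows) + 1L]] <- data.frame(
        taxon_a = aln$taxa[i], taxon_b = aln$taxa[j],
        tn93 = as.numeric(d), s_prop = s / nc, v_prop = v / nc,
        position = position, stringsAsFactors = FALSE)
    }
  }
  points <- do.call(rbind, rows)
  if (is.null(points) || all(is.na(points$tn93))) {
    stop("all pairwise distances missing", call. = FALSE)
  }
  ok <- !is.na(points$tn93)
  sx2 <- sum(points$tn93[ok]^2)
  s_slope <- if (sx2 > 0) sum(points$tn93[ok] * points$s_prop[ok]) / sx2 else NA_real_
  v_slope <- if (sx2 > 0) sum(points$tn93[ok] * points$v_prop[ok]) / sx2 else NA_real_
  list(points = points, s_slope = s_slope, v_slope = v_slope)
}

#' Per-gene diversity and Ka/Ks table
#'
#' @param alignments List of codon [gene_alignment()]s.
#' @param deletion Gap handling for pi, see [nucleotide_diversity()].
#' @return data.frame with one row per gene: pi, Ka, Ks, Ka/Ks.
#' @export
diversity_table <- function(alignments, deletion = "pairwise") {
  do.call(rbind, lapply(alignments, function(aln) {
    div <- nucleotide_diversity(aln, deletion = deletion)
    kk <- if (aln$is_codon) ng86_kaks(aln) else
      list(Ka = NA_real_, Ks = NA_real_, ratio = NA_real_)
    data.frame(gene = aln$gene, n = length(aln$taxa), pi = div$pi,
               Ka = kk$Ka, Ks = kk$Ks, ka_ks = kk$ratio,
               stringsAsFactors = FALSE)
  }))
}
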