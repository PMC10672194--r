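# Desk-scale phylogenetic chain: supermatrix assembly with a simplified
# conserved-block filter, neighbor-joining distance trees, and minimum-age
# calibrated mean-path-length (MPL) dating. These are deliberately
# lightweight, clearly-labelled stand-ins for site-heterogeneous Bayesian/ML
# inference and relaxed-clock dating, which are out of scope; the pipeline
# also accepts an externally supplied fixed topology so dating can run on a
# published tree shape.

#' Assemble a concatenated supermatrix from gene alignments
#'
#' Genes are concatenated in a fixed documented order (alphabetical by gene
#' name, protein-coding genes before rRNAs). Under scheme `"PCG123RNA"` all
#' nucleotide columns are kept; under `"PCGAA"` codon alignments are
#' translated under the invertebrate mitochondrial code and concatenated as
#' amino acids. Taxa missing a gene are padded with `?`.
#'
#' @param gene_alignments List of [gene_alignment()]s sharing a taxon
#'   namespace.
#' @param scheme `"PCG123RNA"` or `"PCGAA"`.
#' @return A `supermatrix`: taxa, rows (named character vector), partitions
#'   data.frame (label, start, end, kind; 0-based half-open, tiling the
#'   matrix).
#' @export
build_supermatrix <- function(gene_alignments, scheme = c("PCG123RNA", "PCGAA")) {
  scheme <- match.arg(scheme)
  stopifnot(length(gene_alignments) > 0)
  genes <- vapply(gene_alignments, function(a) a$gene, "")
  is_codon <- vapply(gene_alignments, function(a) a$is_codon, TRUE)
  if (scheme == "PCGAA") {
    keep <- is_codon
    if (!any(keep)) stop("PCGAA needs codon alignments", call. = FALSE)
    gene_alignments <- gene_alignments[keep]
    genes <- genes[keep]
    is_codon <- is_codon[keep]
  }
  ord <- order(!is_codon, genes)  # PCGs first, then rRNAs; alphabetical within
  gene_alignments <- gene_alignments[ord]
  genes <- genes[ord]; is_codon <- is_codon[ord]

  taxa <- sort(unique(unlist(lapply(gene_alignments, function(a) a$taxa))))
  rows <- stats::setNames(rep("", length(taxa)), taxa)
  parts <- list()
  pos <- 0L
  for (i in seq_along(gene_alignments)) {
    aln <- gene_alignments[[i]]
    if (scheme == "PCGAA") {
      block <- vapply(aln$seqs, translate_alignment_row, "")
      kind <- "aminoAcid"
    } else {
      block <- aln$seqs
      kind <- if (is_codon[i]) "PCG" else "rRNA"
    }
    blen <- nchar(block[[1]])
    pad <- paste(rep("?", blen), collapse = "")
    for (t in taxa) {
      piece <- if (t %in% aln$taxa) block[[match(t, aln$taxa)]] else pad
      rows[t] <- paste0(rows[t], piece)
    }
    parts[[i]] <- data.frame(label = genes[i], start = pos, end = pos + blen,
                             kind = kind, stringsAsFactors = FALSE)
    pos <- pos + blen
  }
  structure(list(taxa = taxa, rows = rows,
                 partitions = do.call(rbind, parts), scheme = scheme,
                 length = pos),
            class = "supermatrix")
}

# translate one aligned codon row: '---' stays '-', partial-gap or ambiguous
# codons become 'X'
translate_alignment_row <- function(row) {
  codons <- split_codons(row)
  aa <- vapply(codons, function(cd) {
    if (cd == "---") return("-")
    if (grepl("[^ACGT]", cd)) return("X")
    gc5()[[cd]]
  }, "")
  c2s(aa)
}

#' Simplified conserved-block filter for alignments
#'
#' A restatement of the familiar conserved-block trimming rules: a position
#' is conserved when its majority residue frequency exceeds `conserved`
#' (highly conserved above `highly_conserved`); positions gapped in at least
#' half the rows are nonconserved ("with half" gap handling); runs of more
#' than `max_nonconserved` contiguous nonconserved positions are removed,
#' and surviving blocks shorter than `min_block` are removed too.
#'
#' @param seqs Character vector of aligned rows (>= 4), or a
#'   [gene_alignment()].
#' @param conserved,highly_conserved Majority-frequency thresholds.
#' @param max_nonconserved Longest nonconserved run kept (positions).
#' @param min_block Shortest block kept (positions).
#' @return List: `seqs` (filtered rows), `kept` (0-based kept positions),
#'   `removed_fraction`.
#' @export
filter_blocks <- function(seqs, conserved = 0.5, highly_conserved = 0.85,
                          max_nonconserved = 8, min_block = 10) {
  aln <- NULL
  if (inherits(seqs, "gene_alignment")) { aln <- seqs; seqs <- aln$seqs }
  if (length(seqs) < 4) stop("block filter needs >= 4 rows", call. = FALSE)
  m <- do.call(rbind, lapply(seqs, function(s) s2c(toupper(s))))
  n <- nrow(m); L <- ncol(m)
  status <- vapply(seq_len(L), function(j) {
    col <- m[, j]
    gaps <- sum(col %in% c("-", "?"))
    if (gaps >= n / 2) return(FALSE)
    res <- col[!col %in% c("-", "?")]
    max(table(res)) / n > conserved
  }, TRUE)
  # nonconserved runs <= max_nonconserved are retained inside blocks; longer
  # runs are removed, and surviving blocks shorter than min_block go too
  keep <- rep(TRUE, L)
  r <- rle(status)
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(!r$values & r$lengths > max_nonconserved)) {
    keep[starts[k]:ends[k]] <- FALSE
  }
  r2 <- rle(keep)
  ends2 <- cumsum(r2$lengths); starts2 <- ends2 - r2$lengths + 1L
  for (k in which(r2$values & r2$lengths < min_block)) {
    keep[starts2[k]:ends2[k]] <- FALSE
  }
  kept <- which(keep)
  out <- vapply(seqs, function(s) c2s(s2c(s)[kept]), "", USE.NAMES = FALSE)
  names(out) <- names(seqs)
  list(seqs = out, kept = kept - 1L, removed_fraction = 1 - length(kept) / L)
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via ape), with taxa normalized to
#' label order for deterministic tie-breaking and negative branch lengths
#' clamped to zero with a warning.
#'
#' @param dm Symmetric distance matrix with taxon dimnames, no missing
#'   entries.
#' @return An unrooted `phylo` tree.
#' @export
nj_tree <- function(dm) {
  dm <- as.matrix(dm)
  if (is.null(rownames(dm))) stop("distance matrix needs taxon names", call. = FALSE)
  if (nrow(dm) < 3) stop("neighbor joining needs >= 3 taxa", call. = FALSE)
  if (any(is.na(dm))) stop("missing distances", call. = FALSE)
  if (max(abs(dm - t(dm))) > 1e-12) stop("distance matrix not symmetric", call. = FALSE)
  ord <- order(rownames(dm))
  dm <- dm[ord, ord]
  tree <- ape::nj(stats::as.dist(dm))
  if (any(tree$edge.length < 0)) {
    warning("negative branch length(s) clamped to 0", call. = FALSE)
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  tree
}

#' Define a minimum-age calibration point
#'
#' @param tips Character vector of tip labels whose MRCA carries the bound.
#' @param min_age Hard minimum age (Ma), > 0.
#' @param label Source label (e.g. a fossil name).
#' @return A `calibration_point` list.
#' @export
calibration_point <- function(tips, min_age, label = "") {
  stopifnot(length(tips) >= 1, min_age > 0)
  structure(list(tips = tips, min_age = min_age, label = label),
            class = "calibration_point")
}

# mean path length: average branch-length distance from each node to its
# descendant tips; returned for all nodes (tips = 0)
mean_path_lengths <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  sums <- numeric(nnode)
  counts <- integer(nnode)
  counts[seq_len(ntip)] <- 1L
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    sums[parent] <- sums[parent] + sums[child] + counts[child] * ord$edge.length[e]
    counts[parent] <- counts[parent] + counts[child]
  }
  sums / counts
}

clade_mrca <- function(tree, tips) {
  miss <- setdiff(tips, tree$tip.label)
  if (length(miss) > 0) {
    stop("calibration tips not in tree: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (length(tips) == 1) return(match(tips, tree$tip.label))
  ape::getMRCA(tree, tips)
}

tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Mean-path-length dating with hard minimum calibrations
#'
#' Node ages are proportional to the mean path length (MPL) from each node to
#' its descendant tips. The global rate is r = min over calibrations of
#' MPL(calibrated node) / minimum age, so that every calibrated node age
#' MPL/r meets or exceeds its hard bound and at least one attains it. Parent
#' ages younger than a child (possible on non-clocklike trees) are raised to
#' the child's age and flagged.
#'
#' @param tree Rooted `phylo` tree with branch lengths (substitutions/site).
#' @param calibrations List of [calibration_point()]s; clades must be
#'   monophyletic in `tree`.
#' @param root_min Optional hard minimum age for the root (Ma).
#' @return A `dated_tree` list: `tree`, `ages` (per node, Ma; tips 0),
#'   `rate` (substitutions/site/Ma), `calibrations` (data.frame with achieved
#'   ages), `adjusted_nodes`.
#' @export
mpl_date <- function(tree, calibrations, root_min = NULL) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted", call. = FALSE)
  if (length(calibrations) == 0 && is.null(root_min)) {
    stop("need at least one calibration", call. = FALSE)
  }
  mpl <- mean_path_lengths(tree)
  ntip <- length(tree$tip.label)
  root <- ntip + 1L

  cal_rows <- list()
  rates <- numeric(0)
  for (cp in calibrations) {
    node <- clade_mrca(tree, cp$tips)
    clade_tips <- tips_under(tree, node)
    extra <- setdiff(clade_tips, cp$tips)
    if (length(extra) > 0) {
      stop("calibrated clade not monophyletic; MRCA also contains: ",
           paste(extra, collapse = ", "), call. = FALSE)
    }
    if (mpl[node] <= 0) stop("calibrated node has zero depth", call. = FALSE)
    rates <- c(rates, mpl[node] / cp$min_age)
    cal_rows[[length(cal_rows) + 1L]] <-
      data.frame(label = cp$label, node = node, min_age = cp$min_age,
                 stringsAsFactors = FALSE)
  }
  if (!is.null(root_min)) {
    rates <- c(rates, mpl[root] / root_min)
    cal_rows[[length(cal_rows) + 1L]] <-
      data.frame(label = "root", node = root, min_age = root_min,
                 stringsAsFactors = FALSE)
  }
  rate <- min(rates)
  if (rate <= 0) stop("non-positive rate implied by calibrations", call. = FALSE)
  ages <- mpl / rate
  ages[seq_len(ntip)] <- 0

  # enforce parent >= child
  adjusted <- integer(0)
  ord <- ape::reorder.phylo(tree, "postorder")
  for (e in seq_len(nrow(ord$edge))) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    if (ages[parent] < ages[child]) {
      ages[parent] <- ages[child]
      adjusted <- c(adjusted, parent)
    }
  }
  cals <- do.call(rbind, cal_rows)
  cals$age <- ages[cals$node]
  structure(list(tree = tree, ages = ages, rate = rate, calibrations = cals,
                 adjusted_nodes = unique(adjusted)),
            class = "dated_tree")
}

#' @export
print.dated_tree <- function(x, ...) {
  ntip <- length(x$tree$tip.label)
  cat(sprintf("<dated tree> %d tips, rate %.4g subs/site/Ma, root age %.1f Ma\n",
              ntip, x$rate, x$ages[ntip + 1]))
  print(x$calibrations)
  invisible(x)
}

#' Write a supermatrix with partition file
#'
#' Writes relaxed PHYLIP and FASTA versions of the matrix plus a RAxML-style
#' partition file; protein-coding partitions are expanded into codon-position
#' strata using `start-end\\3` notation.
#'
#' @param sm A [build_supermatrix()] result.
#' @param stem Output path stem; writes `<stem>.phy`, `<stem>.fasta`,
#'   `<stem>.partitions`.
#' @return `stem`, invisibly.
#' @export
write_supermatrix <- function(sm, stem) {
  phy <- c(sprintf("%d %d", length(sm$taxa), sm$length),
           sprintf("%-12s %s", sm$taxa, sm$rows[sm$taxa]))
  writeLines(phy, paste0(stem, ".phy"))
  fa <- as.vector(rbind(paste0(">", sm$taxa), sm$rows[sm$taxa]))
  writeLines(fa, paste0(stem, ".fasta"))
  parts <- sm$partitions
  lines <- character(0)
  for (i in seq_len(nrow(parts))) {
    p <- parts[i, ]
    a <- p$start + 1L; b <- p$end
    if (p$kind == "PCG") {
      lines <- c(lines, sprintf("DNA, %s_pos%d = %d-%d\\3", p$label, 1:3, a + 0:2, b))
    } else if (p$kind == "rRNA") {
      lines <- c(lines, sprintf("DNA, %s = %d-%d", p$label, a, b))
    } else {
      lines <- c(lines, sprintf("PROT, %s = %d-%d", p$label, a, b))
    }
  }
  writeLines(lines, paste0(stem, ".partitions"))
  invisible(stem)
}
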