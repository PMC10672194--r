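# Codon-level services under the invertebrate mitochondrial code: start/stop
# calling with incomplete stop codons (terminal T or TA completed to TAA by
# polyadenylation when a tRNA follows), codon counting, and relative
# synonymous codon usage (RSCU).

#' Call the start and stop codon of a protein-coding gene
#'
#' The start is the first codon (ATN is the typical mitochondrial vocabulary;
#' anything else is flagged atypical). The stop is decided by CDS length mod
#' 3 and the terminal bases: a full TAA/TAG when the length is a multiple of
#' 3; `"TA-tRNA"` / `"T-tRNA"` when the length is 2 / 1 over a multiple of 3,
#' the trailing bases are TA / T, and the next feature in transcription
#' direction is a tRNA (recorded in `completed_by`).
#'
#' @param genome A [mitogenome()].
#' @param pcg Canonical PCG name (e.g. `"nad5"`).
#' @return A `start_stop_call` list: `gene`, `start_codon`, `atypical_start`,
#'   `stop_codon` (TAA/TAG/"TA-tRNA"/"T-tRNA"), `completed_by`, `atypical_stop`.
#' @export
call_start_stop <- function(genome, pcg) {
  feature <- get_feature(genome, pcg)
  if (feature$kind != "PCG") stop(sprintf("'%s' is not a PCG", pcg), call. = FALSE)
  cds <- extract_gene_sequence(genome, feature)
  n <- nchar(cds)
  start_codon <- substr(cds, 1, 3)
  atypical_start <- substr(start_codon, 1, 2) != "AT"

  rem <- n %% 3L
  completed_by <- NA_character_
  atypical_stop <- FALSE
  if (rem == 0L) {
    stop_codon <- substr(cds, n - 2, n)
    if (!stop_codon %in% mt_stop_codons()) atypical_stop <- TRUE
  } else {
    tail_bases <- substr(cds, n - rem + 1L, n)
    expected <- if (rem == 1L) "T" else "TA"
    if (tail_bases != expected) {
      stop(sprintf("inconsistent-annotation: %s has length = %d mod 3 but trailing '%s'",
                   pcg, rem, tail_bases), call. = FALSE)
    }
    stop_codon <- if (rem == 1L) "T-tRNA" else "TA-tRNA"
    nxt <- next_feature_coding_direction(genome, feature)
    if (!is.null(nxt) && nxt$kind == "tRNA") {
      completed_by <- nxt$name
    } else {
      warning(sprintf("%s: incomplete stop not followed by a tRNA", pcg), call. = FALSE)
      atypical_stop <- TRUE
    }
  }
  structure(list(gene = pcg, start_codon = start_codon,
                 atypical_start = atypical_start, stop_codon = stop_codon,
                 completed_by = completed_by, atypical_stop = atypical_stop),
            class = "start_stop_call")
}

# The feature immediately downstream in transcription direction: next by
# genomic order for J-strand genes, previous for N-strand genes (wrapping on
# circular genomes).
next_feature_coding_direction <- function(genome, feature) {
  fts <- genome$features
  i <- match(feature$name, fts$name)
  if (nrow(fts) < 2) return(NULL)
  j <- if (feature$strand == "J") i %% nrow(fts) + 1L else (i - 2L) %% nrow(fts) + 1L
  if (!genome$circular && ((feature$strand == "J" && j < i) ||
                           (feature$strand == "N" && j > i))) return(NULL)
  fts[j, , drop = FALSE]
}

#' Start/stop codon table for all PCGs of a genome
#'
#' @param genome A [mitogenome()].
#' @return data.frame with one row per PCG.
#' @export
start_stop_table <- function(genome) {
  pcgs <- genome$features$name[genome$features$kind == "PCG"]
  do.call(rbind, lapply(pcgs, function(g) {
    cl <- call_start_stop(genome, g)
    data.frame(genome = genome$id, gene = g, start_codon = cl$start_codon,
               atypical_start = cl$atypical_start, stop_codon = cl$stop_codon,
               completed_by = cl$completed_by, atypical_stop = cl$atypical_stop,
               stringsAsFactors = FALSE)
  }))
}

#' Count codons across a set of coding sequences
#'
#' Trailing incomplete codons (1-2 bases) are dropped, and a complete
#' terminal stop codon (TAA/TAG) is excluded: stop codons have no synonymous
#' family and would distort RSCU.
#'
#' @param cds_list List or character vector of in-frame coding sequences.
#' @param source Label for the counted set.
#' @return A `codon_count_table`: named count vector over the 64 codons,
#'   `total`, and `source`.
#' @export
count_codons <- function(cds_list, source = "CDS set") {
  counts <- stats::setNames(integer(64), names(gc5()))
  for (cds in as.list(cds_list)) {
    cds <- toupper(cds)
    cds <- substr(cds, 1, nchar(cds) - nchar(cds) %% 3L)
    if (nchar(cds) == 0) next
    codons <- split_codons(cds)
    if (codons[length(codons)] %in% mt_stop_codons()) {
      codons <- codons[-length(codons)]
    }
    codons <- codons[codons %in% names(counts)]  # ambiguous codons dropped
    tab <- table(codons)
    counts[names(tab)] <- counts[names(tab)] + as.integer(tab)
  }
  structure(list(counts = counts, total = sum(counts), source = source),
            class = "codon_count_table")
}

#' Relative synonymous codon usage
#'
#' For codon c in synonymous family F (see [codon_families()]),
#' RSCU(c) = count(c) * |F| / sum of counts over F. A family with zero total
#' reports `NA` for all members (no usage observed, not zero preference);
#' an unused codon in a used family reports 0.
#'
#' @param counts A [count_codons()] table.
#' @return data.frame with columns codon (DNA), codon_rna, aa, family, count,
#'   family_total, rscu.
#' @export
rscu <- function(counts) {
  fam <- codon_families()
  fam$count <- as.integer(counts$counts[fam$codon])
  totals <- tapply(fam$count, fam$family, sum)
  sizes <- tapply(fam$count, fam$family, length)
  fam$family_total <- as.integer(totals[fam$family])
  fam$rscu <- ifelse(fam$family_total == 0, NA_real_,
                     fam$count * as.integer(sizes[fam$family]) / fam$family_total)
  fam$codon_rna <- dna_to_rna(fam$codon)
  fam[, c("codon", "codon_rna", "aa", "family", "count", "family_total", "rscu")]
}

#' Codon usage (counts + RSCU) of the PCGs of a genome
#'
#' @param genome A [mitogenome()].
#' @return data.frame as from [rscu()], with a `genome` column.
#' @export
rscu_report <- function(genome) {
  pcgs <- genome$features$name[genome$features$kind == "PCG"]
  cds <- lapply(pcgs, function(g) extract_gene_sequence(genome, g))
  out <- rscu(count_codons(cds, source = genome$id))
  cbind(genome = genome$id, out, stringsAsFactors = FALSE)
}
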