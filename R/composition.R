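# Base composition and strand-asymmetry (skew) statistics. AT-skew =
# (A - T)/(A + T), GC-skew = (G - C)/(G + C); ambiguity codes are tallied
# separately and excluded from every denominator, which keeps both skews in
# [-1, 1]. Full precision is kept internally; reports round to 2 decimals.

#' Exact base composition of a DNA string
#'
#' @param seq DNA string (IUPAC codes allowed; anything else is an error
#'   naming the offending position).
#' @param context Free-text label for reports (e.g. `"whole genome"`,
#'   `"codon position 3"`).
#' @return A `base_composition` object: counts of A/C/G/T, `other` (ambiguity
#'   codes), and the context label.
#' @export
base_composition <- function(seq, context = "sequence") {
  seq <- toupper(seq)
  if (nchar(seq) == 0) stop("empty sequence", call. = FALSE)
  check_dna(seq)
  chars <- s2c(seq)
  tab <- table(factor(chars, levels = IUPAC_DNA))
  structure(list(A = unname(tab[["A"]]), C = unname(tab[["C"]]),
                 G = unname(tab[["G"]]), T = unname(tab[["T"]]),
                 other = nchar(seq) - sum(tab[c("A", "C", "G", "T")]),
                 context = context),
            class = "base_composition")
}

#' @export
print.base_composition <- function(x, ...) {
  cat(sprintf("<base_composition: %s> A=%d C=%d G=%d T=%d other=%d\n",
              x$context, x$A, x$C, x$G, x$T, x$other))
  invisible(x)
}

#' AT/GC skew and A+T content of a base composition
#'
#' @param comp A [base_composition()] (or a mitogenome / DNA string, which is
#'   counted first).
#' @return A `skew_result` list: `at_skew`, `gc_skew` (dimensionless, `NA`
#'   when the denominator is zero) and `at_content` (percent of unambiguous
#'   bases).
#' @export
skew <- function(comp) {
  if (is.character(comp)) comp <- base_composition(comp)
  if (inherits(comp, "mitogenome")) comp <- base_composition(comp$sequence, "whole genome")
  at <- comp$A + comp$T
  gc <- comp$G + comp$C
  structure(list(
    at_skew = if (at == 0) NA_real_ else (comp$A - comp$T) / at,
    gc_skew = if (gc == 0) NA_real_ else (comp$G - comp$C) / gc,
    at_content = if (at + gc == 0) NA_real_ else 100 * at / (at + gc),
    context = comp$context), class = "skew_result")
}

#' @export
print.skew_result <- function(x, ...) {
  cat(sprintf("<skew: %s> AT%% = %.2f, AT-skew = %.2f, GC-skew = %.2f\n",
              x$context, x$at_content, x$at_skew, x$gc_skew))
  invisible(x)
}

#' Pooled base composition at the three codon positions
#'
#' @param cds_set Named list (or character vector) of in-frame coding
#'   sequences; each length must be divisible by 3 (strip incomplete stop
#'   bases first).
#' @return List of three [base_composition()] objects, one per codon position.
#' @export
codon_position_composition <- function(cds_set) {
  if (length(cds_set) == 0) stop("empty CDS set", call. = FALSE)
  cds_set <- as.list(cds_set)
  nm <- names(cds_set)
  if (is.null(nm)) nm <- paste0("cds", seq_along(cds_set))
  pooled <- c("", "", "")
  for (i in seq_along(cds_set)) {
    cds <- toupper(cds_set[[i]])
    if (nchar(cds) %% 3 != 0) {
      stop(sprintf("CDS '%s' has length %d, not divisible by 3", nm[i], nchar(cds)),
           call. = FALSE)
    }
    chars <- s2c(cds)
    for (p in 1:3) {
      pooled[p] <- paste0(pooled[p], c2s(chars[seq(p, length(chars), by = 3)]))
    }
  }
  lapply(1:3, function(p) base_composition(pooled[p], sprintf("codon position %d", p)))
}

#' Composition and skew report for a mitogenome
#'
#' One row per context: whole genome, pooled PCGs, each codon position of the
#' pooled PCGs, each rRNA, and the control region when annotated. The machine
#' twin of the usual AT%/skew comparison figures.
#'
#' @param genome A [mitogenome()].
#' @return data.frame with counts, A+T%, AT-skew and GC-skew per context.
#' @export
composition_report <- function(genome) {
  row <- function(comp) {
    sk <- skew(comp)
    data.frame(genome = genome$id, context = comp$context,
               A = comp$A, C = comp$C, G = comp$G, T = comp$T, other = comp$other,
               at_content = sk$at_content, at_skew = sk$at_skew,
               gc_skew = sk$gc_skew, stringsAsFactors = FALSE)
  }
  out <- list(row(base_composition(genome$sequence, "whole genome")))
  pcgs <- genome$features[genome$features$kind == "PCG", ]
  if (nrow(pcgs) > 0) {
    cds <- stats::setNames(
      lapply(pcgs$name, function(g) extract_gene_sequence(genome, g)), pcgs$name)
    out <- c(out, list(row(base_composition(paste(unlist(cds), collapse = ""), "PCGs"))))
    trimmed <- lapply(cds, function(s) substr(s, 1, nchar(s) - nchar(s) %% 3))
    out <- c(out, lapply(codon_position_composition(trimmed), row))
  }
  for (r in RRNA_NAMES) {
    if (r %in% genome$features$name) {
      out <- c(out, list(row(base_composition(extract_gene_sequence(genome, r), r))))
    }
  }
  if ("control_region" %in% genome$features$name) {
    out <- c(out, list(row(base_composition(
      extract_gene_sequence(genome, "control_region"), "control region"))))
  }
  do.call(rbind, out)
}
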