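# Low-level DNA string utilities shared across the package. Sequences are plain
# uppercase character scalars; positions are 0-based half-open internally.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V", "N")

s2c <- function(x) strsplit(x, "", fixed = TRUE)[[1]]
c2s <- function(x) paste(x, collapse = "")

#' Reverse complement of a DNA string
#'
#' IUPAC ambiguity codes are complemented; any other character is an error.
#'
#' @param seq DNA string.
#' @return The reverse complement as an uppercase string.
#' @export
revcomp <- function(seq) {
  seq <- toupper(seq)
  check_dna(seq)
  comp <- chartr("ACGTRYSWKMBDHVN", "TGCAYRSWMKVHDBN", seq)
  c2s(rev(s2c(comp)))
}

# Hard error naming the first offending position (1-based in the message).
check_dna <- function(seq, allow_gap = FALSE) {
  chars <- s2c(toupper(seq))
  ok <- chars %in% IUPAC_DNA
  if (allow_gap) ok <- ok | chars %in% c("-", "?")
  if (!all(ok)) {
    bad <- which(!ok)[1]
    stop(sprintf("non-IUPAC character '%s' at position %d", chars[bad], bad),
         call. = FALSE)
  }
  invisible(TRUE)
}

# Slice [start, end) with 0-based half-open coordinates; wraps around the
# origin when end > nchar(seq) and circular = TRUE.
slice_seq <- function(seq, start, end, circular = FALSE) {
  n <- nchar(seq)
  stopifnot(start >= 0, end > start)
  if (end <= n) return(substr(seq, start + 1, end))
  if (!circular) {
    stop(sprintf("slice [%d,%d) exceeds sequence length %d on a non-circular genome",
                 start, end, n), call. = FALSE)
  }
  if (end - start > n) stop("slice longer than the circular sequence", call. = FALSE)
  paste0(substr(seq, start + 1, n), substr(seq, 1, end - n))
}

split_codons <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3", call. = FALSE)
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, by = 3L), seq(3L, n, by = 3L))
}

is_transition <- function(a, b) {
  (a == "A" & b == "G") | (a == "G" & b == "A") |
    (a == "C" & b == "T") | (a == "T" & b == "C")
}

#' The invertebrate mitochondrial genetic code (translation table 5)
#'
#' Codon-to-amino-acid map as a named character vector of length 64 (DNA
#' alphabet, `*` for stop). Relative to the standard code: `TGA` is Trp,
#' `ATA` is Met, and `AGA`/`AGG` are Ser.
#'
#' @return Named character vector mapping codons to one-letter amino acids.
#' @export
mt_genetic_code <- function() {
  b <- c("T", "C", "A", "G")
  grid <- expand.grid(b3 = b, b2 = b, b1 = b, stringsAsFactors = FALSE)
  codons <- paste0(grid$b1, grid$b2, grid$b3)
  aas <- s2c(paste0(
    "FFLLSSSSYY**CCWW", # TTx TCx TAx TGx
    "LLLLPPPPHHQQRRRR", # CTx CCx CAx CGx
    "IIMMTTTTNNKKSSSS", # ATx ACx AAx AGx
    "VVVVAAAADDEEGGGG"  # GTx GCx GAx GGx
  ))
  stats::setNames(aas, codons)
}

# cached copy, built once per session
.mc_env <- new.env(parent = emptyenv())

gc5 <- function() {
  if (is.null(.mc_env$code)) .mc_env$code <- mt_genetic_code()
  .mc_env$code
}

mt_stop_codons <- function() names(gc5())[gc5() == "*"]

#' Synonymous codon families under the invertebrate mitochondrial code
#'
#' Families follow the usual mitochondrial convention of splitting the
#' six-fold amino acids: Leu1 = UUR, Leu2 = CUN, Ser1 = AGN, Ser2 = UCN.
#' Stop codons belong to no family.
#'
#' @return A data.frame with columns `codon` (DNA), `aa` and `family`.
#' @export
codon_families <- function() {
  code <- gc5()
  codons <- names(code)[code != "*"]
  aa <- code[codons]
  fam <- unname(aa)
  fam[codons %in% c("TTA", "TTG")] <- "Leu1"
  fam[substr(codons, 1, 2) == "CT"] <- "Leu2"
  fam[substr(codons, 1, 2) == "AG"] <- "Ser1"
  fam[substr(codons, 1, 2) == "TC"] <- "Ser2"
  long <- c(F = "Phe", Y = "Tyr", C = "Cys", W = "Trp", P = "Pro", H = "His",
            Q = "Gln", R = "Arg", I = "Ile", M = "Met", T = "Thr", N = "Asn",
            K = "Lys", V = "Val", A = "Ala", D = "Asp", E = "Glu", G = "Gly")
  plain <- fam %in% names(long)
  fam[plain] <- long[fam[plain]]
  data.frame(codon = codons, aa = unname(aa), family = fam,
             stringsAsFactors = FALSE)
}

#' Translate a coding sequence under the invertebrate mitochondrial code
#'
#' Ambiguous codons translate to `X`. Internal stop codons translate to `*`
#' and raise a warning (annotation errors surface without aborting a batch).
#'
#' @param cds In-frame DNA string, length divisible by 3.
#' @return Protein string (one-letter code, `*` for stops).
#' @export
mt_translate <- function(cds) {
  cds <- toupper(cds)
  codons <- split_codons(cds)
  code <- gc5()
  aa <- code[codons]
  aa[is.na(aa)] <- "X"
  if (length(aa) > 1 && any(aa[-length(aa)] == "*")) {
    warning("internal stop codon(s) at codon position(s) ",
            paste(which(aa[-length(aa)] == "*"), collapse = ", "),
            call. = FALSE)
  }
  c2s(aa)
}

dna_to_rna <- function(x) chartr("T", "U", x)
rna_to_dna <- function(x) chartr("U", "T", x)
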