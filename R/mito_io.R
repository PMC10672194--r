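# Annotated mitogenome container and I/O: single-record GenBank flatfiles and
# FASTA + TSV feature tables. Internally all coordinates are 0-based half-open;
# GenBank's 1-based inclusive coordinates are converted at the I/O boundary.
# end > sequence length encodes an origin-spanning feature on a circular genome.

PCG_NAMES <- c("atp6", "atp8", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6")
TRNA_NAMES <- paste0("trn", c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
                              "L1", "L2", "K", "M", "F", "P", "S1", "S2", "T",
                              "W", "Y", "V"))
RRNA_NAMES <- c("rrnS", "rrnL")
GENE_VOCAB <- c(PCG_NAMES, TRNA_NAMES, RRNA_NAMES, "control_region")

#' Construct a gene feature row
#'
#' @param name Canonical gene symbol (see [canonicalize_gene_name()]).
#' @param kind One of `"PCG"`, `"tRNA"`, `"rRNA"`, `"control_region"`.
#' @param start,end 0-based half-open coordinates; `end` may exceed the
#'   sequence length to encode an origin-spanning feature on a circular genome.
#' @param strand `"J"` (heavy/majority strand) or `"N"` (light strand).
#' @param anticodon Optional 3-mer (DNA alphabet) for tRNAs.
#' @return One-row data.frame usable in a mitogenome feature table.
#' @export
gene_feature <- function(name, kind, start, end, strand = "J", anticodon = NA_character_) {
  stopifnot(kind %in% c("PCG", "tRNA", "rRNA", "control_region"),
            strand %in% c("J", "N"))
  if (start >= end) stop(sprintf("%s: start (%d) must be < end (%d)", name, start, end),
                         call. = FALSE)
  len <- end - start
  if (kind == "PCG") {
    if (!name %in% PCG_NAMES) stop(sprintf("'%s' is not a PCG symbol", name), call. = FALSE)
    if (len < 3) stop(sprintf("%s: PCG shorter than one codon", name), call. = FALSE)
  }
  if (kind == "rRNA" && !name %in% RRNA_NAMES)
    stop(sprintf("'%s' is not an rRNA symbol", name), call. = FALSE)
  if (kind == "tRNA" && (len < 50 || len > 100))
    warning(sprintf("%s: tRNA length %d outside the usual 50-100 bp", name, len),
            call. = FALSE)
  data.frame(name = name, kind = kind, start = as.integer(start),
             end = as.integer(end), strand = strand,
             anticodon = toupper(anticodon), stringsAsFactors = FALSE)
}

#' Construct an annotated mitogenome
#'
#' @param id Record identifier.
#' @param organism Organism name.
#' @param sequence DNA string (uppercased on input).
#' @param circular Is the molecule circular?
#' @param complete Is the genome complete?
#' @param features data.frame of gene features (rows from [gene_feature()]).
#' @param warnings Character vector of loader warnings to carry along.
#' @return An object of class `mitogenome`.
#' @export
mitogenome <- function(id, organism, sequence, circular = TRUE, complete = TRUE,
                       features = NULL, warnings = character(0)) {
  sequence <- toupper(sequence)
  if (nchar(sequence) == 0) stop("missing sequence", call. = FALSE)
  check_dna(sequence)
  if (is.null(features)) {
    features <- data.frame(name = character(0), kind = character(0),
                           start = integer(0), end = integer(0),
                           strand = character(0), anticodon = character(0),
                           stringsAsFactors = FALSE)
  }
  dup <- features$name[duplicated(features$name)]
  if (length(dup) > 0) {
    stop("duplicate canonical gene name(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  features <- features[order(features$start), , drop = FALSE]
  rownames(features) <- NULL
  structure(list(id = id, organism = organism, sequence = sequence,
                 circular = isTRUE(circular), complete = isTRUE(complete),
                 features = features, warnings = warnings),
            class = "mitogenome")
}

#' @export
print.mitogenome <- function(x, ...) {
  cat(sprintf("<mitogenome> %s (%s)\n", x$id, x$organism))
  cat(sprintf("  %d bp, %s, %s\n", nchar(x$sequence),
              if (x$circular) "circular" else "linear",
              if (x$complete) "complete" else "partial"))
  tab <- table(factor(x$features$kind, levels = c("PCG", "tRNA", "rRNA", "control_region")))
  cat(sprintf("  features: %d PCG, %d tRNA, %d rRNA, %d control region\n",
              tab["PCG"], tab["tRNA"], tab["rRNA"], tab["control_region"]))
  invisible(x)
}

genome_length <- function(genome) nchar(genome$sequence)

get_feature <- function(genome, name) {
  i <- match(name, genome$features$name)
  if (is.na(i)) stop(sprintf("feature '%s' not found in %s", name, genome$id),
                     call. = FALSE)
  genome$features[i, , drop = FALSE]
}

#' Map a raw gene/product label to a canonical gene symbol
#'
#' Case and synonym variants collapse onto the 37-gene mitochondrial
#' vocabulary (`cox1`..`cox3`, `cob`, `nad1`..`nad6`, `nad4L`, `atp6`, `atp8`,
#' `rrnS`, `rrnL`, `trnX`, `control_region`). Leucine and serine tRNAs are
#' disambiguated by anticodon: trnL1 = CUN (anticodon UAG), trnL2 = UUR (UAA),
#' trnS1 = AGN (GCU/UCU), trnS2 = UCN (UGA); when no anticodon is given the
#' raw/product text is searched for an L1/L2/S1/S2 or codon-family tag.
#' Unresolvable labels return `"unknown"` with a warning, never a guess.
#'
#' @param raw Gene label as found in a GenBank record (e.g. `"COI"`, `"ND4L"`).
#' @param product Optional `/product` text (e.g. `"tRNA-Ser"`).
#' @param anticodon Optional anticodon 3-mer (RNA or DNA alphabet).
#' @return A canonical gene symbol, or `"unknown"`.
#' @export
canonicalize_gene_name <- function(raw, product = "", anticodon = NULL) {
  txt <- tolower(paste(raw, product))
  key <- gsub("[^a-z0-9]", "", tolower(raw))
  keys <- unique(c(key, gsub("[^a-z0-9]", "", tolower(product))))
  keys <- keys[nzchar(keys)]

  pcg_syn <- c(
    cox1 = "co1 coi cox1 coxi cytochromecoxidasesubuniti cytochromecoxidasesubunit1",
    cox2 = "co2 coii cox2 coxii cytochromecoxidasesubunitii cytochromecoxidasesubunit2",
    cox3 = "co3 coiii cox3 coxiii cytochromecoxidasesubunitiii cytochromecoxidasesubunit3",
    cob  = "cob cytb cytochromeb",
    nad1 = "nd1 nad1 nadhdehydrogenasesubunit1",
    nad2 = "nd2 nad2 nadhdehydrogenasesubunit2",
    nad3 = "nd3 nad3 nadhdehydrogenasesubunit3",
    nad4 = "nd4 nad4 nadhdehydrogenasesubunit4",
    nad4L = "nd4l nad4l nadhdehydrogenasesubunit4l",
    nad5 = "nd5 nad5 nadhdehydrogenasesubunit5",
    nad6 = "nd6 nad6 nadhdehydrogenasesubunit6",
    atp6 = "atp6 atpase6 atpsynthasef0subunit6 atpsynthasesubunit6",
    atp8 = "atp8 atpase8 atpsynthasef0subunit8 atpsynthasesubunit8")
  for (sym in names(pcg_syn)) {
    if (any(keys %in% strsplit(pcg_syn[[sym]], " ")[[1]])) return(sym)
  }

  if (any(keys %in% c("rrns", "12s", "12srrna", "srrna", "ssurrna",
                      "smallsubunitribosomalrna", "12sribosomalrna"))) return("rrnS")
  if (any(keys %in% c("rrnl", "16s", "16srrna", "lrrna", "lsurrna",
                      "largesubunitribosomalrna", "16sribosomalrna"))) return("rrnL")
  if (grepl("dloop|controlregion|atrichregion", gsub("[^a-z]", "", txt)))
    return("control_region")

  # tRNAs: accept trnX, trnX1/2, tRNA-Xxx forms
  aa3 <- c(ala = "A", arg = "R", asn = "N", asp = "D", cys = "C", glu = "E",
           gln = "Q", gly = "G", his = "H", ile = "I", leu = "L", lys = "K",
           met = "M", phe = "F", pro = "P", ser = "S", thr = "T", trp = "W",
           tyr = "Y", val = "V")
  letter <- NULL
  m <- regmatches(key, regexec("^trn([a-z])([12]?)$", key))[[1]]
  if (length(m) == 3 && m[2] != "") {
    letter <- toupper(m[2]); tag <- m[3]
  } else {
    tag <- ""
    m2 <- regmatches(txt, regexec("trna-?([a-z]{3})", txt))[[1]]
    if (length(m2) == 2 && m2[2] %in% names(aa3)) letter <- aa3[[m2[2]]]
  }
  if (!is.null(letter)) {
    if (!letter %in% c("L", "S")) {
      cand <- paste0("trn", letter)
      if (cand %in% TRNA_NAMES) return(cand)
    } else {
      if (tag %in% c("1", "2")) return(paste0("trn", letter, tag))
      ac <- if (is.null(anticodon) || is.na(anticodon) || !nzchar(anticodon)) NULL else
        rna_to_dna(toupper(anticodon))
      if (!is.null(ac)) {
        if (letter == "L" && ac == "TAG") return("trnL1")
        if (letter == "L" && ac == "TAA") return("trnL2")
        if (letter == "S" && ac %in% c("GCT", "TCT")) return("trnS1")
        if (letter == "S" && ac == "TGA") return("trnS2")
      }
      flat <- gsub("[^a-z0-9]", "", txt)
      if (letter == "L") {
        if (grepl("l1|cun", flat)) return("trnL1")
        if (grepl("l2|uur", flat)) return("trnL2")
      } else {
        if (grepl("s1|agn|agy", flat)) return("trnS1")
        if (grepl("s2|ucn", flat)) return("trnS2")
      }
    }
  }

  warning(sprintf("could not canonicalize gene label '%s'%s", raw,
                  if (nzchar(product)) sprintf(" (product '%s')", product) else ""),
          call. = FALSE)
  "unknown"
}

#' Extract the coding-sense sequence of a feature
#'
#' Slices `[start, end)` from the genome, wrapping around the origin when
#' `end` exceeds the sequence length on a circular genome, and
#' reverse-complements for N-strand features so the result reads 5'->3' in
#' coding orientation.
#'
#' @param genome A [mitogenome()].
#' @param feature A canonical gene name, or a one-row feature data.frame.
#' @return DNA string of length `end - start`.
#' @export
extract_gene_sequence <- function(genome, feature) {
  if (is.character(feature)) feature <- get_feature(genome, feature)
  s <- slice_seq(genome$sequence, feature$start, feature$end,
                 circular = genome$circular)
  if (feature$strand == "N") revcomp(s) else s
}

# ---- GenBank flatfile I/O ---------------------------------------------------

format_location <- function(start, end, strand, seqlen) {
  if (end <= seqlen) {
    loc <- sprintf("%d..%d", start + 1L, end)
  } else {
    loc <- sprintf("join(%d..%d,1..%d)", start + 1L, seqlen, end - seqlen)
  }
  if (strand == "N") loc <- sprintf("complement(%s)", loc)
  loc
}

parse_location <- function(loc, seqlen) {
  strand <- "J"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "N"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    rng <- lapply(parts, function(p) as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    if (length(rng) == 2 && rng[[1]][2] == seqlen && rng[[2]][1] == 1L) {
      return(list(start = rng[[1]][1] - 1L, end = seqlen + rng[[2]][2], strand = strand))
    }
    stop("unsupported join() location: ", loc, call. = FALSE)
  }
  ab <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  list(start = ab[1] - 1L, end = ab[2], strand = strand)
}

#' Write a mitogenome as a single-record GenBank flatfile
#'
#' @param genome A [mitogenome()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_genbank <- function(genome, path) {
  n <- genome_length(genome)
  lines <- character(0)
  lines <- c(lines, sprintf("LOCUS       %-16s %d bp    DNA     %-8s INV 01-JAN-2026",
                            genome$id, n, if (genome$circular) "circular" else "linear"))
  lines <- c(lines, sprintf("DEFINITION  %s mitochondrion, %s genome.",
                            genome$organism,
                            if (genome$complete) "complete" else "partial"))
  lines <- c(lines, sprintf("ACCESSION   %s", genome$id))
  lines <- c(lines, sprintf("SOURCE      %s", genome$organism))
  lines <- c(lines, sprintf("  ORGANISM  %s", genome$organism))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  lines <- c(lines, sprintf("     source          1..%d", n))
  lines <- c(lines, sprintf("                     /organism=\"%s\"", genome$organism))
  q <- function(k, v) sprintf("                     /%s=\"%s\"", k, v)
  fts <- genome$features
  if (nrow(fts) > 0) {
    for (i in seq_len(nrow(fts))) {
      f <- fts[i, ]
      key <- switch(f$kind, PCG = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                    control_region = "misc_feature")
      loc <- format_location(f$start, f$end, f$strand, n)
      lines <- c(lines, sprintf("     %-15s %s", key, loc))
      lines <- c(lines, q("gene", f$name))
      if (f$kind == "tRNA" && !is.na(f$anticodon)) {
        lines <- c(lines, q("note", sprintf("anticodon:%s", f$anticodon)))
      }
      if (f$kind == "control_region") {
        lines <- c(lines, q("note", "control region"))
      }
    }
  }
  lines <- c(lines, "ORIGIN")
  seq <- tolower(genome$sequence)
  for (off in seq(1L, n, by = 60L)) {
    chunk <- substr(seq, off, min(off + 59L, n))
    groups <- substring(chunk, seq(1, nchar(chunk), 10), pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", off, paste(groups, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a single-record GenBank flatfile into a mitogenome
#'
#' CDS, tRNA, rRNA and misc_feature/D-loop entries are mapped onto canonical
#' gene features; unmapped features are collected in the returned object's
#' `warnings`. Circularity is taken from the LOCUS line, the organism from the
#' ORGANISM line, completeness from the DEFINITION line.
#'
#' @param path Path to a GenBank flatfile containing one record.
#' @return A [mitogenome()].
#' @export
read_genbank <- function(path) {
  lines <- readLines(path, warn = FALSE)
  locus <- grep("^LOCUS", lines, value = TRUE)
  if (length(locus) == 0) stop("not a GenBank flatfile: no LOCUS line", call. = FALSE)
  toks <- strsplit(trimws(locus[1]), "\\s+")[[1]]
  id <- toks[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))
  defline <- grep("^DEFINITION", lines, value = TRUE)
  complete <- length(defline) == 0 || grepl("complete", defline[1], ignore.case = TRUE)
  orgline <- grep("^  ORGANISM", lines, value = TRUE)
  organism <- if (length(orgline) > 0) trimws(sub("^  ORGANISM", "", orgline[1])) else id

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0) stop("missing sequence: no ORIGIN section", call. = FALSE)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec) > 0) endrec[1] else length(lines) + 1L
  seq_lines <- lines[(ori[1] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0) stop("missing sequence", call. = FALSE)
  n <- nchar(sequence)

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  warnings <- character(0)
  if (length(fstart) > 0) {
    block <- lines[(fstart[1] + 1L):(ori[1] - 1L)]
    # group physical lines into features: a new feature starts with 5 spaces + key
    idx <- grep("^     \\S", block)
    for (k in seq_along(idx)) {
      from <- idx[k]
      to <- if (k < length(idx)) idx[k + 1] - 1L else length(block)
      chunk <- block[from:to]
      key <- sub("^\\s*(\\S+).*$", "\\1", chunk[1])
      if (key == "source") next
      rest <- trimws(sub("^\\s*\\S+\\s*", "", chunk[1]))
      body <- chunk[-1]
      # location may wrap before the first qualifier line
      qual_at <- grep("^\\s+/", body)
      loc_extra <- if (length(qual_at) > 0 && qual_at[1] > 1) body[1:(qual_at[1] - 1)] else
        if (length(qual_at) == 0) body else character(0)
      loc <- paste0(rest, paste(trimws(loc_extra), collapse = ""))
      quals <- body[grep("^\\s+/", body)]
      getq <- function(name) {
        hit <- grep(sprintf("^\\s+/%s=", name), quals, value = TRUE)
        if (length(hit) == 0) return("")
        gsub("\"", "", sub(sprintf("^\\s+/%s=", name), "", hit[1]))
      }
      gene <- getq("gene"); product <- getq("product"); note <- getq("note")
      anticodon <- NA_character_
      acm <- regmatches(note, regexec("anticodon:([A-Za-z]{3})", note))[[1]]
      if (length(acm) == 2) anticodon <- toupper(acm[2])
      acq <- getq("anticodon")
      if (is.na(anticodon) && nzchar(acq)) {
        acs <- regmatches(acq, regexec("seq:([A-Za-z]{3})", acq))[[1]]
        if (length(acs) == 2) anticodon <- toupper(acs[2])
      }
      if (!key %in% c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")) {
        warnings <- c(warnings, sprintf("unmapped feature type '%s' at %s", key, loc))
        next
      }
      pos <- parse_location(loc, n)
      kind <- switch(key, CDS = "PCG", tRNA = "tRNA", rRNA = "rRNA",
                     misc_feature = "control_region", `D-loop` = "control_region")
      if (key == "misc_feature" &&
          !grepl("control region|d-loop|at-rich", tolower(paste(gene, note, product)))) {
        warnings <- c(warnings, sprintf("unmapped misc_feature at %s", loc))
        next
      }
      raw_name <- if (nzchar(gene)) gene else product
      name <- if (kind == "control_region") "control_region" else
        withCallingHandlers(
          canonicalize_gene_name(raw_name, product, anticodon),
          warning = function(w) {
            warnings <<- c(warnings, conditionMessage(w))
            invokeRestart("muffleWarning")
          })
      if (name == "unknown") {
        warnings <- c(warnings, sprintf("feature '%s' left unmapped", raw_name))
        next
      }
      feats[[length(feats) + 1L]] <-
        gene_feature(name, kind, pos$start, pos$end, pos$strand, anticodon)
    }
  }
  features <- if (length(feats) > 0) do.call(rbind, feats) else NULL
  mitogenome(id, organism, sequence, circular, complete, features, warnings)
}

# ---- FASTA + TSV feature table ----------------------------------------------

#' Write a mitogenome as FASTA plus a TSV feature table
#'
#' @param genome A [mitogenome()].
#' @param fasta_path,features_path Output paths.
#' @return `fasta_path`, invisibly.
#' @export
write_fasta_genome <- function(genome, fasta_path, features_path) {
  seq <- genome$sequence
  chunks <- substring(seq, seq(1, nchar(seq), 70), pmin(seq(70, nchar(seq) + 69, 70), nchar(seq)))
  writeLines(c(sprintf(">%s %s", genome$id, genome$organism), chunks), fasta_path)
  hdr <- c(sprintf("#id=%s", genome$id),
           sprintf("#organism=%s", genome$organism),
           sprintf("#circular=%s", genome$circular),
           sprintf("#complete=%s", genome$complete),
           paste(c("name", "kind", "start", "end", "strand", "anticodon"), collapse = "\t"))
  rows <- apply(genome$features, 1, function(r) paste(r, collapse = "\t"))
  writeLines(c(hdr, rows), features_path)
  invisible(fasta_path)
}

#' Read a mitogenome from FASTA plus a TSV feature table
#'
#' @param fasta_path FASTA file with a single sequence.
#' @param features_path TSV with columns name, kind, start, end, strand,
#'   anticodon (0-based half-open coordinates) and optional `#id=`,
#'   `#organism=`, `#circular=`, `#complete=` header comments.
#' @return A [mitogenome()].
#' @export
read_fasta_genome <- function(fasta_path, features_path) {
  lines <- readLines(fasta_path, warn = FALSE)
  hdr_i <- grep("^>", lines)
  if (length(hdr_i) != 1) stop("expected exactly one FASTA record", call. = FALSE)
  hdr <- sub("^>", "", lines[hdr_i])
  id <- strsplit(hdr, "\\s+")[[1]][1]
  organism <- trimws(sub("^\\S+\\s*", "", hdr))
  if (!nzchar(organism)) organism <- id
  sequence <- toupper(paste(lines[-seq_len(hdr_i)], collapse = ""))

  flines <- readLines(features_path, warn = FALSE)
  meta <- grep("^#", flines, value = TRUE)
  getmeta <- function(k, default) {
    hit <- grep(sprintf("^#%s=", k), meta, value = TRUE)
    if (length(hit) == 0) default else sub(sprintf("^#%s=", k), "", hit[1])
  }
  id <- getmeta("id", id)
  organism <- getmeta("organism", organism)
  circular <- as.logical(getmeta("circular", "TRUE"))
  complete <- as.logical(getmeta("complete", "TRUE"))
  tab <- utils::read.delim(text = flines[!grepl("^#", flines)], sep = "\t",
                           stringsAsFactors = FALSE)
  feats <- do.call(rbind, lapply(seq_len(nrow(tab)), function(i) {
    gene_feature(tab$name[i], tab$kind[i], tab$start[i], tab$end[i],
                 tab$strand[i], as.character(tab$anticodon[i]))
  }))
  mitogenome(id, organism, sequence, circular, complete, feats)
}

#' Strand usage summary of a mitogenome
#'
#' Reports how many genes of each kind sit on the J (heavy/majority) and N
#' (light) strands. For complete lacewing-like mitogenomes, the expected
#' partition is 9 PCGs + 14 tRNAs on J and 4 PCGs + 8 tRNAs + 2 rRNAs on N;
#' the comparison is emitted as a report row, never enforced.
#'
#' @param genome A [mitogenome()].
#' @return data.frame with one row per (kind, strand) and a `matches_typical`
#'   attribute.
#' @export
strand_report <- function(genome) {
  f <- genome$features[genome$features$kind != "control_region", ]
  out <- as.data.frame(table(kind = f$kind, strand = f$strand),
                       stringsAsFactors = FALSE)
  names(out)[3] <- "n"
  cnt <- function(kind, strand) sum(f$kind == kind & f$strand == strand)
  attr(out, "matches_typical") <-
    cnt("PCG", "J") == 9 && cnt("tRNA", "J") == 14 &&
    cnt("PCG", "N") == 4 && cnt("tRNA", "N") == 8 && cnt("rRNA", "N") == 2
  out
}
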