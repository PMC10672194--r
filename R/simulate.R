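# Seeded simulator for annotated insect mitogenomes evolved along a
# phylogeny with known parameters. The ancestral genome is drawn from
# composition targets over a 37-gene lacewing-like gene order; protein-coding
# genes then evolve under a rejection-sampled codon scheme (proposed
# mutations follow target base frequencies with a kappa transition bias;
# proposals creating stops are rejected, nonsynonymous proposals are accepted
# with probability omega), and RNAs/control region evolve under the same
# HKY-style nucleotide scheme with all proposals accepted. Gene order,
# overlaps, incomplete stop codons and planted control-region repeats are
# preserved by construction (their sites are frozen). No indels are
# simulated, so per-gene alignments across taxa are exact by construction.

BASES <- c("A", "C", "G", "T")

default_gene_table <- function() {
  pcg <- function(name, len, strand, start_codon = "ATG", stop = "TAA",
                  omega = 0.2, rate = 1) {
    data.frame(name = name, kind = "PCG", length = len, strand = strand,
               anticodon = NA_character_, start_codon = start_codon,
               stop = stop, omega = omega, rate = rate, stringsAsFactors = FALSE)
  }
  trna <- function(name, strand, anticodon) {
    data.frame(name = name, kind = "tRNA", length = 63L, strand = strand,
               anticodon = anticodon, start_codon = NA, stop = NA,
               omega = NA_real_, rate = 1, stringsAsFactors = FALSE)
  }
  rrna <- function(name, len, strand) {
    data.frame(name = name, kind = "rRNA", length = len, strand = strand,
               anticodon = NA, start_codon = NA, stop = NA,
               omega = NA_real_, rate = 0.7, stringsAsFactors = FALSE)
  }
  rbind(
    trna("trnI", "J", "GAT"), trna("trnQ", "N", "TTG"), trna("trnM", "J", "CAT"),
    pcg("nad2", 1023L, "J", "ATT", omega = 0.30),
    trna("trnW", "J", "TCA"), trna("trnC", "N", "GCA"), trna("trnY", "N", "GTA"),
    pcg("cox1", 1536L, "J", omega = 0.05, rate = 0.8),
    trna("trnL2", "J", "TAA"),
    pcg("cox2", 687L, "J", omega = 0.10),
    trna("trnK", "J", "CTT"), trna("trnD", "J", "GTC"),
    pcg("atp8", 162L, "J", "ATT", omega = 0.55, rate = 1.4),
    pcg("atp6", 678L, "J", omega = 0.25),
    pcg("cox3", 789L, "J", omega = 0.12),
    trna("trnG", "J", "TCC"),
    pcg("nad3", 354L, "J", "ATT", omega = 0.25),
    trna("trnA", "J", "TGC"), trna("trnR", "J", "TCG"), trna("trnN", "J", "GTT"),
    trna("trnS1", "J", "GCT"), trna("trnE", "J", "TTC"), trna("trnF", "N", "GAA"),
    pcg("nad5", 1720L, "N", "ATT", stop = "T", omega = 0.20),
    trna("trnH", "N", "GTG"),
    pcg("nad4", 1341L, "N", omega = 0.22),
    pcg("nad4L", 297L, "N", omega = 0.25),
    trna("trnT", "J", "TGT"), trna("trnP", "N", "TGG"),
    pcg("nad6", 525L, "J", "ATT", omega = 0.35, rate = 1.3),
    pcg("cob", 1140L, "J", omega = 0.12),
    trna("trnS2", "J", "TGA"),
    pcg("nad1", 942L, "N", omega = 0.15),
    trna("trnL1", "N", "TAG"),
    rrna("rrnL", 1310L, "N"),
    trna("trnV", "N", "TAC"),
    rrna("rrnS", 780L, "N"),
    data.frame(name = "control_region", kind = "control_region", length = 2000L,
               strand = "J", anticodon = NA, start_codon = NA, stop = NA,
               omega = NA_real_, rate = 0.5, stringsAsFactors = FALSE))
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of complete lacewing mitogenomes:
#' a 37-gene order with 9 PCGs + 14 tRNAs on the J strand, ~80% A+T overall
#' with a strongly AT-rich third codon position and control region, purifying
#' selection on all PCGs (omega well below 1, strongest on cox1, weakest on
#' atp8), 7-nt ATGATAA/ATGTTAA overlaps at atp8-atp6 and nad4-nad4L, a
#' single-base overlap at atp6-cox3, an incomplete T stop on nad5, and a
#' control region carrying a (TA)12 microsatellite, a 250-bp tandem
#' duplication and a T-run.
#'
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @param tree Rooted `phylo` with branch lengths in expected proposed
#'   mutations/site; default is a 6-taxon coalescent clock tree of depth
#'   `tree_depth`.
#' @param n_taxa,tree_depth Used only when `tree` is NULL.
#' @param genes Per-gene table (see `mitocomp:::default_gene_table`).
#' @param kappa Transition/transversion proposal bias.
#' @param pcg3_freq Base frequencies at third codon positions (named A/C/G/T).
#' @param pcg12_freq Base frequencies at first+second codon positions.
#' @param rna_freq,cr_freq Base frequencies for RNAs / control region.
#' @param cr_length Control region length (bp).
#' @param plant Plant overlaps/repeats/incomplete stops (TRUE for the
#'   standard study conditions).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, tree = NULL, n_taxa = 6, tree_depth = 0.05,
                       genes = default_gene_table(), kappa = 2,
                       pcg3_freq = c(A = 0.46, C = 0.06, G = 0.06, T = 0.42),
                       pcg12_freq = c(A = 0.33, C = 0.11, G = 0.14, T = 0.42),
                       rna_freq = c(A = 0.43, C = 0.07, G = 0.09, T = 0.41),
                       cr_freq = c(A = 0.46, C = 0.055, G = 0.055, T = 0.43),
                       cr_length = 2000L, plant = TRUE) {
  norm <- function(f) f[BASES] / sum(f)
  genes$length[genes$name == "control_region"] <- as.integer(cr_length)
  structure(list(seed = as.integer(seed), tree = tree, n_taxa = n_taxa,
                 tree_depth = tree_depth, genes = genes, kappa = kappa,
                 pcg3_freq = norm(pcg3_freq), pcg12_freq = norm(pcg12_freq),
                 rna_freq = norm(rna_freq), cr_freq = norm(cr_freq),
                 cr_length = as.integer(cr_length), plant = isTRUE(plant)),
            class = "sim_config")
}

sample_bases <- function(n, freq) {
  if (n <= 0) return(character(0))
  sample(BASES, n, replace = TRUE, prob = freq)
}

# a random sense (non-stop) codon honouring position-specific targets
sample_sense_codons <- function(n, f12, f3) {
  if (n <= 0) return(character(0))
  out <- character(n)
  filled <- 0L
  code <- gc5()
  while (filled < n) {
    m <- n - filled
    cand <- paste0(sample_bases(m, f12), sample_bases(m, f12), sample_bases(m, f3))
    ok <- code[cand] != "*"
    k <- sum(ok)
    if (k > 0) out[(filled + 1):(filled + k)] <- cand[ok]
    filled <- filled + k
  }
  out
}

build_pcg_seq <- function(len, start_codon, stop, f12, f3) {
  rem <- len %% 3L
  ncod <- len %/% 3L
  if (rem == 0L) {
    body <- sample_sense_codons(ncod - 2L, f12, f3)
    seq <- paste0(start_codon, c2s(body), "TAA")
  } else {
    body <- sample_sense_codons(ncod - 1L, f12, f3)
    seq <- paste0(start_codon, c2s(body), if (rem == 1L) "T" else "TA")
  }
  stopifnot(nchar(seq) == len)
  seq
}

# canonical cloverleaf tRNA, 63 nt; trnS2-style builds lack the D-arm stem.
# Returns the sequence and the coding positions of the anticodon.
build_trna_seq <- function(anticodon, d_arm = TRUE) {
  pairable <- function(n) {
    # AT-rich stem halves; complement gives perfect pairing
    s <- sample(c("A", "T", "G", "C"), n, replace = TRUE,
                prob = c(0.3, 0.3, 0.2, 0.2))
    c2s(s)
  }
  comp <- function(s) c2s(rev(s2c(chartr("ACGT", "TGCA", s))))
  acc <- pairable(7)
  dstem <- pairable(4)
  acs <- pairable(5)
  tstem <- pairable(5)
  loop_fill <- function(n) c2s(sample(c("A", "T"), n, replace = TRUE))
  d_section <- if (d_arm) {
    paste0(dstem, loop_fill(5), comp(dstem))
  } else {
    c2s(sample(c("T", "C"), 13, replace = TRUE))  # unpairable simple loop
  }
  ac_loop <- paste0(loop_fill(2), anticodon, loop_fill(2))
  seq <- paste0(acc, "TA", d_section, "A", acs, ac_loop, comp(acs),
                "A", tstem, loop_fill(5), comp(tstem), comp(acc))
  stopifnot(nchar(seq) == 63)
  list(seq = seq, anticodon_pos = (7 + 2 + 13 + 1 + 5 + 2) + 1:3)
}

build_cr_seq <- function(len, freq, plant = TRUE) {
  seq <- c2s(sample_bases(len, freq))
  planted <- list()
  if (plant && len >= 1200) {
    ms <- paste(rep("TA", 12), collapse = "")
    seq <- paste0(substr(seq, 1, 100), ms, substr(seq, 101 + nchar(ms), len))
    planted$microsatellite <- list(start = 100L, motif = "AT", copies = 12L,
                                   length = nchar(ms))
    unit <- c2s(sample_bases(250, freq))
    dup <- paste0(unit, unit)
    seq <- paste0(substr(seq, 1, 400), dup, substr(seq, 401 + nchar(dup), len))
    planted$long_repeat <- list(start = 400L, copy_length = 250L)
    trun <- paste(rep("T", 10), collapse = "")
    seq <- paste0(substr(seq, 1, 950), trun, substr(seq, 961, len))
    planted$t_run <- list(start = 950L, length = 10L)
  }
  stopifnot(nchar(seq) == len)
  list(seq = seq, planted = planted)
}

# Overlap plan: left/right genes in genomic order, length, and the motif in
# coding orientation. For J/J pairs the motif sits at the left gene's coding
# end and the right gene's coding start; for N/N pairs the roles flip.
overlap_plan <- function() {
  data.frame(left = c("atp8", "atp6", "nad4"),
             right = c("atp6", "cox3", "nad4L"),
             length = c(7L, 1L, 7L),
             motif = c("ATGATAA", "A", "ATGTTAA"),
             stringsAsFactors = FALSE)
}

ur_plan <- function() {
  data.frame(after = c("trnQ", "trnC", "trnS1"),
             length = c(3L, 45L, 17L), stringsAsFactors = FALSE)
}

# plant a coding-orientation motif at the start or end of a coding sequence,
# repairing any internal stop codon the overwrite creates (first base -> C)
plant_motif <- function(seq, motif, where = c("start", "end")) {
  where <- match.arg(where)
  L <- nchar(seq)
  k <- nchar(motif)
  if (where == "start") {
    seq <- paste0(motif, substr(seq, k + 1, L))
  } else {
    seq <- paste0(substr(seq, 1, L - k), motif)
  }
  full <- L - L %% 3L
  codons <- split_codons(substr(seq, 1, full))
  stops <- which(codons %in% mt_stop_codons())
  stops <- stops[stops < length(codons)]
  for (i in stops) {
    pos <- (i - 1L) * 3L + 1L
    substr(seq, pos, pos) <- "C"
  }
  seq
}

# frozen coding positions for a PCG: start codon, stop region, planted motifs
pcg_frozen_mask <- function(len, stop, extra_start = 0L, extra_end = 0L) {
  mask <- rep(FALSE, len)
  mask[1:max(3L, extra_start)] <- TRUE
  rem <- len %% 3L
  tail_len <- if (rem == 0L) 3L else rem
  mask[(len - max(tail_len, extra_end) + 1L):len] <- TRUE
  mask
}

# one proposed mutation: new base drawn with target-frequency x kappa weights
propose_base <- function(ref, freq, kappa) {
  alts <- setdiff(BASES, ref)
  w <- freq[alts] * ifelse(is_transition(rep(ref, 3), alts), kappa, 1)
  sample(alts, 1, prob = w)
}

# evolve one gene's coding sequence along one branch; returns sequence and
# number of accepted substitutions
evolve_gene_branch <- function(seq, kind, omega, rate, bl, frozen, freqs, kappa) {
  chars <- s2c(seq)
  L <- length(chars)
  free <- which(!frozen)
  if (length(free) == 0 || bl <= 0) return(list(seq = seq, nsub = 0L))
  nmut <- stats::rpois(1, bl * rate * L)
  nsub <- 0L
  code <- gc5()
  full <- L - L %% 3L
  for (k in seq_len(nmut)) {
    pos <- free[sample.int(length(free), 1)]
    if (kind == "PCG" && pos <= full) {
      f <- if (pos %% 3L == 0L) freqs$p3 else freqs$p12
      newb <- propose_base(chars[pos], f, kappa)
      ci <- (pos - 1L) %/% 3L
      cod <- c2s(chars[(ci * 3L + 1L):(ci * 3L + 3L)])
      newcod <- cod
      substr(newcod, (pos - 1L) %% 3L + 1L, (pos - 1L) %% 3L + 1L) <- newb
      if (code[[newcod]] == "*") next
      if (code[[newcod]] != code[[cod]] && stats::runif(1) > omega) next
      chars[pos] <- newb
      nsub <- nsub + 1L
    } else {
      f <- freqs$bg
      chars[pos] <- propose_base(chars[pos], f, kappa)
      nsub <- nsub + 1L
    }
  }
  list(seq = c2s(chars), nsub = nsub)
}

#' Simulate annotated mitogenomes along a phylogeny
#'
#' See [sim_config()] for the study conditions the defaults encode. The
#' result is fully deterministic given the config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genomes` (list of [mitogenome()], one per tip) and
#'   `truth` (generating tree, per-gene parameters, per-branch realized
#'   substitution counts, planted-feature registry, ancestral proteins).
#' @export
simulate_mitogenomes <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tree <- config$tree
  if (is.null(tree)) {
    tree <- ape::rcoal(config$n_taxa, tip.label = paste0("sim", seq_len(config$n_taxa)))
    tree$edge.length <- tree$edge.length / max(ape::node.depth.edgelength(tree)) *
      config$tree_depth
  }
  if (!ape::is.rooted(tree)) stop("simulation tree must be rooted", call. = FALSE)
  if (any(tree$edge.length * max(config$genes$rate, na.rm = TRUE) > 2)) {
    warning("very long branch(es): most sites will saturate", call. = FALSE)
  }

  genes <- config$genes
  plan <- if (config$plant) overlap_plan() else overlap_plan()[0, ]
  urs <- if (config$plant) ur_plan() else ur_plan()[0, ]

  # ---- ancestral coding sequences ----
  anc <- list(); frozen <- list(); anticodon_pos <- list(); cr_planted <- list()
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    if (g$kind == "PCG") {
      stop_spec <- g$stop
      seq <- build_pcg_seq(g$length, g$start_codon, stop_spec,
                           config$pcg12_freq, config$pcg3_freq)
      anc[[g$name]] <- seq
      frozen[[g$name]] <- pcg_frozen_mask(g$length, stop_spec)
    } else if (g$kind == "tRNA") {
      tr <- build_trna_seq(g$anticodon, d_arm = g$name != "trnS2")
      anc[[g$name]] <- tr$seq
      fz <- rep(FALSE, 63L); fz[tr$anticodon_pos] <- TRUE
      frozen[[g$name]] <- fz
    } else if (g$kind == "rRNA") {
      anc[[g$name]] <- c2s(sample_bases(g$length, config$rna_freq))
      frozen[[g$name]] <- rep(FALSE, g$length)
    } else {
      cr <- build_cr_seq(g$length, config$cr_freq, plant = config$plant)
      anc[[g$name]] <- cr$seq
      fz <- rep(FALSE, g$length)
      for (p in cr$planted) fz[(p$start + 1L):(p$start + (p$length %||% (2 * p$copy_length)))] <- TRUE
      frozen[[g$name]] <- fz
      cr_planted <- cr$planted
    }
  }

  # ---- plant overlap motifs and freeze them ----
  strand_of <- stats::setNames(genes$strand, genes$name)
  for (i in seq_len(nrow(plan))) {
    p <- plan[i, ]
    k <- p$length
    if (strand_of[p$left] == "J") {
      anc[[p$left]] <- plant_motif(anc[[p$left]], p$motif, "end")
      anc[[p$right]] <- plant_motif(anc[[p$right]], p$motif, "start")
      nL <- nchar(anc[[p$left]])
      frozen[[p$left]][(nL - k + 1L):nL] <- TRUE
      frozen[[p$right]][1:k] <- TRUE
    } else {
      anc[[p$left]] <- plant_motif(anc[[p$left]], p$motif, "start")
      anc[[p$right]] <- plant_motif(anc[[p$right]], p$motif, "end")
      nR <- nchar(anc[[p$right]])
      frozen[[p$left]][1:k] <- TRUE
      frozen[[p$right]][(nR - k + 1L):nR] <- TRUE
    }
  }

  ur_seqs <- stats::setNames(
    lapply(urs$length, function(n) c2s(sample_bases(n, config$cr_freq))),
    urs$after)

  # ---- evolve along the tree ----
  ntip <- length(tree$tip.label)
  ord <- ape::reorder.phylo(tree, "postorder")
  edge_order <- rev(seq_len(nrow(ord$edge)))  # preorder over edges
  node_seqs <- vector("list", ntip + tree$Nnode)
  node_seqs[[ntip + 1L]] <- anc
  branch_subs <- numeric(nrow(ord$edge))
  freqs_for <- function(kind) {
    list(p12 = config$pcg12_freq, p3 = config$pcg3_freq,
         bg = if (kind == "control_region") config$cr_freq else config$rna_freq)
  }
  for (e in edge_order) {
    parent <- ord$edge[e, 1]; child <- ord$edge[e, 2]
    bl <- ord$edge.length[e]
    cur <- node_seqs[[parent]]
    total <- 0L
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      ev <- evolve_gene_branch(cur[[g$name]], g$kind,
                               omega = if (is.na(g$omega)) 1 else g$omega,
                               rate = g$rate, bl = bl,
                               frozen = frozen[[g$name]],
                               freqs = freqs_for(g$kind), kappa = config$kappa)
      cur[[g$name]] <- ev$seq
      total <- total + ev$nsub
    }
    node_seqs[[child]] <- cur
    branch_subs[e] <- total
  }

  # ---- assemble genomes ----
  assemble <- function(seqs, id, organism) {
    pieces <- character(0)
    feats <- list()
    pos <- 0L
    ov_after <- stats::setNames(plan$length, plan$left)
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      seg <- if (g$strand == "N") revcomp(seqs[[g$name]]) else seqs[[g$name]]
      k <- if (i > 1 && genes$name[i - 1] %in% names(ov_after))
        ov_after[[genes$name[i - 1]]] else 0L
      if (k > 0L) {
        prev_tail <- substr(pieces[length(pieces)],
                            nchar(pieces[length(pieces)]) - k + 1L,
                            nchar(pieces[length(pieces)]))
        stopifnot(substr(seg, 1, k) == prev_tail)
        seg_add <- substr(seg, k + 1L, nchar(seg))
        start <- pos - k
      } else {
        seg_add <- seg
        start <- pos
      }
      pieces <- c(pieces, seg_add)
      pos <- start + nchar(seqs[[g$name]])
      feats[[length(feats) + 1L]] <-
        gene_feature(g$name, g$kind, start, pos, g$strand,
                     if (g$kind == "tRNA") g$anticodon else NA_character_)
      if (g$name %in% names(ur_seqs)) {
        pieces <- c(pieces, ur_seqs[[g$name]])
        pos <- pos + nchar(ur_seqs[[g$name]])
      }
    }
    mitogenome(id, organism, paste(pieces, collapse = ""),
               circular = TRUE, complete = TRUE,
               features = do.call(rbind, feats))
  }

  genomes <- lapply(seq_len(ntip), function(t) {
    assemble(node_seqs[[t]], tree$tip.label[t],
             paste("Simulated lacewing", tree$tip.label[t]))
  })
  names(genomes) <- tree$tip.label

  pcgs <- genes$name[genes$kind == "PCG"]
  anc_proteins <- stats::setNames(lapply(pcgs, function(g) {
    s <- anc[[g]]
    suppressWarnings(mt_translate(substr(s, 1, nchar(s) - nchar(s) %% 3L)))
  }), pcgs)

  truth <- list(tree = tree, genes = genes,
                branch_substitutions = data.frame(
                  parent = ord$edge[, 1], child = ord$edge[, 2],
                  length = ord$edge.length, substitutions = branch_subs),
                planted = list(overlaps = plan, urs = urs,
                               incomplete_stops = genes$name[!is.na(genes$stop) &
                                                               genes$stop != "TAA"],
                               control_region = cr_planted),
                ancestral_proteins = anc_proteins,
                seed = config$seed, config = config)
  list(genomes = genomes, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Per-gene alignments from a set of simulated (indel-free) genomes
#'
#' Extracts each gene's coding sequence from every genome; since the
#' simulator introduces no indels these are exact alignments. Codon
#' alignments are trimmed of trailing incomplete-stop bases.
#'
#' @param genomes List of [mitogenome()]s with identical annotations.
#' @param kinds Feature kinds to include.
#' @return Named list of [gene_alignment()]s.
#' @export
genome_set_alignments <- function(genomes, kinds = c("PCG", "rRNA")) {
  stopifnot(length(genomes) >= 2)
  taxa <- vapply(genomes, function(g) g$id, "")
  fts <- genomes[[1]]$features
  fts <- fts[fts$kind %in% kinds, , drop = FALSE]
  alns <- lapply(seq_len(nrow(fts)), function(i) {
    f <- fts[i, ]
    seqs <- vapply(genomes, function(g) extract_gene_sequence(g, f$name), "")
    if (f$kind == "PCG") {
      seqs <- substr(seqs, 1, nchar(seqs) - nchar(seqs) %% 3L)
    }
    gene_alignment(f$name, taxa, unname(seqs), is_codon = f$kind == "PCG")
  })
  stats::setNames(alns, fts$name)
}

#' Deterministic fixture genome carrying every architectural edge case
#'
#' One complete circular genome built for testing: ATGTTAA overlap at
#' nad4-nad4L, ATGATAA at atp8-atp6, a single shared 'A' at atp6-cox3, an
#' incomplete T stop on nad5 completed by the following tRNA, a control
#' region with a (TA)12 microsatellite, a 250-bp tandem duplication and a
#' T-run, and a trnS2 whose D-arm is a simple loop. To keep all three
#' planted overlap 7-mers literal J-strand slices, nad4/nad4L (and nad5 with
#' its downstream trnH) sit on the J strand here, unlike their usual
#' light-strand orientation; a handful of tRNAs keep the N strand so
#' reverse-complement extraction stays exercised.
#'
#' @param seed Integer seed.
#' @return A [mitogenome()].
#' @export
make_fixture_genome <- function(seed = 1) {
  genes <- default_gene_table()
  genes$strand <- ifelse(genes$name %in% c("trnQ", "trnC", "trnY"), "N", "J")
  genes$length[genes$name == "control_region"] <- 1300L
  cfg <- sim_config(seed = seed, genes = genes, cr_length = 1300L,
                    tree = ape::read.tree(text = "(fixture:0,x:0);"))
  sim <- simulate_mitogenomes(cfg)
  g <- sim$genomes[["fixture"]]
  g$id <- "FIXTURE1"
  g$organism <- "Synthetic lacewing fixture"
  g
}
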