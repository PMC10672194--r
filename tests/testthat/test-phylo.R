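test_that("supermatrix concatenation keeps exact partition bookkeeping", {
  set.seed(141)
  mk <- function(gene, taxa, len, codon) {
    gene_alignment(gene, taxa,
                   replicate(length(taxa), paste(sample(ORACLE_BASES, len,
                                                        replace = TRUE),
                                                 collapse = "")),
                   is_codon = codon)
  }
  taxa <- paste0("t", 1:5)
  a <- mk("cox1", taxa, 300, TRUE)
  b <- mk("rrnS", taxa, 600, FALSE)
  sm <- build_supermatrix(list(b, a), "PCG123RNA")
  expect_identical(sm$length, 900L)
  expect_identical(sm$partitions$label, c("cox1", "rrnS"))  # PCGs first
  expect_identical(sm$partitions$start, c(0L, 300L))
  expect_identical(sm$partitions$end, c(300L, 900L))
  expect_identical(sum(sm$partitions$end - sm$partitions$start), sm$length)
  expect_true(all(nchar(sm$rows) == 900))

  # PCGAA: 300 nt -> 100 amino-acid columns, rRNA dropped
  sm2 <- build_supermatrix(list(a, b), "PCGAA")
  expect_identical(sm2$length, 100L)
  expect_identical(sm2$partitions$kind, "aminoAcid")

  # a taxon missing one gene is padded with ? across exactly that partition
  a2 <- mk("cox1", taxa[1:4], 300, TRUE)
  sm3 <- build_supermatrix(list(a2, b), "PCG123RNA")
  row5 <- sm3$rows[["t5"]]
  expect_identical(substr(row5, 1, 300), paste(rep("?", 300), collapse = ""))
  expect_false(grepl("\\?", substr(row5, 301, 900)))
})

test_that("block filter implements the stated rules (checked rule-for-rule)", {
  # all-identical alignment: unchanged
  rows <- rep(paste(rep("ACGT", 25), collapse = ""), 5)
  fb <- filter_blocks(rows)
  expect_equal(fb$removed_fraction, 0)
  expect_identical(fb$seqs, stats::setNames(rows, NULL))

  # a 60%-gapped column inside a conserved run shorter than min_block is removed
  rows2 <- c("AAAAA-AA", "AAAAA-AA", "AAAAA-AA", "AAAAAAAA", "AAAAAAAA")
  fb2 <- filter_blocks(rows2)
  expect_identical(fb2$seqs[[1]], "")
  expect_equal(fb2$removed_fraction, 1)

  # randomized shuffled columns: agreement with an independent loop-based
  # implementation of the same rules
  set.seed(151)
  for (k in 1:5) {
    n <- 8; L <- 200
    m <- matrix(sample(ORACLE_BASES, L, replace = TRUE), n, L, byrow = TRUE)
    shuffle <- sample(L, 40)
    for (j in shuffle) m[, j] <- sample(ORACLE_BASES, n, replace = TRUE)
    gap <- sample(L, 10)
    for (j in gap) m[sample(n, 5), j] <- "-"
    rows3 <- apply(m, 1, paste, collapse = "")
    fb3 <- filter_blocks(rows3)
    expect_identical(fb3$kept, oracle_filter_kept(rows3))
  }
})

test_that("neighbor joining is exact on additive distances", {
  # ultrametric 3-taxon case has a closed form
  dm <- matrix(c(0, 2, 8, 2, 0, 8, 8, 8, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr <- nj_tree(dm)
  cd <- ape::cophenetic.phylo(tr)[rownames(dm), colnames(dm)]
  expect_equal(unname(cd), unname(dm), tolerance = 1e-10)

  # 50 random additive trees (n <= 8) recovered exactly from path distances
  set.seed(161)
  for (k in 1:50) {
    n <- sample(4:8, 1)
    true <- ape::rtree(n, br = function(x) runif(x, 0.05, 1))
    dm <- ape::cophenetic.phylo(true)
    est <- nj_tree(dm)
    cd <- ape::cophenetic.phylo(est)[rownames(dm), colnames(dm)]
    expect_lt(max(abs(cd - dm)), 1e-8)
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(true), est)), 0)
  }
})

test_that("NJ on TN93 distances recovers the generating topology", {
  genes <- rbind(
    data.frame(name = "cox1", kind = "PCG", length = 1500L, strand = "J",
               anticodon = NA_character_, start_codon = "ATG", stop = "TAA",
               omega = 0.2, rate = 1, stringsAsFactors = FALSE),
    data.frame(name = "rrnS", kind = "rRNA", length = 780L, strand = "J",
               anticodon = NA_character_, start_codon = NA, stop = NA,
               omega = NA_real_, rate = 1, stringsAsFactors = FALSE))
  true <- ape::read.tree(
    text = "(((A:0.05,B:0.05):0.03,(C:0.04,D:0.04):0.04):0.03,(E:0.06,F:0.06):0.05);")
  ok <- vapply(1:20, function(seed) {
    sim <- simulate_mitogenomes(sim_config(seed = seed, tree = true,
                                           genes = genes, plant = FALSE))
    alns <- genome_set_alignments(sim$genomes, kinds = c("PCG", "rRNA"))
    sm <- build_supermatrix(alns, "PCG123RNA")
    aln <- gene_alignment("sm", sm$taxa, unname(sm$rows[sm$taxa]))
    est <- nj_tree(tn93_matrix(aln))
    ape::dist.topo(ape::unroot(true), est) == 0
  }, logical(1))
  expect_true(all(ok))
})

test_that("MPL dating: clock-like identity and binding/slack calibrations", {
  # perfectly clock-like tree with a root calibration at the implied depth:
  # ages proportional to depth, root age equals the calibration age
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1.5,d:1.5):0.5);")
  dated <- mpl_date(tr, list(calibration_point(c("a", "b", "c", "d"), 100, "root")))
  expect_equal(dated$ages[5], 100)           # root
  expect_equal(dated$ages[6], 50)            # (a,b) at depth 1 of 2
  expect_equal(dated$ages[7], 75)            # (c,d) at depth 1.5 of 2
  expect_equal(dated$rate, 2 / 100)

  # two calibrations, one binding: the binding one attains equality.
  # MPL(root) = 2, MPL(ab) = 1. Calibrations: root >= 100 (rate 0.02),
  # ab >= 80 (rate 0.0125, binding). r = 0.0125: ab = 80, root = 160 > 100.
  dated2 <- mpl_date(tr, list(
    calibration_point(c("a", "b", "c", "d"), 100, "root"),
    calibration_point(c("a", "b"), 80, "ab")))
  expect_equal(dated2$ages[6], 80)
  expect_equal(dated2$ages[5], 160)
  expect_true(all(dated2$calibrations$age >= dated2$calibrations$min_age - 1e-9))

  # non-monophyletic calibration clade errors, listing the offender
  expect_error(mpl_date(tr, list(calibration_point(c("a", "c"), 10, "bad"))),
               "monophyletic")
})

test_that("MPL dating satisfies every hard minimum on random draws", {
  set.seed(171)
  for (k in 1:50) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n, br = function(x) runif(x, 0.01, 0.5))
    ntip <- length(tr$tip.label)
    internal <- (ntip + 2):(ntip + tr$Nnode)  # exclude root; add it separately
    picks <- sample(internal, min(3, length(internal)))
    cals <- lapply(picks, function(nd) {
      calibration_point(ape::extract.clade(tr, nd)$tip.label,
                        runif(1, 5, 150), sprintf("cal%d", nd))
    })
    cals <- c(cals, list(calibration_point(tr$tip.label, runif(1, 50, 300), "root")))
    dated <- mpl_date(tr, cals)
    expect_true(all(dated$calibrations$age >= dated$calibrations$min_age - 1e-9))
    # parent never younger than child
    for (e in seq_len(nrow(tr$edge))) {
      expect_gte(dated$ages[tr$edge[e, 1]], dated$ages[tr$edge[e, 2]] - 1e-9)
    }
  }
})

test_that("clock-tree node ages are recovered within 10% from realized substitutions", {
  ing <- ape::read.tree(text = paste0("((in1:10,in2:10):20,((in3:12,in4:12):10,",
                                      "(in5:15,(in6:9,in7:9):6):7):8);"))
  subs <- ing
  subs$edge.length <- ing$edge.length * 0.01  # 0.01 substitutions/site/Ma
  depth <- ape::node.depth.edgelength(ing)
  true_age <- max(depth) - depth
  for (seed in 1:3) {
    sim <- simulate_mitogenomes(sim_config(seed = seed, tree = subs))
    L <- nchar(sim$genomes[[1]]$sequence)
    bs <- sim$truth$branch_substitutions
    est <- sim$truth$tree
    eo <- match(paste(est$edge[, 1], est$edge[, 2]), paste(bs$parent, bs$child))
    est$edge.length <- bs$substitutions[eo] / L
    dated <- mpl_date(est, list(calibration_point(paste0("in", 1:7), 30, "root")))
    for (nd in 8:(7 + ing$Nnode)) {
      tips <- ape::extract.clade(ing, nd)$tip.label
      nd2 <- if (length(tips) > 1) ape::getMRCA(est, tips) else match(tips, est$tip.label)
      expect_lt(abs(dated$ages[nd2] - true_age[nd]) / true_age[nd], 0.10)
    }
  }
})

test_that("supermatrix writers emit consistent PHYLIP/FASTA/partition files", {
  sim <- simulate_mitogenomes(sim_config(seed = 181, n_taxa = 4))
  alns <- genome_set_alignments(sim$genomes)
  sm <- build_supermatrix(alns, "PCG123RNA")
  stem <- withr::local_tempfile()
  write_supermatrix(sm, stem)
  phy <- readLines(paste0(stem, ".phy"))
  expect_identical(phy[1], sprintf("%d %d", length(sm$taxa), sm$length))
  parts <- readLines(paste0(stem, ".partitions"))
  expect_identical(sum(grepl("\\\\3", parts)), 3L * 13L)
  expect_identical(sum(grepl("^DNA, rrn", parts)), 2L)
})
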