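test_that("nucleotide diversity matches hand-enumerated values", {
  # identical rows
  aln <- gene_alignment("g", c("a", "b"), c("ACGTACGTAC", "ACGTACGTAC"))
  expect_equal(nucleotide_diversity(aln)$pi, 0)

  # one difference over 10 sites
  aln <- gene_alignment("g", c("a", "b"), c("ACGTACGTAC", "ACGTACGTAA"))
  expect_equal(nucleotide_diversity(aln)$pi, 0.1)

  # 3 rows with pairwise differences 1, 2, 3 over 10 sites: pi = 0.2 exactly
  r1 <- "AAAAAAAAAA"
  r2 <- "CAAAAAAAAA"   # d(r1,r2) = 1
  r3 <- "CCGAAAAAAA"   # d(r2,r3) = 2, d(r1,r3) = 3
  aln <- gene_alignment("g", c("a", "b", "c"), c(r1, r2, r3))
  expect_equal(nucleotide_diversity(aln)$pi, 0.2)
})

test_that("pi of a 2-row alignment equals its pairwise p-distance", {
  set.seed(21)
  for (k in 1:25) {
    n <- 60
    a <- sample(ORACLE_BASES, n, replace = TRUE)
    b <- a
    mut <- sample(n, sample(0:20, 1))
    b[mut] <- sample(ORACLE_BASES, length(mut), replace = TRUE)
    aln <- gene_alignment("g", c("x", "y"),
                          c(paste(a, collapse = ""), paste(b, collapse = "")))
    expect_equal(nucleotide_diversity(aln)$pi, mean(a != b))
  }
})

test_that("gap handling: pairwise vs complete deletion", {
  aln <- gene_alignment("g", c("a", "b", "c"),
                        c("ACGTAC", "AC-TAC", "ACGTAA"))
  pw <- nucleotide_diversity(aln, "pairwise")
  cd <- nucleotide_diversity(aln, "complete")
  # pairwise: d(ab)=0/5, d(ac)=1/6, d(bc)=1/5
  expect_equal(pw$pi, (0 + 1 / 6 + 1 / 5) / 3)
  # complete: column 3 dropped everywhere: d(ab)=0, d(ac)=1/5, d(bc)=1/5
  expect_equal(cd$pi, (0 + 1 / 5 + 1 / 5) / 3)
})

test_that("NG86 site and difference counts match the exhaustive pathway oracle", {
  tabs <- mitocomp:::ng86_tables()
  code <- oracle_code5()

  # per-codon synonymous sites, all 60 sense codons
  for (cd in names(code)[code != "*"]) {
    expect_equal(tabs$syn_sites[[cd]], oracle_syn_sites(cd, code), info = cd)
  }

  # 200 seeded random codon pairs against explicit pathway enumeration
  set.seed(33)
  for (k in 1:200) {
    a <- random_sense_codon(code)
    b <- random_sense_codon(code)
    ora <- oracle_diff_counts(a, b, code)
    expect_equal(tabs$sd[a, b], ora[["Sd"]], info = paste(a, b))
    expect_equal(tabs$nd[a, b], ora[["Nd"]], info = paste(a, b))
  }
})

test_that("NG86 on known small cases", {
  # TTT vs TTC is one synonymous difference (Phe/Phe); with a single codon
  # the synonymous proportion saturates the Jukes-Cantor correction
  aln <- gene_alignment("g", c("a", "b"), c("TTT", "TTC"), is_codon = TRUE)
  kk <- suppressWarnings(ng86_kaks(aln))
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Nd, 0)
  expect_equal(kk$Ka, 0)
  expect_true(is.na(kk$Ks))

  # embedded in a neutral background the same difference gives Ks > 0, Ka = 0
  bg <- "ATGAAACATCGA"
  aln <- gene_alignment("g", c("a", "b"),
                        c(paste0(bg, "TTT"), paste0(bg, "TTC")), is_codon = TRUE)
  kk <- ng86_kaks(aln)
  expect_equal(kk$Sd, 1)
  expect_equal(kk$Nd, 0)
  expect_gt(kk$Ks, 0)
  expect_equal(kk$Ka, 0)

  # identical sequences: Ka = Ks = 0, ratio missing
  aln <- gene_alignment("g", c("a", "b"), c("ATGAAATTT", "ATGAAATTT"),
                        is_codon = TRUE)
  kk <- ng86_kaks(aln)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, 0)
  expect_true(is.na(kk$ratio))

  # N + S = 3 x compared codons
  set.seed(41)
  cods <- replicate(50, random_sense_codon())
  aln <- gene_alignment("g", c("a", "b"),
                        rep(paste(cods, collapse = ""), 2), is_codon = TRUE)
  kk <- ng86_kaks(aln)
  expect_lt(abs(kk$N + kk$S - 150), 1e-6)
})

test_that("NG86 recovers omega on simulated purifying-selection data", {
  # single 500-codon gene, omega 0.2, kappa 2, uniform composition (the
  # regime where the counting method is consistent), 6-taxon clock tree
  u <- c(A = .25, C = .25, G = .25, T = .25)
  ratios <- vapply(1:20, function(seed) {
    genes <- data.frame(name = "cox1", kind = "PCG", length = 1500L,
                        strand = "J", anticodon = NA_character_,
                        start_codon = "ATG", stop = "TAA",
                        omega = 0.2, rate = 1, stringsAsFactors = FALSE)
    cfg <- sim_config(seed = seed, genes = genes, plant = FALSE, n_taxa = 6,
                      tree_depth = 0.15, pcg12_freq = u, pcg3_freq = u)
    sim <- simulate_mitogenomes(cfg)
    aln <- genome_set_alignments(sim$genomes, kinds = "PCG")[["cox1"]]
    ng86_kaks(aln)$ratio
  }, numeric(1))
  expect_true(all(ratios >= 0.1 & ratios <= 0.3))
  # purifying selection always shows Ka/Ks < 1
  expect_true(all(ratios < 1))
})

test_that("NG86 sampling error halves (at least) from 500 to 5000 codons", {
  u <- c(A = .25, C = .25, G = .25, T = .25)
  est <- function(seed, len) {
    genes <- data.frame(name = "cox1", kind = "PCG", length = len, strand = "J",
                        anticodon = NA_character_, start_codon = "ATG",
                        stop = "TAA", omega = 0.2, rate = 1,
                        stringsAsFactors = FALSE)
    cfg <- sim_config(seed = seed, genes = genes, plant = FALSE, n_taxa = 2,
                      tree_depth = 0.2, pcg12_freq = u, pcg3_freq = u)
    sim <- simulate_mitogenomes(cfg)
    ng86_kaks(genome_set_alignments(sim$genomes, kinds = "PCG")[["cox1"]])$ratio
  }
  r500 <- vapply(1:20, est, numeric(1), len = 1500L)
  r5000 <- vapply(1:20, est, numeric(1), len = 15000L)
  # a 10x longer gene should at least halve the replicate-to-replicate
  # scatter (expected: ~1/sqrt(10)); the small residual counting bias of the
  # method does not shrink with length and is assessed separately above
  expect_lt(sd(r5000), sd(r500) / 2)
  expect_lt(abs(mean(r5000) - 0.2), 0.05)
})

test_that("TN93 distance has the right limits and symmetry", {
  expect_equal(tn93_distance("ACGTACGT", "ACGTACGT"), 0)

  set.seed(55)
  a <- paste(sample(ORACLE_BASES, 300, replace = TRUE), collapse = "")
  bv <- strsplit(a, "")[[1]]
  mut <- sample(300, 30)
  bv[mut] <- sample(ORACLE_BASES, 30, replace = TRUE)
  b <- paste(bv, collapse = "")
  expect_equal(tn93_distance(a, b), tn93_distance(b, a))

  # equal-frequency equal-rate regime: TN93 approaches the JC distance
  p <- mean(strsplit(a, "")[[1]] != bv)
  jc <- -0.75 * log(1 - 4 * p / 3)
  expect_lt(abs(tn93_distance(a, b) - jc) / jc, 0.01)
})

test_that("TN93 agrees with the reference implementation in ape", {
  set.seed(66)
  for (k in 1:10) {
    n <- 400
    a <- sample(ORACLE_BASES, n, replace = TRUE, prob = c(.4, .1, .1, .4))
    b <- a
    mut <- sample(n, 60)
    b[mut] <- sample(ORACLE_BASES, 60, replace = TRUE, prob = c(.4, .1, .1, .4))
    d_pkg <- tn93_distance(paste(a, collapse = ""), paste(b, collapse = ""))
    bin <- ape::as.DNAbin(rbind(a = tolower(a), b = tolower(b)))
    d_ape <- as.numeric(ape::dist.dna(bin, model = "TN93"))
    expect_equal(as.numeric(d_pkg), d_ape, tolerance = 1e-8)
  }
})

test_that("saturated comparisons return NA with a flag", {
  a <- paste(rep("A", 100), collapse = "")
  b <- paste(rep("G", 100), collapse = "")
  d <- tn93_distance(a, b)
  expect_true(is.na(d))
  expect_true(isTRUE(attr(d, "saturated")))
})

test_that("saturation profile separates transitions from transversions", {
  # transitions only: v_prop is 0 for every pair. Balanced random background
  # with a few planted transitions keeps every TN93 logarithm defined.
  set.seed(71)
  av <- sample(ORACLE_BASES, 90, replace = TRUE)
  ts_of <- c(A = "G", G = "A", C = "T", T = "C")
  bv <- av; for (p in c(4, 35, 66)) bv[p] <- ts_of[[av[p]]]
  cv <- av; for (p in c(12, 80)) cv[p] <- ts_of[[av[p]]]
  a <- paste(av, collapse = ""); b <- paste(bv, collapse = "")
  c <- paste(cv, collapse = "")
  aln <- gene_alignment("g", c("a", "b", "c"), c(a, b, c), is_codon = TRUE)
  sp <- saturation_profile(aln, "all")
  expect_true(all(sp$points$v_prop == 0))
  expect_true(all(sp$points$s_prop > 0))
  # s + v equals the p-distance for each pair at each position
  sp3 <- saturation_profile(aln, "3")
  idx3 <- seq(3, nchar(a), by = 3)
  for (i in seq_len(nrow(sp3$points))) {
    pa <- strsplit(aln$seqs[[sp3$points$taxon_a[i]]], "")[[1]][idx3]
    pb <- strsplit(aln$seqs[[sp3$points$taxon_b[i]]], "")[[1]][idx3]
    expect_equal(sp3$points$s_prop[i] + sp3$points$v_prop[i], mean(pa != pb))
  }

  # zero substitutions: all points at the origin
  aln0 <- gene_alignment("g", c("a", "b", "c"), rep(a, 3), is_codon = TRUE)
  sp0 <- saturation_profile(aln0, "all")
  expect_true(all(sp0$points$tn93 == 0))
  expect_true(all(sp0$points$s_prop == 0 & sp0$points$v_prop == 0))
})

test_that("third positions saturate faster than first positions in deep simulations", {
  sim <- simulate_mitogenomes(sim_config(seed = 77, n_taxa = 6, tree_depth = 0.6))
  alns <- genome_set_alignments(sim$genomes, kinds = "PCG")
  sm <- build_supermatrix(alns, "PCG123RNA")
  concat <- gene_alignment("concat", sm$taxa, unname(sm$rows[sm$taxa]),
                           is_codon = TRUE)
  p1 <- saturation_profile(concat, "1")
  p3 <- saturation_profile(concat, "3")
  # more substitution per unit distance accrues at position 3, and the
  # transition signal flattens there (declining S/V linearity)
  expect_gt(mean(p3$points$s_prop + p3$points$v_prop),
            mean(p1$points$s_prop + p1$points$v_prop))
  expect_lt(p3$s_slope / p3$v_slope, p1$s_slope / p1$v_slope)
})
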