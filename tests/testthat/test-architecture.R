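test_that("junction table classifies overlap, abutment and UR correctly", {
  seq <- paste(rep("ACGT", 100), collapse = "")  # 400 bp
  feats <- rbind(gene_feature("cox1", "PCG", 0, 100, "J"),
                 gene_feature("cox2", "PCG", 93, 200, "J"),
                 gene_feature("cox3", "PCG", 200, 300, "J"),
                 gene_feature("nad1", "PCG", 320, 400, "J"))
  g <- mitogenome("J1", "x", seq, circular = TRUE, complete = TRUE,
                  features = feats)
  jt <- junction_table(g)
  expect_identical(jt$relation, c("overlap", "abut", "UR", "abut"))
  expect_identical(jt$length, c(7L, 0L, 20L, 0L))
  expect_identical(jt$sequence[1], substr(seq, 94, 100))

  # containment of same-kind features is an annotation error
  feats2 <- rbind(gene_feature("cox1", "PCG", 0, 100, "J"),
                  gene_feature("cox2", "PCG", 10, 50, "J"))
  g2 <- mitogenome("J2", "x", seq, features = feats2)
  expect_error(junction_table(g2), "fully contains")
})

test_that("fixture genome shows the three planted overlaps and nothing else", {
  jt <- junction_table(fixture_genome_cached())
  ov <- jt[jt$relation == "overlap", ]
  expect_identical(nrow(ov), 3L)
  expect_identical(ov$sequence[ov$upstream == "nad4"], "ATGTTAA")
  expect_identical(ov$sequence[ov$upstream == "atp8"], "ATGATAA")
  expect_identical(ov$sequence[ov$upstream == "atp6"], "A")
  expect_identical(ov$length, c(7L, 1L, 7L))
})

test_that("junction lengths conserve the genome length on 50 simulated genomes", {
  count <- 0L
  for (seed in 1:5) {
    sim <- simulate_mitogenomes(sim_config(seed = seed, n_taxa = 10,
                                           tree_depth = 0.05))
    for (g in sim$genomes) {
      jt <- junction_table(g)
      lhs <- sum(g$features$end - g$features$start) -
        sum(jt$length[jt$relation == "overlap"]) +
        sum(jt$length[jt$relation == "UR"])
      expect_equal(lhs, nchar(g$sequence))
      count <- count + 1L
    }
  }
  expect_identical(count, 50L)
})

test_that("microsatellite finder matches hand-checked and oracle results", {
  hits <- find_microsatellites("GGATATATATATGG")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$motif, "AT")
  expect_identical(hits$copies, 5L)
  expect_identical(c(hits$start, hits$end), c(2L, 12L))

  # canonical rotation: CG/GC collapse onto CG
  hits <- find_microsatellites("GCGCGCGCGC", min_length = 10)
  expect_identical(hits$motif, "CG")
  expect_identical(hits$copies, 5L)

  # seeded random 500-mers: detector spans agree exactly with an exhaustive
  # every-start every-motif scan (maximal spans, containment removed)
  set.seed(91)
  for (k in 1:6) {
    prob <- sample(c(.42, .42, .08, .08))
    seq <- paste(sample(c("G", "C", "A", "T"), 500, replace = TRUE,
                        prob = prob), collapse = "")
    hits <- find_microsatellites(seq, min_length = 12)
    spans <- oracle_microsat_maximal(oracle_microsat_spans(seq, min_length = 12))
    expect_identical(cbind(start = hits$start, end = hits$end),
                     matrix(as.integer(spans), ncol = 2,
                            dimnames = list(NULL, c("start", "end"))),
                     info = paste("rep", k))
  }
})

test_that("microsatellite calls are invariant to rotation of a circular sequence", {
  cr <- extract_gene_sequence(fixture_genome_cached(), "control_region")
  base_hits <- find_microsatellites(cr)
  n <- nchar(cr)
  for (shift in c(137, 611)) {
    rot <- paste0(substr(cr, shift + 1, n), substr(cr, 1, shift))
    rot_hits <- find_microsatellites(rot)
    # every hit not cut by the rotation point must reappear, shifted
    for (i in seq_len(nrow(base_hits))) {
      s <- (base_hits$start[i] - shift) %% n
      e <- s + (base_hits$end[i] - base_hits$start[i])
      if (e > n) next
      match <- rot_hits$start == s & rot_hits$end == e &
        rot_hits$motif == base_hits$motif[i]
      expect_true(any(match), info = sprintf("hit %d shift %d", i, shift))
    }
  }
})

test_that("long repeat finder detects planted duplications", {
  set.seed(101)
  bg <- function(n) paste(sample(ORACLE_BASES, n, replace = TRUE), collapse = "")
  unit <- bg(250)

  # exact tandem duplicate in 1 kb
  seq <- paste0(bg(200), unit, unit, bg(300))
  hits <- find_long_repeats(seq)
  expect_identical(nrow(hits), 1L)
  expect_gte(hits$copy_length, 250L)
  expect_equal(hits$identity, 1)

  # duplicate with 5% point mutations still found at >= 0.9 identity
  mv <- strsplit(unit, "")[[1]]
  mut <- sample(250, 12)
  mv[mut] <- sample(ORACLE_BASES, 12, replace = TRUE)
  seq2 <- paste0(bg(200), unit, paste(mv, collapse = ""), bg(300))
  hits2 <- find_long_repeats(seq2)
  expect_identical(nrow(hits2), 1L)
  expect_gte(hits2$identity, 0.9)
  expect_gte(hits2$copy_length, 200L)

  # random sequence with no duplication: detector empty, confirmed by the
  # all-pairs oracle at reduced scale
  seq3 <- bg(400)
  expect_identical(nrow(find_long_repeats(seq3, min_copy_len = 80)), 0L)
  expect_false(oracle_has_long_repeat(seq3, 80))
})

test_that("control region report flags all four identification criteria on the fixture", {
  cr <- control_region_report(fixture_genome_cached())
  expect_true(all(cr$criteria))
  expect_identical(cr$length, 1300L)
  expect_gt(cr$at_content, cr$genome_at_content)
  expect_true(any(cr$microsatellites$motif == "AT" & cr$microsatellites$copies >= 12))
  expect_identical(nrow(cr$long_repeats), 1L)
  expect_gte(cr$long_repeats$copy_length, 250L)
  expect_true(any(cr$t_rich_runs$length >= 10))
})

test_that("an unannotated genome falls back to the longest UR, warning when short", {
  set.seed(111)
  seq <- paste(sample(ORACLE_BASES, 460, replace = TRUE), collapse = "")
  feats <- rbind(gene_feature("cox1", "PCG", 0, 150, "J"),
                 gene_feature("cox2", "PCG", 150, 300, "J"),
                 gene_feature("cox3", "PCG", 330, 460, "J"))
  g <- mitogenome("U1", "x", seq, circular = TRUE, complete = TRUE,
                  features = feats)
  cr <- control_region_report(g)
  expect_identical(cr$length, 30L)
  expect_true("short CR candidate" %in% cr$warnings)

  # no UR at all and no annotation: unresolved
  feats2 <- rbind(gene_feature("cox1", "PCG", 0, 200, "J"),
                  gene_feature("cox2", "PCG", 200, 460, "J"))
  g2 <- mitogenome("U2", "x", seq, circular = TRUE, complete = TRUE,
                   features = feats2)
  expect_error(control_region_report(g2), "unresolved")
})

test_that("cloverleaf checker finds all arms in canonical constructs", {
  set.seed(121)
  tr <- mitocomp:::build_trna_seq("CAT", d_arm = TRUE)
  rep <- check_cloverleaf(tr$seq, "CAT")
  expect_true(rep$acceptor_stem$found)
  expect_true(rep$d_arm$found)
  expect_true(rep$anticodon_arm$found)
  expect_true(rep$t_arm$found)
  expect_true(rep$anticodon_matches)

  # trnS2 pattern: D-arm replaced by a simple loop, everything else intact
  tr2 <- mitocomp:::build_trna_seq("TGA", d_arm = FALSE)
  rep2 <- check_cloverleaf(tr2$seq, "TGA")
  expect_false(rep2$d_arm$found)
  expect_true(rep2$acceptor_stem$found)
  expect_true(rep2$anticodon_arm$found)
  expect_true(rep2$t_arm$found)
})

test_that("a random 70-mer does not fake an acceptor stem", {
  set.seed(131)
  seq <- paste(sample(ORACLE_BASES, 70, replace = TRUE), collapse = "")
  rep <- suppressWarnings(check_cloverleaf(seq, "CAT"))
  # oracle: count pairings of the first 7 against the last 7 explicitly
  chars <- strsplit(seq, "")[[1]]
  pairs <- 0
  for (i in 1:7) {
    x <- chars[i]; y <- chars[71 - i]
    if (paste0(x, y) %in% c("AT", "TA", "GC", "CG", "GT", "TG")) pairs <- pairs + 1
  }
  expect_identical(rep$acceptor_stem$pairs, as.integer(pairs))
  expect_false(rep$acceptor_stem$found)
})

test_that("fixture cloverleaf table isolates trnS2 as the D-arm exception", {
  tab <- cloverleaf_table(fixture_genome_cached())
  expect_identical(nrow(tab), 22L)
  expect_false(tab$d_arm[tab$trna == "trnS2"])
  expect_true(all(tab$d_arm[tab$trna != "trnS2"]))
  expect_true(all(tab$acceptor & tab$anticodon_arm & tab$t_arm))
  expect_true(all(tab$anticodon_matches))
})
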