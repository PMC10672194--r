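# Orchestration: genomes -> composition/codon/junction/control-region
# reports -> per-gene alignments -> pi / Ka/Ks / saturation -> supermatrix ->
# NJ tree -> calibrated dating. Alignment is consumed, not produced: the
# pipeline accepts pre-aligned per-gene FASTA, and the simulator path
# produces exact alignments (no indels) so the aligner step vanishes.

#' Pipeline run configuration
#'
#' @param genome_paths Character vector of GenBank flatfile paths, or NULL.
#' @param simulation A [sim_config()] to generate inputs instead of reading
#'   them, or NULL.
#' @param alignment_dir Directory of pre-aligned per-gene FASTA files
#'   (`<gene>.fasta`, headers = taxon ids), or NULL.
#' @param scheme Supermatrix scheme, `"PCG123RNA"` or `"PCGAA"`.
#' @param calibrations List of [calibration_point()]s for dating (optional).
#' @param root_min Optional root minimum age (Ma).
#' @param outgroup Optional tip id used to root the NJ tree for dating.
#' @param block_filter Apply the conserved-block filter to the supermatrix?
#' @param microsat_min_len Minimum microsatellite run length (bp).
#' @param seed Seed recorded in the manifest and used for any stochastic step.
#' @return A `run_config` list.
#' @export
run_config <- function(genome_paths = NULL, simulation = NULL,
                       alignment_dir = NULL, scheme = "PCG123RNA",
                       calibrations = list(), root_min = NULL, outgroup = NULL,
                       block_filter = TRUE, microsat_min_len = 10, seed = 1) {
  if (is.null(genome_paths) && is.null(simulation)) {
    stop("need at least one input source (genome_paths or simulation)", call. = FALSE)
  }
  structure(list(genome_paths = genome_paths, simulation = simulation,
                 alignment_dir = alignment_dir, scheme = scheme,
                 calibrations = calibrations, root_min = root_min,
                 outgroup = outgroup, block_filter = isTRUE(block_filter),
                 microsat_min_len = microsat_min_len, seed = as.integer(seed)),
            class = "run_config")
}

read_alignment_dir <- function(dir) {
  files <- list.files(dir, pattern = "\\.(fa|fasta)$", full.names = TRUE)
  alns <- lapply(files, function(f) {
    gene <- sub("\\.(fa|fasta)$", "", basename(f))
    lines <- readLines(f, warn = FALSE)
    hdr <- grep("^>", lines)
    taxa <- sub("^>(\\S+).*", "\\1", lines[hdr])
    bounds <- c(hdr, length(lines) + 1L)
    seqs <- vapply(seq_along(hdr), function(i) {
      paste(lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)], collapse = "")
    }, "")
    gene_alignment(gene, taxa, toupper(seqs), is_codon = gene %in% PCG_NAMES)
  })
  stats::setNames(alns, vapply(alns, function(a) a$gene, ""))
}

#' Run the full comparative-mitogenomics pipeline
#'
#' Stages run in dependency order; stages whose preconditions are unmet
#' (e.g. tree inference with fewer than 4 taxa) are skipped with a notice in
#' the manifest rather than failing the run. A stage failure on one genome is
#' recorded and the partial bundle returned.
#'
#' @param config A [run_config()].
#' @return A `report_bundle` list: `composition`, `rscu`, `start_stop`,
#'   `junctions`, `control_regions`, `cloverleaf`, `diversity`, `saturation`,
#'   `supermatrix`, `tree`, `dated`, `manifest`, `notices`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  notices <- character(0)
  truth <- NULL
  if (!is.null(config$simulation)) {
    sim <- simulate_mitogenomes(config$simulation)
    genomes <- sim$genomes
    truth <- sim$truth
  } else {
    genomes <- list()
    for (p in config$genome_paths) {
      g <- tryCatch(read_genbank(p), error = function(e) e)
      if (inherits(g, "error")) {
        notices <- c(notices, sprintf("failed to read %s: %s", p, conditionMessage(g)))
      } else {
        genomes[[g$id]] <- g
      }
    }
    if (length(genomes) == 0) stop("no parsable genome", call. = FALSE)
  }

  per_genome <- function(fn, label) {
    out <- list()
    for (g in genomes) {
      r <- tryCatch(fn(g), error = function(e) e)
      if (inherits(r, "error")) {
        notices <<- c(notices, sprintf("%s failed for %s: %s", label, g$id,
                                       conditionMessage(r)))
      } else {
        out[[g$id]] <- r
      }
    }
    out
  }

  composition <- do.call(rbind, per_genome(composition_report, "composition"))
  rscu_tab <- do.call(rbind, per_genome(rscu_report, "rscu"))
  start_stop <- do.call(rbind, per_genome(start_stop_table, "start_stop"))
  junctions <- do.call(rbind, per_genome(function(g) {
    cbind(genome = g$id, junction_table(g), stringsAsFactors = FALSE)
  }, "junctions"))
  control_regions <- per_genome(function(g) {
    control_region_report(g, microsat_min_len = config$microsat_min_len)
  }, "control_region")
  cloverleaf <- do.call(rbind, per_genome(cloverleaf_table, "cloverleaf"))

  alignments <- NULL
  if (!is.null(config$alignment_dir)) {
    alignments <- read_alignment_dir(config$alignment_dir)
  } else if (!is.null(truth) && length(genomes) >= 2) {
    alignments <- genome_set_alignments(genomes)
  }

  diversity <- NULL; saturation <- NULL; sm <- NULL; tree <- NULL; dated <- NULL
  if (!is.null(alignments)) {
    codon_alns <- Filter(function(a) a$is_codon, alignments)
    diversity <- diversity_table(codon_alns)
    if (length(alignments[[1]]$taxa) >= 3 && length(codon_alns) > 0) {
      concat <- build_supermatrix(codon_alns, "PCG123RNA")
      concat_aln <- gene_alignment("PCG_concat", concat$taxa,
                                   unname(concat$rows[concat$taxa]), is_codon = TRUE)
      saturation <- do.call(rbind, lapply(c("1", "2", "3", "all"), function(p) {
        sp <- saturation_profile(concat_aln, p)
        sp$points
      }))
    } else {
      notices <- c(notices, "saturation skipped: needs >= 3 taxa")
    }
    if (length(alignments[[1]]$taxa) >= 4) {
      sm <- build_supermatrix(alignments, config$scheme)
      rows <- sm$rows
      if (config$block_filter && length(rows) >= 4) {
        fb <- filter_blocks(rows)
        notices <- c(notices, sprintf("block filter removed %.2f%% of sites",
                                      100 * fb$removed_fraction))
        rows <- fb$seqs
      }
      dm_aln <- gene_alignment("supermatrix", sm$taxa, unname(rows[sm$taxa]),
                               is_codon = FALSE)
      dm <- tn93_matrix(dm_aln)
      if (!any(is.na(dm))) {
        tree <- nj_tree(dm)
        if (length(config$calibrations) > 0 || !is.null(config$root_min)) {
          rooted <- NULL
          if (!is.null(config$outgroup) && config$outgroup %in% tree$tip.label) {
            rooted <- ape::root(tree, outgroup = config$outgroup,
                                resolve.root = TRUE)
          } else if (!is.null(truth)) {
            rooted <- truth$tree
          }
          if (is.null(rooted)) {
            notices <- c(notices, "dating skipped: no outgroup to root the tree")
          } else {
            dated <- tryCatch(
              mpl_date(rooted, config$calibrations, root_min = config$root_min),
              error = function(e) {
                notices <<- c(notices, paste("dating failed:", conditionMessage(e)))
                NULL
              })
          }
        }
      } else {
        notices <- c(notices, "tree skipped: saturated (missing) distances")
      }
    } else {
      notices <- c(notices, "tree stages skipped: needs >= 4 taxa")
    }
  } else {
    notices <- c(notices, "diversity/tree stages skipped: no alignments available")
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("mitocomp")),
    seed = config$seed,
    n_genomes = length(genomes),
    genome_ids = vapply(genomes, function(g) g$id, ""),
    config_hash = config_hash(config),
    scheme = config$scheme)

  structure(list(genomes = genomes, truth = truth, composition = composition,
                 rscu = rscu_tab, start_stop = start_stop, junctions = junctions,
                 control_regions = control_regions, cloverleaf = cloverleaf,
                 diversity = diversity, saturation = saturation,
                 supermatrix = sm, tree = tree, dated = dated,
                 manifest = manifest, notices = notices),
            class = "report_bundle")
}

# deterministic digest of the config (md5 of its deparsed form)
config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(deparse(config[setdiff(names(config), "simulation_tree")]), tmp)
  unname(tools::md5sum(tmp))
}

#' Write a report bundle to a directory
#'
#' TSV tables, newick trees, JSON control-region reports and a JSON manifest;
#' every file is reproducible byte-identically from the same config and seed.
#'
#' @param bundle A [run_pipeline()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(df, name) {
    if (!is.null(df)) {
      utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    }
  }
  wr(bundle$composition, "composition.tsv")
  wr(bundle$rscu, "rscu.tsv")
  wr(bundle$start_stop, "start_stop.tsv")
  wr(bundle$junctions, "junctions.tsv")
  wr(bundle$cloverleaf, "cloverleaf.tsv")
  wr(bundle$diversity, "diversity.tsv")
  wr(bundle$saturation, "saturation.tsv")
  if (length(bundle$control_regions) > 0) {
    crs <- lapply(bundle$control_regions, function(cr) {
      cr_out <- unclass(cr)
      cr_out$criteria <- as.list(cr$criteria)
      cr_out
    })
    jsonlite::write_json(crs, file.path(dir, "control_regions.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(bundle$supermatrix)) {
    write_supermatrix(bundle$supermatrix, file.path(dir, "supermatrix"))
  }
  if (!is.null(bundle$tree)) {
    ape::write.tree(bundle$tree, file.path(dir, "nj_tree.nwk"))
  }
  if (!is.null(bundle$dated)) {
    tr <- bundle$dated$tree
    ntip <- length(tr$tip.label)
    tr$node.label <- sprintf("[age=%.2f]", bundle$dated$ages[(ntip + 1):length(bundle$dated$ages)])
    ape::write.tree(tr, file.path(dir, "dated_tree.nwk"))
    utils::write.table(bundle$dated$calibrations, file.path(dir, "calibrations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  jsonlite::write_json(c(bundle$manifest, list(notices = bundle$notices)),
                       file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
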