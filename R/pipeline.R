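# End-to-end orchestration: simulate (optional) -> all-vs-all -> filter
# -> network -> MCL (+ inflation scan) -> residue calls -> family table
# -> star MSA -> iterative HMM -> cutoffs -> search -> neighborhoods ->
# phyletic census -> NJ tree -> clade assignment, with a checksum
# manifest for reproducibility.

#' Pipeline configuration
#'
#' @param synth a [synth_config()] describing the synthetic dataset (the
#'   pipeline can also consume files written by [write_dataset()] via
#'   `input_dir`).
#' @param input_dir directory of a written dataset; overrides `synth`
#'   when given.
#' @param scoring a [scoring_params()].
#' @param mcl an [mcl_params()] (inflation 1.4 by default).
#' @param inflation_values inflation sweep values.
#' @param min_coverage,max_evalue similarity-network filter thresholds
#'   (0.8 / 0.05).
#' @param identity_reduce redundancy threshold inside HMM iteration
#'   (0.8).
#' @param n_seeds seed-sequence count for the HMM (8); seeds are chosen
#'   diversity-balanced by farthest-point selection on pairwise
#'   distances among the family candidates.
#' @param window gene-neighborhood window (5).
#' @param max_gap_bp operon gap threshold (100).
#' @param max_rounds HMM iteration cap.
#' @param min_bitscore reference-map reliability floor.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(synth, input_dir = NULL,
                            scoring = scoring_params(), mcl = mcl_params(),
                            inflation_values = c(1.0, 1.2, 1.4, 2, 6),
                            min_coverage = 0.8, max_evalue = 0.05,
                            identity_reduce = 0.8, n_seeds = 8,
                            window = 5, max_gap_bp = 100, max_rounds = 5,
                            min_bitscore = 20) {
  stopifnot(min_coverage >= 0, min_coverage <= 1, max_evalue >= 0,
            identity_reduce > 0, identity_reduce <= 1, n_seeds >= 1,
            window >= 1, max_rounds >= 1)
  structure(list(synth = synth, input_dir = input_dir, scoring = scoring,
                 mcl = mcl, inflation_values = inflation_values,
                 min_coverage = min_coverage, max_evalue = max_evalue,
                 identity_reduce = identity_reduce, n_seeds = n_seeds,
                 window = window, max_gap_bp = max_gap_bp,
                 max_rounds = max_rounds, min_bitscore = min_bitscore),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields override the [pipeline_config()] defaults; `synth:` holds
#' [synth_config()] arguments (seed mandatory).
#' @param path YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sy <- y$synth
  for (f in c("genomes_per_phylum", "pyp_prevalence", "neighbor_freqs",
              "substitution_rates", "gap_range", "gene_length_range"))
    if (!is.null(sy[[f]])) sy[[f]] <- unlist(sy[[f]])
  if (!is.null(sy$motif_spec))
    sy$motif_spec <- lapply(sy$motif_spec, unlist)
  sc <- do.call(synth_config, sy)
  args <- y[setdiff(names(y), c("synth", "scoring", "mcl"))]
  if (!is.null(args$inflation_values))
    args$inflation_values <- as.numeric(unlist(args$inflation_values))
  args$synth <- sc
  if (!is.null(y$scoring)) args$scoring <- do.call(scoring_params, y$scoring)
  if (!is.null(y$mcl)) args$mcl <- do.call(mcl_params, y$mcl)
  do.call(pipeline_config, args)
}

.read_dataset <- function(dir) {
  seqs <- read_fasta(file.path(dir, "sequences.fasta"))
  tax_seq <- read.table(file.path(dir, "taxonomy.tsv"), sep = "\t",
                        header = TRUE, stringsAsFactors = FALSE)
  sequences <- data.frame(id = names(seqs), residues = unname(seqs),
                          stringsAsFactors = FALSE)
  sequences <- merge(sequences, tax_seq, by = "id", sort = FALSE)
  gt_path <- file.path(dir, "ground_truth.tsv")
  gt <- if (file.exists(gt_path))
    read.table(gt_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
               na.strings = "NA")
  else NULL
  ref <- read_fasta(file.path(dir, "reference.fasta"))
  list(sequences = sequences,
       genes = read_genes(file.path(dir, "genes.tsv")),
       taxonomy = read.table(file.path(dir, "genomes.tsv"), sep = "\t",
                             header = TRUE, stringsAsFactors = FALSE),
       reference = list(id = names(ref)[1], residues = unname(ref)[1]),
       ground_truth = gt)
}

.log_stage <- function(stage, t0) {
  message(sprintf("[pypfam] %-14s %6.1fs", stage,
                  as.numeric(Sys.time()) - t0))
}

#' Run the full analysis pipeline
#'
#' Executes every stage on the configured dataset, writes all artifacts
#' (TSV/FASTA/Newick/JSON) plus a checksum manifest into `out_dir`, and
#' returns a run report.  Reruns with the same configuration produce
#' byte-identical artifacts and manifest.  When the dataset carries
#' planted ground truth, the report additionally evaluates the run
#' against it (clustering ARI, family recall/precision, clade-assignment
#' accuracy); these evaluation fields consume the hidden truth labels and
#' exist only for benchmarking.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory.
#' @param quiet suppress stage log messages.
#' @return The run report (list), invisibly; also written as
#'   `report.json`.
#' @export
run_pipeline <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- as.numeric(Sys.time())
  say <- function(stage) if (!quiet) .log_stage(stage, t0)
  report <- list()

  # --- simulate / load ------------------------------------------------
  if (!is.null(config$input_dir)) {
    ds <- .read_dataset(config$input_dir)
  } else {
    ds <- generate_dataset(config$synth)
    write_dataset(ds, file.path(out_dir, "dataset"))
  }
  say("simulate")
  seqs <- ds$sequences
  ref <- ds$reference
  allseq <- stats::setNames(seqs$residues, seqs$id)
  pool <- c(stats::setNames(ref$residues, ref$id), allseq)

  # --- all-vs-all + filter + network ---------------------------------
  hits <- all_vs_all(pool, config$scoring)
  write_hits(hits, file.path(out_dir, "hits.tsv"))
  say("allvsall")
  filtered <- filter_hits(hits, config$min_coverage, config$max_evalue)
  net <- build_network(filtered, nodes = names(pool))
  write_network(net, file.path(out_dir, "network.tsv"))

  # --- MCL + inflation scan ------------------------------------------
  clustering <- suppressWarnings(mcl(net, config$mcl))
  write_clustering(clustering, file.path(out_dir, "clusters.tsv"))
  cg <- cluster_graph(clustering, net)
  write_cluster_graph(cg, file.path(out_dir, "cluster_nodes.tsv"),
                      file.path(out_dir, "cluster_edges.tsv"))
  scan <- scan_inflation(net, config$inflation_values, config$mcl)
  write.table(scan, file.path(out_dir, "inflation_scan.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  say("cluster")
  report$clustering <- list(
    n_clusters = length(clustering$sizes),
    sizes = as.integer(clustering$sizes),
    converged = clustering$converged,
    pyp_cluster = unname(clustering$assignment[ref$id]),
    pyp_cluster_size = clustering$sizes[clustering$assignment[ref$id]])
  report$inflation_scan <- scan

  # --- residue calls + family table ----------------------------------
  calls <- call_residues_many(allseq, ref, config$scoring,
                              min_bitscore = config$min_bitscore)
  write.table(calls_table(calls), file.path(out_dir, "residue_calls.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  # the family candidates: members of the cluster containing the reference
  pyp_cluster <- clustering$assignment[ref$id]
  cluster_ids <- setdiff(names(clustering$assignment)[
    clustering$assignment == pyp_cluster], ref$id)
  fam <- classify_family(calls[cluster_ids])
  write.table(fam$table, file.path(out_dir, "family_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  say("classify")
  report$family <- list(
    n_candidates = fam$n,
    n_members = length(fam$members),
    member_fraction = fam$member_fraction,
    triad_fraction = fam$triad_fraction,
    label_counts = as.list(fam$label_counts),
    y42_e46_cooccurrence = fam$y42_e46_cooccurrence)

  # --- iterative profile HMM -----------------------------------------
  # seed set: n_seeds functional members, balanced across phyla
  members <- fam$members
  if (length(members) <= config$n_seeds) {
    seed_ids <- members
  } else {
    # diversity-balanced seed set: farthest-point selection on pairwise
    # distances so every subclade of the candidate set is represented
    mem_msa <- suppressWarnings(
      star_msa(allseq[members], ref, config$scoring, config$min_bitscore))
    ids <- setdiff(mem_msa$ids, ref$id)
    D <- distance_matrix(mem_msa)[ids, ids, drop = FALSE]
    seed_ids <- ids[which.min(rowSums(D))]  # medoid first
    while (length(seed_ids) < min(config$n_seeds, length(ids))) {
      rest <- setdiff(ids, seed_ids)
      mind <- apply(D[rest, seed_ids, drop = FALSE], 1, min)
      pick <- rest[mind >= max(mind) - 1e-12]
      seed_ids <- c(seed_ids, sort(pick)[1])
    }
  }
  it <- iterate_build(allseq[seed_ids], allseq, ref, config$scoring,
                      max_rounds = config$max_rounds,
                      identity_reduce = config$identity_reduce,
                      calls = calls)
  write_hmm(it$hmm, file.path(out_dir, "family.hmm"))
  final_hits <- hmm_search(it$hmm, allseq, cutoff = "GA")
  write_search_results(final_hits, file.path(out_dir, "hmm_hits.tsv"))
  say("hmm")
  report$hmm <- list(
    n_match = it$hmm$n_match,
    cutoffs = as.list(it$hmm$cutoffs),
    n_rounds = it$n_rounds, converged = it$converged,
    oscillated = it$oscillated,
    n_seed = length(seed_ids),
    n_hits = nrow(final_hits))

  # --- neighborhoods --------------------------------------------------
  functional_ids <- names(calls)[vapply(calls, `[[`, TRUE, "functional")]
  functional_hits <- intersect(final_hits$sequence_id, functional_ids)
  genes <- ds$genes
  pyp_gene_ids <- genes$gene_id[!is.na(genes$sequence_id) &
                                  genes$sequence_id %in% functional_hits]
  if (length(pyp_gene_ids) > 0) {
    cfr <- category_fractions(pyp_gene_ids, genes, window = config$window)
    write.table(data.frame(category = names(cfr), fraction = unname(cfr)),
                file.path(out_dir, "neighbor_fractions.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    report$neighborhood <- as.list(cfr)
  } else {
    report$neighborhood <- list()
  }
  report$n_functional_pyp_genes <- length(pyp_gene_ids)
  say("neighbors")

  # --- phyletic census ------------------------------------------------
  fun_genomes <- unique(seqs$genome_id[seqs$id %in% functional_hits])
  fun_genomes <- fun_genomes[!is.na(fun_genomes)]
  phyl <- phyletic_summary(ds$taxonomy, fun_genomes)
  write.table(phyl, file.path(out_dir, "phyletic_summary.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  say("phyletics")
  report$phyletics <- list(
    n_phyla_with_family = sum(phyl$genomes_with_functional_pyp > 0),
    n_displayed = sum(phyl$displayed),
    n_hgt_flagged = sum(phyl$hgt_flagged))

  # --- tree + clades --------------------------------------------------
  tree <- NULL; clades <- NULL
  fam_for_tree <- final_hits$sequence_id
  if (length(fam_for_tree) >= 3) {
    msa <- suppressWarnings(
      star_msa(allseq[fam_for_tree], ref, config$scoring,
               config$min_bitscore))
    D <- distance_matrix(msa)
    write_distance_matrix(D, file.path(out_dir, "distances.tsv"))
    tree <- nj_tree(D)
    write_newick(tree, file.path(out_dir, "tree.nwk"))
  }
  say("tree")

  # --- evaluation against planted truth (benchmarking only) ----------
  if (!is.null(ds$ground_truth)) {
    gt <- ds$ground_truth
    truth_part <- gt$planted_family
    names(truth_part) <- gt$id
    common <- intersect(names(clustering$assignment), names(truth_part))
    report$evaluation <- list(
      clustering_ari = adjusted_rand_index(
        unname(clustering$assignment[common]),
        unname(truth_part[common])))
    planted <- gt$id[!is.na(gt$planted_family) & gt$planted_family == "PYP"]
    hit_ids <- final_hits$sequence_id
    report$evaluation$family_recall <-
      if (length(planted)) length(intersect(hit_ids, planted)) / length(planted)
      else NA
    # the family proper is Cys69-defined: recall over planted members that
    # kept the cysteine (no indels in the generator, so position 69 is 69)
    planted_fun <- planted[substr(allseq[planted], 69, 69) == "C"]
    report$evaluation$family_recall_functional <-
      if (length(planted_fun))
        length(intersect(hit_ids, planted_fun)) / length(planted_fun)
      else NA
    report$evaluation$family_precision <-
      if (length(hit_ids)) length(intersect(hit_ids, planted)) / length(hit_ids)
      else NA
    report$evaluation$decoy_hits <- length(setdiff(hit_ids, c(planted, ref$id)))
    if (!is.null(tree)) {
      truth_clade <- stats::setNames(gt$planted_clade, gt$id)
      leaves <- intersect(tree$tip.label, names(truth_clade))
      leaves <- leaves[!is.na(truth_clade[leaves])]
      anchors <- character(0)
      for (cl in unique(truth_clade[leaves])) {
        cand <- leaves[truth_clade[leaves] == cl]
        anchors <- c(anchors, stats::setNames(rep(cl, min(2, length(cand))),
                                              utils::head(sort(cand), 2)))
      }
      got <- suppressWarnings(assign_clades(tree, anchors))
      test_leaves <- setdiff(leaves, names(anchors))
      if (length(test_leaves) > 0) {
        report$evaluation$clade_accuracy <-
          mean(got[test_leaves] == truth_clade[test_leaves], na.rm = TRUE)
      }
    }
  }

  # --- manifest -------------------------------------------------------
  params <- config
  params$synth$lut <- NULL; params$scoring$lut <- NULL
  params$scoring$matrix <- NULL
  jsonlite::write_json(params, file.path(out_dir, "params.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE),
                        "manifest.tsv"))
  md5 <- tools::md5sum(file.path(out_dir, files))
  manifest <- data.frame(file = files, md5 = unname(md5))
  write.table(manifest, file.path(out_dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  say("done")
  invisible(report)
}
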