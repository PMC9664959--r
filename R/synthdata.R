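# Synthetic protein families, taxonomy, and genome gene tables with the
# statistical structure the downstream analysis assumes: several diverged
# decoy families plus one planted "PYP" family whose members carry
# constrained residues at reference positions (42/46/50/69 and the
# clade-specific 92/96/100/119 signatures), genomes with category-labelled
# gene neighbors around the family gene, and per-phylum prevalence.

.default_motifs <- function() {
  common <- c("42" = "Y", "46" = "E", "50" = "S", "69" = "C", "119" = "W")
  list(A = c(common, "92" = "F", "96" = "F"),
       B = c(common, "92" = "F", "96" = "F"),
       C = c(common, "100" = "M"))
}

#' Configuration for the synthetic dataset generator
#'
#' The defaults define the study conditions used throughout the package's
#' tests: a planted three-clade family with the chromophore-binding motif
#' (Tyr42, Glu46, Ser50, Cys69, Trp119, plus Phe92/Phe96 in clades A and B
#' and Met100 in clade C), substitution rates for the labelled variants,
#' unrelated decoy families of the same length scale, and genomes whose
#' family gene carries category-labelled neighbors within the 5-gene
#' window at configured frequencies.
#'
#' @param seed mandatory integer seed; a fixed config (including seed)
#'   yields byte-identical outputs.
#' @param clade_labels family clade names.
#' @param motif_spec named list per clade: reference position (1-based,
#'   character names) -> required residue.
#' @param substitution_rates named probabilities for planted substitutions
#'   ("Y42F" style labels; a trailing "x" means a random non-reference
#'   residue).
#' @param n_decoy_families,decoy_family_size decoy families carry no motif
#'   constraints.
#' @param seq_length ancestor length (125 residues, the PYP fold scale).
#' @param site_mutation_rate per-site substitution probability per tree
#'   branch.
#' @param clade_divergence per-site substitution probability separating a
#'   clade ancestor from the family ancestor.
#' @param genomes_per_phylum named integer vector.
#' @param pyp_prevalence named probability per phylum that a genome
#'   carries a family gene.
#' @param neighbor_freqs named probability per neighbor category of being
#'   placed within the 5-gene window of a family gene.
#' @param genes_per_contig genes per genome contig.
#' @param gap_range intergenic gap range in bp (negative = overlap).
#' @param gene_length_range gene length range in bp.
#' @param operon_gap_bp max intergenic gap used when placing the DLD
#'   neighbor in the same operon as the family gene.
#' @return Object of class `synth_config`.
#' @export
synth_config <- function(seed,
                         clade_labels = c("A", "B", "C"),
                         motif_spec = .default_motifs(),
                         substitution_rates = c(Y42F = 0.10, E46Q = 0.05,
                                                C69x = 0.05),
                         n_decoy_families = 4,
                         decoy_family_size = 50,
                         seq_length = 125,
                         site_mutation_rate = 0.02,
                         clade_divergence = 0.12,
                         genomes_per_phylum = c(
                           Proteobacteria = 60, Myxococcota = 25,
                           Spirochaetota = 30, Bacteroidota = 30,
                           Gemmatimonadota = 12, Actinobacteria = 40,
                           Firmicutes = 50, Acidobacteria = 15),
                         pyp_prevalence = c(
                           Proteobacteria = 0.25, Myxococcota = 0.8,
                           Spirochaetota = 0.3, Bacteroidota = 0.25,
                           Gemmatimonadota = 0.15, Actinobacteria = 0.05,
                           Firmicutes = 0, Acidobacteria = 0.1),
                         neighbor_freqs = c(
                           TAL = 0.15, pCL = 0.35, HMOX = 0.1, DLD = 0.1,
                           MCP = 0.1, GGDEF = 0.1, EAL = 0.05, HK = 0.2,
                           RR = 0.2),
                         genes_per_contig = 25,
                         gap_range = c(-30, 300),
                         gene_length_range = c(300, 2400),
                         operon_gap_bp = 50) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("'seed' is mandatory")
  stopifnot(all(names(motif_spec) %in% clade_labels) || length(motif_spec) == 0,
            all(substitution_rates >= 0 & substitution_rates <= 1),
            all(pyp_prevalence >= 0 & pyp_prevalence <= 1),
            all(neighbor_freqs >= 0 & neighbor_freqs <= 1),
            all(genomes_per_phylum >= 0),
            n_decoy_families >= 0, decoy_family_size >= 0,
            seq_length >= 1,
            site_mutation_rate >= 0, site_mutation_rate <= 1,
            clade_divergence >= 0, clade_divergence <= 1)
  for (cl in names(motif_spec)) {
    pos <- as.integer(names(motif_spec[[cl]]))
    if (any(is.na(pos)) || any(pos < 1) || any(pos > seq_length))
      stop("motif_spec positions must be valid 1-based reference positions")
  }
  if (!all(names(pyp_prevalence) %in% names(genomes_per_phylum)))
    stop("pyp_prevalence names must match genomes_per_phylum")
  structure(as.list(environment()), class = "synth_config")
}

.random_ancestor <- function(len) {
  bg <- blosum62_background()
  paste(sample(names(bg), len, replace = TRUE, prob = bg), collapse = "")
}

.mutate_seq <- function(chars, rate) {
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) > 0) {
    for (i in hit) {
      alt <- AA_ALPHABET[AA_ALPHABET != chars[i]]
      chars[i] <- alt[sample.int(19, 1)]
    }
  }
  chars
}

# Evolve `size` leaves from an ancestor along a random bifurcating
# (Yule-like) tree: repeatedly split a random lineage, each child a
# mutated copy of its parent (uniform replacement at `rate` per site).
.evolve_family <- function(ancestor, size, rate) {
  pool <- list(strsplit(ancestor, "", fixed = TRUE)[[1]])
  while (length(pool) < size) {
    i <- sample.int(length(pool), 1)
    parent <- pool[[i]]
    pool[[i]] <- .mutate_seq(parent, rate)
    pool[[length(pool) + 1]] <- .mutate_seq(parent, rate)
  }
  pool
}

.parse_sub_label <- function(label) {
  m <- regmatches(label, regexec("^([A-Z])([0-9]+)([A-Zx-])$", label))[[1]]
  if (length(m) != 4) stop("bad substitution label: ", label)
  list(ref = m[2], pos = as.integer(m[3]), obs = m[4])
}

# Restore the clade motif at its positions; with the configured
# probability a labelled substitution is planted instead.
.apply_motif <- function(chars, motif, sub_rates) {
  subs <- lapply(names(sub_rates), .parse_sub_label)
  for (p in names(motif)) {
    pos <- as.integer(p)
    required <- motif[[p]]
    planted <- FALSE
    for (k in seq_along(subs)) {
      s <- subs[[k]]
      if (s$pos == pos && s$ref == required && runif(1) < sub_rates[[k]]) {
        obs <- s$obs
        if (obs == "x") {
          alt <- AA_ALPHABET[AA_ALPHABET != required]
          obs <- alt[sample.int(19, 1)]
        }
        chars[pos] <- obs
        planted <- TRUE
        break
      }
    }
    if (!planted) chars[pos] <- required
  }
  chars
}

.gen_family_internal <- function(config, family, clade, size, ancestor,
                                 id_prefix, constrained = TRUE) {
  leaves <- .evolve_family(ancestor, size, config$site_mutation_rate)
  motif <- if (constrained) config$motif_spec[[clade]] else character(0)
  res <- character(size)
  for (i in seq_len(size)) {
    chars <- leaves[[i]]
    if (length(motif) > 0)
      chars <- .apply_motif(chars, motif, config$substitution_rates)
    res[i] <- paste(chars, collapse = "")
  }
  data.frame(id = sprintf("%s%03d", id_prefix, seq_len(size)),
             residues = res,
             genome_id = NA_character_, phylum = NA_character_,
             order = NA_character_,
             planted_family = family,
             planted_clade = if (constrained) clade else NA_character_,
             stringsAsFactors = FALSE)
}

#' Generate one planted family clade
#'
#' Members evolve from a random ancestor along a random bifurcating tree
#' with uniform per-site replacement; motif positions of the clade are
#' restored afterwards except where a labelled substitution is planted at
#' its configured rate.  Ground-truth labels are recorded in
#' `planted_family` / `planted_clade` and must only be consumed by tests.
#'
#' @param config a [synth_config()].
#' @param clade one of `config$clade_labels`.
#' @param size number of members (>= 1).
#' @return SequenceRecord data.frame.
#' @export
generate_family <- function(config, clade, size) {
  stopifnot(inherits(config, "synth_config"), size >= 1)
  if (!clade %in% config$clade_labels)
    stop("unknown clade: ", clade)
  set.seed(config$seed)
  ancestor <- .random_ancestor(config$seq_length)
  .gen_family_internal(config, "PYP", clade, size, ancestor,
                       paste0("pyp", clade, "_"))
}

.make_taxonomy <- function(config) {
  rows <- lapply(names(config$genomes_per_phylum), function(ph) {
    n <- config$genomes_per_phylum[[ph]]
    if (n == 0) return(NULL)
    data.frame(genome_id = sprintf("%s_g%03d", ph, seq_len(n)),
               phylum = ph,
               order = sprintf("%s_order%d", ph,
                               1 + (seq_len(n) - 1) %% 3),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Build one genome gene table around a focal family gene.  Neighbor
# categories are placed independently with their configured probabilities
# at free slots of the +/-5 window; DLD, when drawn, is placed adjacent to
# the focal gene on the same strand with a small gap (operon emulation).
.make_gene_table <- function(config, genome_id, focal_seq_id) {
  n <- config$genes_per_contig
  focal <- sample(6:(n - 5), 1)
  category <- rep("other", n)
  strand <- sample(c("+", "-"), n, replace = TRUE)
  category[focal] <- "PYP"
  window <- setdiff(seq(focal - 5, focal + 5), focal)
  free <- window
  operon_with <- integer(0)
  for (cat in names(config$neighbor_freqs)) {
    if (length(free) == 0) break
    if (runif(1) < config$neighbor_freqs[[cat]]) {
      if (cat == "DLD") {
        adj <- intersect(c(focal - 1, focal + 1), free)
        slot <- if (length(adj) > 0) adj[sample.int(length(adj), 1)]
                else free[sample.int(length(free), 1)]
        strand[slot] <- strand[focal]
        if (abs(slot - focal) == 1) operon_with <- c(operon_with, slot)
      } else {
        slot <- free[sample.int(length(free), 1)]
      }
      category[slot] <- cat
      free <- setdiff(free, slot)
    }
  }
  len <- round(runif(n, config$gene_length_range[1], config$gene_length_range[2]))
  gap <- round(runif(n, config$gap_range[1], config$gap_range[2]))
  for (s in operon_with) {  # keep the operon junction tight, same strand
    j <- max(focal, s)      # gap[j] precedes gene j
    gap[j] <- sample.int(config$operon_gap_bp + 1, 1) - 1
  }
  start <- integer(n); end <- integer(n)
  pos <- 1
  for (i in seq_len(n)) {
    if (i > 1) pos <- end[i - 1] + gap[i] + 1
    start[i] <- max(pos, if (i > 1) 1 else 1)
    end[i] <- start[i] + len[i] - 1
  }
  data.frame(genome_id = genome_id, contig = paste0(genome_id, "_c1"),
             gene_id = sprintf("%s_gene%02d", genome_id, seq_len(n)),
             start = start, end = end, strand = strand,
             index = seq_len(n), category = category,
             sequence_id = ifelse(seq_len(n) == focal, focal_seq_id,
                                  NA_character_),
             stringsAsFactors = FALSE)
}

#' Generate the full synthetic dataset
#'
#' Taxonomy first: each genome of each phylum carries the family gene with
#' its phylum's prevalence; the planted family is then generated with
#' exactly one member per carrier genome (clades assigned uniformly at
#' random), decoy families are generated unconstrained and scattered over
#' genomes without gene placement, and each carrier genome receives a gene
#' table whose 5-gene window is populated per `neighbor_freqs`.
#'
#' @param config a [synth_config()].
#' @return List: `sequences` (SequenceRecord data.frame, family + decoys),
#'   `genes` (gene table data.frame), `taxonomy`, `reference` (list with
#'   `id`, `residues`: the family ancestor with the full canonical motif),
#'   and `ground_truth` (id, planted_family, planted_clade).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  taxonomy <- .make_taxonomy(config)

  # reference: family ancestor carrying the canonical residue set
  anc <- strsplit(.random_ancestor(config$seq_length), "", fixed = TRUE)[[1]]
  canonical <- c("42" = "Y", "46" = "E", "50" = "S", "69" = "C",
                 "92" = "F", "96" = "F", "100" = "M", "119" = "W")
  canonical <- canonical[as.integer(names(canonical)) <= config$seq_length]
  anc[as.integer(names(canonical))] <- canonical
  family_ancestor <- paste(anc, collapse = "")
  reference <- list(id = "PYP_ref", residues = family_ancestor)

  # carriers per phylum
  carrier <- character(0)
  if (!is.null(taxonomy)) {
    for (ph in names(config$pyp_prevalence)) {
      g <- taxonomy$genome_id[taxonomy$phylum == ph]
      if (length(g) == 0) next
      take <- runif(length(g)) < config$pyp_prevalence[[ph]]
      carrier <- c(carrier, g[take])
    }
  }
  n_fam <- length(carrier)

  seqs <- NULL
  if (n_fam > 0) {
    clades <- sample(config$clade_labels, n_fam, replace = TRUE)
    # per-clade ancestors diverge from the family ancestor
    clade_anc <- lapply(config$clade_labels, function(cl)
      paste(.mutate_seq(anc, config$clade_divergence), collapse = ""))
    names(clade_anc) <- config$clade_labels
    fam_rows <- lapply(config$clade_labels, function(cl) {
      k <- sum(clades == cl)
      if (k == 0) return(NULL)
      .gen_family_internal(config, "PYP", cl, k, clade_anc[[cl]],
                           paste0("pyp", cl, "_"))
    })
    seqs <- do.call(rbind, fam_rows)
    # attach carriers (clade blocks in order)
    ord <- order(match(clades, config$clade_labels))
    seqs$genome_id <- carrier[ord]
    ti <- match(seqs$genome_id, taxonomy$genome_id)
    seqs$phylum <- taxonomy$phylum[ti]
    seqs$order <- taxonomy$order[ti]
  }

  # decoy families: unrelated ancestors, no constraints
  if (config$n_decoy_families > 0 && config$decoy_family_size > 0) {
    decoys <- lapply(seq_len(config$n_decoy_families), function(d) {
      danc <- .random_ancestor(config$seq_length)
      .gen_family_internal(config, paste0("decoy", d), NA_character_,
                           config$decoy_family_size, danc,
                           sprintf("dec%d_", d), constrained = FALSE)
    })
    decoys <- do.call(rbind, decoys)
    if (!is.null(taxonomy)) {
      gi <- sample.int(nrow(taxonomy), nrow(decoys), replace = TRUE)
      decoys$genome_id <- taxonomy$genome_id[gi]
      decoys$phylum <- taxonomy$phylum[gi]
      decoys$order <- taxonomy$order[gi]
    }
    seqs <- rbind(seqs, decoys)
  }
  if (is.null(seqs))
    stop("configuration generates no sequences")

  # gene tables for carrier genomes
  genes <- NULL
  if (n_fam > 0) {
    fam <- seqs[seqs$planted_family == "PYP" & !is.na(seqs$planted_family), ]
    tabs <- lapply(seq_len(nrow(fam)), function(i)
      .make_gene_table(config, fam$genome_id[i], fam$id[i]))
    genes <- do.call(rbind, tabs)
  } else {
    genes <- data.frame(genome_id = character(0), contig = character(0),
                        gene_id = character(0), start = integer(0),
                        end = integer(0), strand = character(0),
                        index = integer(0), category = character(0),
                        sequence_id = character(0), stringsAsFactors = FALSE)
  }
  rownames(seqs) <- NULL
  if (!is.null(genes)) rownames(genes) <- NULL
  list(sequences = seqs, genes = genes, taxonomy = taxonomy,
       reference = reference,
       ground_truth = seqs[, c("id", "planted_family", "planted_clade")])
}

#' Write / read the synthetic dataset as plain-text files
#'
#' Writes `sequences.fasta`, `reference.fasta`, `taxonomy.tsv`
#' (id, genome_id, phylum, order), `ground_truth.tsv`, `genes.tsv`, and
#' `genes.gff3`.
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(stats::setNames(ds$sequences$residues, ds$sequences$id),
              file.path(dir, "sequences.fasta"))
  write_fasta(stats::setNames(ds$reference$residues, ds$reference$id),
              file.path(dir, "reference.fasta"))
  tx <- data.frame(id = ds$sequences$id, genome_id = ds$sequences$genome_id,
                   phylum = ds$sequences$phylum, order = ds$sequences$order)
  write.table(tx, file.path(dir, "taxonomy.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(ds$taxonomy, file.path(dir, "genomes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(ds$ground_truth, file.path(dir, "ground_truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_genes(ds$genes, file.path(dir, "genes.tsv"))
  write_genes_gff3(ds$genes, file.path(dir, "genes.gff3"))
  invisible(dir)
}

#' FASTA read/write helpers
#'
#' Thin wrappers over Biostrings with named character vectors as the
#' in-memory representation.
#' @param seqs named character vector of residues.
#' @param path file path.
#' @return `read_fasta` returns a named character vector.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::AAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(x), names(x))
}
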