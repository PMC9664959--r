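# Gene-neighborhood analysis (+/-5 genes, bp distances, operon calls,
# category tallies) and the phyletic-distribution census with the display
# and horizontal-gene-transfer flags.

.gene_row <- function(genes, gene_id) {
  i <- which(genes$gene_id == gene_id)
  if (length(i) != 1) stop("gene not in table: ", gene_id)
  genes[i, , drop = FALSE]
}

#' Genes within a window of gene-index offsets
#'
#' Neighbors are genes on the same contig whose ordinal index differs from
#' the focal gene's by 1..`window` (both directions, strand-agnostic),
#' clipped at contig ends.
#'
#' @param gene_id focal gene id (must be present in `genes`).
#' @param genes gene table data.frame (columns `genome_id`, `contig`,
#'   `gene_id`, `start`, `end`, `strand`, `index`, `category`, optionally
#'   `sequence_id`).
#' @param window gene-count window (default 5).
#' @return The neighbor rows, ordered by index.
#' @export
neighbors_within <- function(gene_id, genes, window = 5) {
  g <- .gene_row(genes, gene_id)
  same <- genes$contig == g$contig & genes$genome_id == g$genome_id
  d <- abs(genes$index - g$index)
  nb <- genes[same & d >= 1 & d <= window, , drop = FALSE]
  nb <- nb[order(nb$index), , drop = FALSE]
  rownames(nb) <- NULL
  nb
}

#' Intergenic distance in bp (negative for overlaps)
#'
#' Under 1-based inclusive coordinates the distance between the upstream
#' and downstream gene is `start2 - end1 - 1`: book-ended genes are 0 bp
#' apart and overlapping genes have negative distances.
#'
#' @param g1,g2 one-row gene records on the same contig (order by start is
#'   established internally).
#' @return Integer bp distance.
#' @export
intergenic_distance <- function(g1, g2) {
  if (g1$contig != g2$contig) stop("genes are on different contigs")
  if (g1$start > g2$start) { tmp <- g1; g1 <- g2; g2 <- tmp }
  as.integer(g2$start - g1$end - 1)
}

#' Operon co-membership call
#'
#' Two genes are called same-operon iff every gene on the index path
#' between them (inclusive) lies on the same strand and every consecutive
#' intergenic gap along the path is at most `max_gap_bp`.
#'
#' @param g1,g2 one-row gene records on the same contig.
#' @param genes full gene table (needed when the genes are not adjacent).
#' @param max_gap_bp maximum intergenic gap (default 100 bp, a common
#'   prokaryotic heuristic).
#' @return Logical.
#' @export
same_operon <- function(g1, g2, genes = NULL, max_gap_bp = 100) {
  if (g1$contig != g2$contig) stop("genes are on different contigs")
  if (g1$strand != g2$strand) return(FALSE)
  lo <- min(g1$index, g2$index); hi <- max(g1$index, g2$index)
  if (hi - lo == 1) {
    path <- rbind(g1, g2)
  } else {
    if (is.null(genes)) stop("'genes' table required for non-adjacent genes")
    sel <- genes$contig == g1$contig & genes$genome_id == g1$genome_id &
      genes$index >= lo & genes$index <= hi
    path <- genes[sel, , drop = FALSE]
  }
  path <- path[order(path$index), , drop = FALSE]
  if (length(unique(path$strand)) > 1) return(FALSE)
  if (nrow(path) >= 2) {
    for (i in seq_len(nrow(path) - 1)) {
      if (intergenic_distance(path[i, ], path[i + 1, ]) > max_gap_bp)
        return(FALSE)
    }
  }
  TRUE
}

#' Neighborhood report for a focal gene
#'
#' @inheritParams neighbors_within
#' @param max_gap_bp operon gap threshold passed to [same_operon()].
#' @return List: `focal_gene`, `neighbors` (data.frame with `gene_id`,
#'   `category`, `offset` in genes, `distance_bp` to the focal gene,
#'   `same_operon`), `category_present` (named logical).
#' @export
neighborhood_report <- function(gene_id, genes, window = 5, max_gap_bp = 100) {
  g <- .gene_row(genes, gene_id)
  nb <- neighbors_within(gene_id, genes, window)
  n <- nrow(nb)
  dist_bp <- integer(n); operon <- logical(n)
  for (i in seq_len(n)) {
    dist_bp[i] <- intergenic_distance(g, nb[i, ])
    operon[i] <- same_operon(g, nb[i, ], genes, max_gap_bp)
  }
  cats <- sort(unique(nb$category))
  list(focal_gene = gene_id,
       neighbors = data.frame(gene_id = nb$gene_id, category = nb$category,
                              offset = nb$index - g$index,
                              distance_bp = dist_bp, same_operon = operon,
                              stringsAsFactors = FALSE),
       category_present = stats::setNames(rep(TRUE, length(cats)), cats))
}

#' Fractions of focal genes with a neighbor of each category
#'
#' For each category, the fraction of the supplied (functional) family
#' genes that have at least one neighbor of that category within the
#' gene-count window.
#'
#' @param pyp_gene_ids gene ids of the (functional) family genes.
#' @param genes gene table covering them.
#' @param categories categories to tally (default: all neighbor
#'   categories present).
#' @param window gene-count window (default 5).
#' @return Named numeric vector of fractions between 0 and 1.
#' @export
category_fractions <- function(pyp_gene_ids, genes, categories = NULL,
                               window = 5) {
  if (length(pyp_gene_ids) == 0) stop("empty focal gene list")
  if (is.null(categories))
    categories <- setdiff(sort(unique(genes$category)), c("PYP", "other"))
  hitmat <- matrix(FALSE, length(pyp_gene_ids), length(categories),
                   dimnames = list(pyp_gene_ids, categories))
  for (i in seq_along(pyp_gene_ids)) {
    nb <- neighbors_within(pyp_gene_ids[i], genes, window)
    hitmat[i, ] <- categories %in% nb$category
  }
  colMeans(hitmat)
}

#' Phyletic census with display and HGT flags
#'
#' Per phylum: total genomes, genomes with at least one functional family
#' gene, the percentage, the display rule (shown iff >= 10 genomes
#' available AND >= 5 family-containing genomes) and the
#' horizontal-gene-transfer heuristic (flagged iff 0 < containing
#' genomes < 5).
#'
#' @param taxonomy data.frame with `genome_id` and `phylum`.
#' @param functional_genome_ids genome ids containing at least one
#'   functional family gene; every id must occur in `taxonomy`.
#' @return Data frame: `phylum`, `genomes_total`,
#'   `genomes_with_functional_pyp`, `percentage`, `displayed`,
#'   `hgt_flagged`, ordered by decreasing totals.
#' @export
phyletic_summary <- function(taxonomy, functional_genome_ids) {
  functional_genome_ids <- unique(functional_genome_ids)
  orphan <- setdiff(functional_genome_ids, taxonomy$genome_id)
  if (length(orphan) > 0)
    stop("functional genome ids missing from taxonomy: ",
         paste(orphan, collapse = ", "))
  phyla <- unique(taxonomy$phylum)
  total <- vapply(phyla, function(p) sum(taxonomy$phylum == p), 0L)
  withp <- vapply(phyla, function(p)
    length(intersect(functional_genome_ids,
                     taxonomy$genome_id[taxonomy$phylum == p])), 0L)
  d <- data.frame(phylum = phyla, genomes_total = total,
                  genomes_with_functional_pyp = withp,
                  percentage = 100 * withp / total,
                  displayed = total >= 10 & withp >= 5,
                  hgt_flagged = withp > 0 & withp < 5,
                  stringsAsFactors = FALSE)
  d <- d[order(-d$genomes_total, d$phylum), , drop = FALSE]
  rownames(d) <- NULL
  d
}

#' Gene-table TSV and GFF3 input/output
#'
#' The TSV dialect is the package's primary format (columns `genome_id`,
#' `contig`, `gene_id`, `start`, `end`, `strand`, `index`, `category`,
#' `sequence_id`).  GFF3 writes one CDS row per gene with the category in
#' the `product` attribute (via rtracklayer); reading reconstructs
#' per-contig indices from coordinate order.
#' @param genes gene table data.frame.
#' @param path file path.
#' @export
write_genes <- function(genes, path) {
  write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genes
#' @export
read_genes <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             na.strings = "NA")
}

#' @rdname write_genes
#' @export
write_genes_gff3 <- function(genes, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = genes$contig,
    ranges = IRanges::IRanges(start = genes$start, end = genes$end),
    strand = genes$strand)
  S4Vectors::mcols(gr)$type <- "CDS"
  S4Vectors::mcols(gr)$phase <- 0L
  S4Vectors::mcols(gr)$ID <- genes$gene_id
  S4Vectors::mcols(gr)$product <- genes$category
  S4Vectors::mcols(gr)$genome_id <- genes$genome_id
  S4Vectors::mcols(gr)$sequence_id <- genes$sequence_id
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' @rdname write_genes
#' @export
read_genes_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  d <- data.frame(
    genome_id = S4Vectors::mcols(gr)$genome_id,
    contig = as.character(GenomicRanges::seqnames(gr)),
    gene_id = S4Vectors::mcols(gr)$ID,
    start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    category = S4Vectors::mcols(gr)$product,
    sequence_id = if (!is.null(S4Vectors::mcols(gr)$sequence_id))
      S4Vectors::mcols(gr)$sequence_id else NA_character_,
    stringsAsFactors = FALSE)
  d <- d[order(d$contig, d$start), , drop = FALSE]
  d$index <- stats::ave(seq_len(nrow(d)), d$contig,
                        FUN = seq_along)
  rownames(d) <- NULL
  d[, c("genome_id", "contig", "gene_id", "start", "end", "strand",
        "index", "category", "sequence_id")]
}
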