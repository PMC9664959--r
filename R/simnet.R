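# Filtered similarity network, Markov clustering, cluster-graph summary,
# and the inflation sweep.

#' Filter all-vs-all hits for network construction
#'
#' Keeps hits whose query AND subject coverage are both at least
#' `min_coverage` and whose E-value is at most `max_evalue`; self-hits are
#' dropped.  Defaults follow the >=80% coverage / <=0.05 E-value filter
#' used to build the PAS similarity network.
#'
#' @param hits data.frame as from [all_vs_all()].
#' @param min_coverage,max_evalue filter thresholds.
#' @return The surviving rows.
#' @export
filter_hits <- function(hits, min_coverage = 0.8, max_evalue = 0.05) {
  keep <- hits$query_coverage >= min_coverage &
    hits$subject_coverage >= min_coverage &
    hits$e_value <= max_evalue &
    hits$query_id != hits$subject_id
  hits[keep, , drop = FALSE]
}

#' Build the unweighted similarity network
#'
#' One undirected edge per unordered pair with at least one surviving hit
#' in either direction; the directed hits themselves are retained for
#' cluster-graph weighting.
#'
#' @param hits filtered hits ([filter_hits()]).
#' @param nodes node ids; defaults to the ids present in `hits`.  Pass the
#'   full sequence id set so unmatched sequences appear as singletons.
#' @return Object of class `similarity_network` with `nodes`, `edges`
#'   (two-column data.frame, a < b) and `directed_hits`.
#' @export
build_network <- function(hits, nodes = NULL) {
  if (is.null(nodes)) nodes <- sort(unique(c(hits$query_id, hits$subject_id)))
  nodes <- sort(unique(as.character(nodes)))
  if (!all(c(hits$query_id, hits$subject_id) %in% nodes))
    stop("hits reference ids missing from 'nodes'")
  dh <- data.frame(query_id = hits$query_id, subject_id = hits$subject_id,
                   stringsAsFactors = FALSE)
  a <- pmin(dh$query_id, dh$subject_id)
  b <- pmax(dh$query_id, dh$subject_id)
  keep <- a != b
  e <- unique(data.frame(a = a[keep], b = b[keep], stringsAsFactors = FALSE))
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(nodes = nodes, edges = e, directed_hits = dh),
            class = "similarity_network")
}

#' @export
print.similarity_network <- function(x, ...) {
  cat(sprintf("similarity_network: %d nodes, %d edges, %d directed hits\n",
              length(x$nodes), nrow(x$edges), nrow(x$directed_hits)))
  invisible(x)
}

#' Markov-cluster parameters
#'
#' @param inflation entrywise power I (> 1 for meaningful granularity;
#'   I = 1 is admitted and expected to be degenerate).
#' @param expansion matrix power (integer >= 2).
#' @param prune_threshold entries below this are zeroed after inflation,
#'   followed by column renormalization.
#' @param max_iter,tol iteration cap and max-abs-change convergence
#'   tolerance.
#' @return Object of class `mcl_params`.
#' @export
mcl_params <- function(inflation = 1.4, expansion = 2,
                       prune_threshold = 1e-5, max_iter = 200, tol = 1e-6) {
  stopifnot(inflation >= 1, expansion >= 2, expansion == as.integer(expansion),
            prune_threshold >= 0, max_iter >= 1, tol > 0)
  structure(list(inflation = inflation, expansion = as.integer(expansion),
                 prune_threshold = prune_threshold,
                 max_iter = as.integer(max_iter), tol = tol),
            class = "mcl_params")
}

.colnorm <- function(M) {
  cs <- colSums(M)
  cs[cs == 0] <- 1
  sweep(M, 2, cs, "/")
}

#' Markov cluster algorithm on an unweighted network
#'
#' Adjacency plus unit self-loops is column-normalized and iterated:
#' expansion (matrix power), inflation (entrywise power, column
#' renormalization), pruning of small entries (renormalized again), until
#' the iterate changes by less than `tol` or `max_iter` is reached.
#' Clusters are read off the attractor structure; a node attracted to
#' several attractor systems is assigned to the largest (ties to the
#' lowest cluster id).  Cluster ids 1..k are ordered by decreasing size.
#'
#' @param network a `similarity_network` (or any list with `nodes` and
#'   `edges`).
#' @param params an [mcl_params()] object.
#' @return Object of class `mcl_clustering`: `assignment` (named integer
#'   vector node -> cluster id), `sizes`, `converged`, `n_iter`.
#' @export
mcl <- function(network, params = mcl_params()) {
  nodes <- network$nodes
  n <- length(nodes)
  if (n == 0) stop("empty network")
  A <- matrix(0, n, n, dimnames = list(nodes, nodes))
  if (nrow(network$edges) > 0) {
    ia <- match(network$edges$a, nodes); ib <- match(network$edges$b, nodes)
    A[cbind(ia, ib)] <- 1; A[cbind(ib, ia)] <- 1
  }
  diag(A) <- 1  # self-loops: guarantees aperiodicity
  M <- .colnorm(A)
  converged <- FALSE; it <- 0L
  while (it < params$max_iter) {
    it <- it + 1L
    Mprev <- M
    for (e in seq_len(params$expansion - 1L)) M <- M %*% Mprev  # expansion
    M <- .colnorm(M^params$inflation)                            # inflation
    if (params$prune_threshold > 0) {
      keep_max <- apply(M, 2, max)
      M[M < params$prune_threshold & M < rep(keep_max, each = n)] <- 0
      M <- .colnorm(M)
    }
    stopifnot(max(abs(colSums(M) - 1)) < 1e-9)
    if (max(abs(M - Mprev)) < params$tol) { converged <- TRUE; break }
  }
  thr <- max(params$prune_threshold, 1e-9)
  attract <- which(diag(M) >= thr)
  if (length(attract) == 0) attract <- seq_len(n)
  # attractor systems: connected components among attractors
  S <- (M >= thr) | t(M >= thr)
  g <- igraph::graph_from_adjacency_matrix(S[attract, attract, drop = FALSE],
                                           mode = "undirected", diag = FALSE)
  sys_of_attr <- igraph::components(g)$membership
  n_sys <- max(sys_of_attr)
  # which systems each node flows into (M[a, j] >= thr, a attractor)
  member_sets <- vector("list", n_sys)
  pending <- list()
  assignment <- integer(n)
  for (j in seq_len(n)) {
    sys <- unique(sys_of_attr[M[attract, j] >= thr])
    if (j %in% attract) sys <- unique(c(sys, sys_of_attr[match(j, attract)]))
    if (length(sys) == 1) assignment[j] <- sys
    else if (length(sys) == 0) assignment[j] <- NA_integer_
    else pending[[length(pending) + 1]] <- list(node = j, sys = sys)
  }
  sys_size <- tabulate(assignment[!is.na(assignment)], nbins = n_sys)
  for (p in pending) {  # overlap resolution: largest system, then lowest id
    best <- p$sys[order(-sys_size[p$sys], p$sys)][1]
    assignment[p$node] <- best
  }
  # orphans (no attractor flow): own singleton clusters
  orphan <- which(is.na(assignment))
  if (length(orphan) > 0)
    assignment[orphan] <- n_sys + seq_along(orphan)
  # renumber by decreasing size (stable: ties by current id)
  sizes <- tabulate(assignment)
  new_id <- integer(length(sizes))
  new_id[order(-sizes, seq_along(sizes))] <- seq_along(sizes)
  assignment <- new_id[assignment]
  sizes <- tabulate(assignment)
  if (!converged)
    warning(sprintf("MCL did not converge in %d iterations (inflation %g)",
                    params$max_iter, params$inflation))
  structure(list(assignment = stats::setNames(assignment, nodes),
                 sizes = sizes, converged = converged, n_iter = it),
            class = "mcl_clustering")
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat(sprintf("mcl_clustering: %d nodes in %d clusters (sizes %s)%s\n",
              length(x$assignment), length(x$sizes),
              paste(utils::head(x$sizes, 10), collapse = ","),
              if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' Summarize a clustering as a weighted cluster graph
#'
#' Node display size is `log10(cluster size)`.  The weight between
#' clusters A and B is the number of observed directed hits crossing them
#' divided by the number of possible mutual hits; with the default
#' `"ordered"` denominator that is `2 * |A| * |B|` (both directions of
#' every pair), the `"unordered"` alternative uses `|A| * |B|`.
#'
#' @param clustering an `mcl_clustering`.
#' @param network the `similarity_network` it was computed from.
#' @param denominator `"ordered"` (default) or `"unordered"`.
#' @return List with `nodes` (cluster, size, display_size) and `edges`
#'   (a, b, weight between 0 and 1).
#' @export
cluster_graph <- function(clustering, network,
                          denominator = c("ordered", "unordered")) {
  denominator <- match.arg(denominator)
  asg <- clustering$assignment
  if (!all(network$nodes %in% names(asg))) stop("clustering does not cover network")
  sizes <- clustering$sizes
  nodes <- data.frame(cluster = seq_along(sizes), size = sizes,
                      display_size = log10(sizes))
  dh <- network$directed_hits
  ca <- asg[dh$query_id]; cb <- asg[dh$subject_id]
  cross <- ca != cb
  edges <- data.frame(a = integer(0), b = integer(0), weight = numeric(0))
  if (any(cross)) {
    lo <- pmin(ca[cross], cb[cross]); hi <- pmax(ca[cross], cb[cross])
    key <- paste(lo, hi)
    cnt <- table(key)
    parts <- strsplit(names(cnt), " ", fixed = TRUE)
    a <- as.integer(vapply(parts, `[[`, "", 1))
    b <- as.integer(vapply(parts, `[[`, "", 2))
    denom <- sizes[a] * sizes[b] * if (denominator == "ordered") 2 else 1
    edges <- data.frame(a = a, b = b, weight = as.numeric(cnt) / denom)
    edges <- edges[order(edges$a, edges$b), , drop = FALSE]
    rownames(edges) <- NULL
  }
  list(nodes = nodes, edges = edges)
}

#' Sweep MCL inflation values
#'
#' Runs [mcl()] at each inflation value and tabulates granularity.
#' Inflation 1.0 is admitted; it is the identity on columns and is
#' expected to come out degenerate (a single cluster per component and/or
#' non-convergence).
#'
#' @param network a `similarity_network`.
#' @param values numeric inflation values (>= 1).
#' @param params template [mcl_params()] supplying the remaining knobs.
#' @return Data frame: `inflation`, `n_clusters`,
#'   `largest_cluster_fraction`, `converged`.
#' @export
scan_inflation <- function(network, values = c(1.0, 1.2, 1.3, 1.4, 2, 6),
                           params = mcl_params()) {
  rows <- lapply(values, function(I) {
    p <- params; p$inflation <- I
    cl <- withCallingHandlers(mcl(network, p),
                              warning = function(w) invokeRestart("muffleWarning"))
    data.frame(inflation = I, n_clusters = length(cl$sizes),
               largest_cluster_fraction = max(cl$sizes) / length(cl$assignment),
               converged = cl$converged)
  })
  do.call(rbind, rows)
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items.
#' @param x,y equal-length label vectors.
#' @return Numeric ARI (1 = identical partitions).
#' @export
adjusted_rand_index <- function(x, y) {
  stopifnot(length(x) == length(y))
  tab <- table(x, y)
  n <- length(x)
  a <- sum(choose(tab, 2))
  b <- sum(choose(rowSums(tab), 2))
  cc <- sum(choose(colSums(tab), 2))
  expected <- b * cc / choose(n, 2)
  maxidx <- (b + cc) / 2
  if (maxidx == expected) return(1)
  (a - expected) / (maxidx - expected)
}

#' Export network, clustering and cluster graph as TSV
#'
#' `write_network` writes an edge list (`a`, `b`); `write_clustering`
#' writes two columns (`sequence_id`, `cluster`); `write_cluster_graph`
#' writes the node-attribute table and weighted edge list usable by graph
#' viewers.
#' @param network,clustering,cg the objects to export.
#' @param path,node_path,edge_path output files.
#' @export
write_network <- function(network, path) {
  write.table(network$edges, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
write_clustering <- function(clustering, path) {
  d <- data.frame(sequence_id = names(clustering$assignment),
                  cluster = unname(clustering$assignment))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
write_cluster_graph <- function(cg, node_path, edge_path) {
  write.table(cg$nodes, node_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cg$edges, edge_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(node_path)
}
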