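# Distance-based phylogeny: Poisson-corrected distances from aligned
# rows, Saitou-Nei neighbor joining with deterministic tie-breaking,
# Newick I/O (via ape), and anchor-based clade assignment.

#' Poisson-corrected distance between two aligned rows
#'
#' Columns where either row has a gap are skipped (pairwise deletion);
#' `p` is the mismatch fraction over the compared columns and
#' `d = -ln(1 - p)`.  For `p >= 0.95` the distance is capped at
#' `-ln(0.05)` and flagged via the `"capped"` attribute.
#'
#' @param a,b equal-length gapped strings.
#' @return Numeric distance with attribute `capped`.
#' @export
pairwise_distance <- function(a, b) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  if (length(ca) != length(cb)) stop("aligned rows differ in length")
  use <- ca != "-" & cb != "-"
  if (!any(use)) stop("zero comparable columns")
  p <- mean(ca[use] != cb[use])
  capped <- p >= 0.95
  if (capped) p <- 0.95
  structure(-log(1 - p), capped = capped)
}

#' Distance matrix from aligned sequences
#'
#' @param aln a `star_msa` or named character vector of equal-length
#'   gapped strings.
#' @return Symmetric numeric matrix with zero diagonal; attribute
#'   `capped` marks saturated pairs.
#' @export
distance_matrix <- function(aln) {
  v <- if (inherits(aln, "star_msa")) msa_strings(aln) else aln
  n <- length(v)
  D <- matrix(0, n, n, dimnames = list(names(v), names(v)))
  capped <- matrix(FALSE, n, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      d <- pairwise_distance(v[[i]], v[[j]])
      D[i, j] <- D[j, i] <- as.numeric(d)
      capped[i, j] <- capped[j, i] <- attr(d, "capped")
    }
  }
  structure(D, capped = capped)
}

#' Neighbor-joining tree
#'
#' Saitou-Nei neighbor joining with the standard Q-criterion.  Ties in Q
#' are broken deterministically by the lexicographically lowest id pair.
#' Negative branch lengths are clamped to zero with the deficit moved to
#' the sister branch.  Two taxa yield the trivial two-leaf tree; fewer
#' than two is an error.
#'
#' @param D symmetric distance matrix with dimnames (ids).
#' @return An [ape::phylo] unrooted tree.
#' @export
nj_tree <- function(D) {
  ids <- rownames(D)
  n <- length(ids)
  if (n < 2) stop("need at least 2 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("distance matrix must be symmetric")
  if (n == 2) {
    txt <- sprintf("(%s:%.10g,%s:%.10g);", ids[1], D[1, 2] / 2,
                   ids[2], D[1, 2] / 2)
    return(ape::read.tree(text = txt))
  }
  # active nodes carried as Newick subtree strings
  lab <- ids
  sub <- ids
  Dm <- D
  while (length(lab) > 3) {
    m <- length(lab)
    tot <- rowSums(Dm)
    # Q matrix
    Q <- (m - 2) * Dm - outer(tot, tot, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    best <- NULL
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      if (Q[i, j] <= qmin + 1e-12) {
        key <- sort(c(lab[i], lab[j]))
        if (is.null(best) || key[1] < best$key[1] ||
            (key[1] == best$key[1] && key[2] < best$key[2]))
          best <- list(i = i, j = j, key = key)
      }
    }
    i <- best$i; j <- best$j
    li <- Dm[i, j] / 2 + (tot[i] - tot[j]) / (2 * (m - 2))
    lj <- Dm[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    newsub <- sprintf("(%s:%.10g,%s:%.10g)", sub[i], li, sub[j], lj)
    newlab <- paste0("(", best$key[1], ")")
    dnew <- (Dm[i, ] + Dm[j, ] - Dm[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dnew[keep]),
                 c(dnew[keep], 0))
    lab <- c(lab[keep], newlab)
    sub <- c(sub[keep], newsub)
    dimnames(Dm2) <- NULL
    Dm <- Dm2
  }
  # terminal three-point: branch lengths from the three-point formulas
  d12 <- Dm[1, 2]; d13 <- Dm[1, 3]; d23 <- Dm[2, 3]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  if (l1 < 0) { l2 <- l2 + l1; l3 <- l3 + l1; l1 <- 0 }
  if (l2 < 0) { l1 <- l1 + l2; l3 <- l3 + l2; l2 <- 0 }
  if (l3 < 0) { l1 <- l1 + l3; l2 <- l2 + l3; l3 <- 0 }
  txt <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 sub[1], l1, sub[2], l2, sub[3], l3)
  ape::read.tree(text = txt)
}

#' Newick read/write
#' @param tree an [ape::phylo] object.
#' @param path file path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Distance-matrix TSV I/O (square, header row and column)
#' @param D matrix with dimnames.
#' @param path file path.
#' @export
write_distance_matrix <- function(D, path) {
  d <- data.frame(id = rownames(D), D, check.names = FALSE)
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(d[, -1, drop = FALSE])
  rownames(m) <- d$id
  m
}

#' Assign leaves to clades by nearest anchor
#'
#' Every unanchored leaf inherits the clade of the path-length-nearest
#' anchor leaf; exact ties leave the leaf unassigned (`NA`) with a
#' warning.
#'
#' @param tree an [ape::phylo] tree.
#' @param anchors named character vector: anchor leaf id -> clade label.
#' @return Named character vector leaf -> clade (`NA` where tied).
#' @export
assign_clades <- function(tree, anchors) {
  if (length(anchors) == 0 || is.null(names(anchors)))
    stop("anchors must be a named leaf -> clade vector")
  missing_anchor <- setdiff(names(anchors), tree$tip.label)
  if (length(missing_anchor) > 0)
    stop("anchor leaves not in tree: ", paste(missing_anchor, collapse = ", "))
  pd <- ape::cophenetic.phylo(tree)
  leaves <- tree$tip.label
  out <- stats::setNames(rep(NA_character_, length(leaves)), leaves)
  tied <- character(0)
  for (lf in leaves) {
    if (lf %in% names(anchors)) { out[lf] <- anchors[[lf]]; next }
    d <- pd[lf, names(anchors)]
    nearest <- names(anchors)[d <= min(d) + 1e-12]
    clades <- unique(unname(anchors[nearest]))
    if (length(clades) == 1) out[lf] <- clades
    else tied <- c(tied, lf)
  }
  if (length(tied) > 0)
    warning("tied anchor distances; leaving unassigned: ",
            paste(tied, collapse = ", "))
  out
}
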