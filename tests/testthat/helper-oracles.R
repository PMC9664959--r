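# Independent oracles used across the suite.  These deliberately avoid
# the package's DP/iteration code paths: alignments are enumerated and
# scored by a standalone affine scorer, profile-HMM scores come from
# explicit path enumeration, and the minimal Markov-clustering iteration
# is written separately from pypfam::mcl().

# ---- alignment enumeration -------------------------------------------

# All alignment "shapes" for lengths (la, lb): list of integer vectors
# with moves 1 = diagonal, 2 = up (consume a), 3 = left (consume b).
# Cached per length pair.
.shape_cache <- new.env()
alignment_shapes <- function(la, lb) {
  key <- paste(la, lb)
  if (!is.null(.shape_cache[[key]])) return(.shape_cache[[key]])
  rec <- function(i, j) {
    if (i == 0 && j == 0) return(list(integer(0)))
    out <- list()
    if (i > 0 && j > 0)
      out <- c(out, lapply(rec(i - 1, j - 1), function(s) c(s, 1L)))
    if (i > 0)
      out <- c(out, lapply(rec(i - 1, j), function(s) c(s, 2L)))
    if (j > 0)
      out <- c(out, lapply(rec(i, j - 1), function(s) c(s, 3L)))
    out
  }
  res <- rec(la, lb)
  .shape_cache[[key]] <- res
  res
}

# Score one gapped alignment under gap(k) = open + k * ext.
score_gapped <- function(ga, gb, mat, open, ext) {
  stopifnot(length(ga) == length(gb))
  s <- 0
  run_a <- 0; run_b <- 0  # current gap-run lengths in each row
  for (k in seq_along(ga)) {
    if (ga[k] == "-") {
      run_a <- run_a + 1
      if (run_b > 0) { s <- s - (open + run_b * ext); run_b <- 0 }
    } else if (gb[k] == "-") {
      run_b <- run_b + 1
      if (run_a > 0) { s <- s - (open + run_a * ext); run_a <- 0 }
    } else {
      if (run_a > 0) { s <- s - (open + run_a * ext); run_a <- 0 }
      if (run_b > 0) { s <- s - (open + run_b * ext); run_b <- 0 }
      s <- s + mat[ga[k], gb[k]]
    }
  }
  if (run_a > 0) s <- s - (open + run_a * ext)
  if (run_b > 0) s <- s - (open + run_b * ext)
  s
}

# Brute-force optimal global score by enumerating every alignment.
enum_global_score <- function(a, b, mat, open = 11, ext = 1) {
  ca <- strsplit(a, "", fixed = TRUE)[[1]]
  cb <- strsplit(b, "", fixed = TRUE)[[1]]
  shapes <- alignment_shapes(length(ca), length(cb))
  best <- -Inf
  for (sh in shapes) {
    ga <- character(length(sh)); gb <- character(length(sh))
    i <- 0; j <- 0
    for (k in seq_along(sh)) {
      if (sh[k] != 3L) { i <- i + 1; ga[k] <- ca[i] } else ga[k] <- "-"
      if (sh[k] != 2L) { j <- j + 1; gb[k] <- cb[j] } else gb[k] <- "-"
    }
    best <- max(best, score_gapped(ga, gb, mat, open, ext))
  }
  best
}

# Brute-force optimal local score: max over all substring pairs (and the
# empty alignment, score 0) of the enumerated global score.
enum_local_score <- function(a, b, mat, open = 11, ext = 1) {
  best <- 0
  na <- nchar(a); nb <- nchar(b)
  for (i1 in seq_len(na)) for (i2 in i1:na) {
    sa <- substr(a, i1, i2)
    for (j1 in seq_len(nb)) for (j2 in j1:nb) {
      sb <- substr(b, j1, j2)
      best <- max(best, enum_global_score(sa, sb, mat, open, ext))
    }
  }
  best
}

# Small 4-letter scoring system (a BLOSUM62 sub-block) for exhaustive runs
tiny_alphabet <- c("A", "C", "D", "E")
tiny_matrix <- function() pypfam::blosum62()[tiny_alphabet, tiny_alphabet]
tiny_params <- function() pypfam::scoring_params(matrix = tiny_matrix())

random_tiny_seq <- function(len) {
  paste(sample(tiny_alphabet, len, replace = TRUE), collapse = "")
}

all_tiny_seqs <- function(max_len) {
  out <- character(0)
  for (L in seq_len(max_len)) {
    grid <- do.call(expand.grid, rep(list(tiny_alphabet), L))
    out <- c(out, apply(grid, 1, paste, collapse = ""))
  }
  out
}

# ---- profile-HMM path enumeration ------------------------------------

# Total and maximum path probability P(path, seq | model) over the glocal
# topology (M_0 = begin, no I<->D moves), by explicit recursion over
# states.  Returns probabilities, not bits.
enum_hmm_paths <- function(hmm, seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], pypfam::aa_alphabet())
  n <- hmm$n_match
  L <- length(x)
  tr <- hmm$transitions
  em <- hmm$emissions_match
  ei <- hmm$emissions_insert
  total <- 0; best <- 0
  # state: "M"/"I"/"D" at node k having emitted i residues
  rec <- function(state, k, i, p) {
    if (p == 0) return(invisible(NULL))
    # transitions out of (state, k)
    if (state == "M" || state == "D") node <- k else node <- k
    row <- tr[k + 1, ]
    pick <- function(lbl) row[[lbl]]
    if (k == n) {
      # may exit to end
      pe <- switch(state, M = pick("MM"), I = pick("IM"), D = pick("DM"))
      if (i == L && pe > 0) {
        total <<- total + p * pe
        best <<- max(best, p * pe)
      }
    }
    # insert self/entry
    if (state %in% c("M", "I") && i < L) {
      pi <- switch(state, M = pick("MI"), I = pick("II"))
      if (pi > 0) rec("I", k, i + 1, p * pi * ei[k + 1, x[i + 1]])
    }
    if (k < n) {
      pm <- switch(state, M = pick("MM"), I = pick("IM"), D = pick("DM"))
      if (i < L && pm > 0)
        rec("M", k + 1, i + 1, p * pm * em[k + 1, x[i + 1]])
      pd <- switch(state, M = pick("MD"), I = 0, D = pick("DD"))
      if (pd > 0) rec("D", k + 1, i, p * pd)
    }
    invisible(NULL)
  }
  rec("M", 0, 0, 1)
  list(total = unname(total), best = unname(best))
}

# Background probability of a sequence under the model's null
bg_prob <- function(hmm, seq) {
  x <- match(strsplit(seq, "", fixed = TRUE)[[1]], pypfam::aa_alphabet())
  prod(hmm$background[x])
}

# Random small valid profile HMM (Dirichlet-ish emissions, valid
# transition rows over each state's legal moves).
random_small_hmm <- function(n_match) {
  rnorm_simplex <- function(k) { v <- rexp(k); v / sum(v) }
  bg <- pypfam::blosum62_background()
  em <- t(vapply(seq_len(n_match), function(k) rnorm_simplex(20), numeric(20)))
  colnames(em) <- pypfam::aa_alphabet()
  ei <- matrix(rep(bg, n_match + 1), n_match + 1, 20, byrow = TRUE,
               dimnames = list(NULL, pypfam::aa_alphabet()))
  tr <- matrix(0, n_match + 1, 7,
               dimnames = list(NULL, c("MM","MI","MD","IM","II","DM","DD")))
  for (k in 0:n_match) {
    if (k < n_match) {
      tr[k + 1, c("MM", "MI", "MD")] <- rnorm_simplex(3)
      tr[k + 1, c("IM", "II")] <- rnorm_simplex(2)
      if (k >= 1) tr[k + 1, c("DM", "DD")] <- rnorm_simplex(2)
    } else {
      tr[k + 1, c("MM", "MI")] <- rnorm_simplex(2)
      tr[k + 1, c("IM", "II")] <- rnorm_simplex(2)
      if (k >= 1) tr[k + 1, "DM"] <- 1
    }
  }
  structure(list(n_match = n_match, emissions_match = em,
                 emissions_insert = ei, transitions = tr, background = bg,
                 cutoffs = c(GA = NA_real_, TC = NA_real_, NC = NA_real_),
                 match_columns = seq_len(n_match)),
            class = "profile_hmm")
}

random_aa_seq <- function(len) {
  paste(sample(pypfam::aa_alphabet(), len, replace = TRUE), collapse = "")
}

# ---- independent minimal Markov clustering ---------------------------

# Plain expansion/inflation iteration written independently of the
# package: no pruning, clusters read as unique supports of the limit rows.
simple_mcl <- function(adj, inflation, max_iter = 300) {
  n <- nrow(adj)
  A <- adj
  diag(A) <- 1
  M <- sweep(A, 2, colSums(A), "/")
  for (it in seq_len(max_iter)) {
    Mold <- M
    M <- M %*% M
    M <- M^inflation
    M <- sweep(M, 2, colSums(M), "/")
    if (max(abs(M - Mold)) < 1e-8) break
  }
  supp <- M > 1e-6
  # rows with any support define clusters; overlapping supports merged
  groups <- list()
  for (i in which(rowSums(supp) > 0)) {
    members <- which(supp[i, ])
    merged <- FALSE
    for (g in seq_along(groups)) {
      if (length(intersect(groups[[g]], members)) > 0) {
        groups[[g]] <- union(groups[[g]], members); merged <- TRUE; break
      }
    }
    if (!merged) groups[[length(groups) + 1]] <- members
  }
  # repeat merge until stable
  repeat {
    done <- TRUE
    for (g1 in seq_along(groups)) for (g2 in seq_along(groups)) {
      if (g1 < g2 && length(intersect(groups[[g1]], groups[[g2]])) > 0) {
        groups[[g1]] <- union(groups[[g1]], groups[[g2]])
        groups[[g2]] <- integer(0); done <- FALSE
      }
    }
    groups <- groups[lengths(groups) > 0]
    if (done) break
  }
  lab <- integer(n)
  for (g in seq_along(groups)) lab[groups[[g]]] <- g
  lab
}

# Random undirected graph as a similarity_network-like object
random_network <- function(n, p) {
  nodes <- sprintf("n%02d", seq_len(n))
  e <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (runif(1) < p) e <- rbind(e, data.frame(a = nodes[i], b = nodes[j]))
  }
  if (is.null(e)) e <- data.frame(a = character(0), b = character(0))
  dh <- rbind(data.frame(query_id = e$a, subject_id = e$b),
              data.frame(query_id = e$b, subject_id = e$a))
  structure(list(nodes = nodes, edges = e, directed_hits = dh),
            class = "similarity_network")
}

# Two-block planted-partition network
two_block_network <- function(n_per = 20, p_in = 0.9, p_out = 0.05) {
  n <- 2 * n_per
  nodes <- sprintf("n%02d", seq_len(n))
  block <- rep(1:2, each = n_per)
  e <- NULL
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    p <- if (block[i] == block[j]) p_in else p_out
    if (runif(1) < p) e <- rbind(e, data.frame(a = nodes[i], b = nodes[j]))
  }
  dh <- rbind(data.frame(query_id = e$a, subject_id = e$b),
              data.frame(query_id = e$b, subject_id = e$a))
  list(net = structure(list(nodes = nodes, edges = e, directed_hits = dh),
                       class = "similarity_network"),
       truth = block)
}

# Network of two disjoint triangles
triangles_network <- function() {
  e <- data.frame(a = c("a1","a1","a2","b1","b1","b2"),
                  b = c("a2","a3","a3","b2","b3","b3"))
  dh <- rbind(data.frame(query_id = e$a, subject_id = e$b),
              data.frame(query_id = e$b, subject_id = e$a))
  structure(list(nodes = c("a1","a2","a3","b1","b2","b3"), edges = e,
                 directed_hits = dh),
            class = "similarity_network")
}

# ---- misc -------------------------------------------------------------

# Tiny gene table builder for genomics tests
gene_table <- function(starts, ends, strands = NULL, categories = NULL,
                       genome_id = "g1", contig = "c1") {
  n <- length(starts)
  if (is.null(strands)) strands <- rep("+", n)
  if (is.null(categories)) categories <- rep("other", n)
  ord <- order(starts)
  data.frame(genome_id = genome_id, contig = contig,
             gene_id = sprintf("%s_gene%02d", genome_id, seq_len(n)),
             start = starts[ord], end = ends[ord], strand = strands[ord],
             index = seq_len(n), category = categories[ord],
             sequence_id = NA_character_, stringsAsFactors = FALSE)
}
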