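# Profile hidden Markov model of a family: build from the star MSA,
# Viterbi/forward scoring in log2-odds against the background, database
# search, iterative build-search-rebuild, and gathering/trusted/noise
# cutoffs derived from Cys69 conservation.

.TRANS_NAMES <- c("MM", "MI", "MD", "IM", "II", "DM", "DD")

#' Build a profile HMM from a star MSA
#'
#' Columns with non-gap occupancy at least `match_occupancy` become match
#' states.  Match emissions are `(counts + w * background)` normalized
#' (`w = pseudocount_weight`); insert emissions default to the background;
#' transition probabilities are estimated from the observed per-sequence
#' state paths with add-`w` smoothing over each state's valid moves.  The
#' background is the BLOSUM62 amino-acid frequency vector.
#'
#' @param msa a `star_msa` (all rows, reference included, are training
#'   observations).
#' @param match_occupancy fraction in (0, 1]; default 0.5.
#' @param pseudocount_weight background-mixture weight `w >= 0`
#'   (default 1).
#' @return Object of class `profile_hmm`: `n_match`, `emissions_match`
#'   (n x 20), `emissions_insert` ((n+1) x 20), `transitions`
#'   ((n+1) x 7, columns MM MI MD IM II DM DD; row k holds the moves out
#'   of node k, row 0 being the begin node), `background`, `cutoffs`
#'   (GA/TC/NC, NA until [set_cutoffs()]), `match_columns`.
#' @export
build_hmm <- function(msa, match_occupancy = 0.5, pseudocount_weight = 1) {
  stopifnot(inherits(msa, "star_msa"), match_occupancy > 0,
            match_occupancy <= 1, pseudocount_weight >= 0)
  X <- msa$rows
  nseq <- nrow(X)
  occ <- colMeans(X != "-")
  match_cols <- which(occ >= match_occupancy)
  n <- length(match_cols)
  if (n == 0) stop("MSA has zero match columns at occupancy ", match_occupancy)
  bg <- blosum62_background()
  w <- pseudocount_weight

  em <- matrix(0, n, 20, dimnames = list(NULL, AA_ALPHABET))
  for (k in seq_len(n)) {
    col <- X[, match_cols[k]]
    cnt <- table(factor(col[col != "-"], levels = AA_ALPHABET))
    em[k, ] <- (as.numeric(cnt) + w * bg) / (sum(cnt) + w)
  }
  ei <- matrix(rep(bg, n + 1), n + 1, 20, byrow = TRUE,
               dimnames = list(NULL, AA_ALPHABET))

  # observed state paths -> transition counts per node
  node_of_col <- cumsum(seq_len(ncol(X)) %in% match_cols)  # node after col
  is_match <- seq_len(ncol(X)) %in% match_cols
  cnt_tr <- matrix(0, n + 1, 7, dimnames = list(NULL, .TRANS_NAMES))
  for (s in seq_len(nseq)) {
    prev_state <- "M"; prev_node <- 0L
    for (j in seq_len(ncol(X))) {
      if (is_match[j]) {
        st <- if (X[s, j] != "-") "M" else "D"
        cnt_tr[prev_node + 1, paste0(prev_state, st)] <-
          cnt_tr[prev_node + 1, paste0(prev_state, st)] + 1
        prev_state <- st; prev_node <- node_of_col[j]
      } else if (X[s, j] != "-") {
        if (prev_state == "D") next  # no D->I transitions in this topology
        cnt_tr[prev_node + 1, paste0(prev_state, "I")] <-
          cnt_tr[prev_node + 1, paste0(prev_state, "I")] + 1
        prev_state <- "I"
      }
    }
    # exit to the end state (recorded as *M at node n)
    cnt_tr[n + 1, paste0(prev_state, "M")] <-
      cnt_tr[n + 1, paste0(prev_state, "M")] + 1
  }

  tr <- matrix(0, n + 1, 7, dimnames = list(NULL, .TRANS_NAMES))
  valid <- function(k, st) {
    if (st == "M") if (k < n) c("MM", "MI", "MD") else c("MM", "MI")
    else if (st == "I") c("IM", "II")
    else if (k >= 1) { if (k < n) c("DM", "DD") else "DM" } else character(0)
  }
  for (k in 0:n) {
    for (st in c("M", "I", "D")) {
      vv <- valid(k, st)
      if (length(vv) == 0) next
      cc <- cnt_tr[k + 1, vv]
      tot <- sum(cc)
      if (tot + w * length(vv) == 0) {
        tr[k + 1, vv] <- 1 / length(vv)  # unvisited state, w = 0: uniform
      } else {
        tr[k + 1, vv] <- (cc + w) / (tot + w * length(vv))
      }
    }
  }
  structure(list(n_match = n, emissions_match = em, emissions_insert = ei,
                 transitions = tr, background = bg,
                 cutoffs = c(GA = NA_real_, TC = NA_real_, NC = NA_real_),
                 match_columns = match_cols),
            class = "profile_hmm")
}

#' @export
print.profile_hmm <- function(x, ...) {
  co <- x$cutoffs
  cat(sprintf("profile_hmm: %d match states; cutoffs GA=%s TC=%s NC=%s\n",
              x$n_match, format(co[["GA"]]), format(co[["TC"]]),
              format(co[["NC"]])))
  invisible(x)
}

.hmm_logs <- function(hmm) {
  lz <- function(x) { l <- log(x); l[!is.finite(l)] <- -1e300; l }
  list(lem = lz(sweep(hmm$emissions_match, 2, hmm$background, "/")),
       lei = lz(sweep(hmm$emissions_insert, 2, hmm$background, "/")),
       ltr = lz(hmm$transitions))
}

.encode_seq <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  idx <- match(chars, AA_ALPHABET)
  if (any(is.na(idx))) .check_residues(seq)
  idx - 1L
}

#' Viterbi score and state path
#'
#' Maximum-probability glocal path (all match/delete columns traversed,
#' flanks absorbed by the terminal insert states), scored in log2-odds
#' against the i.i.d. background.  Ties are broken M > D > I.
#'
#' @param hmm a `profile_hmm`.
#' @param seq residue string (non-empty).
#' @return List: `bit_score`, `path` (character vector like
#'   `c("I0","M1",...)`).
#' @export
hmm_viterbi <- function(hmm, seq) {
  if (!nzchar(seq)) stop("empty sequence")
  l <- .hmm_logs(hmm)
  r <- cpp_hmm_score(.encode_seq(seq), l$lem, l$lei, l$ltr, TRUE)
  list(bit_score = r$viterbi, path = r$path)
}

#' Forward score
#'
#' Total path probability in log2-odds; always at least the Viterbi
#' score.
#' @inheritParams hmm_viterbi
#' @return Numeric bit score.
#' @export
hmm_forward <- function(hmm, seq) {
  if (!nzchar(seq)) stop("empty sequence")
  l <- .hmm_logs(hmm)
  cpp_hmm_score(.encode_seq(seq), l$lem, l$lei, l$ltr, FALSE)$forward
}

#' Search a sequence database with a profile HMM
#'
#' Scores every sequence with the forward algorithm and returns hits at or
#' above the selected cutoff, sorted by score (descending, ties by id).
#'
#' @param hmm a `profile_hmm` (cutoffs must be set unless
#'   `cutoff = "none"`).
#' @param db SequenceRecord data.frame or named character vector.
#' @param cutoff `"GA"`, `"TC"`, `"NC"` or `"none"`.
#' @return Data frame: `sequence_id`, `bit_score`, `passes_NC`,
#'   `passes_GA`, `passes_TC`.
#' @export
hmm_search <- function(hmm, db, cutoff = c("GA", "TC", "NC", "none")) {
  cutoff <- match.arg(cutoff)
  v <- .as_seq_vector(db)
  if (length(v) == 0)
    return(data.frame(sequence_id = character(0), bit_score = numeric(0),
                      passes_NC = logical(0), passes_GA = logical(0),
                      passes_TC = logical(0)))
  l <- .hmm_logs(hmm)
  sc <- vapply(v, function(s)
    cpp_hmm_score(.encode_seq(s), l$lem, l$lei, l$ltr, FALSE)$forward, 0)
  co <- hmm$cutoffs
  d <- data.frame(sequence_id = names(v), bit_score = unname(sc),
                  passes_NC = if (is.na(co[["NC"]])) NA else sc >= co[["NC"]],
                  passes_GA = if (is.na(co[["GA"]])) NA else sc >= co[["GA"]],
                  passes_TC = if (is.na(co[["TC"]])) NA else sc >= co[["TC"]],
                  stringsAsFactors = FALSE)
  d <- d[order(-d$bit_score, d$sequence_id), , drop = FALSE]
  rownames(d) <- NULL
  if (cutoff != "none") {
    thr <- co[[cutoff]]
    if (is.na(thr)) stop("cutoff ", cutoff, " is not set on this model")
    d <- d[d$bit_score >= thr, , drop = FALSE]
  }
  d
}

#' Set noise/trusted/gathering cutoffs from Cys69 conservation
#'
#' TC (trusted) is the minimum score among functional (Cys69-conserved)
#' training-set members; NC (noise) is the maximum score among scored
#' sequences that are not functional (0 bits if there are none); GA
#' (gathering) is the midpoint of TC and NC in bits, floored at NC.  If
#' the functional and non-functional score ranges overlap (NC > TC) the
#' model is flagged non-separable and both GA and NC are collapsed onto
#' TC so that NC <= GA <= TC always holds.
#'
#' @param hmm a `profile_hmm`.
#' @param scores named numeric vector of bit scores (ids -> score).
#' @param functional named logical vector over the same ids (the Cys69
#'   call).
#' @param training_ids ids of the training-set members (defaults to all
#'   scored ids).
#' @return The model with `cutoffs` filled in; attribute `"separable"`
#'   records whether TC >= NC held before clamping.
#' @export
set_cutoffs <- function(hmm, scores, functional,
                        training_ids = names(scores)) {
  stopifnot(!is.null(names(scores)))
  functional <- functional[names(scores)]
  if (any(is.na(functional)))
    stop("every scored sequence needs a residue call (functional flag)")
  train_fun <- intersect(training_ids, names(scores)[functional])
  if (length(train_fun) == 0) stop("no functional sequence among the training set")
  TC <- min(scores[train_fun])
  nonfun <- names(scores)[!functional]
  NC <- if (length(nonfun) > 0) max(scores[nonfun]) else 0
  GA <- max(NC, (TC + NC) / 2)
  separable <- NC <= TC
  if (!separable) {
    warning("functional and non-functional scores overlap (NC > TC); ",
            "cutoffs collapsed to TC")
    NC <- TC; GA <- TC
  }
  hmm$cutoffs <- c(GA = GA, TC = TC, NC = NC)
  attr(hmm, "separable") <- separable
  hmm
}

#' Iterative profile-HMM building
#'
#' Repeats the family-modelling cycle: star-align the training set to the
#' reference, reduce redundancy at `identity_reduce`, build the HMM, score
#' the database, set cutoffs from the Cys69 calls, search at GA, and union
#' the hits into the training set; stops when the hit set is unchanged
#' between rounds (or cycles, which is flagged as oscillation) or after
#' `max_rounds`.
#'
#' @param seed_seqs starting training set (SequenceRecord data.frame or
#'   named character vector).
#' @param db database to search (same formats).
#' @param reference reference record (Cys69 numbering anchor).
#' @param params a [scoring_params()].
#' @param max_rounds cap on build/search cycles.
#' @param identity_reduce redundancy threshold for the training set
#'   (default 0.8).
#' @param match_occupancy,pseudocount_weight passed to [build_hmm()].
#' @param calls optional precomputed residue calls for `db` (list from
#'   [call_residues_many()]); computed if missing.
#' @return List: `hmm` (final model with cutoffs), `rounds` (per-round
#'   hit id sets), `hits` (final), `converged`, `oscillated`, `n_rounds`.
#' @export
iterate_build <- function(seed_seqs, db, reference,
                          params = scoring_params(), max_rounds = 5,
                          identity_reduce = 0.8, match_occupancy = 0.5,
                          pseudocount_weight = 1, calls = NULL) {
  seeds <- .as_seq_vector(seed_seqs)
  if (length(seeds) == 0) stop("empty seed set")
  dbv <- .as_seq_vector(db)
  if (is.null(calls))
    calls <- call_residues_many(dbv, reference, params)
  functional <- vapply(calls, `[[`, TRUE, "functional")[names(dbv)]
  names(functional) <- names(dbv)

  training <- seeds
  rounds <- list()
  hmm <- NULL; hits <- character(0)
  converged <- FALSE; oscillated <- FALSE
  for (round in seq_len(max_rounds)) {
    red <- reduce_redundancy(training, identity_reduce, params)
    tr_set <- training[red$representatives]
    msa <- star_msa(tr_set, reference, params)
    hmm <- build_hmm(msa, match_occupancy, pseudocount_weight)
    scored <- hmm_search(hmm, dbv, cutoff = "none")
    scores <- stats::setNames(scored$bit_score, scored$sequence_id)
    hmm <- suppressWarnings(
      set_cutoffs(hmm, scores, functional,
                  training_ids = intersect(names(training), names(scores))))
    hit_ids <- hmm_search(hmm, dbv, cutoff = "GA")$sequence_id
    rounds[[round]] <- hit_ids
    if (round > 1 && setequal(hit_ids, rounds[[round - 1]])) {
      converged <- TRUE; hits <- hit_ids; break
    }
    if (round > 2) {
      for (prev in seq_len(round - 2)) {
        if (setequal(hit_ids, rounds[[prev]])) { oscillated <- TRUE; break }
      }
      if (oscillated) {
        warning("hit set oscillates between rounds; stopping")
        hits <- hit_ids; break
      }
    }
    hits <- hit_ids
    training <- c(training, dbv[setdiff(hit_ids, names(training))])
  }
  list(hmm = hmm, rounds = rounds, hits = hits, converged = converged,
       oscillated = oscillated, n_rounds = length(rounds))
}

#' Serialize / read a profile HMM as plain text
#'
#' Fixed-point 6-decimal format with exact re-write stability:
#' header (`PYPFAM_HMM 1`, `NMATCH`, `CUTOFFS GA TC NC`, `ALPHABET`,
#' `BACKGROUND`), then per node `MATCH k`, `INSERT k` and `TRANS k` lines.
#' @param hmm a `profile_hmm`.
#' @param path file path.
#' @return `read_hmm` returns a `profile_hmm`.
#' @export
write_hmm <- function(hmm, path) {
  f6 <- function(x) paste(sprintf("%.6f", x), collapse = " ")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "PYPFAM_HMM 1",
    paste("NMATCH", hmm$n_match),
    paste("CUTOFFS", f6(hmm$cutoffs[c("GA", "TC", "NC")])),
    paste("ALPHABET", paste(AA_ALPHABET, collapse = " ")),
    paste("BACKGROUND", f6(hmm$background))), con)
  for (k in seq_len(hmm$n_match))
    writeLines(paste("MATCH", k, f6(hmm$emissions_match[k, ])), con)
  for (k in 0:hmm$n_match)
    writeLines(paste("INSERT", k, f6(hmm$emissions_insert[k + 1, ])), con)
  for (k in 0:hmm$n_match)
    writeLines(paste("TRANS", k, f6(hmm$transitions[k + 1, ])), con)
  invisible(path)
}

#' @rdname write_hmm
#' @export
read_hmm <- function(path) {
  lines <- readLines(path)
  if (!startsWith(lines[1], "PYPFAM_HMM")) stop("not a pypfam HMM file")
  fields <- strsplit(lines, " +")
  key <- vapply(fields, `[[`, "", 1)
  nums <- function(x, from) as.numeric(x[-seq_len(from)])
  n <- as.integer(fields[[which(key == "NMATCH")[1]]][2])
  cutoffs <- nums(fields[[which(key == "CUTOFFS")[1]]], 1)
  names(cutoffs) <- c("GA", "TC", "NC")
  bg <- nums(fields[[which(key == "BACKGROUND")[1]]], 1)
  names(bg) <- AA_ALPHABET
  em <- matrix(0, n, 20, dimnames = list(NULL, AA_ALPHABET))
  for (f in fields[key == "MATCH"]) em[as.integer(f[2]), ] <- nums(f, 2)
  ei <- matrix(0, n + 1, 20, dimnames = list(NULL, AA_ALPHABET))
  for (f in fields[key == "INSERT"]) ei[as.integer(f[2]) + 1, ] <- nums(f, 2)
  tr <- matrix(0, n + 1, 7, dimnames = list(NULL, .TRANS_NAMES))
  for (f in fields[key == "TRANS"]) tr[as.integer(f[2]) + 1, ] <- nums(f, 2)
  structure(list(n_match = n, emissions_match = em, emissions_insert = ei,
                 transitions = tr, background = bg, cutoffs = cutoffs,
                 match_columns = seq_len(n)),
            class = "profile_hmm")
}

#' Write search results as TSV
#' @param hits data.frame from [hmm_search()].
#' @param path file path.
#' @export
write_search_results <- function(hits, path) {
  write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
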