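# Pairwise alignment (global and local, affine gaps), Karlin-Altschul
# E-values, greedy redundancy reduction, and the hits TSV interchange
# format.  These are the in-package stand-ins for BLAST and CD-HIT.

.alignment_result <- function(r, a, b, qid, sid, params, local) {
  len <- r$length
  identity <- if (len > 0) r$identical / len else 0
  if (local) {
    qcov <- if (len > 0) (r$a_end - r$a_start + 1) / nchar(a) else 0
    scov <- if (len > 0) (r$b_end - r$b_start + 1) / nchar(b) else 0
  } else {
    qcov <- if (nchar(a) > 0) 1 else 0
    scov <- if (nchar(b) > 0) 1 else 0
  }
  m <- if (is.na(params$search_space_m)) nchar(a) else params$search_space_m
  n <- if (is.na(params$search_space_n)) nchar(b) else params$search_space_n
  bit <- (params$lambda * r$score - log(params$K)) / log(2)
  ev <- if (m > 0 && n > 0) params$K * m * n * exp(-params$lambda * r$score) else NA_real_
  ga <- strsplit(r$aligned_a, "", fixed = TRUE)[[1]]
  gb <- strsplit(r$aligned_b, "", fixed = TRUE)[[1]]
  qpos <- spos <- integer(length(ga))
  qi <- r$a_start - 1L; si <- r$b_start - 1L
  for (k in seq_along(ga)) {
    if (ga[k] != "-") { qi <- qi + 1L; qpos[k] <- qi } else qpos[k] <- NA_integer_
    if (gb[k] != "-") { si <- si + 1L; spos[k] <- si } else spos[k] <- NA_integer_
  }
  structure(list(
    query_id = qid, subject_id = sid,
    raw_score = r$score, bit_score = bit, e_value = ev,
    identity = identity, query_coverage = qcov, subject_coverage = scov,
    aligned_query = r$aligned_a, aligned_subject = r$aligned_b,
    query_span = c(r$a_start, r$a_end), subject_span = c(r$b_start, r$b_end),
    aligned_pairs = data.frame(query_pos = qpos, subject_pos = spos)),
    class = "alignment_result")
}

#' @export
print.alignment_result <- function(x, ...) {
  cat(sprintf("%s vs %s: score %g (%.1f bits, E=%.3g), identity %.3f, cov %.2f/%.2f\n",
              x$query_id, x$subject_id, x$raw_score, x$bit_score, x$e_value,
              x$identity, x$query_coverage, x$subject_coverage))
  invisible(x)
}

.check_pair_input <- function(a, b, allow_empty) {
  if (!is.character(a) || !is.character(b) || length(a) != 1 || length(b) != 1)
    stop("sequences must be single character strings")
  if (nchar(a) == 0 && !allow_empty) stop("empty input sequence 'a'")
  if (nchar(b) == 0 && !allow_empty) stop("empty input sequence 'b'")
  if (nchar(a) > 0) .check_residues(a, "sequence 'a'")
  if (nchar(b) > 0) .check_residues(b, "sequence 'b'")
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' End-to-end optimal alignment under the gap cost
#' `gap(k) = gap_open + k * gap_extend`.  Traceback ties are broken
#' deterministically: diagonal > up (gap in `b`) > left (gap in `a`).
#'
#' @param a,b residue strings over [aa_alphabet()].
#' @param params a [scoring_params()] object.
#' @param query_id,subject_id labels carried into the result.
#' @param allow_empty permit an empty sequence (scored as one long gap);
#'   by default empty input is an error.
#' @return An `alignment_result` with raw/bit scores, E-value, identity
#'   (identical columns / alignment length, gaps included), per-sequence
#'   coverage, and the aligned column pairs in 1-based coordinates.
#' @export
global_align <- function(a, b, params = scoring_params(),
                         query_id = "query", subject_id = "subject",
                         allow_empty = FALSE) {
  .check_pair_input(a, b, allow_empty)
  r <- cpp_align(a, b, params$lut, params$gap_open, params$gap_extend, FALSE)
  .alignment_result(r, a, b, query_id, subject_id, params, local = FALSE)
}

#' Local (Smith-Waterman) alignment with affine gaps
#'
#' Optimal local alignment with score floored at 0 (the empty alignment is
#' always admissible).  Coverage is the aligned span divided by each full
#' sequence length.
#' @inheritParams global_align
#' @return An `alignment_result`.
#' @export
local_align <- function(a, b, params = scoring_params(),
                        query_id = "query", subject_id = "subject") {
  .check_pair_input(a, b, allow_empty = FALSE)
  r <- cpp_align(a, b, params$lut, params$gap_open, params$gap_extend, TRUE)
  .alignment_result(r, a, b, query_id, subject_id, params, local = TRUE)
}

#' Karlin-Altschul E-value for a raw alignment score
#'
#' `E = K * m * n * exp(-lambda * S)`, strictly decreasing in S.
#' @param raw_score raw alignment score in matrix units.
#' @param params a [scoring_params()]; `search_space_m` / `search_space_n`
#'   must be positive residue counts.
#' @return Expected number of chance hits at this score.
#' @export
estimate_evalue <- function(raw_score, params) {
  m <- params$search_space_m; n <- params$search_space_n
  if (is.na(m) || is.na(n) || m <= 0 || n <= 0)
    stop("search_space_m and search_space_n must be positive")
  params$K * m * n * exp(-params$lambda * raw_score)
}

#' Pairwise identity from the global alignment
#'
#' Identical columns divided by the full alignment length (gap columns
#' included in the denominator).
#' @inheritParams global_align
#' @return Fraction between 0 and 1.
#' @export
pairwise_identity <- function(a, b, params = scoring_params()) {
  r <- cpp_align(a, b, params$lut, params$gap_open, params$gap_extend, FALSE)
  if (r$length == 0) 0 else r$identical / r$length
}

#' Greedy incremental redundancy reduction
#'
#' CD-HIT-style clustering: sequences are sorted longest first (ties by
#' id), each sequence joins the first existing representative whose global
#' identity to it is at least `identity_threshold`, otherwise it becomes a
#' new representative.
#'
#' @param seqs SequenceRecord data.frame or named character vector.
#' @param identity_threshold fraction in (0, 1].
#' @param params a [scoring_params()].
#' @return List with `representatives` (ids, in admission order) and
#'   `membership` (named character vector: member id -> representative id).
#' @export
reduce_redundancy <- function(seqs, identity_threshold = 0.95,
                              params = scoring_params()) {
  if (identity_threshold <= 0 || identity_threshold > 1)
    stop("identity_threshold must be in (0, 1]")
  v <- .as_seq_vector(seqs)
  if (length(v) == 0)
    return(list(representatives = character(0), membership = character(0)))
  ord <- order(-nchar(v), names(v))
  v <- v[ord]
  reps <- character(0)
  membership <- character(length(v)); names(membership) <- names(v)
  for (i in seq_along(v)) {
    placed <- FALSE
    for (r in reps) {
      if (pairwise_identity(v[[i]], v[[r]], params) >= identity_threshold) {
        membership[[names(v)[i]]] <- r; placed <- TRUE; break
      }
    }
    if (!placed) {
      reps <- c(reps, names(v)[i])
      membership[[names(v)[i]]] <- names(v)[i]
    }
  }
  list(representatives = reps, membership = membership)
}

#' All-vs-all local alignment
#'
#' Aligns every ordered pair of distinct sequences (the BLAST stand-in
#' behind the similarity network).  The E-value search space per hit is
#' query length times the summed residue count of the database.
#'
#' @inheritParams reduce_redundancy
#' @return Data frame with one row per ordered pair: `query_id`,
#'   `subject_id`, `raw_score`, `bit_score`, `e_value`, `identity`,
#'   `query_coverage`, `subject_coverage`.
#' @export
all_vs_all <- function(seqs, params = scoring_params()) {
  v <- .as_seq_vector(seqs)
  for (i in seq_along(v)) .check_residues(v[[i]], names(v)[i])
  r <- cpp_all_vs_all(unname(v), params$lut, params$gap_open, params$gap_extend)
  total_res <- sum(nchar(v))
  qlen <- nchar(v)[r$query]
  data.frame(
    query_id = names(v)[r$query], subject_id = names(v)[r$subject],
    raw_score = r$score,
    bit_score = (params$lambda * r$score - log(params$K)) / log(2),
    e_value = params$K * qlen * total_res * exp(-params$lambda * r$score),
    identity = r$identity,
    query_coverage = r$qcov, subject_coverage = r$scov,
    stringsAsFactors = FALSE)
}

#' Write / read alignment hits as outfmt6-style TSV
#'
#' Columns, in order: qseqid, sseqid, pident, length, evalue, bitscore,
#' qcovs, scovs.  pident/qcovs/scovs are percentages with two decimals;
#' `length` is omitted as -1 when unknown.
#' @param hits data.frame as returned by [all_vs_all()].
#' @param path file path.
#' @return `read_hits` returns a data.frame in [all_vs_all()] layout.
#' @export
write_hits <- function(hits, path) {
  out <- data.frame(
    qseqid = hits$query_id, sseqid = hits$subject_id,
    pident = sprintf("%.2f", 100 * hits$identity),
    length = if ("length" %in% names(hits)) hits$length else -1L,
    evalue = sprintf("%.6g", hits$e_value),
    bitscore = sprintf("%.4f", hits$bit_score),
    qcovs = sprintf("%.2f", 100 * hits$query_coverage),
    scovs = sprintf("%.2f", 100 * hits$subject_coverage))
  write.table(out, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  d <- read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  data.frame(query_id = d$qseqid, subject_id = d$sseqid,
             raw_score = NA_real_, bit_score = d$bitscore,
             e_value = d$evalue, identity = d$pident / 100,
             query_coverage = d$qcovs / 100, subject_coverage = d$scovs / 100,
             stringsAsFactors = FALSE)
}
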