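# Reference-anchored residue analysis: map homologs onto the reference
# PYP numbering, call the chromophore-binding residues (Tyr42, Glu46,
# Cys69 and the clade signatures), define family membership by the Cys69
# rule, and build a star MSA with conservation profiles.

PYP_POSITIONS <- c(42L, 46L, 50L, 69L, 92L, 96L, 100L, 119L)

.as_record <- function(x) {
  if (is.list(x) && !is.data.frame(x) && !is.null(x$residues))
    return(list(id = if (is.null(x$id)) "seq" else x$id, residues = x$residues))
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1)
    return(list(id = x$id, residues = x$residues))
  }
  if (is.character(x) && length(x) == 1)
    return(list(id = if (is.null(names(x))) "seq" else names(x),
                residues = unname(x)))
  stop("expected a sequence record (list/one-row data.frame/named string)")
}

#' Map a sequence onto reference coordinates
#'
#' Globally aligns the target to the reference; every reference position
#' (1-based) is mapped to the aligned target residue or to the gap marker
#' `"-"`.  Target residues inserted relative to the reference are recorded
#' per preceding reference position (0 = before the first).
#'
#' @param seq,reference sequence records (list with `id`/`residues`,
#'   one-row SequenceRecord data.frame, or named string).
#' @param params a [scoring_params()].
#' @param min_bitscore reliability floor: maps whose alignment bit score
#'   falls below it are flagged unreliable (default 20 bits).
#' @return Object of class `reference_map` with `sequence_id`, `mapping`
#'   (character vector of length `nchar(reference)`), `insertions`,
#'   `alignment_score`, `bit_score`, `reliable`.
#' @export
map_to_reference <- function(seq, reference, params = scoring_params(),
                             min_bitscore = 20) {
  s <- .as_record(seq); r <- .as_record(reference)
  aln <- global_align(s$residues, r$residues, params,
                      query_id = s$id, subject_id = r$id)
  ga <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1]]
  gb <- strsplit(aln$aligned_subject, "", fixed = TRUE)[[1]]
  nref <- nchar(r$residues)
  mapping <- rep("-", nref)
  insertions <- rep("", nref + 1)  # slot p+1 = insertions after ref pos p
  rp <- 0L
  for (k in seq_along(gb)) {
    if (gb[k] != "-") {
      rp <- rp + 1L
      mapping[rp] <- ga[k]
    } else if (ga[k] != "-") {
      insertions[rp + 1L] <- paste0(insertions[rp + 1L], ga[k])
    }
  }
  structure(list(sequence_id = s$id, mapping = mapping,
                 insertions = insertions,
                 alignment_score = aln$raw_score, bit_score = aln$bit_score,
                 reliable = aln$bit_score >= min_bitscore),
            class = "reference_map")
}

#' Call residues at reference-anchored positions
#'
#' Reads the mapped residue at each probed position, emits substitution
#' labels of the form `"Y42F"` (reference residue, position, observed;
#' gaps written `"-"`) wherever the observed residue differs, and sets the
#' functional flag by the Cys69 rule: functional iff the residue mapped to
#' reference position 69 is `C`.
#'
#' @param refmap a `reference_map`.
#' @param reference the reference record the map was built against.
#' @param positions probed reference positions (default the PYP set
#'   42/46/50/69/92/96/100/119).
#' @return Object of class `residue_call`: `sequence_id`, `residues_at`
#'   (named by position), `substitution_labels`, `functional`, `reliable`.
#' @export
call_residues <- function(refmap, reference, positions = PYP_POSITIONS) {
  r <- .as_record(reference)
  nref <- nchar(r$residues)
  if (any(positions < 1 | positions > nref))
    stop("position outside reference length (1..", nref, ")")
  refres <- strsplit(r$residues, "", fixed = TRUE)[[1]]
  obs <- refmap$mapping[positions]
  names(obs) <- positions
  labels <- character(0)
  for (i in seq_along(positions)) {
    p <- positions[i]
    if (obs[i] != refres[p])
      labels <- c(labels, paste0(refres[p], p, obs[i]))
  }
  functional <- if (69L %in% positions) unname(obs[as.character(69)]) == "C"
                else refmap$mapping[69] == "C"
  structure(list(sequence_id = refmap$sequence_id, residues_at = obs,
                 substitution_labels = labels,
                 functional = isTRUE(functional),
                 reliable = refmap$reliable),
            class = "residue_call")
}

#' Residue calls for a whole sequence set
#'
#' Convenience wrapper: maps each sequence to the reference and calls the
#' probed positions; unreliable maps are kept but flagged.
#' @param seqs SequenceRecord data.frame or named character vector.
#' @inheritParams map_to_reference
#' @inheritParams call_residues
#' @return List of `residue_call` objects, named by sequence id.
#' @export
call_residues_many <- function(seqs, reference, params = scoring_params(),
                               positions = PYP_POSITIONS, min_bitscore = 20) {
  v <- .as_seq_vector(seqs)
  out <- lapply(seq_along(v), function(i) {
    rm <- map_to_reference(list(id = names(v)[i], residues = v[[i]]),
                           reference, params, min_bitscore)
    call_residues(rm, reference, positions)
  })
  stats::setNames(out, names(v))
}

#' Tabulate residue calls
#'
#' @param calls list of `residue_call` objects.
#' @return Data frame: id, one residue column per probed position,
#'   semicolon-joined labels, `functional`, `reliable`.
#' @export
calls_table <- function(calls) {
  pos <- names(calls[[1]]$residues_at)
  d <- data.frame(id = vapply(calls, `[[`, "", "sequence_id"),
                  stringsAsFactors = FALSE)
  for (p in pos)
    d[[paste0("res", p)]] <- vapply(calls, function(cl) cl$residues_at[[p]], "")
  d$labels <- vapply(calls, function(cl)
    paste(cl$substitution_labels, collapse = ";"), "")
  d$functional <- vapply(calls, `[[`, TRUE, "functional")
  d$reliable <- vapply(calls, `[[`, TRUE, "reliable")
  rownames(d) <- NULL
  d
}

#' Classify family membership from residue calls
#'
#' Members are the functional calls (Cys69 conserved).  The summary
#' reports the member fraction, the fraction with the fully conserved
#' Tyr42/Glu46/Cys69 triad, per-label counts and fractions, and whether
#' any functional member carries both a 42-substitution and a
#' 46-substitution (a co-occurrence never observed in the real family).
#'
#' @param calls list of `residue_call` objects.
#' @return List: `table` (per-sequence calls with membership),
#'   `members` (ids), `n`, `member_fraction`, `triad_fraction`,
#'   `label_counts`, `label_fractions`, `y42_e46_cooccurrence`.
#' @export
classify_family <- function(calls) {
  tab <- calls_table(calls)
  tab$member <- tab$functional
  n <- nrow(tab)
  labs <- lapply(calls, `[[`, "substitution_labels")
  has42 <- vapply(labs, function(l) any(grepl("^.42", l)), TRUE)
  has46 <- vapply(labs, function(l) any(grepl("^.46", l)), TRUE)
  triad <- tab$functional & !has42 & !has46
  all_labels <- unlist(labs)
  label_counts <- if (length(all_labels)) table(all_labels) else table(character(0))
  list(table = tab,
       members = tab$id[tab$member],
       n = n,
       member_fraction = mean(tab$member),
       triad_fraction = mean(triad),
       label_counts = label_counts,
       label_fractions = if (n > 0) label_counts / n else label_counts,
       y42_e46_cooccurrence = any(tab$functional & has42 & has46))
}

#' Reference-anchored star multiple alignment
#'
#' Merges the pairwise global alignments of each sequence to the
#' reference on the reference positions.  Insertions relative to the
#' reference become insert columns (left-aligned, gap-padded in all other
#' rows); the reference row is gap-free in reference-anchored columns.
#' Sequences whose map is unreliable are excluded with a warning.
#'
#' @inheritParams call_residues_many
#' @return Object of class `star_msa`: `ids` (reference first), `rows`
#'   (character matrix, one row per sequence), `is_ref_column`,
#'   `ref_position` (NA at insert columns).
#' @export
star_msa <- function(seqs, reference, params = scoring_params(),
                     min_bitscore = 20) {
  v <- .as_seq_vector(seqs)
  r <- .as_record(reference)
  nref <- nchar(r$residues)
  maps <- lapply(seq_along(v), function(i)
    map_to_reference(list(id = names(v)[i], residues = v[[i]]),
                     reference, params, min_bitscore))
  ok <- vapply(maps, `[[`, TRUE, "reliable")
  if (any(!ok))
    warning(sprintf("excluding %d sequence(s) with unreliable reference maps: %s",
                    sum(!ok), paste(names(v)[!ok], collapse = ", ")))
  maps <- maps[ok]; v <- v[ok]
  ins_len <- rep(0L, nref + 1)
  for (m in maps) ins_len <- pmax(ins_len, nchar(m$insertions))
  width <- nref + sum(ins_len)
  is_ref <- logical(0); ref_position <- integer(0)
  for (p in 0:nref) {
    if (ins_len[p + 1] > 0) {
      is_ref <- c(is_ref, rep(FALSE, ins_len[p + 1]))
      ref_position <- c(ref_position, rep(NA_integer_, ins_len[p + 1]))
    }
    if (p < nref) { is_ref <- c(is_ref, TRUE); ref_position <- c(ref_position, p + 1L) }
  }
  # note: insertion slot p+1 holds residues between ref pos p and p+1,
  # so slot order is: ins(0), pos1, ins(1), pos2, ..., posn, ins(n)
  build_row <- function(mapping, insertions) {
    out <- character(0)
    for (p in 0:nref) {
      if (ins_len[p + 1] > 0) {
        ins <- strsplit(insertions[p + 1], "", fixed = TRUE)[[1]]
        out <- c(out, ins, rep("-", ins_len[p + 1] - length(ins)))
      }
      if (p < nref) out <- c(out, mapping[p + 1])
    }
    out
  }
  refchars <- strsplit(r$residues, "", fixed = TRUE)[[1]]
  rows <- matrix("-", nrow = length(v) + 1, ncol = width,
                 dimnames = list(c(r$id, names(v)), NULL))
  rows[1, ] <- build_row(refchars, rep("", nref + 1))
  for (i in seq_along(maps))
    rows[i + 1, ] <- build_row(maps[[i]]$mapping, maps[[i]]$insertions)
  # fix column metadata (built above for p<nref; append trailing inserts)
  structure(list(ids = c(r$id, names(v)), rows = rows,
                 is_ref_column = is_ref, ref_position = ref_position),
            class = "star_msa")
}

#' @export
print.star_msa <- function(x, ...) {
  cat(sprintf("star_msa: %d rows x %d columns (%d reference-anchored)\n",
              nrow(x$rows), ncol(x$rows), sum(x$is_ref_column)))
  invisible(x)
}

#' Aligned rows of a star MSA as strings
#' @param msa a `star_msa`.
#' @return Named character vector of equal-length gapped strings.
#' @export
msa_strings <- function(msa) {
  stats::setNames(apply(msa$rows, 1, paste, collapse = ""), msa$ids)
}

#' Write a star MSA as aligned FASTA
#' @param msa a `star_msa`.
#' @param path file path.
#' @export
write_msa <- function(msa, path) {
  write_fasta(msa_strings(msa), path)
}

#' Per-position conservation profiles by group
#'
#' For every reference-anchored column and every group, the frequencies of
#' the 20 residues plus gap (summing to 1).  Insert columns are excluded:
#' profiles are reference-anchored by design.
#'
#' @param msa a `star_msa`.
#' @param group_labels named vector mapping row ids to group labels; rows
#'   absent from it (e.g. the reference) are skipped.
#' @return Named list of 21 x n_ref matrices (rows: residues then `"-"`),
#'   columns named by reference position.
#' @export
conservation_profile <- function(msa, group_labels) {
  groups <- unique(group_labels)
  refcols <- which(msa$is_ref_column)
  out <- list()
  for (g in groups) {
    ids <- names(group_labels)[group_labels == g]
    ri <- match(ids, msa$ids)
    ri <- ri[!is.na(ri)]
    if (length(ri) == 0) stop("empty group: ", g)
    sub <- msa$rows[ri, refcols, drop = FALSE]
    prof <- matrix(0, nrow = 21, ncol = length(refcols),
                   dimnames = list(c(AA_ALPHABET, "-"),
                                   msa$ref_position[refcols]))
    for (j in seq_along(refcols)) {
      tb <- table(factor(sub[, j], levels = c(AA_ALPHABET, "-")))
      prof[, j] <- as.numeric(tb) / length(ri)
    }
    out[[g]] <- prof
  }
  out
}
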