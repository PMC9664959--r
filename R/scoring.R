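# Substitution matrix, background frequencies, and scoring parameters.

# BLOSUM62 background amino-acid frequencies (marginals of the BLOSUM62
# target frequencies, Henikoff & Henikoff), in AA_ALPHABET order.
BLOSUM62_BACKGROUND <- c(
  A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
  Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
  L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
  S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)

#' BLOSUM62 substitution matrix over the 20 canonical residues
#'
#' Subset of the Biostrings BLOSUM62 matrix restricted to the standard
#' alphabet, in [aa_alphabet()] order.
#' @return 20 x 20 symmetric integer matrix.
#' @export
blosum62 <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62[AA_ALPHABET, AA_ALPHABET]
  storage.mode(m) <- "double"
  m
}

#' Background amino-acid frequencies of the BLOSUM62 model
#' @return Named numeric vector of length 20 summing to 1.
#' @export
blosum62_background <- function() {
  b <- BLOSUM62_BACKGROUND
  b / sum(b)
}

# Build a 26 x 26 lookup table indexed by (letter - 'A') for the C++ DP.
.score_lut <- function(matrix) {
  lut <- matrix(0, 26, 26)
  idx <- match(rownames(matrix), LETTERS)
  lut[idx, idx] <- matrix
  lut
}

#' Scoring parameters for pairwise alignment and E-value estimation
#'
#' Bundles the substitution matrix, affine gap penalties (a gap of length k
#' costs `gap_open + k * gap_extend`), the Karlin-Altschul parameters
#' lambda and K, and the effective search-space sizes m and n (residue
#' counts).  Defaults are the BLAST gapped-BLOSUM62 constants.
#'
#' @param matrix 20 x 20 symmetric substitution matrix with residue
#'   dimnames (default [blosum62()]).
#' @param gap_open,gap_extend positive gap penalties (default 11 / 1).
#' @param lambda,K positive Karlin-Altschul constants (default 0.267 /
#'   0.041, the gapped BLOSUM62 11/1 values).
#' @param search_space_m,search_space_n residue counts of the query and
#'   database sides; `NA` means "derive from the sequences at hand".
#' @return An object of class `scoring_params`.
#' @export
scoring_params <- function(matrix = blosum62(), gap_open = 11, gap_extend = 1,
                           lambda = 0.267, K = 0.041,
                           search_space_m = NA_real_,
                           search_space_n = NA_real_) {
  stopifnot(is.matrix(matrix), nrow(matrix) == ncol(matrix),
            !is.null(rownames(matrix)),
            identical(rownames(matrix), colnames(matrix)))
  if (max(abs(matrix - t(matrix))) > 0) stop("substitution matrix must be symmetric")
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be positive")
  if (lambda <= 0 || K <= 0) stop("lambda and K must be positive")
  structure(list(matrix = matrix, gap_open = gap_open, gap_extend = gap_extend,
                 lambda = lambda, K = K,
                 search_space_m = search_space_m,
                 search_space_n = search_space_n,
                 lut = .score_lut(matrix)),
            class = "scoring_params")
}

#' @export
print.scoring_params <- function(x, ...) {
  cat(sprintf("scoring_params: %dx%d matrix, gap %g/%g, lambda=%g K=%g\n",
              nrow(x$matrix), ncol(x$matrix), x$gap_open, x$gap_extend,
              x$lambda, x$K))
  invisible(x)
}
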