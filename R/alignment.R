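# Order-preserving SSE alignment: the similarity matrix D(R_opt) plays the
# role of a substitution matrix and a standard pairwise alignment DP
# (Needleman-Wunsch / free-end-gap / Smith-Waterman) finds the map M that
# maximizes the summed similarity under strict sequence-order precedence.

#' Length-mismatch factor for an SSE pair
#'
#' `exp(-(dL / len_tol)^2)`: 1 when the two SSEs have equal residue
#' length, strictly decreasing in the absolute length difference, and
#' `exp(-1)` at `dL = len_tol`.
#'
#' @param delta_L Non-negative absolute residue-length difference.
#' @param len_tol Positive tolerance (residues).
#' @return Factor in `(0, 1]`.
#' @export
length_mismatch_factor <- function(delta_L, len_tol) {
  if (any(delta_L < 0)) stop("delta_L must be non-negative", call. = FALSE)
  if (len_tol <= 0) stop("len_tol must be positive", call. = FALSE)
  exp(-(delta_L / len_tol)^2)
}

#' Order-preserving SSE alignment by dynamic programming
#'
#' Finds the index map `M: i -> j` that is strictly increasing in both
#' coordinates and maximizes the sum of `D[i, M(i)]` minus gap penalties.
#' The gap model is a constant opening penalty (`gap_open`, typically -1)
#' with free extension. The reported `total_score` is the pure sum of D
#' over matched pairs: unmatched SSEs are ignored by the score.
#'
#' Modes: `"global"` (end gaps pay), `"semiglobal"` (free end gaps; the
#' default for substructure search) and `"local"` (best-scoring local
#' block). Traceback ties are broken deterministically: match, then gap in
#' the target, then gap in the query.
#'
#' @param D A `similarity_matrix` or plain numeric matrix (query rows,
#'   target columns; entries are finite, typically in `[0, 1]`).
#' @param gap_open Gap-opening penalty (<= 0 expected). Default -1.
#' @param mode `"global"`, `"semiglobal"` or `"local"`.
#' @return Object of class `"sse_alignment"`: `pairs` (k x 2 matrix of
#'   1-based (i, j)), `total_score` (sum of matched D entries),
#'   `dp_score` (DP objective incl. gap penalties), `gap_count`
#'   (number of gap openings on the traced path) and `mode`.
#' @export
align_sses <- function(D, gap_open = -1, mode = c("semiglobal", "global", "local")) {
  mode <- match.arg(mode)
  S <- sim_values(D)
  n <- nrow(S); m <- ncol(S)
  if (is.null(n) || n == 0 || m == 0) {
    return(structure(list(pairs = matrix(integer(0), ncol = 2),
                          total_score = 0, dp_score = 0, gap_count = 0L,
                          mode = mode), class = "sse_alignment"))
  }
  if (any(!is.finite(S))) stop("similarity matrix must be finite", call. = FALSE)
  res <- cpp_align(S, gap_open, match(mode, c("global", "semiglobal", "local")) - 1L)
  pairs <- res$pairs
  storage.mode(pairs) <- "integer"
  structure(list(pairs = pairs, total_score = res$total_score,
                 dp_score = res$dp_score, gap_count = as.integer(res$gap_count),
                 mode = mode), class = "sse_alignment")
}

#' @export
print.sse_alignment <- function(x, ...) {
  cat(sprintf("<sse_alignment> %s: %d pairs, T = %.4f (dp %.4f, %d gap openings)\n",
              x$mode, nrow(x$pairs), x$total_score, x$dp_score, x$gap_count))
  if (nrow(x$pairs)) {
    cat(" ", paste(sprintf("%d:%d", x$pairs[, 1], x$pairs[, 2]), collapse = " "), "\n")
  }
  invisible(x)
}

#' Brute-force optimal order-preserving map (test oracle)
#'
#' Exhaustively enumerates every strictly order-preserving partial map
#' between rows and columns and returns the one maximizing the summed
#' similarity (no gap penalties). Exponential; refuses matrices larger
#' than 8x8. Used only as an independent oracle for [align_sses()].
#'
#' @param D Numeric matrix (or `similarity_matrix`), at most 8x8.
#' @return List with `pairs` (k x 2 matrix) and `score`.
#' @export
brute_force_best_map <- function(D) {
  S <- sim_values(D)
  n <- nrow(S); m <- ncol(S)
  if (n == 0 || m == 0) return(list(pairs = matrix(integer(0), ncol = 2), score = 0))
  if (n > 8 || m > 8) stop("brute_force_best_map is limited to 8x8", call. = FALSE)
  rec <- function(i0, j0) {
    best <- 0; bestp <- NULL
    if (i0 > n || j0 > m) return(list(score = 0, pairs = NULL))
    for (i in i0:n) {
      for (j in j0:m) {
        sub <- rec(i + 1, j + 1)
        s <- S[i, j] + sub$score
        if (s > best) { best <- s; bestp <- rbind(c(i, j), sub$pairs) }
      }
    }
    list(score = best, pairs = bestp)
  }
  out <- rec(1, 1)
  pairs <- if (is.null(out$pairs)) matrix(integer(0), ncol = 2) else out$pairs
  list(pairs = unname(pairs), score = out$score)
}
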