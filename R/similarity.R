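# Pairwise Gaussian similarity between typed SSE direction vectors, the
# similarity matrix D(R), and the rotation-space match score F.

#' Matching parameters
#'
#' One configuration object for the whole pipeline. Angles are radians for
#' `delta` (the Gaussian width of the angular similarity) and degrees for
#' the rotation-space thresholds.
#'
#' @param delta Gaussian width of the angular similarity, radians.
#'   Defaults to 0.5 (classification-style scans); use 0.3 with a length
#'   penalty for conformer searches and 0.1 for exact-match tests.
#' @param len_tol Length-mismatch tolerance in residues, or `NULL` to
#'   disable the length penalty (default).
#' @param m Index truncation for initial-guess enumeration: vector pairs
#'   `(i, j)` are considered only for `i < j <= i + m`. Default 3.
#' @param group_eps Direction-grouping angle in degrees, or `NULL` (default)
#'   for no grouping.
#' @param gap_open Gap-opening penalty in the SSE alignment (default -1;
#'   gap extension is free).
#' @param align_mode Alignment mode: `"semiglobal"` (default; free end
#'   gaps, suited to substructure search), `"global"`, or `"local"`.
#' @param mc_samples Monte-Carlo sample size for the rotational standard
#'   deviation of F (>= 1000).
#' @param seed Integer seed for every stochastic step (Monte-Carlo
#'   rotations).
#' @param z_cut Significance threshold: a local minimum is kept only if
#'   its rotational z-score is `<= z_cut` (default -2).
#' @param dedup_eps Rotations closer than this (degrees) are considered
#'   duplicates; for minima the deeper F is kept. Default 5.
#' @param collinear_eps Initial-guess generator pairs with an internal
#'   angle below this (degrees) are skipped as ill-conditioned. Default 5.
#' @param max_starts Steepest descent is run from at most this many of the
#'   lowest-scoring (deepest-F) deduplicated initial guesses. Default 16.
#' @param grad_tol Descent stops when the tangent-space gradient norm
#'   falls below this. Default 1e-8.
#' @param max_iter Maximum descent iterations per start. Default 500.
#' @param top_k Number of lowest-z minima fed to the flexible pair search.
#'   Default 10.
#' @param min_separation Minimum angular distance (degrees) between the
#'   two rotations of a flexible match. Default 15.
#' @param flex_margin A flexible match must improve the combined aligned
#'   score over the best rigid one by at least this much. Default 0.5.
#' @return A list of class `"match_params"`.
#' @export
match_params <- function(delta = 0.5, len_tol = NULL, m = 3, group_eps = NULL,
                         gap_open = -1, align_mode = c("semiglobal", "global", "local"),
                         mc_samples = 1000, seed = 1L, z_cut = -2,
                         dedup_eps = 5, collinear_eps = 5, max_starts = 16,
                         grad_tol = 1e-8, max_iter = 500, top_k = 10,
                         min_separation = 15, flex_margin = 0.5) {
  align_mode <- match.arg(align_mode)
  stopifnot(delta > 0, m >= 1, mc_samples >= 1000,
            is.null(len_tol) || len_tol > 0,
            is.null(group_eps) || group_eps > 0)
  structure(list(delta = delta, len_tol = len_tol, m = as.integer(m),
                 group_eps = group_eps, gap_open = gap_open,
                 align_mode = align_mode, mc_samples = as.integer(mc_samples),
                 seed = as.integer(seed), z_cut = z_cut, dedup_eps = dedup_eps,
                 collinear_eps = collinear_eps, max_starts = as.integer(max_starts),
                 grad_tol = grad_tol, max_iter = as.integer(max_iter),
                 top_k = as.integer(top_k), min_separation = min_separation,
                 flex_margin = flex_margin),
            class = "match_params")
}

#' Angular similarity of two typed unit vectors
#'
#' `exp(-theta^2 / delta^2)` for two SSE vectors of the same type, with
#' `theta` the angle between them in `[0, pi]`; exactly 0 for a
#' helix/strand type mismatch. Directions are N->C and antiparallel
#' vectors are *not* identified: parallel and antiparallel strands are
#' structurally distinct.
#'
#' @param v,w Unit 3-vectors.
#' @param type_v,type_w SSE types (`"helix"`/`"strand"`).
#' @param delta Gaussian width (radians).
#' @return Similarity in `[0, 1]`.
#' @export
element_similarity <- function(v, w, type_v, type_w, delta) {
  if (abs(sum(v^2) - 1) > 1e-6 || abs(sum(w^2) - 1) > 1e-6) {
    stop("element_similarity expects unit vectors", call. = FALSE)
  }
  if (delta <= 0) stop("delta must be positive", call. = FALSE)
  if (type_v != type_w) return(0)
  theta <- acos(min(1, max(-1, sum(v * w))))
  exp(-theta^2 / delta^2)
}

# Rotation-independent pair weights: type indicator, optionally times the
# length-mismatch factor.
pair_weights <- function(X, Y, len_tol = NULL) {
  w <- outer(X$types, Y$types, `==`) * 1
  if (!is.null(len_tol)) {
    dL <- abs(outer(X$lengths, Y$lengths, `-`))
    w <- w * exp(-(dL / len_tol)^2)
  }
  w
}

#' Similarity matrix between two representations at a rotation
#'
#' Evaluates the pairwise angular similarity between every rotated query
#' vector and every target vector; optionally weighted by the SSE
#' length-mismatch factor (see [length_mismatch_factor()]).
#'
#' @param X,Y `reduced_rep` objects (query and target).
#' @param r A `rotation` applied to `X`'s vectors.
#' @param params A [match_params()] object (`delta`, `len_tol` are used).
#' @return Object of class `"similarity_matrix"`: the `N_x x N_y` matrix
#'   in `$values`, plus `$rotation` and `$length_weighted`.
#' @export
similarity_matrix <- function(X, Y, r, params = match_params()) {
  stopifnot(inherits(X, "reduced_rep"), inherits(Y, "reduced_rep"))
  R <- rotation_matrix(r)
  rv <- X$vectors %*% t(R)
  cosang <- rv %*% t(Y$vectors)
  cosang[cosang > 1] <- 1
  cosang[cosang < -1] <- -1
  theta <- acos(cosang)
  D <- pair_weights(X, Y, params$len_tol) * exp(-theta^2 / params$delta^2)
  dimnames(D) <- NULL
  structure(list(values = D, rotation = rotation(as.numeric(r)),
                 length_weighted = !is.null(params$len_tol)),
            class = "similarity_matrix")
}

sim_values <- function(D) {
  if (inherits(D, "similarity_matrix")) D$values else as.matrix(D)
}

#' Total match score F at a rotation
#'
#' `F(R; X, Y) = -sum_ij D_ij(R)`: the negative sum of all pairwise
#' similarities. More negative is better; `F` lies in
#' `[-N_x * N_y, 0]`. For two exactly matching substructures and
#' `delta -> 0` the minimum tends to minus the number of SSEs in the
#' smaller structure.
#'
#' @inheritParams similarity_matrix
#' @return Scalar `F <= 0`.
#' @export
total_match_score <- function(X, Y, r, params = match_params()) {
  wts <- pair_weights(X, Y, params$len_tol)
  q <- matrix(as.numeric(r), nrow = 1)
  cpp_match_scores(X$vectors, Y$vectors, wts, q, params$delta)[1]
}

# F at many quaternions at once (rows of `quats`).
match_score_profile <- function(X, Y, quats, params = match_params(),
                                wts = pair_weights(X, Y, params$len_tol)) {
  cpp_match_scores(X$vectors, Y$vectors, wts, quats, params$delta)
}
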