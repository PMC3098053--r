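# Search for rotations minimizing F: rotational moments and z-score,
# initial-guess enumeration, steepest descent over unit quaternions,
# direction grouping, and collection of significant local minima.

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Mean over uniform rotations of the per-pair similarity
# exp(-theta^2/delta^2): for Haar-random R the angle theta between R v and
# w has density sin(theta)/2 on [0, pi] regardless of v, w, so the mean is
# (1/2) * int_0^pi exp(-theta^2/delta^2) sin(theta) dtheta.
mean_pair_similarity <- function(delta) {
  0.5 * stats::integrate(function(t) exp(-t^2 / delta^2) * sin(t),
                         lower = 0, upper = pi,
                         rel.tol = 1e-10, abs.tol = 1e-14)$value
}

#' Rotational moments of the match score
#'
#' Mean and standard deviation of `F(R; X, Y)` over uniform (Haar) random
#' rotations `R`. The mean is semi-analytic: for a uniform rotation the
#' angle between a rotated and a fixed unit vector has density
#' `sin(theta)/2`, so each pair contributes the same quadrature integral,
#' and `mean_F = -sum_ij w_ij * meanD(delta)` (weights include the type
#' indicator and any length factor). The standard deviation is estimated
#' by Monte Carlo over `params$mc_samples` uniform rotations with the
#' fixed `params$seed`.
#'
#' @param X,Y `reduced_rep` objects.
#' @param params A [match_params()].
#' @return List of class `"rotation_stats"` with `mean_F`, `std_F`,
#'   `mean_pair` and `n_pairs` (sum of weights).
#' @export
rotation_statistics <- function(X, Y, params = match_params()) {
  wts <- pair_weights(X, Y, params$len_tol)
  wsum <- sum(wts)
  if (wsum == 0) {
    stop("no same-type SSE pair between the two representations: rotational statistics undefined",
         call. = FALSE)
  }
  meanD <- mean_pair_similarity(params$delta)
  mean_F <- -wsum * meanD
  Fs <- with_seed(params$seed, {
    quats <- random_rotations(params$mc_samples)
    cpp_match_scores(X$vectors, Y$vectors, wts, quats, params$delta)
  })
  std_F <- stats::sd(Fs)
  structure(list(mean_F = mean_F, std_F = std_F, mean_pair = meanD,
                 n_pairs = wsum, mc_mean_F = mean(Fs),
                 mc_samples = params$mc_samples),
            class = "rotation_stats")
}

#' Rotational z-score of a match score
#'
#' `z = (F - mean_F) / std_F`: how far a score is below what uniform
#' random orientation achieves, in standard deviations. Deep, meaningful
#' minima give strongly negative z; near-zero or positive z is dismissed
#' as insignificant.
#'
#' @param F Match score.
#' @param stats A `rotation_stats` from [rotation_statistics()].
#' @return The z-score.
#' @export
z_score <- function(F, stats) {
  if (!is.finite(stats$std_F) || stats$std_F <= 0) {
    stop("rotational standard deviation is zero: z-score undefined", call. = FALSE)
  }
  (F - stats$mean_F) / stats$std_F
}

# Greedy dedup of quaternion rows closer than eps degrees; keeps the first
# occurrence (rows are assumed pre-sorted by preference). Returns indices.
dedup_quat_idx <- function(quats, eps_deg) {
  if (nrow(quats) <= 1) return(seq_len(nrow(quats)))
  cos_half <- cos(eps_deg * pi / 360)
  keep <- integer(0)
  for (r in seq_len(nrow(quats))) {
    if (length(keep) == 0 ||
        all(abs(quats[keep, , drop = FALSE] %*% quats[r, ]) < cos_half)) {
      keep <- c(keep, r)
    }
  }
  keep
}

dedup_quats <- function(quats, eps_deg) {
  quats[dedup_quat_idx(quats, eps_deg), , drop = FALSE]
}

#' Initial rotation guesses from vector pairs
#'
#' Enumerates ordered vector pairs `(i, j)`, `i < j <= i + m`, in the
#' query and same-type, same-order pairs `(k, l)`, `k < l <= k + m`, in
#' the target, and for each combination builds the rotation that maps
#' `v_i` onto `w_k` and the plane spanned by `(v_i, v_j)` onto the plane
#' spanned by `(w_k, w_l)`. Near-collinear generator pairs are skipped
#' (the plane is ill-conditioned) and near-duplicate rotations removed.
#'
#' @param X,Y `reduced_rep` objects.
#' @param params A [match_params()] (`m`, `collinear_eps`, `dedup_eps`).
#' @return Matrix of unit quaternions (rows); possibly zero rows.
#' @export
initial_rotations <- function(X, Y, params = match_params()) {
  cpp_initial_rotations(X$vectors, match(X$types, SSE_TYPES),
                        Y$vectors, match(Y$types, SSE_TYPES),
                        params$m, params$collinear_eps, params$dedup_eps)
}

#' Steepest-descent minimization of F over rotations
#'
#' Minimizes `F(R; X, Y)` over unit quaternions starting from `r0`, using
#' the analytic gradient of F projected onto the tangent space of the
#' unit-quaternion sphere and a backtracking line search with
#' renormalization after every step. The F sequence is monotone
#' non-increasing; iteration stops when the tangent gradient norm falls
#' below `params$grad_tol` or after `params$max_iter` iterations.
#'
#' @param X,Y `reduced_rep` objects.
#' @param r0 Starting `rotation`.
#' @param params A [match_params()].
#' @param stats Optional precomputed [rotation_statistics()]; computed on
#'   demand when `NULL`.
#' @return A `local_minimum`: list with `rotation`, `F` and `z`.
#' @export
minimize_match_score <- function(X, Y, r0, params = match_params(), stats = NULL) {
  wts <- pair_weights(X, Y, params$len_tol)
  res <- cpp_descend(X$vectors, Y$vectors, wts, as.numeric(r0),
                     params$delta, params$grad_tol, params$max_iter)
  if (!is.finite(res$F)) stop("non-finite match score in descent", call. = FALSE)
  if (is.null(stats)) stats <- rotation_statistics(X, Y, params)
  local_minimum(rotation(res$q), res$F, z_score(res$F, stats))
}

local_minimum <- function(rot, F, z) {
  structure(list(rotation = rot, F = F, z = z), class = "local_minimum")
}

#' @export
print.local_minimum <- function(x, ...) {
  cat(sprintf("<local_minimum> F = %.4f, z = %.2f\n", x$F, x$z))
  print(x$rotation)
  invisible(x)
}

#' Group nearly parallel same-type directions
#'
#' Single-linkage clustering of the representation's vectors (within each
#' SSE type) at angular distance `group_eps`; each group is replaced by
#' its normalized mean direction. The unfold map sends each compact index
#' back to the original indices, so alignments can be computed on the full
#' representation after the rotation search.
#'
#' @param X A `reduced_rep`.
#' @param group_eps Grouping angle, degrees.
#' @return List with `rep` (compact `reduced_rep`, `n <= N`) and `unfold`
#'   (list: original index vector per compact vector).
#' @export
group_directions <- function(X, group_eps) {
  stopifnot(group_eps > 0)
  n <- X$count
  labels <- integer(n)
  nextlab <- 0L
  for (ty in unique(X$types)) {
    idx <- which(X$types == ty)
    if (length(idx) == 1) {
      nextlab <- nextlab + 1L
      labels[idx] <- nextlab
      next
    }
    V <- X$vectors[idx, , drop = FALSE]
    cosang <- V %*% t(V)
    cosang[cosang > 1] <- 1; cosang[cosang < -1] <- -1
    ang <- acos(cosang) * 180 / pi
    hc <- stats::hclust(stats::as.dist(ang), method = "single")
    cl <- stats::cutree(hc, h = group_eps)
    labels[idx] <- nextlab + cl
    nextlab <- nextlab + max(cl)
  }
  groups <- split(seq_len(n), labels)
  # keep sequence order: order groups by first member
  groups <- groups[order(vapply(groups, min, 1L))]
  vecs <- t(vapply(groups, function(g) {
    v <- colMeans(X$vectors[g, , drop = FALSE])
    v / sqrt(sum(v^2))
  }, numeric(3)))
  dimnames(vecs) <- NULL
  comp <- reduced_representation(
    id = paste0(X$id, "_grouped"),
    vectors = vecs,
    types = vapply(groups, function(g) X$types[g[1]], ""),
    lengths = vapply(groups, function(g) as.integer(round(mean(X$lengths[g]))), 1L)
  )
  list(rep = comp, unfold = unname(groups))
}

#' Collect significant local minima of F
#'
#' Runs the full rotation search for one pair: initial-guess enumeration
#' (on grouped directions when `params$group_eps` is set), screening of
#' the guesses by their starting F (descent is run from the
#' `params$max_starts` deepest distinct starts), steepest descent,
#' deduplication of converged rotations (keeping the deeper F), z-scoring
#' and significance filtering. The result is sorted by ascending z-score
#' (most significant first).
#'
#' @param X,Y `reduced_rep` objects.
#' @param params A [match_params()].
#' @param stats Optional precomputed [rotation_statistics()].
#' @param keep_all If `TRUE`, insignificant minima (z > `params$z_cut`)
#'   are retained instead of discarded (used for reporting).
#' @return List of `local_minimum`, ascending z; possibly empty.
#' @export
collect_minima <- function(X, Y, params = match_params(), stats = NULL,
                           keep_all = FALSE) {
  wts <- pair_weights(X, Y, params$len_tol)
  if (sum(wts) == 0) return(list())
  Xg <- X; Yg <- Y
  if (!is.null(params$group_eps)) {
    Xg <- group_directions(X, params$group_eps)$rep
    Yg <- group_directions(Y, params$group_eps)$rep
  }
  q0s <- initial_rotations(Xg, Yg, params)
  if (nrow(q0s) == 0) return(list())
  F0 <- cpp_match_scores(X$vectors, Y$vectors, wts, q0s, params$delta)
  ord <- order(F0)
  q0s <- q0s[ord[seq_len(min(length(ord), params$max_starts))], , drop = FALSE]
  res <- cpp_descend_batch(X$vectors, Y$vectors, wts, q0s,
                           params$delta, params$grad_tol, params$max_iter)
  # dedup converged minima: sort by F (deepest first), merge within dedup_eps
  ordF <- order(res$F)
  qsorted <- res$q[ordF, , drop = FALSE]
  kept <- dedup_quat_idx(qsorted, params$dedup_eps)
  qs <- qsorted[kept, , drop = FALSE]
  Fs <- res$F[ordF][kept]
  if (is.null(stats)) stats <- rotation_statistics(X, Y, params)
  zs <- (Fs - stats$mean_F) / stats$std_F
  keep <- if (keep_all) seq_along(zs) else which(zs <= params$z_cut)
  keep <- keep[order(zs[keep])]
  lapply(keep, function(k) local_minimum(rotation(qs[k, ]), Fs[k], zs[k]))
}
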