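# Conformationally flexible matching: a flexible match is two local
# minima of F at genuinely different rotations, each aligning one rigid
# structural domain; the combined correspondence is computed on the
# entrywise maximum of the two similarity matrices.

#' Entrywise maximum of two similarity matrices
#'
#' `D^max_ij = max(D_ij(R1), D_ij(R2))`: each SSE pair is scored by
#' whichever of the two rotations matches it better.
#'
#' @param D1,D2 `similarity_matrix` objects (or plain matrices) of the
#'   same shape.
#' @return A plain numeric matrix.
#' @export
combined_similarity <- function(D1, D2) {
  A <- sim_values(D1); B <- sim_values(D2)
  if (!all(dim(A) == dim(B))) {
    stop("similarity matrices must have the same shape", call. = FALSE)
  }
  pmax(A, B)
}

#' Heuristic score for a flexible match
#'
#' `((|z1| + |z2|) / 2) * T_max`: the mean significance of the two
#' rotation minima times the total aligned score on the combined
#' similarity matrix. Larger is better; zero when nothing aligns.
#'
#' @param z1,z2 Rotational z-scores of the two minima.
#' @param T_max Total aligned score on `D^max` (non-negative).
#' @return The heuristic score.
#' @export
flexible_score <- function(z1, z2, T_max) {
  if (T_max < 0) stop("T_max must be non-negative", call. = FALSE)
  ((abs(z1) + abs(z2)) / 2) * T_max
}

#' Search for a two-rotation (flexible) match
#'
#' Takes the `params$top_k` most significant rotation minima for the pair,
#' and for every combination of two minima separated by at least
#' `params$min_separation` degrees builds the combined similarity matrix,
#' aligns it, and scores the candidate with [flexible_score()]. A
#' candidate is admissible only if (i) both z-scores pass the significance
#' threshold (guaranteed by [collect_minima()]), (ii) each rotation
#' contributes at least one matched pair on which its similarity is the
#' larger one (complementarity), and (iii) the combined aligned score
#' exceeds the best single-rotation aligned score by at least
#' `params$flex_margin`. The best admissible candidate by heuristic score
#' is returned.
#'
#' @param X,Y `reduced_rep` objects.
#' @param params A [match_params()]; conformer searches typically use
#'   `delta = 0.3` with a length penalty.
#' @param minima Optional precomputed result of [collect_minima()].
#' @return A `flexible_match` (list with `r1`, `r2`, `z1`, `z2`,
#'   `combined_alignment`, `score`, `separation`, `best_rigid_T`,
#'   `domains`), or `NULL` when no admissible two-rotation match exists.
#' @export
flexible_search <- function(X, Y, params = match_params(), minima = NULL) {
  if (is.null(minima)) minima <- collect_minima(X, Y, params)
  if (length(minima) < 2) return(NULL)
  minima <- minima[seq_len(min(length(minima), params$top_k))]
  Ds <- lapply(minima, function(mn) sim_values(similarity_matrix(X, Y, mn$rotation, params)))
  rigid_T <- vapply(Ds, function(D) {
    align_sses(D, gap_open = params$gap_open, mode = params$align_mode)$total_score
  }, numeric(1))
  best_rigid <- max(rigid_T)
  best <- NULL
  for (a in seq_len(length(minima) - 1)) {
    for (b in (a + 1):length(minima)) {
      sep <- rotation_separation(minima[[a]]$rotation, minima[[b]]$rotation)
      if (sep < params$min_separation) next
      Dmax <- combined_similarity(Ds[[a]], Ds[[b]])
      aln <- align_sses(Dmax, gap_open = params$gap_open, mode = params$align_mode)
      if (nrow(aln$pairs) == 0) next
      if (aln$total_score <= best_rigid + params$flex_margin) next
      # complementarity: attribute each matched pair to the rotation whose
      # D is larger (ties to the first); both must contribute
      owner <- ifelse(Ds[[a]][aln$pairs] >= Ds[[b]][aln$pairs], 1L, 2L)
      if (!all(c(1L, 2L) %in% owner)) next
      sc <- flexible_score(minima[[a]]$z, minima[[b]]$z, aln$total_score)
      if (is.null(best) || sc > best$score) {
        best <- structure(list(
          r1 = minima[[a]]$rotation, r2 = minima[[b]]$rotation,
          z1 = minima[[a]]$z, z2 = minima[[b]]$z,
          combined_alignment = aln, score = sc, separation = sep,
          best_rigid_T = best_rigid,
          domains = list(which(owner == 1L), which(owner == 2L))
        ), class = "flexible_match")
      }
    }
  }
  best
}

#' @export
print.flexible_match <- function(x, ...) {
  cat(sprintf("<flexible_match> score = %.3f, separation = %.1f deg, z = (%.2f, %.2f), T(D^max) = %.3f\n",
              x$score, x$separation, x$z1, x$z2, x$combined_alignment$total_score))
  aa1 <- rotation_to_axis_angle(x$r1); aa2 <- rotation_to_axis_angle(x$r2)
  cat(sprintf("  R1: %.1f deg about (%.2f, %.2f, %.2f); %d matched pairs\n",
              aa1$angle, aa1$axis[1], aa1$axis[2], aa1$axis[3], length(x$domains[[1]])))
  cat(sprintf("  R2: %.1f deg about (%.2f, %.2f, %.2f); %d matched pairs\n",
              aa2$angle, aa2$axis[1], aa2$axis[2], aa2$axis[3], length(x$domains[[2]])))
  invisible(x)
}
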