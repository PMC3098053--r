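# Synthetic fixtures: random typed unit-vector representations, angular
# perturbations, planted hinge-motion conformer pairs, decoy databases and
# ideal-geometry C-alpha PDB files. Everything is reproducible from a seed.

runif_sphere <- function(n) {
  v <- matrix(stats::rnorm(3 * n), ncol = 3)
  v / sqrt(rowSums(v^2))
}

#' Random reduced representation
#'
#' `n` directions drawn uniformly on the unit sphere; types helix/strand
#' drawn independently with probability `helix_fraction`; lengths uniform
#' over conventional SSE ranges (helices 6-20 residues, strands 3-10).
#' Note what this emulates and what it does not: real folds have
#' correlated SSE directions (bundles, sheets) and packing constraints;
#' these decoys have neither.
#'
#' @param n Number of SSEs (>= 1).
#' @param helix_fraction Probability that an SSE is a helix (default 0.5).
#' @param seed Integer seed.
#' @param id Label (default `"synth_<seed>"`).
#' @return A `reduced_rep`.
#' @export
random_representation <- function(n, helix_fraction = 0.5, seed = 1L,
                                  id = paste0("synth_", seed)) {
  stopifnot(n >= 1, helix_fraction >= 0, helix_fraction <= 1)
  with_seed(seed, {
    vecs <- runif_sphere(n)
    types <- ifelse(stats::runif(n) < helix_fraction, "helix", "strand")
    lengths <- ifelse(types == "helix",
                      sample(6:20, n, replace = TRUE),
                      sample(3:10, n, replace = TRUE))
    reduced_representation(id, vecs, types, as.integer(lengths))
  })
}

# Rodrigues rotation of unit vector v by `angle` radians about unit `axis`.
rodrigues <- function(v, axis, angle) {
  v * cos(angle) +
    c(axis[2] * v[3] - axis[3] * v[2],
      axis[3] * v[1] - axis[1] * v[3],
      axis[1] * v[2] - axis[2] * v[1]) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

#' Angular perturbation of a representation
#'
#' Tilts each vector independently by an angle `|Normal(0, sigma)|` about
#' a uniformly random axis perpendicular to it. Types, lengths and order
#' are unchanged.
#'
#' @param X A `reduced_rep`.
#' @param noise_sigma Tilt standard deviation, degrees (>= 0).
#' @param seed Integer seed.
#' @return The perturbed `reduced_rep`.
#' @export
perturb <- function(X, noise_sigma, seed = 1L) {
  stopifnot(noise_sigma >= 0)
  if (noise_sigma == 0) return(X)
  with_seed(seed, {
    v <- X$vectors
    for (i in seq_len(X$count)) {
      r <- stats::rnorm(3)
      ax <- r - sum(r * v[i, ]) * v[i, ]
      nrm <- sqrt(sum(ax^2))
      if (nrm < 1e-9) { ax <- c(v[i, 2], -v[i, 1], 0); nrm <- sqrt(sum(ax^2)) }
      ax <- ax / nrm
      ang <- abs(stats::rnorm(1, 0, noise_sigma)) * pi / 180
      vi <- rodrigues(v[i, ], ax, ang)
      v[i, ] <- vi / sqrt(sum(vi^2))
    }
    reduced_representation(X$id, v, X$types, X$lengths, meta = X$meta)
  })
}

#' Planted hinge-motion conformer pair
#'
#' Emulates a two-domain conformational change in which each domain keeps
#' its internal organization: conformer A is a random representation;
#' conformer B is A with the vectors at indices `> split_index` rotated by
#' `hinge_angle` degrees about `hinge_axis`, then angularly perturbed by
#' `noise_sigma`. Both conformers share types, lengths and order.
#'
#' @param n_sse Number of SSEs.
#' @param split_index Last index of the fixed domain
#'   (`1 <= split_index < n_sse`).
#' @param hinge_axis Rotation axis (3-vector; normalized internally).
#' @param hinge_angle Hinge angle, degrees in `[0, 180]`.
#' @param noise_sigma Angular noise on conformer B, degrees.
#' @param seed Integer seed.
#' @param helix_fraction Passed to [random_representation()].
#' @return List with `a` and `b` (`reduced_rep`) and `spec`, the
#'   generator settings used.
#' @export
hinge_pair <- function(n_sse, split_index, hinge_axis = c(0, 0, 1),
                       hinge_angle = 70, noise_sigma = 0, seed = 1L,
                       helix_fraction = 0.5) {
  stopifnot(split_index >= 1, split_index < n_sse,
            hinge_angle >= 0, hinge_angle <= 180, noise_sigma >= 0)
  a <- random_representation(n_sse, helix_fraction, seed = seed,
                             id = paste0("hingeA_", seed))
  axis <- hinge_axis / sqrt(sum(hinge_axis^2))
  v <- a$vectors
  moving <- (split_index + 1):n_sse
  for (i in moving) {
    vi <- rodrigues(v[i, ], axis, hinge_angle * pi / 180)
    v[i, ] <- vi / sqrt(sum(vi^2))
  }
  b <- reduced_representation(paste0("hingeB_", seed), v, a$types, a$lengths)
  if (noise_sigma > 0) b <- perturb(b, noise_sigma, seed = seed + 104729L)
  list(a = a, b = b,
       spec = list(n_sse = n_sse, split_index = split_index, hinge_axis = axis,
                   hinge_angle = hinge_angle, noise_sigma = noise_sigma,
                   seed = seed))
}

#' Decoy database of random representations
#'
#' @param n_entries Number of entries (>= 1).
#' @param size_range Integer range of SSE counts, default `c(4, 20)`
#'   (entries below 4 SSEs would be rejected by the database filter).
#' @param seed Integer seed.
#' @param helix_fraction Passed to [random_representation()].
#' @return List of `reduced_rep` with unique ids `decoy_001`, ...
#' @export
decoy_database <- function(n_entries, size_range = c(4, 20), seed = 1L,
                           helix_fraction = 0.5) {
  stopifnot(n_entries >= 1, length(size_range) == 2, size_range[1] >= 1)
  sizes <- with_seed(seed, sample(size_range[1]:size_range[2], n_entries,
                                  replace = TRUE))
  lapply(seq_len(n_entries), function(k) {
    random_representation(sizes[k], helix_fraction,
                          seed = seed + 7919L * k,
                          id = sprintf("decoy_%03d", k))
  })
}

#' Ideal-geometry C-alpha PDB fixture
#'
#' Writes a single-chain, C-alpha-only PDB text for one ideal SSE along a
#' given axis: an alpha-helix with 1.5 Angstrom rise and 100 degrees twist
#' per residue on a 2.3 Angstrom radius, or an extended strand with 3.5
#' Angstrom per residue; the matching HELIX/SHEET record is included so
#' that [load_ca_trace()] + [assign_sses()] reproduce the segment.
#'
#' @param kind `"helix"` or `"strand"`.
#' @param n_res Number of residues (>= 3).
#' @param axis Direction of the SSE axis (default +z).
#' @param origin Translation of the first residue's frame (default origin).
#' @param chain Chain identifier (default "A").
#' @return Character vector of PDB lines (use `writeLines` to save).
#' @export
ideal_sse_pdb <- function(kind = c("helix", "strand"), n_res, axis = c(0, 0, 1),
                          origin = c(0, 0, 0), chain = "A") {
  kind <- match.arg(kind)
  if (n_res < 3) stop("n_res must be >= 3", call. = FALSE)
  axis <- axis / sqrt(sum(axis^2))
  k <- 0:(n_res - 1)
  if (kind == "helix") {
    local <- cbind(2.3 * cos(k * 100 * pi / 180),
                   2.3 * sin(k * 100 * pi / 180),
                   1.5 * k)
  } else {
    local <- cbind(0 * k, 0 * k, 3.5 * k)
  }
  # rotate local +z onto the requested axis
  z <- c(0, 0, 1)
  d <- sum(z * axis)
  if (d > 1 - 1e-12) {
    R <- diag(3)
  } else if (d < -1 + 1e-12) {
    R <- diag(c(1, -1, -1))  # 180 deg about x
  } else {
    rotax <- c(z[2] * axis[3] - z[3] * axis[2],
               z[3] * axis[1] - z[1] * axis[3],
               z[1] * axis[2] - z[2] * axis[1])
    rotax <- rotax / sqrt(sum(rotax^2))
    R <- rotation_matrix(rotation_axis_angle(rotax, acos(d) * 180 / pi))
  }
  xyz <- sweep(local %*% t(R), 2, origin, `+`)
  header <- if (kind == "helix") {
    sprintf("HELIX    1   1 ALA %s%5d  ALA %s%5d  1%36d", chain, 1L, chain, n_res, n_res)
  } else {
    sprintf("SHEET    1   A 1 ALA %s%4d  ALA %s%4d  0", chain, 1L, chain, n_res)
  }
  atoms <- sprintf("ATOM  %5d  CA  ALA %s%4d    %8.3f%8.3f%8.3f  1.00  0.00           C",
                   seq_len(n_res), chain, seq_len(n_res),
                   xyz[, 1], xyz[, 2], xyz[, 3])
  c(header, atoms, "END")
}
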