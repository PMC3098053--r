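# Shared fixtures for the test suite. All geometry is constructed
# explicitly so expected values can be derived by hand.

# Representation from (possibly unnormalized) row vectors.
make_rep <- function(vectors, types, lengths = NULL, id = "fixture") {
  vectors <- matrix(vectors, ncol = 3)
  vectors <- vectors / sqrt(rowSums(vectors^2))
  n <- nrow(vectors)
  if (is.null(lengths)) lengths <- rep(10L, n)
  reduced_representation(id, vectors, types, as.integer(lengths))
}

# Four mutually well-separated unit vectors (tetrahedral directions),
# pairwise angle acos(-1/3) ~ 109.47 degrees.
tetra_rep <- function(types = rep("helix", 4), id = "tetra") {
  s <- 1 / sqrt(3)
  make_rep(rbind(c(s, s, s), c(s, -s, -s), c(-s, s, -s), c(-s, -s, s)),
           types, id = id)
}

# Three orthogonal axes, mixed types.
ortho_rep <- function(types = c("helix", "helix", "strand"), id = "ortho") {
  make_rep(diag(3), types, id = id)
}

# Strictly increasing in both columns?
is_order_preserving <- function(pairs) {
  if (nrow(pairs) <= 1) return(TRUE)
  all(diff(pairs[, 1]) > 0) && all(diff(pairs[, 2]) > 0)
}

# DP objective of an explicit order-preserving map under the package's gap
# model (constant opening penalty, free extension). Internal gaps only
# (semiglobal); used as a feasibility oracle for align_sses.
map_dp_score <- function(S, pairs, gap_open) {
  if (nrow(pairs) == 0) return(0)
  sc <- sum(S[pairs])
  if (nrow(pairs) > 1) {
    di <- diff(pairs[, 1]); dj <- diff(pairs[, 2])
    sc <- sc + gap_open * (sum(di > 1) + sum(dj > 1))
  }
  sc
}
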