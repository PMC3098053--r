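test_that("mean pair similarity agrees with an independent quadrature", {
  for (delta in c(0.1, 0.3, 0.5, 1.0)) {
    got <- ssematch:::mean_pair_similarity(delta)
    # same integral after the substitution u = cos(theta)
    alt <- 0.5 * stats::integrate(function(u) exp(-acos(u)^2 / delta^2),
                                  lower = -1, upper = 1,
                                  rel.tol = 1e-10)$value
    expect_equal(got, alt, tolerance = 1e-8)
  }
  # widths: the mean grows with delta and stays in (0, 1)
  ms <- vapply(c(0.1, 0.3, 0.5, 1), ssematch:::mean_pair_similarity, numeric(1))
  expect_true(all(diff(ms) > 0))
  expect_true(all(ms > 0 & ms < 1))
})

test_that("rotation_statistics is deterministic and internally consistent", {
  X <- random_representation(6, seed = 31, id = "x")
  Y <- random_representation(7, seed = 32, id = "y")
  p <- match_params(delta = 0.3, seed = 5)
  s1 <- rotation_statistics(X, Y, p)
  s2 <- rotation_statistics(X, Y, p)
  expect_identical(s1$mean_F, s2$mean_F)
  expect_identical(s1$std_F, s2$std_F)
  expect_equal(s1$mean_F, -s1$n_pairs * s1$mean_pair, tolerance = 1e-12)
  expect_gt(s1$std_F, 0)
  # Monte-Carlo mean consistent with the quadrature mean (5 SE at n = 1000)
  expect_lt(abs(s1$mc_mean_F - s1$mean_F), 5 * s1$std_F / sqrt(p$mc_samples))
})

test_that("rotation_statistics fails cleanly on type-disjoint pairs", {
  X <- make_rep(diag(3), rep("helix", 3))
  Y <- make_rep(diag(3), rep("strand", 3))
  expect_error(rotation_statistics(X, Y), "same-type")
})

test_that("z_score is the standardized deviation", {
  s <- structure(list(mean_F = -2, std_F = 0.5), class = "rotation_stats")
  expect_equal(z_score(-4, s), -4)
  expect_equal(z_score(-2, s), 0)
  expect_error(z_score(-1, structure(list(mean_F = 0, std_F = 0),
                                     class = "rotation_stats")))
})

test_that("stochastic steps do not disturb the caller's RNG stream", {
  set.seed(99)
  a <- stats::runif(2)
  set.seed(99)
  invisible(stats::runif(1))
  invisible(rotation_statistics(tetra_rep(), tetra_rep(), match_params()))
  invisible(random_representation(5, seed = 77))
  b <- stats::runif(1)
  expect_identical(a[2], b)
})

test_that("initial_rotations contains the exact self-match rotation", {
  X <- tetra_rep()
  q0 <- initial_rotations(X, X, match_params())
  expect_true(nrow(q0) >= 1)
  expect_equal(rowSums(q0^2), rep(1, nrow(q0)), tolerance = 1e-9)
  seps <- apply(q0, 1, function(q) rotation_separation(rotation(q), rotation_identity()))
  expect_lt(min(seps), 1e-6)
})

test_that("initial_rotations respects types, order and the m truncation", {
  # same-type generator pairs only: helix query vs all-strand target
  X <- make_rep(diag(3), rep("helix", 3))
  Y <- make_rep(diag(3), rep("strand", 3))
  expect_equal(nrow(initial_rotations(X, Y, match_params())), 0)
  # m = 1 only admits adjacent pairs: 2 query pairs x 2 target pairs max
  Z <- tetra_rep()
  n1 <- nrow(initial_rotations(Z, Z, match_params(m = 1)))
  n3 <- nrow(initial_rotations(Z, Z, match_params(m = 3)))
  expect_lte(n1, n3)
})

test_that("near-collinear generator pairs are filtered", {
  eps <- 2 * pi / 180
  v2 <- c(sin(eps), 0, cos(eps))  # 2 degrees from +z, below the 5-degree cut
  X <- make_rep(rbind(c(0, 0, 1), v2), rep("helix", 2))
  expect_equal(nrow(initial_rotations(X, X, match_params())), 0)
})

test_that("steepest descent recovers a planted rotation", {
  X <- random_representation(8, seed = 41, id = "x")
  r_true <- rotation_axis_angle(c(1, 2, -1), 77)
  Y <- apply_rotation(X, r_true)
  p <- match_params(delta = 0.1)
  stats <- rotation_statistics(X, Y, p)
  q0 <- initial_rotations(X, Y, p)
  F0 <- min(vapply(seq_len(nrow(q0)),
                   function(k) total_match_score(X, Y, rotation(q0[k, ]), p),
                   numeric(1)))
  best <- NULL
  for (k in seq_len(nrow(q0))) {
    mn <- minimize_match_score(X, Y, rotation(q0[k, ]), p, stats = stats)
    if (is.null(best) || mn$F < best$F) best <- mn
  }
  expect_lte(best$F, F0)  # descent never increases F
  expect_lt(rotation_separation(best$rotation, r_true), 0.1)
  expect_lt(abs(best$F - total_match_score(X, Y, r_true, p)), 1e-6)
  expect_lt(best$z, -3)
})

test_that("descent with max_iter = 0 returns the starting point", {
  X <- random_representation(5, seed = 43)
  Y <- random_representation(5, seed = 44)
  p <- match_params(delta = 0.5, max_iter = 0)
  r0 <- rotation(random_rotations(1)[1, ])
  stats <- rotation_statistics(X, Y, match_params(delta = 0.5))
  mn <- minimize_match_score(X, Y, r0, p, stats = stats)
  expect_equal(mn$F, total_match_score(X, Y, r0, match_params(delta = 0.5)),
               tolerance = 1e-12)
  expect_lt(rotation_separation(mn$rotation, r0), 1e-9)
})

test_that("group_directions merges near-parallel same-type vectors", {
  a <- 3 * pi / 180
  X <- make_rep(rbind(c(0, 0, 1),
                      c(sin(a), 0, cos(a)),
                      c(0, sin(a), cos(a)),
                      c(1, 0, 0),
                      c(0, 0, 1)),
                c("helix", "helix", "helix", "helix", "strand"))
  g <- group_directions(X, group_eps = 10)
  expect_equal(g$rep$count, 3L)  # helix bundle, lone helix, strand
  expect_setequal(g$unfold[[1]], 1:3)
  expect_equal(g$rep$types, c("helix", "helix", "strand"))
  expect_equal(unname(rowSums(g$rep$vectors^2)), rep(1, 3), tolerance = 1e-12)
  # a tight threshold merges nothing
  g2 <- group_directions(X, group_eps = 1)
  expect_equal(g2$rep$count, 5L)
})

test_that("collect_minima finds the self match first and filters by z", {
  X <- random_representation(7, seed = 45)
  p <- match_params(delta = 0.3)
  mins <- collect_minima(X, X, p)
  expect_gt(length(mins), 0)
  expect_lt(rotation_separation(mins[[1]]$rotation, rotation_identity()), 0.5)
  zs <- vapply(mins, `[[`, numeric(1), "z")
  expect_true(all(diff(zs) >= 0))       # ascending z
  expect_true(all(zs <= p$z_cut))       # all significant
  # pairwise distinct rotations
  if (length(mins) > 1) {
    for (a in 1:(length(mins) - 1)) {
      for (b in (a + 1):length(mins)) {
        expect_gte(rotation_separation(mins[[a]]$rotation, mins[[b]]$rotation),
                   p$dedup_eps - 1e-6)
      }
    }
  }
})

test_that("collect_minima returns an empty list for type-disjoint pairs", {
  X <- make_rep(diag(3), rep("helix", 3))
  Y <- make_rep(diag(3), rep("strand", 3))
  expect_identical(collect_minima(X, Y, match_params()), list())
})

test_that("direction grouping preserves the found self-match rotation", {
  X <- random_representation(9, seed = 46)
  p <- match_params(delta = 0.3, group_eps = 10)
  mins <- collect_minima(X, X, p)
  expect_gt(length(mins), 0)
  expect_lt(rotation_separation(mins[[1]]$rotation, rotation_identity()), 1)
})

test_that("the analytic gradient of F matches central differences", {
  X <- random_representation(6, seed = 47)
  Y <- random_representation(7, seed = 48)
  p <- match_params(delta = 0.4)
  wts <- ssematch:::pair_weights(X, Y, p$len_tol)
  Fq <- function(q) {
    q <- q / sqrt(sum(q^2))
    ssematch:::cpp_match_scores(X$vectors, Y$vectors, wts,
                                matrix(q, 1), p$delta)[1]
  }
  h <- 1e-6
  set.seed(49)
  for (rep in 1:5) {
    q <- random_rotations(1)[1, ]
    g <- ssematch:::cpp_match_grad(X$vectors, Y$vectors, wts, q, p$delta)
    # compare along tangent directions of the unit-quaternion sphere (the
    # radial component is irrelevant to the constrained descent)
    for (t in 1:3) {
      d <- stats::rnorm(4)
      d <- d - sum(d * q) * q
      d <- d / sqrt(sum(d^2))
      fd <- (Fq(q + h * d) - Fq(q - h * d)) / (2 * h)
      expect_lt(abs(sum(g * d) - fd), 1e-5 + 1e-4 * abs(fd))
    }
  }
})
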