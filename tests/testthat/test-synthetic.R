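test_that("random_representation is reproducible and well-formed", {
  a <- random_representation(10, seed = 81)
  b <- random_representation(10, seed = 81)
  expect_identical(a$vectors, b$vectors)
  expect_identical(a$types, b$types)
  expect_identical(a$lengths, b$lengths)
  c_ <- random_representation(10, seed = 82)
  expect_false(identical(a$vectors, c_$vectors))
  expect_equal(rowSums(a$vectors^2), rep(1, 10), tolerance = 1e-12)
  expect_true(all(a$types %in% c("helix", "strand")))
  expect_true(all(a$lengths[a$types == "helix"] %in% 6:20))
  expect_true(all(a$lengths[a$types == "strand"] %in% 3:10))
})

test_that("helix_fraction controls the type mix", {
  h <- random_representation(50, helix_fraction = 1, seed = 83)
  s <- random_representation(50, helix_fraction = 0, seed = 83)
  expect_true(all(h$types == "helix"))
  expect_true(all(s$types == "strand"))
})

test_that("sphere sampling has no directional bias", {
  x <- random_representation(4000, seed = 84)
  m <- colMeans(x$vectors)
  # mean of n uniform sphere points has sd ~ 1/sqrt(3n) per coordinate
  expect_true(all(abs(m) < 5 / sqrt(3 * 4000)))
  # each octant populated
  expect_true(all(table(sign(x$vectors[, 1]), sign(x$vectors[, 2])) > 0))
})

test_that("perturb tilts by folded-normal angles and keeps invariants", {
  x <- random_representation(3000, seed = 85)
  y <- perturb(x, noise_sigma = 5, seed = 86)
  expect_identical(y$types, x$types)
  expect_identical(y$lengths, x$lengths)
  cosang <- rowSums(x$vectors * y$vectors)
  ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
  # folded normal: mean = sigma * sqrt(2/pi)
  expect_equal(mean(ang), 5 * sqrt(2 / pi), tolerance = 0.05)
  expect_true(all(ang < 5 * 6))
  # sigma = 0 is the identity
  expect_identical(perturb(x, 0, seed = 1)$vectors, x$vectors)
  # reproducible
  expect_identical(perturb(x, 5, seed = 86)$vectors, y$vectors)
})

test_that("hinge_pair rotates exactly the moving block", {
  hp <- hinge_pair(10, split_index = 4, hinge_axis = c(0, 0, 2),
                   hinge_angle = 60, noise_sigma = 0, seed = 87)
  expect_identical(hp$a$types, hp$b$types)
  expect_identical(hp$a$lengths, hp$b$lengths)
  expect_equal(hp$b$vectors[1:4, ], hp$a$vectors[1:4, ], tolerance = 1e-15)
  R <- rotation_matrix(rotation_axis_angle(c(0, 0, 1), 60))
  expect_equal(hp$b$vectors[5:10, ], hp$a$vectors[5:10, ] %*% t(R),
               tolerance = 1e-12)
  expect_equal(hp$spec$hinge_angle, 60)
})

test_that("hinge_pair applies noise only to conformer B", {
  hp0 <- hinge_pair(8, 4, hinge_angle = 45, noise_sigma = 0, seed = 88)
  hp <- hinge_pair(8, 4, hinge_angle = 45, noise_sigma = 4, seed = 88)
  expect_identical(hp$a$vectors, hp0$a$vectors)
  expect_false(identical(hp$b$vectors, hp0$b$vectors))
  ang <- acos(pmin(1, rowSums(hp$b$vectors * hp0$b$vectors))) * 180 / pi
  expect_true(all(ang < 4 * 6))
})

test_that("decoy_database yields unique ids and sizes in range", {
  db <- decoy_database(25, size_range = c(4, 9), seed = 89)
  ids <- vapply(db, `[[`, "", "id")
  expect_equal(anyDuplicated(ids), 0L)
  expect_identical(ids[1], "decoy_001")
  sizes <- vapply(db, `[[`, 1L, "count")
  expect_true(all(sizes >= 4 & sizes <= 9))
  db2 <- decoy_database(25, size_range = c(4, 9), seed = 89)
  expect_identical(lapply(db, `[[`, "vectors"), lapply(db2, `[[`, "vectors"))
})

test_that("ideal_sse_pdb round-trips through the reduction pipeline", {
  path_h <- withr::local_tempfile(fileext = ".pdb")
  writeLines(ideal_sse_pdb("helix", 12, axis = c(0, 0, 1)), path_h)
  reps <- reduce_file(path_h)
  expect_length(reps, 1)
  x <- reps[[1]]
  expect_equal(x$count, 1L)
  expect_identical(x$types, "helix")
  expect_identical(x$lengths, 12L)
  ang <- acos(min(1, sum(x$vectors[1, ] * c(0, 0, 1)))) * 180 / pi
  expect_lt(ang, 5)  # helix axis fit on 12 residues

  path_s <- withr::local_tempfile(fileext = ".pdb")
  ax <- c(1, 1, 0) / sqrt(2)
  writeLines(ideal_sse_pdb("strand", 6, axis = ax), path_s)
  y <- reduce_file(path_s)[[1]]
  expect_identical(y$types, "strand")
  expect_identical(y$lengths, 6L)
  # a straight strand reproduces its axis essentially exactly, oriented N->C
  expect_equal(y$vectors[1, ], ax, tolerance = 1e-6)
})

test_that("ideal_sse_pdb validates input", {
  expect_error(ideal_sse_pdb("helix", 2), "n_res")
  expect_error(ideal_sse_pdb("turn", 5))
})
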