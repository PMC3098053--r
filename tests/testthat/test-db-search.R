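small_db <- function() decoy_database(8, size_range = c(4, 8), seed = 91)

test_that("build_database filters small entries and rejects duplicates", {
  reps <- c(small_db(), list(random_representation(3, seed = 92, id = "tiny")))
  expect_message(db <- build_database(reps), "tiny")
  expect_length(db, 8)
  dup <- c(small_db(), list(small_db()[[1]]))
  expect_error(build_database(dup), "duplicate")
  expect_error(build_database(list(random_representation(2, seed = 93))),
               "empty database")
})

test_that("build_database accepts JSON-lines and structure files", {
  jl <- withr::local_tempfile(fileext = ".jsonl")
  write_representation(small_db(), jl)
  db <- build_database(jl)
  expect_length(db, 8)
  out <- withr::local_tempfile(fileext = ".jsonl")
  db2 <- build_database(jl, out = out)
  expect_true(file.exists(out))
  expect_length(read_representation(out, simplify = FALSE), 8)
})

test_that("scan_database ranks the self match first with a full alignment", {
  db <- small_db()
  p <- match_params(delta = 0.3)
  q <- db[[4]]
  res <- scan_database(q, db, p)
  expect_equal(nrow(res), 8)
  expect_identical(res$target_id[1], q$id)
  expect_equal(res$rank, 1:8)
  expect_true(all(diff(res$T) <= 1e-12))
  # exact self match: every SSE aligned with similarity 1
  expect_equal(res$T[1], q$count, tolerance = 1e-9)
  expect_equal(res$n_pairs[1], q$count)
  expect_identical(res$alignment[1],
                   paste(sprintf("%d:%d", 1:q$count, 1:q$count), collapse = ";"))
  # self z is the most significant
  expect_equal(which.min(res$z), 1L)
})

test_that("scan_database validates the query and handles edge cases", {
  db <- small_db()
  expect_error(scan_database(random_representation(3, seed = 94), db),
               "at least 4")
  empty <- scan_database(db[[1]], list())
  expect_equal(nrow(empty), 0)
  # type-disjoint target gets T = 0 and no z
  helices <- make_rep(rbind(diag(3), c(1, 1, 1)), rep("helix", 4), id = "h4")
  strands <- make_rep(rbind(diag(3), c(1, 1, 1)), rep("strand", 4), id = "s4")
  res <- scan_database(helices, list(strands), match_params())
  expect_equal(res$T, 0)
  expect_true(is.na(res$z))
})

test_that("flexible scans surface hinge relatives with a flexible score", {
  hp <- hinge_pair(12, split_index = 6, hinge_angle = 70, noise_sigma = 0,
                   seed = 95)
  db <- c(small_db(), list(hp$b))
  p <- match_params(delta = 0.3)
  res <- scan_database(hp$a, db, p, mode = "flexible")
  expect_identical(res$target_id[1], hp$b$id)
  expect_identical(res$mode[1], "flexible")
  expect_false(is.na(res$flex_score[1]))
  expect_lt(abs(res$separation[1] - 70), 5)
  # the planted relative outscores every decoy by a wide margin
  expect_gt(res$flex_score[1], max(res$flex_score[-1], 0, na.rm = TRUE))
})

test_that("scan reports are byte-deterministic", {
  db <- small_db()
  p <- match_params(delta = 0.3)
  res1 <- scan_database(db[[2]], db, p)
  res2 <- scan_database(db[[2]], db, p)
  f1 <- withr::local_tempfile(fileext = ".tsv")
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_scan_report(res1, p, f1, query_id = db[[2]]$id)
  write_scan_report(res2, p, f2, query_id = db[[2]]$id)
  expect_identical(readLines(f1), readLines(f2))
  lines <- readLines(f1)
  expect_true(any(grepl("^# delta\t0.3", lines)))
  expect_true(any(grepl("^# query\tdecoy_002", lines)))
  body <- lines[!startsWith(lines, "#")]
  expect_equal(length(body), 9)  # header row + 8 hits
})
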