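# A small two-SSE chain built from ideal-geometry fixtures: a helix along
# +z (residues 1-12) and a strand along +x (residues 21-26).
two_sse_pdb <- function() {
  helix <- ideal_sse_pdb("helix", 12, axis = c(0, 0, 1))
  strand <- ideal_sse_pdb("strand", 6, axis = c(1, 0, 0), origin = c(10, 0, 0))
  h_atoms <- grep("^ATOM", helix, value = TRUE)
  s_atoms <- grep("^ATOM", strand, value = TRUE)
  # renumber the strand residues/atoms to 21-26
  for (k in seq_along(s_atoms)) {
    s_atoms[k] <- sub(sprintf("ATOM  %5d  CA  ALA A%4d", k, k),
                      sprintf("ATOM  %5d  CA  ALA A%4d", 12 + k, 20 + k),
                      s_atoms[k], fixed = TRUE)
  }
  c(sprintf("HELIX    1   1 ALA A%5d  ALA A%5d  1%36d", 1L, 12L, 12L),
    sprintf("SHEET    1   A 1 ALA A%4d  ALA A%4d  0", 21L, 26L),
    h_atoms, s_atoms, "END")
}

test_that("load_ca_trace reads chains, coordinates and annotations", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(two_sse_pdb(), path)
  traces <- load_ca_trace(path)
  expect_named(traces, "A")
  tr <- traces$A
  expect_equal(tr$resno, c(1:12, 21:26))
  expect_equal(dim(tr$xyz), c(18, 3))
  expect_equal(nrow(tr$annotations), 2)
  expect_setequal(tr$annotations$type, c("helix", "strand"))
  expect_error(load_ca_trace(path, chain = "B"), "chain")
  expect_error(load_ca_trace(file.path(tempdir(), "missing_xyz.pdb")))
})

test_that("assign_sses builds ordered segments and enforces sanity", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(two_sse_pdb(), path)
  tr <- load_ca_trace(path)$A
  segs <- assign_sses(tr)
  expect_length(segs, 2)
  expect_equal(segs[[1]]$sse_type, "helix")
  expect_equal(segs[[2]]$sse_type, "strand")
  expect_equal(nrow(segs[[1]]$ca_coords), 12)
  # external annotations override the file's
  ext <- data.frame(type = "helix", start = 1, end = 12)
  expect_length(assign_sses(tr, ext), 1)
  # minimum-length filtering
  short <- data.frame(type = "strand", start = 21, end = 22)
  expect_length(assign_sses(tr, short), 0)
  # validation
  expect_error(assign_sses(tr, data.frame(type = "loop", start = 1, end = 5)))
  expect_error(assign_sses(tr, data.frame(type = c("helix", "helix"),
                                          start = c(1, 5), end = c(8, 12))),
               "overlap")
  expect_error(assign_sses(tr, data.frame(type = "helix", start = 9, end = 2)))
})

test_that("segment_axis fits the principal axis oriented N->C", {
  seg <- list(ca_coords = cbind(seq(0, 10, length.out = 6), 0, 0))
  ax <- segment_axis(seg)
  expect_equal(ax$vector, c(1, 0, 0), tolerance = 1e-12)
  expect_equal(ax$length, 6L)
  # reversed chain direction flips the vector
  seg_rev <- list(ca_coords = seg$ca_coords[6:1, ])
  expect_equal(segment_axis(seg_rev)$vector, c(-1, 0, 0), tolerance = 1e-12)
  expect_error(segment_axis(list(ca_coords = matrix(1, 1, 3))), "at least 2")
  expect_error(segment_axis(list(ca_coords = matrix(1, 4, 3))), "degenerate")
})

test_that("reduce_file produces an ordered typed representation", {
  path <- withr::local_tempfile(fileext = ".pdb")
  writeLines(two_sse_pdb(), path)
  reps <- reduce_file(path)
  expect_length(reps, 1)
  x <- reps[[1]]
  expect_s3_class(x, "reduced_rep")
  expect_equal(x$count, 2L)
  expect_identical(x$types, c("helix", "strand"))
  expect_identical(x$lengths, c(12L, 6L))
  expect_lt(acos(min(1, x$vectors[1, 3])) * 180 / pi, 5)
  expect_equal(x$vectors[2, ], c(1, 0, 0), tolerance = 1e-6)
  expect_equal(x$meta$start, c(1L, 21L))
  expect_equal(x$meta$end, c(12L, 26L))
})

test_that("chains without SSE segments are skipped with a message", {
  path <- withr::local_tempfile(fileext = ".pdb")
  lines <- ideal_sse_pdb("strand", 6)
  writeLines(lines[-1], path)  # drop the SHEET record: no annotations
  expect_message(out <- reduce_file(path), "skipped")
  expect_length(out, 0)
})
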