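# The reduced representation: one typed unit vector per secondary-structure
# element, in sequence (N->C) order, plus the SSE residue lengths.

SSE_TYPES <- c("helix", "strand")

#' Construct a reduced representation
#'
#' An ordered set of three-dimensional unit vectors, one per secondary
#' structure element (SSE), each carrying its type (alpha-helix or
#' beta-strand) and residue length. Order follows the SSEs' order on the
#' peptide sequence. Spatial placement of the SSEs is deliberately
#' discarded: the representation is a set of typed points on the unit
#' sphere plus their sequential order.
#'
#' @param id Character label for the structure (e.g. `"1abc_A"`).
#' @param vectors Numeric `n x 3` matrix of SSE direction vectors (rows);
#'   each row must have Euclidean norm 1 within `1e-9`.
#' @param types Character vector of `"helix"`/`"strand"`, length `n`.
#' @param lengths Integer vector of residues per SSE, length `n`.
#' @param meta Optional per-SSE metadata `data.frame` (chain, start, end),
#'   carried through file round-trips when present.
#' @return Object of class `"reduced_rep"` with fields `id`, `vectors`,
#'   `types`, `lengths`, `count`.
#' @export
reduced_representation <- function(id, vectors, types, lengths, meta = NULL) {
  vectors <- as.matrix(vectors)
  if (is.null(dim(vectors)) || ncol(vectors) != 3) {
    stop("vectors must be an n x 3 matrix", call. = FALSE)
  }
  storage.mode(vectors) <- "double"
  n <- nrow(vectors)
  types <- as.character(types)
  lengths <- as.integer(lengths)
  if (length(types) != n || length(lengths) != n) {
    stop(sprintf("representation '%s': vectors (%d), types (%d) and lengths (%d) must have equal length",
                 id, n, length(types), length(lengths)), call. = FALSE)
  }
  if (n < 1) stop(sprintf("representation '%s' is empty", id), call. = FALSE)
  if (!all(types %in% SSE_TYPES)) {
    stop(sprintf("representation '%s': types must be 'helix' or 'strand'", id), call. = FALSE)
  }
  norms <- sqrt(rowSums(vectors^2))
  if (any(abs(norms - 1) > 1e-9)) {
    bad <- which(abs(norms - 1) > 1e-9)[1]
    stop(sprintf("representation '%s': vector %d is not a unit vector (norm %.12f)",
                 id, bad, norms[bad]), call. = FALSE)
  }
  if (any(lengths < 1)) stop(sprintf("representation '%s': SSE lengths must be >= 1", id), call. = FALSE)
  structure(list(id = as.character(id), vectors = vectors, types = types,
                 lengths = lengths, count = n, meta = meta),
            class = "reduced_rep")
}

#' @export
print.reduced_rep <- function(x, ...) {
  cat(sprintf("<reduced_rep> %s: %d SSEs (%d helix, %d strand)\n",
              x$id, x$count, sum(x$types == "helix"), sum(x$types == "strand")))
  invisible(x)
}

#' Apply a rotation to a reduced representation
#'
#' Rotates every SSE direction vector by the same rotation; types, lengths
#' and sequential order are unchanged, so all pairwise angles between the
#' vectors are preserved.
#'
#' @param x A `reduced_rep`.
#' @param r A `rotation`.
#' @return The rotated `reduced_rep`.
#' @export
apply_rotation <- function(x, r) {
  stopifnot(inherits(x, "reduced_rep"))
  R <- rotation_matrix(r)
  v <- x$vectors %*% t(R)
  # guard against norm drift from the matrix product
  v <- v / sqrt(rowSums(v^2))
  dimnames(v) <- NULL
  reduced_representation(x$id, v, x$types, x$lengths, meta = x$meta)
}

rep_to_record <- function(x) {
  rec <- list(
    id = x$id,
    type = x$types,
    vector = lapply(seq_len(x$count), function(i) unname(x$vectors[i, ])),
    length = x$lengths
  )
  if (!is.null(x$meta)) {
    rec$chain <- x$meta$chain
    rec$start <- x$meta$start
    rec$end <- x$meta$end
  }
  rec
}

record_to_rep <- function(rec, where = "record") {
  for (f in c("id", "type", "vector", "length")) {
    if (is.null(rec[[f]])) {
      stop(sprintf("%s: missing field '%s'", where, f), call. = FALSE)
    }
  }
  v <- rec$vector
  if (is.matrix(v)) {
    # jsonlite simplifies a list of equal-length vectors to an n x 3 matrix
    storage.mode(v) <- "double"
  } else if (is.list(v)) {
    if (any(vapply(v, length, 1L) != 3L)) {
      stop(sprintf("%s: field 'vector' must contain 3D vectors", where), call. = FALSE)
    }
    v <- do.call(rbind, lapply(v, as.numeric))
  } else {
    v <- matrix(as.numeric(v), ncol = 3, byrow = TRUE)
  }
  if (ncol(v) != 3) {
    stop(sprintf("%s: field 'vector' must contain 3D vectors", where), call. = FALSE)
  }
  meta <- NULL
  if (!is.null(rec$chain) && !is.null(rec$start) && !is.null(rec$end)) {
    meta <- data.frame(chain = as.character(rec$chain),
                       start = as.integer(rec$start),
                       end = as.integer(rec$end),
                       stringsAsFactors = FALSE)
  }
  out <- tryCatch(
    reduced_representation(rec$id, v, rec$type, rec$length, meta = meta),
    error = function(e) stop(sprintf("%s: %s", where, conditionMessage(e)), call. = FALSE)
  )
  out
}

#' Write reduced representations to a JSON-lines file
#'
#' One JSON record per line per structure, with fields `id` and per-SSE
#' `type`, `vector`, `length` (and `chain`/`start`/`end` when known).
#' Numbers are written at full double precision so that a write/read
#' round trip is the identity.
#'
#' @param x A `reduced_rep` or a list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_representation <- function(x, path) {
  if (inherits(x, "reduced_rep")) x <- list(x)
  lines <- vapply(x, function(r) {
    as.character(jsonlite::toJSON(rep_to_record(r), auto_unbox = TRUE,
                                  digits = I(17)))
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read reduced representations from a JSON-lines file
#'
#' @param path File written by [write_representation()].
#' @return A list of `reduced_rep` objects (a single object if the file
#'   holds one record and `simplify = TRUE`).
#' @param simplify If `TRUE` (default) a one-record file yields the bare
#'   `reduced_rep` rather than a list of length one.
#' @export
read_representation <- function(path, simplify = TRUE) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop(sprintf("%s: no records", path), call. = FALSE)
  reps <- lapply(seq_along(lines), function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) stop(sprintf("%s line %d: malformed JSON (%s)",
                                                     path, i, conditionMessage(e)), call. = FALSE))
    record_to_rep(rec, where = sprintf("%s line %d", path, i))
  })
  if (simplify && length(reps) == 1L) reps[[1]] else reps
}
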