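# Database construction and ranked rigid/flexible scans.

MIN_DB_SSES <- 4L  # entries need more than three SSEs

#' Build a representation database
#'
#' Reduces structure files (PDB/mmCIF) and/or collects representation
#' records into one database. Entries with fewer than four SSEs are
#' skipped (with a message), mirroring the usual "more than three SSEs"
#' filter for this kind of search; duplicate ids are an error. Record
#' order is deterministic (input order).
#'
#' @param inputs Character vector of file paths: structure files are
#'   reduced chain-by-chain, `.jsonl`/`.json` files are read as
#'   representation records. A list of `reduced_rep` objects is also
#'   accepted.
#' @param out Optional path: when given, the database is written there as
#'   JSON lines.
#' @param min_sses Minimum SSE count per entry (default 4).
#' @param ... Passed to [reduce_file()] for structure inputs.
#' @return List of `reduced_rep` (invisibly if `out` is given).
#' @export
build_database <- function(inputs, out = NULL, min_sses = MIN_DB_SSES, ...) {
  reps <- list()
  if (is.list(inputs) && all(vapply(inputs, inherits, TRUE, "reduced_rep"))) {
    reps <- inputs
  } else {
    for (p in inputs) {
      if (grepl("\\.jsonl?$", p, ignore.case = TRUE)) {
        reps <- c(reps, read_representation(p, simplify = FALSE))
      } else {
        reps <- c(reps, reduce_file(p, ...))
      }
    }
  }
  keep <- vapply(reps, function(r) r$count >= min_sses, TRUE)
  for (r in reps[!keep]) {
    message(sprintf("skipping %s: only %d SSEs (minimum %d)", r$id, r$count, min_sses))
  }
  reps <- reps[keep]
  if (length(reps) == 0) stop("no valid entries: empty database", call. = FALSE)
  ids <- vapply(reps, `[[`, "", "id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate id(s) in database: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")), call. = FALSE)
  }
  if (!is.null(out)) {
    write_representation(reps, out)
    return(invisible(reps))
  }
  reps
}

fmt_pairs <- function(pairs) {
  if (nrow(pairs) == 0) return("")
  paste(sprintf("%d:%d", pairs[, 1], pairs[, 2]), collapse = ";")
}

#' Scan a query against a representation database
#'
#' For each target: run the rotation search ([collect_minima()]), align
#' the similarity matrix at each significant minimum and keep the best
#' total aligned score T; in flexible mode additionally run
#' [flexible_search()]. Rigid results are ranked by descending T,
#' flexible-mode results by descending heuristic score (then T). The best
#' z-score is reported alongside T so the purely geometric and the
#' order-constrained rankings can both be inspected.
#'
#' @param query A `reduced_rep` with at least 4 SSEs.
#' @param db List of `reduced_rep` (e.g. from [build_database()]) or a
#'   path to a JSON-lines database.
#' @param params A [match_params()].
#' @param mode `"rigid"` (default) or `"flexible"`.
#' @return A `data.frame` with one row per target: `target_id`, `mode`,
#'   `T`, `z`, `flex_score`, `n_pairs`, `separation`, `alignment`
#'   (semicolon-joined `i:j` pairs), `rank`.
#' @export
scan_database <- function(query, db, params = match_params(),
                          mode = c("rigid", "flexible")) {
  mode <- match.arg(mode)
  stopifnot(inherits(query, "reduced_rep"))
  if (query$count < MIN_DB_SSES) {
    stop(sprintf("query '%s' has %d SSEs; scans need at least %d",
                 query$id, query$count, MIN_DB_SSES), call. = FALSE)
  }
  if (is.character(db)) db <- read_representation(db, simplify = FALSE)
  if (inherits(db, "reduced_rep")) db <- list(db)
  if (length(db) == 0) {
    return(data.frame(target_id = character(), mode = character(), T = numeric(),
                      z = numeric(), flex_score = numeric(), n_pairs = integer(),
                      separation = numeric(), alignment = character(),
                      rank = integer(), stringsAsFactors = FALSE))
  }
  rows <- lapply(db, function(target) {
    hit <- list(target_id = target$id, mode = "rigid", T = 0, z = NA_real_,
                flex_score = NA_real_, n_pairs = 0L, separation = NA_real_,
                alignment = "")
    wts_sum <- sum(pair_weights(query, target, NULL))
    if (wts_sum == 0) return(hit)  # type-disjoint
    stats <- rotation_statistics(query, target, params)
    minima <- collect_minima(query, target, params, stats = stats, keep_all = TRUE)
    if (length(minima) == 0) return(hit)
    hit$z <- minima[[1]]$z  # ascending z: most significant first
    signif_min <- Filter(function(mn) mn$z <= params$z_cut, minima)
    if (length(signif_min) == 0) return(hit)
    alns <- lapply(signif_min, function(mn) {
      align_sses(similarity_matrix(query, target, mn$rotation, params),
                 gap_open = params$gap_open, mode = params$align_mode)
    })
    Ts <- vapply(alns, `[[`, numeric(1), "total_score")
    bi <- which.max(Ts)
    hit$T <- Ts[bi]
    hit$n_pairs <- nrow(alns[[bi]]$pairs)
    hit$alignment <- fmt_pairs(alns[[bi]]$pairs)
    if (mode == "flexible") {
      fm <- flexible_search(query, target, params, minima = signif_min)
      if (!is.null(fm)) {
        hit$mode <- "flexible"
        hit$flex_score <- fm$score
        hit$separation <- fm$separation
        hit$T <- fm$combined_alignment$total_score
        hit$n_pairs <- nrow(fm$combined_alignment$pairs)
        hit$alignment <- fmt_pairs(fm$combined_alignment$pairs)
      }
    }
    hit
  })
  res <- do.call(rbind, lapply(rows, function(h) {
    data.frame(h, stringsAsFactors = FALSE)
  }))
  ord <- if (mode == "flexible") {
    order(-ifelse(is.na(res$flex_score), -Inf, res$flex_score), -res$T, res$target_id)
  } else {
    order(-res$T, res$target_id)
  }
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  res
}

#' Write a scan report
#'
#' Tab-separated report with a `#`-prefixed header block recording all
#' matching parameters, then one row per hit. Reports are byte-identical
#' across runs with identical inputs, parameters and seed.
#'
#' @param hits Result of [scan_database()].
#' @param params The [match_params()] used.
#' @param path Output file.
#' @param query_id Query label recorded in the header.
#' @return `path`, invisibly.
#' @export
write_scan_report <- function(hits, params, path, query_id = "") {
  fmt_param <- function(v) {
    if (is.null(v)) "none" else as.character(v)
  }
  hdr <- c(
    sprintf("# ssematch scan report"),
    sprintf("# query\t%s", query_id),
    vapply(names(params), function(nm) sprintf("# %s\t%s", nm, fmt_param(params[[nm]])),
           character(1))
  )
  num <- vapply(hits, is.numeric, TRUE)
  out <- hits
  for (cn in names(out)[num]) out[[cn]] <- sprintf("%.6g", out[[cn]])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
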