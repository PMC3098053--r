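# Reduction of a protein chain to typed SSE direction vectors.
#
# SSE assignment itself is taken as given: HELIX/SHEET records from the
# coordinate file, or an external segment table. No geometric assignment
# (DSSP/STRIDE style) is attempted here.

#' Load C-alpha traces from a structure file
#'
#' Parses a PDB (or mmCIF) file with `bio3d::read.pdb`/`read.cif` and
#' returns, per chain, the ordered C-alpha trace together with any
#' HELIX/SHEET annotations present in the file.
#'
#' @param path Path to a PDB (`.pdb`, `.ent`) or mmCIF (`.cif`) file.
#' @param chain Optional chain identifier; default: all chains with
#'   C-alpha atoms.
#' @return A named list (one element per chain) of traces; each trace is a
#'   list with `chain`, `resno` (author residue numbers, sequence order),
#'   `xyz` (`n x 3` coordinate matrix, Angstrom) and `annotations` (a
#'   `data.frame` of `type`/`start`/`end` from HELIX/SHEET records on that
#'   chain, possibly empty).
#' @export
load_ca_trace <- function(path, chain = NULL) {
  if (!file.exists(path)) stop(sprintf("no such file: %s", path), call. = FALSE)
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    suppressWarnings(if (is_cif) bio3d::read.cif(path) else bio3d::read.pdb(path)),
    error = function(e) stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  atoms <- pdb$atom
  ca <- atoms[atoms$elety == "CA" & atoms$type %in% c("ATOM", "HETATM"), , drop = FALSE]
  # drop alternate locations beyond the first
  if ("alt" %in% names(ca)) {
    keep <- is.na(ca$alt) | ca$alt %in% c("", "A")
    ca <- ca[keep, , drop = FALSE]
  }
  if (nrow(ca) == 0) stop(sprintf("%s: no C-alpha atoms", path), call. = FALSE)
  chains <- unique(ca$chain)
  if (!is.null(chain)) {
    if (!all(chain %in% chains)) {
      stop(sprintf("%s: chain '%s' not found (available: %s)", path,
                   paste(setdiff(chain, chains), collapse = ","),
                   paste(chains, collapse = ",")), call. = FALSE)
    }
    chains <- chain
  }
  ann_all <- annotations_from_pdb(pdb)
  out <- lapply(chains, function(ch) {
    sub <- ca[ca$chain == ch, , drop = FALSE]
    # keep one CA per residue number, in file (sequence) order
    sub <- sub[!duplicated(sub$resno), , drop = FALSE]
    if (any(diff(sub$resno) <= 0)) {
      sub <- sub[order(sub$resno), , drop = FALSE]
    }
    if (any(diff(sub$resno) > 1)) {
      message(sprintf("%s chain %s: gaps in C-alpha trace at %d position(s); missing residues skipped",
                      basename(path), ch, sum(diff(sub$resno) > 1)))
    }
    list(chain = ch,
         resno = sub$resno,
         xyz = unname(as.matrix(sub[, c("x", "y", "z")])),
         annotations = ann_all[ann_all$chain == ch, c("type", "start", "end"), drop = FALSE])
  })
  names(out) <- chains
  out
}

annotations_from_pdb <- function(pdb) {
  grab <- function(rec, type) {
    if (is.null(rec) || length(rec$start) == 0) return(NULL)
    data.frame(type = type,
               chain = as.character(rec$chain),
               start = as.integer(unname(rec$start)),
               end = as.integer(unname(rec$end)),
               stringsAsFactors = FALSE)
  }
  ann <- rbind(grab(pdb$helix, "helix"), grab(pdb$sheet, "strand"))
  if (is.null(ann)) {
    ann <- data.frame(type = character(), chain = character(),
                      start = integer(), end = integer(), stringsAsFactors = FALSE)
  }
  ann
}

#' Assign secondary-structure segments on a C-alpha trace
#'
#' Turns HELIX/SHEET annotations (from the file, or supplied externally)
#' into ordered, non-overlapping SSE segments carrying their C-alpha
#' coordinates. Helices shorter than `min_helix` residues and strands
#' shorter than `min_strand` are discarded: very short segments give
#' unstable axis fits.
#'
#' @param trace A single-chain trace from [load_ca_trace()].
#' @param annotations Optional `data.frame` with columns `type`
#'   (`"helix"`/`"strand"`), `start`, `end` (author residue numbers,
#'   inclusive). Default: the annotations found in the file.
#' @param min_helix,min_strand Minimum residue counts (defaults 4 and 3).
#' @return A list of SSE segments, each a list with `chain`,
#'   `start_residue`, `end_residue`, `sse_type`, `ca_coords`.
#' @export
assign_sses <- function(trace, annotations = NULL, min_helix = 4, min_strand = 3) {
  if (length(trace$resno) == 0) stop("empty C-alpha trace", call. = FALSE)
  ann <- if (is.null(annotations)) trace$annotations else annotations
  if (is.null(ann) || nrow(ann) == 0) return(list())
  ann <- ann[order(ann$start), , drop = FALSE]
  if (!all(ann$type %in% SSE_TYPES)) {
    stop("annotation types must be 'helix' or 'strand'", call. = FALSE)
  }
  if (any(ann$start > ann$end)) stop("annotation with start > end", call. = FALSE)
  if (nrow(ann) > 1 && any(ann$start[-1] <= ann$end[-nrow(ann)])) {
    stop("overlapping SSE annotation records", call. = FALSE)
  }
  segs <- lapply(seq_len(nrow(ann)), function(k) {
    sel <- trace$resno >= ann$start[k] & trace$resno <= ann$end[k]
    n <- sum(sel)
    minlen <- if (ann$type[k] == "helix") min_helix else min_strand
    if (n < max(2, minlen)) return(NULL)
    list(chain = trace$chain,
         start_residue = ann$start[k],
         end_residue = ann$end[k],
         sse_type = ann$type[k],
         ca_coords = trace$xyz[sel, , drop = FALSE])
  })
  segs[!vapply(segs, is.null, TRUE)]
}

#' Direction vector of one SSE segment
#'
#' Fits the first principal axis of the segment's C-alpha point cloud and
#' orients it N->C: the axis is flipped, if needed, so that its dot
#' product with (last CA - first CA) is non-negative.
#'
#' @param segment One segment from [assign_sses()] (needs >= 2 points).
#' @return List with `vector` (unit 3-vector) and `length` (residue count,
#'   i.e. number of C-alpha points in the segment).
#' @export
segment_axis <- function(segment) {
  xyz <- segment$ca_coords
  if (is.null(dim(xyz)) || nrow(xyz) < 2) {
    stop("segment must have at least 2 C-alpha points", call. = FALSE)
  }
  centered <- sweep(xyz, 2, colMeans(xyz))
  if (max(abs(centered)) < 1e-9) {
    stop("degenerate segment geometry: all C-alpha points coincide", call. = FALSE)
  }
  ax <- svd(centered, nu = 0, nv = 1)$v[, 1]
  span <- xyz[nrow(xyz), ] - xyz[1, ]
  if (sum(ax * span) < 0) ax <- -ax
  list(vector = ax / sqrt(sum(ax^2)), length = nrow(xyz))
}

#' Reduce a chain to its typed SSE unit vectors
#'
#' @param trace A single-chain trace from [load_ca_trace()].
#' @param segments Segment list from [assign_sses()] (sequence-ordered).
#' @param id Representation label; default `"<basename>_<chain>"` is not
#'   derivable here, so default is `"structure_<chain>"`.
#' @return A [reduced_representation()] with one entry per segment, in
#'   sequence order.
#' @export
reduce_structure <- function(trace, segments, id = paste0("structure_", trace$chain)) {
  if (length(segments) == 0) {
    stop("no SSE segments survive filtering: empty representation", call. = FALSE)
  }
  axes <- lapply(segments, segment_axis)
  vectors <- do.call(rbind, lapply(axes, `[[`, "vector"))
  meta <- data.frame(
    chain = vapply(segments, `[[`, "", "chain"),
    start = vapply(segments, function(s) as.integer(s$start_residue), 1L),
    end = vapply(segments, function(s) as.integer(s$end_residue), 1L),
    stringsAsFactors = FALSE
  )
  reduced_representation(
    id = id,
    vectors = vectors,
    types = vapply(segments, `[[`, "", "sse_type"),
    lengths = vapply(axes, function(a) as.integer(a$length), 1L),
    meta = meta
  )
}

#' Reduce every chain of a structure file
#'
#' Convenience wrapper: [load_ca_trace()] + [assign_sses()] +
#' [reduce_structure()] per chain. Chains with no surviving SSE segments
#' are skipped with a message.
#'
#' @param path Structure file.
#' @param chain Optional chain selection.
#' @param annotations Optional external segment table (see [assign_sses()]).
#' @param min_helix,min_strand Minimum SSE residue counts.
#' @param id Base label; default the file name without extension.
#' @return A list of `reduced_rep`, one per chain that yields segments.
#' @export
reduce_file <- function(path, chain = NULL, annotations = NULL,
                        min_helix = 4, min_strand = 3,
                        id = sub("\\.(pdb|ent|cif)(\\.gz)?$", "", basename(path),
                                 ignore.case = TRUE)) {
  traces <- load_ca_trace(path, chain = chain)
  out <- list()
  for (tr in traces) {
    segs <- assign_sses(tr, annotations = annotations,
                        min_helix = min_helix, min_strand = min_strand)
    if (length(segs) == 0) {
      message(sprintf("%s chain %s: no SSE segments after filtering; skipped",
                      basename(path), tr$chain))
      next
    }
    out[[length(out) + 1L]] <- reduce_structure(tr, segs, id = paste0(id, "_", tr$chain))
  }
  out
}
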