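#' Structure context for an extein
#'
#' Holds per-residue C-alpha and C-beta coordinates in extein numbering,
#' optional secondary-structure codes, and annotated functional residues
#' (active site, dimer interface).  Structure residue numbers rarely match
#' extein numbering, so the mapping is always an explicit offset or map and
#' never inferred.
#'
#' @param positions integer vector of extein sequence positions (1-based).
#' @param ca numeric matrix `length(positions)` x 3 of C-alpha coordinates
#'   in Angstrom.
#' @param cb like `ca`, C-beta coordinates (C-alpha substituted for glycine).
#' @param ss_codes optional named character vector of one-letter secondary
#'   structure codes (names are extein positions).
#' @param active_site integer vector of annotated active-site positions.
#' @param dimer_interface integer vector of annotated dimer-interface
#'   positions.
#' @param unmapped_annotations annotated positions with no mapped residue.
#' @return object of class `structure_context`.
#' @export
structure_context <- function(positions, ca, cb = NULL, ss_codes = NULL,
                              active_site = integer(),
                              dimer_interface = integer(),
                              unmapped_annotations = integer()) {
  positions <- as.integer(positions)
  ca <- as.matrix(ca)
  if (ncol(ca) != 3L || nrow(ca) != length(positions)) {
    stopf("'ca' must be a %d x 3 coordinate matrix", length(positions))
  }
  if (anyDuplicated(positions)) stopf("duplicate residue positions in structure map")
  if (any(!is.finite(ca))) stopf("non-finite C-alpha coordinates")
  if (is.null(cb)) cb <- ca
  cb <- as.matrix(cb)
  if (!all(dim(cb) == dim(ca))) stopf("'cb' must match 'ca' in shape")
  if (any(!is.finite(cb))) stopf("non-finite C-beta coordinates")
  rownames(ca) <- rownames(cb) <- positions
  ann_check <- function(ann, what) {
    ann <- as.integer(ann)
    missing_ca <- setdiff(ann, c(positions, unmapped_annotations))
    if (length(missing_ca)) {
      stopf("%s position %d has no C-alpha coordinate", what, missing_ca[1L])
    }
    sort(unique(ann))
  }
  structure(
    list(positions = positions, ca = ca, cb = cb,
         ss_codes = ss_codes,
         active_site = ann_check(active_site, "active-site"),
         dimer_interface = ann_check(dimer_interface, "dimer-interface"),
         unmapped_annotations = as.integer(unmapped_annotations)),
    class = "structure_context"
  )
}

#' @export
print.structure_context <- function(x, ...) {
  cat(sprintf("<structure_context> %d residues (positions %d..%d)\n",
              length(x$positions), min(x$positions), max(x$positions)))
  cat(sprintf("  active site: %d, dimer interface: %d, ss codes: %s\n",
              length(x$active_site), length(x$dimer_interface),
              if (is.null(x$ss_codes)) "none" else "present"))
  invisible(x)
}

#' Read a protein chain into a structure context
#'
#' Extracts C-alpha and C-beta coordinates for one chain of a PDB file and
#' maps structure residue numbers into extein numbering through an explicit
#' offset or map.  Glycines have no C-beta; the C-alpha coordinate is
#' substituted, the standard convention for C-beta contact counting.
#' Non-glycine residues missing a C-beta fall back to C-alpha with a
#' warning.
#'
#' @param path path to a PDB file.
#' @param chain chain identifier, or `NULL` for the first chain present.
#' @param offset integer added to structure residue numbers to obtain extein
#'   positions (e.g. offset 28 renumbers structure residue 1 to extein
#'   position 29).  Ignored when `map` is given.
#' @param map optional named integer vector: names are structure residue
#'   numbers, values extein positions.
#' @param annotations optional data frame with columns `position` (extein
#'   numbering) and `type` (`"active_site"` or `"dimer_interface"`), e.g.
#'   from [read_annotations].  Annotated positions without a mapped residue
#'   are reported in `unmapped_annotations` with a warning.
#' @param ss_codes optional secondary-structure codes named by extein
#'   position, e.g. from [read_ss_assignment].
#' @return a [structure_context].
#' @export
read_structure <- function(path, chain = NULL, offset = 0L, map = NULL,
                           annotations = NULL, ss_codes = NULL) {
  if (!file.exists(path)) stopf("PDB file not found: %s", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stopf("no ATOM records in %s", path)
  if (is.null(chain)) chain <- at$chain[1L]
  at <- at[at$chain %in% chain, , drop = FALSE]
  if (!nrow(at)) stopf("chain '%s' not found in %s", chain, path)

  ca <- at[at$elety == "CA", , drop = FALSE]
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  if (!nrow(ca)) stopf("no C-alpha atoms for chain '%s'", chain)
  cb <- at[at$elety == "CB", , drop = FALSE]
  cb <- cb[!duplicated(cb$resno), , drop = FALSE]

  resno <- ca$resno
  if (!is.null(map)) {
    if (is.null(names(map))) stopf("'map' must be named by structure residue number")
    hit <- as.character(resno) %in% names(map)
    resno_kept <- resno[hit]
    positions <- as.integer(map[as.character(resno_kept)])
    ca <- ca[hit, , drop = FALSE]
  } else {
    resno_kept <- resno
    positions <- resno + as.integer(offset)
  }

  ca_xyz <- as.matrix(ca[, c("x", "y", "z")])
  cb_xyz <- ca_xyz
  cb_idx <- match(resno_kept, cb$resno)
  have_cb <- !is.na(cb_idx)
  cb_xyz[have_cb, ] <- as.matrix(cb[cb_idx[have_cb], c("x", "y", "z")])
  no_cb_nongly <- resno_kept[!have_cb & ca$resid != "GLY"]
  if (length(no_cb_nongly)) {
    warnf("%d non-glycine residue(s) missing C-beta; using C-alpha (first: residue %d)",
          length(no_cb_nongly), no_cb_nongly[1L])
  }

  active <- integer(); dimer <- integer(); unmapped <- integer()
  if (!is.null(annotations)) {
    if (!all(c("position", "type") %in% names(annotations))) {
      stopf("'annotations' needs columns 'position' and 'type'")
    }
    ann_pos <- as.integer(annotations$position)
    known <- ann_pos %in% positions
    unmapped <- sort(unique(ann_pos[!known]))
    if (length(unmapped)) {
      warnf("%d annotated position(s) not resolved in the structure: %s",
            length(unmapped), paste(unmapped, collapse = ", "))
    }
    active <- ann_pos[known & annotations$type == "active_site"]
    dimer <- ann_pos[known & annotations$type == "dimer_interface"]
  }

  structure_context(positions, ca_xyz, cb_xyz, ss_codes = ss_codes,
                    active_site = active, dimer_interface = dimer,
                    unmapped_annotations = unmapped)
}

#' Read per-residue secondary-structure assignments
#'
#' Accepts Stride output (`ASG` records) or a plain two-column table of
#' position and one-letter code.  Codes are mapped to extein numbering with
#' `offset`; positions absent from the input are returned as `NA` (unknown)
#' and excluded from junction arithmetic downstream.
#'
#' @param path path to a Stride output file or two-column table.
#' @param text optional character vector of lines instead of `path`.
#' @param offset integer added to the file's residue numbers.
#' @return named character vector of codes among H, G, I, E, B, b, T, C, S;
#'   names are extein positions.  Gaps in the position range are `NA`.
#' @export
read_ss_assignment <- function(path = NULL, text = NULL, offset = 0L) {
  lines <- if (!is.null(text)) text else {
    if (is.null(path) || !file.exists(path)) stopf("SS file not found: %s", path)
    readLines(path, warn = FALSE)
  }
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stopf("empty secondary-structure input")
  asg <- grepl("^ASG\\b", lines)
  if (any(asg)) {
    fields <- strsplit(trimws(lines[asg]), "\\s+")
    # ASG resname chain pdb-resno ordinal code name phi psi area
    pos <- vapply(fields, function(f) suppressWarnings(as.integer(f[4L])), integer(1))
    code <- vapply(fields, function(f) f[6L], character(1))
    if (anyNA(pos)) stopf("malformed ASG record: '%s'", lines[asg][which(is.na(pos))[1L]])
  } else {
    rows <- lines[!grepl("^#", lines)]
    fields <- strsplit(trimws(rows), "\\s+")
    ok <- lengths(fields) >= 2L
    if (!any(ok)) stopf("no parsable position/code rows in secondary-structure input")
    pos <- vapply(fields[ok], function(f) suppressWarnings(as.integer(f[1L])), integer(1))
    code <- vapply(fields[ok], function(f) f[2L], character(1))
    if (anyNA(pos)) stopf("malformed position field in secondary-structure input")
  }
  pos <- pos + as.integer(offset)
  if (anyDuplicated(pos)) {
    stopf("duplicate secondary-structure assignment for position %d",
          pos[anyDuplicated(pos)])
  }
  valid <- c("H", "G", "I", "E", "B", "b", "T", "C", "S")
  bad <- setdiff(unique(code), valid)
  if (length(bad)) stopf("unknown secondary-structure code '%s'", bad[1L])
  full <- rep(NA_character_, max(pos) - min(pos) + 1L)
  names(full) <- seq(min(pos), max(pos))
  full[as.character(pos)] <- code
  full
}

#' Read a functional-residue annotation table
#'
#' Plain TSV with columns `position` and `type`, where type is
#' `active_site` or `dimer_interface`, in extein numbering.
#'
#' @param path path to the table.
#' @return data frame with columns `position` (integer) and `type`.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stopf("annotation file not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("position", "type") %in% names(df))) {
    stopf("annotation table needs columns 'position' and 'type'")
  }
  bad <- setdiff(unique(df$type), c("active_site", "dimer_interface"))
  if (length(bad)) stopf("unknown annotation type '%s'", bad[1L])
  df$position <- as.integer(df$position)
  if (anyNA(df$position)) stopf("non-integer annotation position")
  df[, c("position", "type")]
}

#' Snapshot sets of aligned trajectory frames
#'
#' @param coords numeric array S x N x 3 of C-alpha coordinates: S
#'   snapshots of the same N residues.
#' @param positions optional extein positions of the N residues (default
#'   `1..N`).
#' @return object of class `snapshot_set`.
#' @export
snapshot_set <- function(coords, positions = NULL) {
  coords <- unclass(coords)
  d <- dim(coords)
  if (length(d) != 3L || d[3L] != 3L) stopf("'coords' must be an S x N x 3 array")
  if (d[1L] < 2L) stopf("a snapshot set needs at least 2 snapshots")
  if (any(!is.finite(coords))) stopf("non-finite snapshot coordinates")
  if (is.null(positions)) positions <- seq_len(d[2L])
  positions <- as.integer(positions)
  if (length(positions) != d[2L]) stopf("'positions' must have length N = %d", d[2L])
  structure(list(coords = coords, positions = positions,
                 n_snapshots = d[1L]),
            class = "snapshot_set")
}

#' @export
print.snapshot_set <- function(x, ...) {
  cat(sprintf("<snapshot_set> %d snapshots x %d residues\n",
              x$n_snapshots, length(x$positions)))
  invisible(x)
}

#' Read trajectory snapshots
#'
#' Multi-model PDB (`MODEL`/`ENDMDL` blocks; C-alpha atoms are extracted per
#' model) or a plain text format of one `x y z` line per residue with blank
#' lines separating frames.
#'
#' @param path input file.
#' @param format `"pdb"` or `"xyz"`; guessed from the extension by default.
#' @param offset integer added to PDB residue numbers to obtain extein
#'   positions.
#' @return a [snapshot_set].
#' @export
read_snapshots <- function(path, format = c("auto", "pdb", "xyz"), offset = 0L) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.pdb$", path, ignore.case = TRUE)) "pdb" else "xyz"
  }
  if (!file.exists(path)) stopf("snapshot file not found: %s", path)
  if (format == "pdb") {
    pdb <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
    sel <- bio3d::atom.select(pdb, elety = "CA", verbose = FALSE)
    xyz <- pdb$xyz[, sel$xyz, drop = FALSE]
    n <- length(sel$atom)
    s <- nrow(xyz)
    if (s < 2L) stopf("multi-model PDB has fewer than 2 models")
    coords <- array(NA_real_, c(s, n, 3L))
    for (k in seq_len(s)) {
      coords[k, , ] <- matrix(xyz[k, ], ncol = 3L, byrow = TRUE)
    }
    positions <- pdb$atom$resno[sel$atom] + as.integer(offset)
    snapshot_set(coords, positions)
  } else {
    lines <- readLines(path, warn = FALSE)
    grp <- cumsum(!nzchar(trimws(lines)))
    keep <- nzchar(trimws(lines)) & !grepl("^#", lines)
    frames <- split(lines[keep], grp[keep])
    frames <- frames[lengths(frames) > 0L]
    if (length(frames) < 2L) stopf("fewer than 2 frames in %s", path)
    mats <- lapply(frames, function(fr) {
      m <- do.call(rbind, lapply(strsplit(trimws(fr), "\\s+"), function(f) {
        v <- suppressWarnings(as.numeric(f))
        if (length(v) < 3L || anyNA(v[1:3])) stopf("malformed xyz line: '%s'", paste(f, collapse = " "))
        v[1:3]
      }))
      m
    })
    n <- nrow(mats[[1L]])
    if (any(vapply(mats, nrow, integer(1)) != n)) {
      stopf("snapshots differ in residue count")
    }
    coords <- array(NA_real_, c(length(mats), n, 3L))
    for (k in seq_along(mats)) coords[k, , ] <- mats[[k]]
    snapshot_set(coords)
  }
}
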