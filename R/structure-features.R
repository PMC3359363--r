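#' Group secondary-structure codes
#'
#' Collapses one-letter secondary-structure codes (Stride/DSSP style) into
#' four groups: H is helix, E is sheet, T/S/C are loop, and G, I, B/b (3-10
#' and pi helices, isolated bridges) are "other".  Unknown or missing codes
#' also map to "other".
#'
#' @param codes character vector of one-letter codes (NA allowed).
#' @return character vector among `"helix"`, `"sheet"`, `"loop"`,
#'   `"other"`, same names as `codes`.
#' @export
group_ss_codes <- function(codes) {
  grp <- rep("other", length(codes))
  grp[codes %in% "H"] <- "helix"
  grp[codes %in% "E"] <- "sheet"
  grp[codes %in% c("T", "S", "C")] <- "loop"
  grp[codes %in% c("helix", "sheet", "loop")] <- codes[codes %in% c("helix", "sheet", "loop")]
  names(grp) <- names(codes)
  grp
}

#' Classify a site's secondary-structure context
#'
#' Assigns a candidate site to one of six bins relative to secondary
#' structure/loop junctions: within two residues of a helix/loop junction
#' (`AH/L-junction`), within two of a sheet/loop junction
#' (`BS/L-junction`), middle of a helix, sheet or loop (`mid-AH`,
#' `mid-BS`, `mid-L`), or `other`.  The junction distance is the minimum
#' sequence separation to the nearest residue of the complementary group:
#' for helix and sheet residues the nearest loop residue, for loop residues
#' the nearest helix or sheet residue.  "Other" residues terminate runs but
#' never define a helix- or sheet-junction; they are skipped in the scan.
#' When a loop residue lies within two of both junction types, the nearer
#' wins, with ties going to the sheet/loop junction.
#'
#' @param groups character vector of per-residue groups from
#'   [group_ss_codes()], optionally named by extein position.
#' @param position index into `groups` (by name when named, else 1-based).
#' @return object of class `ss_context`: list with `bin` and
#'   `junction_distance` (integer, `Inf` when no junction exists, `NA`
#'   when the site's own code is unknown/"other").
#' @export
classify_site_ss <- function(groups, position) {
  idx <- if (!is.null(names(groups))) match(as.character(position), names(groups))
         else as.integer(position)
  if (is.na(idx) || idx < 1L || idx > length(groups)) {
    stopf("position %s has no secondary-structure group", position)
  }
  g <- groups[idx]
  nearest <- function(target_groups) {
    hits <- which(groups %in% target_groups)
    if (!length(hits)) return(Inf)
    min(abs(hits - idx))
  }
  out <- if (is.na(g) || g == "other") {
    list(bin = "other", junction_distance = NA_real_)
  } else if (g == "helix") {
    d <- nearest("loop")
    list(bin = if (d <= 2) "AH/L-junction" else "mid-AH", junction_distance = d)
  } else if (g == "sheet") {
    d <- nearest("loop")
    list(bin = if (d <= 2) "BS/L-junction" else "mid-BS", junction_distance = d)
  } else {  # loop
    dh <- nearest("helix")
    de <- nearest("sheet")
    d <- min(dh, de)
    bin <- if (d > 2) "mid-L" else if (de <= dh) "BS/L-junction" else "AH/L-junction"
    list(bin = bin, junction_distance = d)
  }
  structure(out, class = "ss_context")
}

#' @export
print.ss_context <- function(x, ...) {
  d <- x$junction_distance
  cat(sprintf("<ss_context> %s (junction distance %s)\n", x$bin,
              if (is.na(d)) "undefined" else if (d > 2) ">2" else format(d)))
  invisible(x)
}

#' C-beta contact density of a residue
#'
#' Burial proxy: the number of other residues whose C-beta atom lies within
#' 8 Angstrom (closed ball) of the target residue's C-beta.  Glycine uses
#' its C-alpha coordinate.
#'
#' @param structure a [structure_context].
#' @param position extein position of the target residue.
#' @param cutoff neighbour cutoff in Angstrom (default 8).
#' @return non-negative integer count (self excluded).
#' @export
cbeta_density <- function(structure, position, cutoff = 8) {
  stopifnot(inherits(structure, "structure_context"))
  idx <- match(as.integer(position), structure$positions)
  if (is.na(idx)) stopf("position %d has no coordinates in the structure", position)
  d2 <- colSums((t(structure$cb) - structure$cb[idx, ])^2)
  sum(d2[-idx] <= cutoff^2)
}

#' Minimum C-alpha distance to annotated functional residues
#'
#' @param structure a [structure_context] with annotations.
#' @param position extein position of the candidate site.
#' @param which `"active"`, `"dimer"`, or `"either"` (minimum over both
#'   annotation sets, the merged axis used by the combined predictor).
#' @return distance in Angstrom (0 when the site itself is annotated).
#'   An empty annotation set is an error: the feature is missing, never 0.
#' @export
distance_to_functional_site <- function(structure, position,
                                        which = c("either", "active", "dimer")) {
  stopifnot(inherits(structure, "structure_context"))
  which <- match.arg(which)
  ann <- switch(which,
                active = structure$active_site,
                dimer = structure$dimer_interface,
                either = c(structure$active_site, structure$dimer_interface))
  if (!length(ann)) {
    stopf("no %s annotation available; distance feature is missing",
          switch(which, active = "active-site", dimer = "dimer-interface",
                 either = "active-site or dimer-interface"))
  }
  idx <- match(as.integer(position), structure$positions)
  if (is.na(idx)) stopf("position %d has no C-alpha coordinate", position)
  aidx <- match(ann, structure$positions)
  d2 <- colSums((t(structure$ca[aidx, , drop = FALSE]) - structure$ca[idx, ])^2)
  sqrt(min(d2))
}

#' Kabsch superposition of two coordinate sets
#'
#' Least-squares rigid-body superposition (rotation + translation) of
#' `mobile` onto `reference` via the SVD-based Kabsch algorithm, with the
#' determinant correction that excludes reflections.
#'
#' @param mobile numeric N x 3 matrix.
#' @param reference numeric N x 3 matrix, same N >= 3.
#' @return the transformed `mobile` coordinates, with the achieved RMSD in
#'   attribute `"rmsd"`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stopf("'mobile' and 'reference' must be N x 3 matrices of equal size")
  }
  n <- nrow(mobile)
  if (n < 3L) stopf("superposition needs at least 3 atoms")
  mc <- colMeans(mobile); rc <- colMeans(reference)
  A <- sweep(mobile, 2L, mc)
  B <- sweep(reference, 2L, rc)
  s <- svd(crossprod(A, B))           # t(A) %*% B
  if (s$d[2L] < 1e-8 * max(s$d[1L], 1)) {
    stopf("degenerate (collinear) coordinates; superposition is ill-defined")
  }
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  out <- sweep(A %*% t(R), 2L, rc, `+`)
  attr(out, "rmsd") <- sqrt(mean(rowSums((out - reference)^2)))
  out
}

#' Superpose all snapshots onto the first
#'
#' @param snapshots a [snapshot_set].
#' @return a [snapshot_set] with every snapshot rigid-body aligned to
#'   snapshot 1.
#' @export
superpose_snapshots <- function(snapshots) {
  stopifnot(inherits(snapshots, "snapshot_set"))
  coords <- snapshots$coords
  ref <- coords[1L, , ]
  for (s in 2:dim(coords)[1L]) {
    coords[s, , ] <- kabsch_superpose(coords[s, , ], ref)
  }
  snapshot_set(coords, snapshots$positions)
}

#' Per-site flexibility over trajectory snapshots
#'
#' Time-averaged C-alpha deviation of a residue from its position in the
#' first snapshot,
#' \deqn{rmsd_i = \sqrt{\frac{1}{S}\sum_{s=1}^{S} \|x_{i,s} - x_{i,1}\|^2},}
#' over all S snapshots (the reference term contributes 0).  Set
#' `denominator = "S-1"` for the convention that averages over the S-1
#' non-reference snapshots only.
#'
#' @param snapshots a [snapshot_set] (frames already aligned to snapshot 1,
#'   or set `superpose = TRUE`).
#' @param position extein position of the site (must be in
#'   `snapshots$positions`).
#' @param superpose superpose all frames onto snapshot 1 first.
#' @param denominator `"S"` (default) or `"S-1"`.
#' @return flexibility RMSD in Angstrom.
#' @export
site_flexibility <- function(snapshots, position, superpose = FALSE,
                             denominator = c("S", "S-1")) {
  stopifnot(inherits(snapshots, "snapshot_set"))
  denominator <- match.arg(denominator)
  if (superpose) snapshots <- superpose_snapshots(snapshots)
  idx <- match(as.integer(position), snapshots$positions)
  if (is.na(idx)) stopf("position %d is not in the snapshot set", position)
  S <- snapshots$n_snapshots
  if (S < 2L) stopf("flexibility needs at least 2 snapshots")
  ref <- snapshots$coords[1L, idx, ]
  dev2 <- rowSums(sweep(snapshots$coords[, idx, , drop = TRUE], 2L, ref)^2)
  sqrt(sum(dev2) / if (denominator == "S") S else S - 1L)
}
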