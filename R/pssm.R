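#' Position-specific scoring matrices
#'
#' A `pssm` stores one probability distribution over the 20 standard amino
#' acids per sequence position, the `p_ij` that feed the positional-entropy
#' conservation score.  Probabilities are taken from the weighted observed
#' percentage block of a PSI-BLAST (blastpgp) ASCII matrix, not from the
#' log-odds block.
#'
#' @name pssm
NULL

# Column order of the blastpgp ASCII matrix header.
BLAST_AA_ORDER <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                    "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a PSSM from a probability matrix
#'
#' @param probabilities numeric matrix, one row per sequence position and 20
#'   columns.  Columns must be named with the one-letter amino-acid codes
#'   (any order; they are rearranged alphabetically).  Each row must be
#'   non-negative and sum to 1 within `1e-9`.
#' @param residues optional character vector of the query residues.
#' @return object of class `pssm`: list with `probabilities` (positions x
#'   20, alphabetical columns) and `residues`.
#' @export
pssm <- function(probabilities, residues = NULL) {
  probabilities <- as.matrix(probabilities)
  if (ncol(probabilities) != 20L) {
    stopf("PSSM needs 20 amino-acid columns, got %d", ncol(probabilities))
  }
  if (is.null(colnames(probabilities))) {
    colnames(probabilities) <- AA_ALPHABET
  }
  if (!setequal(colnames(probabilities), AA_ALPHABET)) {
    stopf("PSSM column names must be the 20 standard amino acids")
  }
  probabilities <- probabilities[, AA_ALPHABET, drop = FALSE]
  if (any(!is.finite(probabilities)) || any(probabilities < 0)) {
    stopf("PSSM probabilities must be finite and non-negative")
  }
  sums <- rowSums(probabilities)
  off <- which(abs(sums - 1) > 1e-9)
  if (length(off)) {
    stopf("PSSM row %d does not sum to 1 (sum = %.12g)", off[1L], sums[off[1L]])
  }
  rownames(probabilities) <- NULL
  structure(list(probabilities = probabilities, residues = residues),
            class = "pssm")
}

#' @export
print.pssm <- function(x, ...) {
  cat(sprintf("<pssm> %d positions x 20 amino acids\n", nrow(x$probabilities)))
  invisible(x)
}

#' @export
dim.pssm <- function(x) dim(x$probabilities)

#' Read a PSI-BLAST ASCII PSSM
#'
#' Parses the standard `blastpgp -Q` ASCII matrix.  Each data row carries the
#' position, the query residue, 20 log-odds integers, 20 weighted observed
#' percentages, the per-position information content and the relative
#' pseudocount weight.  Probabilities are the percentages divided by 100 and
#' renormalized to sum exactly 1; an all-zero percentage row (positions with
#' no observed alignment weight) becomes the uniform distribution, the
#' maximum-entropy and hence least-conserved fallback.
#'
#' @param path path to the ASCII PSSM file (or a character vector of its
#'   lines via `text`).
#' @param text optional character vector of lines, used instead of `path`.
#' @return a [pssm] object.
#' @export
read_pssm <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else {
    if (is.null(path) || !file.exists(path)) stopf("PSSM file not found: %s", path)
    readLines(path, warn = FALSE)
  }
  if (!length(lines)) stopf("empty PSSM input")
  # data rows: "<pos> <res> <40 integers> <info> <weight>"
  is_row <- grepl("^\\s*[0-9]+\\s+[A-ZX]\\b", lines)
  if (!any(is_row)) stopf("no PSSM data rows found (malformed header?)")
  rows <- lines[is_row]
  nums <- vector("list", length(rows))
  resv <- character(length(rows))
  posv <- integer(length(rows))
  for (k in seq_along(rows)) {
    fields <- strsplit(trimws(rows[[k]]), "\\s+")[[1L]]
    if (length(fields) < 42L) {
      stopf("PSSM line %d: expected 20 log-odds + 20 percentage columns, got %d fields: '%s'",
            which(is_row)[k], length(fields), rows[[k]])
    }
    posv[k] <- as.integer(fields[1L])
    resv[k] <- fields[2L]
    pct <- suppressWarnings(as.numeric(fields[23:42]))
    if (anyNA(pct)) {
      stopf("PSSM line %d: non-numeric percentage field: '%s'",
            which(is_row)[k], rows[[k]])
    }
    nums[[k]] <- pct
  }
  if (any(diff(posv) != 1L)) {
    stopf("PSSM positions are not consecutive at line %d",
          which(is_row)[which(diff(posv) != 1L)[1L] + 1L])
  }
  pct <- do.call(rbind, nums)
  colnames(pct) <- BLAST_AA_ORDER
  prob <- pct / 100
  zero <- rowSums(prob) == 0
  prob[zero, ] <- 1 / 20
  prob <- prob / rowSums(prob)
  pssm(prob, residues = resv)
}

#' Write a PSSM in blastpgp ASCII layout
#'
#' Serializes a [pssm] in the blastpgp ASCII layout so package-generated
#' matrices round-trip through [read_pssm].  The log-odds block is filled
#' with per-position log2 odds against the uniform background, rounded to
#' integers; only the percentage block is read back.
#'
#' @param x a [pssm] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_pssm <- function(x, path) {
  stopifnot(inherits(x, "pssm"))
  p <- x$probabilities[, BLAST_AA_ORDER, drop = FALSE]
  res <- x$residues
  if (is.null(res)) res <- rep("X", nrow(p))
  header1 <- "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"
  header2 <- paste0("           ",
                    paste(sprintf("%3s", BLAST_AA_ORDER), collapse = " "), "  ",
                    paste(sprintf("%3s", BLAST_AA_ORDER), collapse = " "))
  body <- vapply(seq_len(nrow(p)), function(i) {
    odds <- round(2 * log2(pmax(p[i, ], 1e-4) / 0.05))
    pct <- round(p[i, ] * 100)
    info <- -sum(ifelse(p[i, ] > 0, p[i, ] * log2(p[i, ]), 0))
    paste0(sprintf("%5d %s ", i, res[i]),
           paste(sprintf("%3d", odds), collapse = " "), "  ",
           paste(sprintf("%3d", pct), collapse = " "),
           sprintf(" %5.2f %9.2f", log2(20) - info, 1))
  }, character(1))
  writeLines(c(header1, "", header2, body, "", "                      K         Lambda"),
             path)
  invisible(path)
}
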