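# Internal helpers shared across the package.

# Canonical one-letter amino-acid alphabet, alphabetical order.  This fixed
# ordering defines the layout of every one-hot cassette block and of PSSM
# probability rows, so model weights are comparable across runs.
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# Nucleophilic +1 residues that can support protein splicing.
CST <- c("C", "S", "T")

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the random-number generator seeded to `seed`, then
#' restores the caller's RNG state, so seeded package operations never
#' perturb the global random stream.
#'
#' @param seed integer seed, or `NULL` to use the current RNG state.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite number or NULL", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Single uppercase residue string -> character vector of residues.
split_residues <- function(sequence) {
  strsplit(toupper(sequence), "", fixed = TRUE)[[1L]]
}

# Residues outside the 20-letter alphabet are recorded as X.
normalize_residues <- function(res) {
  res <- toupper(res)
  res[!(res %in% AA_ALPHABET)] <- "X"
  res
}

# n distinct draws from lo:hi with pairwise separation >= min_sep; used by
# the synthetic generators so residues written next to one planted site
# (e.g. cassette motif letters at -1/+2) can never overwrite another site
sample_spaced <- function(lo, hi, n, min_sep = 2L) {
  for (try in 1:500) {
    s <- sort(sample(lo:hi, n))
    if (n == 1L || min(diff(s)) >= min_sep) return(s)
  }
  stopf("could not place %d sites with separation >= %d in %d..%d",
        n, min_sep, lo, hi)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
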