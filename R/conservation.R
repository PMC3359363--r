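#' Positional sequence entropy
#'
#' The conservation of a sequence position is measured by the Shannon
#' entropy of its PSSM probability row,
#' \deqn{S_i = -\sum_j p_{ij} \ln p_{ij},}
#' with the convention \eqn{0 \ln 0 = 0}.  Natural logarithms are used; the
#' base only rescales entropies and cannot change any conservation rank.
#' Low entropy means a conserved position.
#'
#' @param pssm a [pssm] object.
#' @param i 1-based sequence position (vectorized).
#' @return numeric entropy in nats, in `[0, ln 20]`.
#' @examples
#' p <- pssm(matrix(1/20, 1, 20, dimnames = list(NULL, c(
#'   "A","C","D","E","F","G","H","I","K","L",
#'   "M","N","P","Q","R","S","T","V","W","Y"))))
#' site_entropy(p, 1)  # log(20)
#' @export
site_entropy <- function(pssm, i) {
  stopifnot(inherits(pssm, "pssm"))
  i <- as.integer(i)
  if (any(is.na(i)) || any(i < 1L) || any(i > nrow(pssm$probabilities))) {
    stopf("position out of range 1..%d", nrow(pssm$probabilities))
  }
  vapply(i, function(k) {
    p <- pssm$probabilities[k, ]
    if (abs(sum(p) - 1) > 1e-9) stopf("PSSM row %d is not normalized", k)
    p <- p[p > 0]
    -sum(p * log(p))
  }, numeric(1))
}

#' Entropy profile of a whole PSSM
#'
#' @param pssm a [pssm] object.
#' @return object of class `entropy_profile`: data frame with columns
#'   `position` and `entropy` (nats).
#' @export
entropy_profile <- function(pssm) {
  stopifnot(inherits(pssm, "pssm"))
  n <- nrow(pssm$probabilities)
  out <- data.frame(position = seq_len(n),
                    entropy = site_entropy(pssm, seq_len(n)))
  class(out) <- c("entropy_profile", "data.frame")
  out
}

#' Conservation rank of a candidate site
#'
#' Ranks a target C/S/T site against all candidate C/S/T sites of the same
#' extein by entropy: 1 is the most conserved candidate (lowest entropy),
#' 0 the least conserved (highest entropy).  With \eqn{n} candidates, the
#' rank is the number of candidates with strictly higher entropy than the
#' target, counting ties as 1/2, divided by \eqn{n - 1}.
#'
#' @param entropies an [entropy_profile] (or data frame with `position` and
#'   `entropy`).
#' @param candidates candidate site table from
#'   [enumerate_candidate_sites()], or an integer vector of candidate
#'   positions.
#' @param target position of the site to rank; must be a candidate.
#' @return rank in `[0, 1]`.
#' @export
conservation_rank <- function(entropies, candidates, target) {
  if (is.data.frame(candidates)) candidates <- candidates$position
  candidates <- as.integer(candidates)
  if (length(candidates) < 2L) {
    stopf("conservation rank is undefined with fewer than 2 candidate sites")
  }
  target <- as.integer(target)
  if (length(target) != 1L || !(target %in% candidates)) {
    stopf("target position %d is not a candidate site", target)
  }
  s <- entropies$entropy[match(candidates, entropies$position)]
  if (anyNA(s)) stopf("missing entropy for a candidate position")
  st <- s[match(target, candidates)]
  others <- s[candidates != target]
  (sum(others > st) + 0.5 * sum(others == st)) / (length(candidates) - 1L)
}

#' Per-site conservation table
#'
#' Computes entropy and conservation rank for every candidate site of an
#' extein; the TSV-ready companion of [conservation_rank()].
#'
#' @param pssm a [pssm] for the extein sequence.
#' @param candidates candidate table from [enumerate_candidate_sites()].
#' @return data frame with columns `position`, `entropy`, `rank`.
#' @export
conservation_table <- function(pssm, candidates) {
  prof <- entropy_profile(pssm)
  pos <- if (is.data.frame(candidates)) candidates$position else as.integer(candidates)
  data.frame(
    position = pos,
    entropy = prof$entropy[match(pos, prof$position)],
    rank = vapply(pos, function(p) conservation_rank(prof, pos, p), numeric(1))
  )
}
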