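#' One-hot encoding of insertion-site cassettes
#'
#' A cassette is encoded as the concatenation of six 20-component one-hot
#' blocks, one per variable position in the fixed order -3, -2, -1, +2, +3,
#' +4; within each block amino acids follow the alphabetical one-letter
#' order A, C, D, ..., Y.  The +1 residue is not encoded: every candidate is
#' C, S or T by construction, so it carries no discriminating signal.  An
#' unknown residue (`X`) leaves its block all-zero, keeping the vector
#' 120-dimensional.
#'
#' @param cassette a [as_cassette()] object (or 7-letter string).
#' @return named numeric vector of length 120 (names like `"-3:A"`).
#' @examples
#' which(encode_cassette("AAASAAA") == 1)
#' @export
encode_cassette <- function(cassette) {
  cassette <- as_cassette(cassette)
  res <- c(cassette$residues_minus, cassette$residues_plus)
  v <- numeric(120L)
  block_names <- c("-3", "-2", "-1", "+2", "+3", "+4")
  names(v) <- paste0(rep(block_names, each = 20L), ":", rep(AA_ALPHABET, 6L))
  for (b in seq_len(6L)) {
    j <- match(res[b], AA_ALPHABET)
    if (!is.na(j)) v[(b - 1L) * 20L + j] <- 1
  }
  v
}

encode_cassettes <- function(cassettes) {
  if (inherits(cassettes, "cassette")) {
    cassettes <- list(cassettes)
  } else if (is.character(cassettes)) {
    cassettes <- as.list(cassettes)
  }
  X <- t(vapply(cassettes, encode_cassette, numeric(120L)))
  colnames(X) <- names(encode_cassette("AAASAAA"))
  X
}

# Cassette identity on the six encoded positions (+1 excluded).
cassette_key <- function(cassette) {
  cassette <- as_cassette(cassette)
  paste(c(cassette$residues_minus, cassette$residues_plus), collapse = "")
}

#' Sample decoy cassettes from an extein
#'
#' Draws `n` distinct non-native candidate C/S/T sites uniformly without
#' replacement and returns their cassettes; these serve as presumed-negative
#' training examples for the cassette SVM.
#'
#' @param extein an [extein_record].
#' @param n number of decoys (default 3, the native-set protocol).
#' @param seed optional seed for a deterministic draw.
#' @return list of `cassette` objects; positions in attribute `"positions"`.
#'   If fewer than `n` non-native candidates exist, all of them are
#'   returned with a warning.
#' @export
sample_decoys <- function(extein, n = 3L, seed = NULL) {
  cand <- enumerate_candidate_sites(extein)
  pool <- cand$position[!cand$is_native]
  if (length(pool) < n) {
    warnf("extein '%s': only %d non-native candidate site(s) available (%d requested)",
          extein$id, length(pool), n)
    chosen <- pool
  } else {
    chosen <- with_seed(seed, pool[sample.int(length(pool), n)])
  }
  out <- lapply(chosen, function(p) extract_cassette(extein, p))
  attr(out, "positions") <- chosen
  out
}

#' Fit a class-weighted linear SVM on encoded cassettes
#'
#' Trains a linear support vector machine separating native insertion-site
#' cassettes (target +1) from decoy cassettes (target -1), with errors on
#' the positive class weighted `cost_factor` times errors on the negative
#' class -- compensating the 1:3 positive:decoy class imbalance of the
#' training protocol.  The decision function is \eqn{w \cdot v + b};
#' positive scores are native-like.
#'
#' @param positives list of cassettes (or encoded matrix) labelled native.
#' @param negatives list of cassettes (or encoded matrix) labelled decoy.
#' @param cost_factor positive-class error weight relative to the negative
#'   class (default 3).
#' @param C soft-margin regularization constant.  The default `1/6` is the
#'   SVMlight-style data-dependent default `1 / mean(||v||^2)`: a complete
#'   cassette vector has exactly six ones.
#' @return object of class `cassette_svm` with elements `weights` (120),
#'   `bias`, and `training_meta`.
#' @seealso [predict.cassette_svm()], [loocv_rank()]
#' @export
fit_cassette_svm <- function(positives, negatives, cost_factor = 3, C = 1 / 6) {
  X_pos <- if (is.matrix(positives)) positives else encode_cassettes(positives)
  X_neg <- if (is.matrix(negatives)) negatives else encode_cassettes(negatives)
  if (nrow(X_pos) < 1L || nrow(X_neg) < 1L) {
    stopf("training needs at least one example of each class")
  }
  if (ncol(X_pos) != 120L || ncol(X_neg) != 120L) {
    stopf("encoded cassettes must be 120-dimensional")
  }
  X <- rbind(X_pos, X_neg)
  y <- factor(rep(c("pos", "neg"), c(nrow(X_pos), nrow(X_neg))),
              levels = c("pos", "neg"))
  fit <- e1071::svm(X, y, kernel = "linear", scale = FALSE, cost = C,
                    class.weights = c(pos = cost_factor, neg = 1))
  # linear kernel: w = sum_i alpha_i y_i SV_i; decision value is w.v - rho
  # with positive values for the first factor level ("pos")
  weights <- as.numeric(drop(t(fit$coefs) %*% fit$SV))
  names(weights) <- colnames(X)
  bias <- -fit$rho
  structure(
    list(weights = weights, bias = bias,
         training_meta = list(cost_factor = cost_factor, C = C,
                              n_pos = nrow(X_pos), n_neg = nrow(X_neg))),
    class = "cassette_svm"
  )
}

#' @export
print.cassette_svm <- function(x, ...) {
  m <- x$training_meta
  cat(sprintf("<cassette_svm> linear, cost-factor %g, C = %.4g (%d pos / %d neg)\n",
              m$cost_factor, m$C, m$n_pos, m$n_neg))
  cat(sprintf("  bias %.4f; largest |weight| %.4f\n", x$bias, max(abs(x$weights))))
  invisible(x)
}

#' @export
coef.cassette_svm <- function(object, ...) {
  c(object$weights, bias = object$bias)
}

#' Score cassettes with a fitted cassette SVM
#'
#' @param object a `cassette_svm` model.
#' @param newdata a cassette, list of cassettes, 7-letter string(s), or an
#'   encoded matrix.
#' @param ... unused.
#' @return numeric scores \eqn{w \cdot v + b}; positive = native-like.
#' @export
predict.cassette_svm <- function(object, newdata, ...) {
  X <- if (is.matrix(newdata)) newdata else encode_cassettes(newdata)
  if (ncol(X) != 120L) stopf("encoded cassettes must be 120-dimensional")
  drop(X %*% object$weights) + object$bias
}

#' Remove redundant native cassettes from an extein set
#'
#' Two exteins whose native insertion-site cassettes are identical on the
#' six encoded positions (-3..-1, +2..+4) carry the same training signal;
#' only the extein with the longer sequence is kept (ties broken by id for
#' determinism).
#'
#' @param exteins list of [extein_record] objects with native sites.
#' @return the deduplicated list, in the original relative order.
#' @export
dedupe_cassettes <- function(exteins) {
  if (!length(exteins)) return(exteins)
  keys <- lapply(exteins, function(ex) {
    vapply(ex$native_sites, function(p) cassette_key(extract_cassette(ex, p)),
           character(1))
  })
  len <- vapply(exteins, function(ex) length(ex$residues), integer(1))
  ids <- vapply(exteins, function(ex) ex$id, character(1))
  pref <- order(-len, ids)           # longest first, id breaks ties
  seen <- character()
  keep <- logical(length(exteins))
  for (k in pref) {
    if (!any(keys[[k]] %in% seen)) {
      keep[k] <- TRUE
      seen <- c(seen, keys[[k]])
    }
  }
  exteins[keep]
}

#' Leave-one-extein-out rank of a native insertion site
#'
#' For a target extein, trains the cassette SVM on the native cassettes of
#' all other exteins plus three freshly sampled decoy cassettes per training
#' extein, scores every candidate C/S/T site of the target, and records the
#' rank of the native site: the fraction of decoy (non-native) candidate
#' cassettes scoring strictly lower, ties counted 1/2.  The decoy draw is
#' re-sampled each repeat -- the random element of the protocol -- and the
#' mean rank over `repeats` is returned.
#'
#' @param exteins list of [extein_record] objects, each with at least one
#'   native site (apply [dedupe_cassettes()] first to mirror the native-set
#'   protocol).
#' @param target_id id of the held-out extein.
#' @param repeats number of training-set resamplings (default 25).
#' @param seed optional integer for deterministic decoy sampling.
#' @param n_decoys decoys drawn per training extein and repeat (default 3).
#' @param cost_factor,C passed to [fit_cassette_svm()].
#' @return mean rank in `[0, 1]`; per-repeat ranks in attribute
#'   `"per_repeat"`.
#' @export
loocv_rank <- function(exteins, target_id, repeats = 25L, seed = NULL,
                       n_decoys = 3L, cost_factor = 3, C = 1 / 6) {
  ids <- vapply(exteins, function(ex) ex$id, character(1))
  ti <- match(target_id, ids)
  if (is.na(ti)) stopf("target extein '%s' is not in the dataset", target_id)
  if (length(exteins) < 2L) stopf("leave-one-out needs at least 2 exteins")
  target <- exteins[[ti]]
  if (!length(target$native_sites)) stopf("target extein '%s' has no native site", target_id)
  cand <- enumerate_candidate_sites(target)
  if (nrow(cand) < 2L) {
    stopf("target extein '%s' has a single candidate site; rank undefined", target_id)
  }
  decoy_pos <- cand$position[!cand$is_native]
  if (!length(decoy_pos)) {
    stopf("target extein '%s' has no decoy candidate sites; rank undefined", target_id)
  }
  training <- exteins[-ti]
  pos_train <- do.call(rbind, lapply(training, function(ex) {
    encode_cassettes(lapply(ex$native_sites, function(p) extract_cassette(ex, p)))
  }))
  target_X <- encode_cassettes(lapply(cand$position, function(p) extract_cassette(target, p)))
  native_rows <- which(cand$is_native)
  decoy_rows <- which(!cand$is_native)

  per_repeat <- with_seed(seed, {
    vapply(seq_len(repeats), function(r) {
      neg_train <- do.call(rbind, lapply(training, function(ex) {
        encode_cassettes(sample_decoys(ex, n = n_decoys))
      }))
      model <- fit_cassette_svm(pos_train, neg_train,
                                cost_factor = cost_factor, C = C)
      sc <- predict(model, target_X)
      mean(vapply(native_rows, function(i) {
        (sum(sc[decoy_rows] < sc[i]) + 0.5 * sum(sc[decoy_rows] == sc[i])) /
          length(decoy_rows)
      }, numeric(1)))
    }, numeric(1))
  })
  structure(mean(per_repeat), per_repeat = per_repeat)
}

#' Read and write cassette tables
#'
#' Plain TSV with columns `extein_id`, `position`, `cassette` (7 letters)
#' and `label` (1 = native insertion site, 0 = decoy); the interchange
#' format for insertion-site cassette collections.
#'
#' @param path file path.
#' @return `read_cassette_table`: data frame with those four columns.
#' @export
read_cassette_table <- function(path) {
  if (!file.exists(path)) stopf("cassette table not found: %s", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("extein_id", "position", "cassette", "label")
  if (!all(need %in% names(df))) {
    stopf("cassette table needs columns: %s", paste(need, collapse = ", "))
  }
  bad <- which(nchar(df$cassette) != 7L)
  if (length(bad)) stopf("row %d: cassette '%s' is not 7 residues", bad[1L], df$cassette[bad[1L]])
  df$position <- as.integer(df$position)
  df$label <- as.integer(df$label)
  df[, need]
}

#' @param table data frame as returned by [read_cassette_table()].
#' @rdname read_cassette_table
#' @export
write_cassette_table <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Persist a cassette SVM as plain text
#'
#' @param model a `cassette_svm`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_svm_model <- function(model, path) {
  stopifnot(inherits(model, "cassette_svm"))
  m <- model$training_meta
  lines <- c(
    sprintf("# cassette_svm cost_factor=%.17g C=%.17g n_pos=%d n_neg=%d",
            m$cost_factor, m$C, m$n_pos, m$n_neg),
    sprintf("bias\t%.17g", model$bias),
    sprintf("%s\t%.17g", names(model$weights), model$weights)
  )
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_svm_model
#' @export
read_svm_model <- function(path) {
  if (!file.exists(path)) stopf("model file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  header <- lines[grepl("^# cassette_svm", lines)]
  if (!length(header)) stopf("not a cassette_svm model file: %s", path)
  get_meta <- function(key) as.numeric(sub(sprintf(".*%s=([-0-9.eE+]+).*", key), "\\1", header))
  rows <- strsplit(lines[!grepl("^#", lines) & nzchar(lines)], "\t")
  keys <- vapply(rows, `[`, character(1), 1L)
  vals <- as.numeric(vapply(rows, `[`, character(1), 2L))
  bias <- vals[keys == "bias"]
  w <- vals[keys != "bias"]
  names(w) <- keys[keys != "bias"]
  if (length(w) != 120L) stopf("model file has %d weights, expected 120", length(w))
  structure(list(weights = w, bias = bias,
                 training_meta = list(cost_factor = get_meta("cost_factor"),
                                      C = get_meta("C"),
                                      n_pos = as.integer(get_meta("n_pos")),
                                      n_neg = as.integer(get_meta("n_neg")))),
            class = "cassette_svm")
}
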