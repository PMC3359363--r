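test_that("one-hot encoding follows the declared block and residue order", {
  v <- encode_cassette("AAASAAA")
  # A is first in every block; blocks start at 1, 21, 41, 61, 81, 101
  expect_equal(which(v == 1), c(1L, 21L, 41L, 61L, 81L, 101L),
               ignore_attr = TRUE)
  expect_equal(sum(v), 6)
  # the +1 residue is not encoded: S vs T centre gives identical vectors
  expect_identical(encode_cassette("AKLSWYD"), encode_cassette("AKLTWYD"))
  # X leaves its block all-zero
  vx <- encode_cassette("AXASAAA")
  expect_equal(sum(vx), 5)
  expect_equal(sum(vx[21:40]), 0)
})

test_that("encoding is injective on the six encoded positions", {
  set.seed(55)
  seen <- character(0)
  for (i in 1:200) {
    cas <- paste0(random_sequence(3), sample(c("C", "S", "T"), 1),
                  random_sequence(3))
    key <- paste(encode_cassette(cas), collapse = "")
    flank <- paste0(substr(cas, 1, 3), substr(cas, 5, 7))
    if (flank %in% names(seen)) {
      expect_identical(key, unname(seen[flank]))
    } else {
      expect_false(key %in% seen)
    }
    seen[flank] <- key
  }
})

test_that("decoy sampling is uniform, deterministic and exhaustive when forced", {
  # exactly 3 non-native candidates -> all of them, any seed
  s <- "AAACAAASAAATAAASAAAA"  # C4, S8, T12, S16 (all with full windows)
  ex <- extein_record("e", s, native_sites = 4)
  d1 <- sample_decoys(ex, 3, seed = 1)
  d2 <- sample_decoys(ex, 3, seed = 999)
  expect_setequal(attr(d1, "positions"), c(8L, 12L, 16L))
  expect_setequal(attr(d2, "positions"), c(8L, 12L, 16L))
  # deterministic under a fixed seed
  big <- extein_record("b", strrep("AAS", 20))
  expect_identical(attr(sample_decoys(big, 3, seed = 7), "positions"),
                   attr(sample_decoys(big, 3, seed = 7), "positions"))
  # fewer available than requested -> all, with warning
  expect_warning(d3 <- sample_decoys(ex, 5, seed = 1), "only 3")
  expect_length(d3, 3L)
})

test_that("decoy selection frequencies match the uniform binomial expectation", {
  # 10 non-native candidate sites, draws of 3: each site should be chosen
  # in ~3/10 of draws (binomial 3-sigma check)
  s <- paste0("AAA", strrep("SAA", 10), "AAA")
  ex <- extein_record("u", s)
  pool <- enumerate_candidate_sites(ex)$position
  expect_length(pool, 10L)
  n_draws <- 10000L
  counts <- integer(length(pool)); names(counts) <- pool
  set.seed(12)
  for (i in seq_len(n_draws)) {
    p <- attr(sample_decoys(ex, 3), "positions")
    counts[as.character(p)] <- counts[as.character(p)] + 1L
  }
  expected <- n_draws * 3 / 10
  tol <- 3 * sqrt(n_draws * 0.3 * 0.7)
  expect_true(all(abs(counts - expected) <= tol))
})

test_that("a separable training set is classified perfectly", {
  # positives always carry A at -1; negatives never do
  positives <- c("KLASWYD", "MNASKLP", "QRASTVM")
  negatives <- c("KLGSWYD", "MNPSKLP", "QRWSTVM")
  model <- fit_cassette_svm(positives, negatives, C = 10)
  expect_true(all(predict(model, positives) > 0))
  expect_true(all(predict(model, negatives) < 0))
})

test_that("duplicating the training set leaves the decision boundary unchanged", {
  set.seed(66)
  positives <- replicate(5, paste0(random_sequence(2), "A",
                                   sample(c("C", "S", "T"), 1), random_sequence(3)))
  negatives <- replicate(15, paste0(random_sequence(2), "G",
                                    sample(c("C", "S", "T"), 1), random_sequence(3)))
  m1 <- fit_cassette_svm(positives, negatives)
  m2 <- fit_cassette_svm(c(positives, positives), c(negatives, negatives))
  probe <- replicate(20, paste0(random_sequence(3), "S", random_sequence(3)))
  expect_equal(predict(m1, probe), predict(m2, probe), tolerance = 1e-3)
})

test_that("training is invariant to example order and single-class input fails", {
  set.seed(67)
  positives <- replicate(6, paste0(random_sequence(3), "S", random_sequence(3)))
  negatives <- replicate(18, paste0(random_sequence(3), "T", random_sequence(3)))
  m1 <- fit_cassette_svm(positives, negatives)
  m2 <- fit_cassette_svm(rev(positives), rev(negatives))
  expect_equal(m1$weights, m2$weights, tolerance = 1e-3)
  expect_equal(m1$bias, m2$bias, tolerance = 1e-3)
  expect_error(fit_cassette_svm(positives, character(0)), "each class")
})

test_that("the margin matches the analytic max-margin solution in 2 active dims", {
  # all blocks identical except -1: positives have A (component 41),
  # negatives have C (component 42).  In that 2-dim subspace the points are
  # (1,0) and (0,1); the max-margin separator is w = (1,-1), b = 0 with
  # margin 2/||w|| = sqrt(2).  Shared components can be absorbed by the
  # bias, so at large C the fitted weights must reproduce this geometry.
  positives <- "AAASAAA"
  negatives <- "AACSAAA"
  model <- fit_cassette_svm(positives, negatives, C = 100)
  w <- model$weights
  expect_equal(unname(w[41]), 1, tolerance = 1e-4)
  expect_equal(unname(w[42]), -1, tolerance = 1e-4)
  expect_equal(unname(predict(model, positives)), 1, tolerance = 1e-4)
  expect_equal(unname(predict(model, negatives)), -1, tolerance = 1e-4)
  margin <- 2 / sqrt(sum(w^2))
  expect_equal(margin, sqrt(2), tolerance = 1e-3)
})

test_that("scores are linear in the encoded vector", {
  set.seed(68)
  positives <- replicate(4, paste0(random_sequence(3), "S", random_sequence(3)))
  negatives <- replicate(12, paste0(random_sequence(3), "S", random_sequence(3)))
  model <- fit_cassette_svm(positives, negatives)
  cas <- "MKVSWYD"
  v <- encode_cassette(cas)
  expect_equal(unname(predict(model, cas)),
               sum(model$weights[v == 1]) + model$bias, tolerance = 1e-12)
})

test_that("models persist to plain text and back", {
  set.seed(69)
  positives <- replicate(4, paste0(random_sequence(3), "S", random_sequence(3)))
  negatives <- replicate(8, paste0(random_sequence(3), "S", random_sequence(3)))
  model <- fit_cassette_svm(positives, negatives)
  tf <- tempfile()
  write_svm_model(model, tf)
  back <- read_svm_model(tf)
  expect_equal(back$weights, model$weights)
  expect_equal(back$bias, model$bias)
  expect_equal(back$training_meta$cost_factor, 3)
})

test_that("cassette deduplication keeps the longer extein on identity", {
  # identical native cassettes (KLM S WYD) in exteins of length 300 and 200
  core <- "KLMSWYD"
  mk <- function(id, n) {
    pad_l <- strrep("A", 10)
    pad_r <- strrep("A", n - 17)
    extein_record(id, paste0(pad_l, core, pad_r), native_sites = 14)
  }
  long <- mk("long", 300); short <- mk("short", 200)
  kept <- dedupe_cassettes(list(short, long))
  expect_equal(vapply(kept, function(e) e$id, character(1)), "long")
  # all-distinct input unchanged
  set.seed(71)
  distinct <- lapply(1:5, function(k) {
    s <- paste0(random_sequence(5), "S", random_sequence(6))
    extein_record(paste0("d", k), s, native_sites = 6)
  })
  expect_length(dedupe_cassettes(distinct), 5L)
})

test_that("deduplication retains the same count as a pairwise oracle", {
  set.seed(72)
  # small cassette alphabet forces collisions
  pool <- replicate(40, {
    paste0(paste(sample(c("A", "G"), 3, TRUE), collapse = ""), "S",
           paste(sample(c("A", "G"), 3, TRUE), collapse = ""))
  })
  exs <- lapply(seq_along(pool), function(k) {
    n_extra <- sample(5:50, 1)
    extein_record(sprintf("x%02d", k),
                  paste0("AAA", pool[k], strrep("A", n_extra)),
                  native_sites = 7)
  })
  kept <- dedupe_cassettes(exs)
  # O(n^2) oracle on the 6 encoded residues
  flank <- paste0(substr(pool, 1, 3), substr(pool, 5, 7))
  expect_length(kept, length(unique(flank)))
  # every retained cassette key is unique
  keys <- vapply(kept, function(e) {
    cas <- extract_cassette(e, e$native_sites[1])
    paste(c(cas$residues_minus, cas$residues_plus), collapse = "")
  }, character(1))
  expect_false(any(duplicated(keys)))
})

test_that("leave-one-extein-out ranks a perfectly separable native site first", {
  # every native cassette shares the GG?PPP flank pattern; decoy windows are
  # drawn from residues that exclude G and P, so the classes are separable.
  # One flank residue varies per extein so deduplication would keep all five.
  set.seed(73)
  bg <- c("A", "D", "E", "F", "H", "I", "K", "L", "M", "N", "Q", "R", "V", "W", "Y")
  mk <- function(id, k) {
    res <- sample(bg, 60, replace = TRUE)
    res[c(10, 20, 30, 40)] <- "S"
    res[c(7:9, 11:13)] <- c("G", "G", bg[k], "P", "P", "P")
    extein_record(id, paste(res, collapse = ""), native_sites = 10)
  }
  exs <- lapply(1:5, function(k) mk(sprintf("p%d", k), k))
  expect_length(dedupe_cassettes(exs), 5L)
  r <- loocv_rank(exs, "p1", repeats = 3, seed = 5)
  expect_equal(as.numeric(r), 1.0)
  expect_length(attr(r, "per_repeat"), 3L)
})

test_that("leave-one-extein-out is deterministic under seed and validates input", {
  set.seed(74)
  exs <- generate_extein_set(4, length = 80, n_decoys = 5, seed = 99)
  r1 <- loocv_rank(exs, exs[[2]]$id, repeats = 2, seed = 11)
  r2 <- loocv_rank(exs, exs[[2]]$id, repeats = 2, seed = 11)
  expect_identical(r1, r2)
  expect_error(loocv_rank(exs, "absent"), "not in the dataset")
  # single-candidate target has an undefined rank
  one <- extein_record("one", "AAASAAA", native_sites = 4)
  expect_error(loocv_rank(c(exs, list(one)), "one"), "single candidate|no decoy")
})

test_that("cassette tables round-trip through TSV", {
  tab <- data.frame(extein_id = c("a", "b"), position = c(10L, 20L),
                    cassette = c("KLMSWYD", "AAATAAA"), label = c(1L, 0L),
                    stringsAsFactors = FALSE)
  tf <- tempfile(fileext = ".tsv")
  write_cassette_table(tab, tf)
  expect_identical(read_cassette_table(tf), tab)
  bad <- tab; bad$cassette[1] <- "KLMSWY"
  write_cassette_table(bad, tf)
  expect_error(read_cassette_table(tf), "not 7 residues")
})
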