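test_that("secondary-structure codes collapse to the four groups", {
  expect_equal(unname(group_ss_codes(c("H", "H", "H", "E", "E", "E", "T", "S", "C"))),
               c(rep("helix", 3), rep("sheet", 3), rep("loop", 3)))
  # 3-10/pi helices and bridges are "other"
  expect_equal(unname(group_ss_codes(c("G", "I", "B"))), rep("other", 3))
  expect_equal(unname(group_ss_codes(c("b", NA, "Z"))), rep("other", 3))
  # grouping is idempotent
  g <- group_ss_codes(c("H", "E", "C", "G"))
  expect_equal(group_ss_codes(g), g)
})

test_that("junction classification follows the nearest-complementary-group rule", {
  g <- group_ss_codes(c("C", "C", "C", "H", "H", "H", "H", "H"))
  ctx <- classify_site_ss(g, 5)
  expect_equal(ctx$bin, "AH/L-junction")
  expect_equal(ctx$junction_distance, 2)  # nearest loop residue is position 3
  ctx4 <- classify_site_ss(g, 4)
  expect_equal(ctx4$junction_distance, 1)
  # deep in a sheet: no boundary within 2
  g2 <- group_ss_codes(rep("E", 7))
  ctx2 <- classify_site_ss(g2, 4)
  expect_equal(ctx2$bin, "mid-BS")
  expect_gt(ctx2$junction_distance, 2)
  # loop residue near both junction types: tie goes to the sheet junction
  g3 <- group_ss_codes(c("E", "C", "H"))
  expect_equal(classify_site_ss(g3, 2)$bin, "BS/L-junction")
  # unknown code -> "other" bin, undefined distance
  g4 <- group_ss_codes(c("H", NA, "H"))
  ctx4b <- classify_site_ss(g4, 2)
  expect_equal(ctx4b$bin, "other")
  expect_true(is.na(ctx4b$junction_distance))
})

test_that("junction bins and distances match the exhaustive scan oracle", {
  set.seed(81)
  for (i in 1:500) {
    codes <- sample(c("H", "E", "C", "T", "S", "G", "I", "B"), sample(5:40, 1),
                    replace = TRUE)
    g <- group_ss_codes(codes)
    for (pos in seq_along(g)) {
      got <- classify_site_ss(g, pos)
      want <- oracle_classify(g, pos)
      expect_identical(got$bin, want$bin)
      expect_equal(got$junction_distance, want$junction_distance)
    }
  }
})

test_that("C-beta density counts neighbours within the 8 A closed ball", {
  # isolated residue
  s1 <- structure_context(1:2, rbind(c(0, 0, 0), c(100, 0, 0)))
  expect_equal(cbeta_density(s1, 1), 0L)
  # three mutually close residues -> 2 each; boundary at exactly 8 A counts
  ca <- rbind(c(0, 0, 0), c(8, 0, 0), c(0, 8, 0))
  s2 <- structure_context(1:3, ca)
  expect_equal(cbeta_density(s2, 1), 2L)
  expect_equal(cbeta_density(s2, 2), 1L)  # (8,0)-(0,8) distance > 8
  expect_error(cbeta_density(s2, 9), "no coordinates")
})

test_that("C-beta density equals the pairwise-matrix oracle and is symmetric", {
  set.seed(82)
  n <- 200
  cb <- matrix(runif(n * 3, 0, 40), n)
  sc <- structure_context(seq_len(n), cb, cb)
  d <- as.matrix(dist(cb))
  oracle <- rowSums(d <= 8) - 1L
  got <- vapply(seq_len(n), function(p) cbeta_density(sc, p), integer(1))
  expect_equal(got, unname(oracle))
  # symmetry: a counts b iff b counts a
  within <- d <= 8
  expect_true(isSymmetric(within))
})

test_that("functional-site distance is an exhaustive minimum over annotations", {
  ca <- rbind(c(0, 0, 0), c(3, 4, 0), c(30, 0, 0))
  sc <- structure_context(1:3, ca, active_site = 2)
  expect_equal(distance_to_functional_site(sc, 1, "active"), 5)  # 3-4-5 triangle
  sc2 <- structure_context(1:3, ca, active_site = 1)
  expect_equal(distance_to_functional_site(sc2, 1, "active"), 0)
  # empty annotation set is missing, never 0
  sc3 <- structure_context(1:3, ca)
  expect_error(distance_to_functional_site(sc3, 1, "active"), "missing")
  # "either" merges the two sets by minimum
  sc4 <- structure_context(1:3, ca, active_site = 3, dimer_interface = 2)
  expect_equal(distance_to_functional_site(sc4, 1, "either"), 5)
  expect_equal(distance_to_functional_site(sc4, 1, "active"), 30)
})

test_that("functional-site distance matches the exhaustive oracle and is monotone", {
  set.seed(83)
  n <- 120
  ca <- matrix(runif(n * 3, 0, 50), n)
  ann <- sort(sample(n, 50))
  sc <- structure_context(seq_len(n), ca, active_site = ann)
  for (p in sample(n, 20)) {
    oracle <- min(sqrt(colSums((t(ca[ann, , drop = FALSE]) - ca[p, ])^2)))
    expect_equal(distance_to_functional_site(sc, p, "active"), oracle,
                 tolerance = 1e-12)
  }
  # adding annotations can only decrease the distance
  more <- sort(unique(c(ann, sample(n, 30))))
  sc_more <- structure_context(seq_len(n), ca, active_site = more)
  for (p in sample(n, 10)) {
    expect_lte(distance_to_functional_site(sc_more, p, "active"),
               distance_to_functional_site(sc, p, "active"))
  }
})

test_that("Kabsch superposition removes rigid-body motion exactly", {
  set.seed(84)
  ref <- matrix(rnorm(30, sd = 5), 10)
  # identity
  out <- kabsch_superpose(ref, ref)
  expect_equal(attr(out, "rmsd"), 0, tolerance = 1e-12)
  # 90-degree rotation about z plus translation is fully removable
  Rz <- matrix(c(0, 1, 0, -1, 0, 0, 0, 0, 1), 3)
  mobile <- ref %*% t(Rz) + matrix(c(10, -4, 2), 10, 3, byrow = TRUE)
  out2 <- kabsch_superpose(mobile, ref)
  expect_equal(attr(out2, "rmsd"), 0, tolerance = 1e-9)
  expect_equal(unname(out2), unname(ref), tolerance = 1e-9, ignore_attr = TRUE)
  expect_error(kabsch_superpose(ref[1:2, ], ref[1:2, ]), "at least 3")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line), "degenerate|collinear")
})

test_that("superposition never increases RMSD and matches the bio3d oracle", {
  set.seed(85)
  for (i in 1:20) {
    ref <- matrix(rnorm(45, sd = 6), 15)
    mobile <- ref + matrix(rnorm(45, sd = 0.7), 15)
    th <- runif(1, 0, 2 * pi)
    Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
    mobile <- mobile %*% t(Rz) + matrix(runif(3, -9, 9), 15, 3, byrow = TRUE)
    pre <- sqrt(mean(rowSums((mobile - ref)^2)))
    out <- kabsch_superpose(mobile, ref)
    expect_lte(attr(out, "rmsd"), pre + 1e-12)
    # independent oracle: bio3d's least-squares fit
    fitted <- suppressWarnings(bio3d::fit.xyz(fixed = as.vector(t(ref)),
                                              mobile = as.vector(t(mobile))))
    oracle <- matrix(fitted, ncol = 3, byrow = TRUE)
    expect_equal(unname(out), oracle, tolerance = 1e-9, ignore_attr = TRUE)
  }
})

test_that("site flexibility reproduces closed forms and the summation oracle", {
  # static trajectory -> 0 everywhere
  base <- matrix(rnorm(15), 5)
  static <- array(rep(base, each = 10), c(10, 5, 3))
  for (s in 1:10) static[s, , ] <- base
  sn <- snapshot_set(static)
  expect_equal(site_flexibility(sn, 3), 0)
  # one site displaced by exactly 1 A in every snapshot after the first
  S <- 50
  coords <- array(rep(base, each = S), c(S, 5, 3))
  for (s in 1:S) coords[s, , ] <- base
  coords[2:S, 2, 1] <- base[2, 1] + 1
  sn2 <- snapshot_set(coords)
  expect_equal(site_flexibility(sn2, 2), sqrt(49 / 50), tolerance = 1e-12)
  expect_equal(site_flexibility(sn2, 2, denominator = "S-1"), 1, tolerance = 1e-12)
  expect_equal(site_flexibility(sn2, 1), 0)
  # per-term summation oracle on a wiggling trace
  set.seed(86)
  wig <- array(rnorm(20 * 5 * 3), c(20, 5, 3))
  sn3 <- snapshot_set(wig)
  for (p in 1:5) {
    acc <- 0
    for (s in 1:20) acc <- acc + sum((wig[s, p, ] - wig[1, p, ])^2)
    expect_equal(site_flexibility(sn3, p), sqrt(acc / 20), tolerance = 1e-12)
  }
})

test_that("flexibility with superposition is invariant to rigid motion of all frames", {
  set.seed(87)
  base <- matrix(rnorm(36, sd = 5), 12)
  S <- 8
  coords <- array(NA_real_, c(S, 12, 3))
  for (s in 1:S) coords[s, , ] <- base + matrix(rnorm(36, sd = 0.4), 12)
  sn <- snapshot_set(coords)
  ref_flex <- vapply(1:12, function(p) site_flexibility(sn, p, superpose = TRUE),
                     numeric(1))
  # apply one arbitrary rigid motion to every frame uniformly
  th <- 1.1
  Rz <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3)
  moved <- coords
  for (s in 1:S) moved[s, , ] <- coords[s, , ] %*% t(Rz) +
    matrix(c(4, 5, -6), 12, 3, byrow = TRUE)
  sn2 <- snapshot_set(moved)
  got <- vapply(1:12, function(p) site_flexibility(sn2, p, superpose = TRUE),
                numeric(1))
  expect_equal(got, ref_flex, tolerance = 1e-9)
})
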