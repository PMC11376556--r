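test_that("shape term A covers the worked cases and the flat-curve convention", {
  x <- c(0, 1, 2)
  expect_equal(pearson_shape(x, x), 1)
  expect_equal(pearson_shape(x, -x), -1)
  expect_equal(pearson_shape(c(0, 1, 0), c(0, 0, 1)), -0.5)
  expect_equal(pearson_shape(c(0, 0, 0), x), 0)  # zero-variance convention
  expect_equal(pearson_shape(x, c(5, 5, 5)), 0)
  expect_error(pearson_shape(c(0, 1), c(0, 1, 2)), "different grids")
  expect_error(pearson_shape(c(0, 1), c(0, 1)), "at least 3")
})

test_that("area term B is the exact piecewise-linear geometry", {
  t5 <- 0:4
  expect_equal(integrated_difference(c(0, 1, 2), c(0, 1, 2), 0:2), 0)
  # integral of t over [0, 4]
  expect_equal(integrated_difference(0:4, rep(0, 5), t5), 8)
  # sign change at t = 0.5: two triangles of area 0.25 each
  expect_equal(integrated_difference(c(-1, 1), c(0, 0), c(0, 1)), 0.5)
  # the endpoint-trapezoid convention reports 1.0 on the same pair
  expect_equal(integrated_difference(c(-1, 1), c(0, 0), c(0, 1),
                                     method = "endpoint"), 1)
  expect_error(integrated_difference(c(0, 1), c(0, 1), c(1, 0)),
               "strictly increasing")
  expect_error(integrated_difference(c(0, 1), c(0, 1, 2), 0:2), "lengths")
})

test_that("score composes A and B and vanishes only when it should", {
  expect_equal(divergence_score(1, 100), 0)
  expect_equal(divergence_score(0, 8), 8)
  expect_equal(divergence_score(-0.5, 1.5), 0.75)
  expect_error(divergence_score(1.5, 1), "\\[-1, 1\\]")
  expect_error(divergence_score(0, -1), "non-negative")

  # worked pair: (0,1,0) vs (0,0,1) on times 0..2. The difference (0,1,-1)
  # crosses zero at t = 1.5, so the exact geometric area is 0.5 + 0.5 = 1.0
  # (Riemann-oracle-verified); the endpoint trapezoid would say 1.5.
  a <- pearson_shape(c(0, 1, 0), c(0, 0, 1))
  b <- integrated_difference(c(0, 1, 0), c(0, 0, 1), 0:2)
  expect_equal(a, -0.5)
  expect_equal(b, 1.0)
  expect_equal(b, riemann_area(c(0, 1, 0), c(0, 0, 1), 0:2), tolerance = 1e-6)
  expect_equal(divergence_score(a, b), 0.5)
  expect_equal(integrated_difference(c(0, 1, 0), c(0, 0, 1), 0:2,
                                     method = "endpoint"), 1.5)
})

test_that("B agrees with a fine Riemann-sum oracle on random curve pairs", {
  set.seed(99)
  for (i in 1:200) {
    ca <- c(0, runif(4, -3, 3)); cb <- c(0, runif(4, -3, 3))
    b <- integrated_difference(ca, cb, 0:4)
    expect_equal(b, riemann_area(ca, cb, 0:4), tolerance = 1e-6)
    a <- pearson_shape(ca, cb)
    expect_equal(divergence_score(a, b), (1 - abs(a)) * b, tolerance = 1e-12)
  }
})

test_that("score is symmetric in groups and positively homogeneous", {
  set.seed(7)
  for (i in 1:50) {
    ca <- c(0, runif(4, -2, 2)); cb <- c(0, runif(4, -2, 2)); cc <- runif(1, 0.1, 5)
    expect_equal(pearson_shape(ca, cb), pearson_shape(cb, ca))
    expect_equal(integrated_difference(ca, cb, 0:4),
                 integrated_difference(cb, ca, 0:4))
    expect_equal(pearson_shape(cc * ca, cc * cb), pearson_shape(ca, cb))
    expect_equal(integrated_difference(cc * ca, cc * cb, 0:4),
                 cc * integrated_difference(ca, cb, 0:4))
  }
})

test_that("score_all ranks, flags at the interpolated percentile, and reports skips", {
  # 8 pairs engineered to score exactly 1..8: flat group-A curve (A := 0)
  # against a group-B triangle of height s, so score = B = s
  flat <- matrix(0, 8, 3, dimnames = list(sprintf("a%d", 1:8), NULL))
  tri <- t(sapply(1:8, function(s) c(0, s, 0)))
  rownames(tri) <- sprintf("b%d", 1:8)
  pa <- profiles_from_curves(flat, group = "A")
  pb <- profiles_from_curves(tri, group = "B")
  map <- ortholog_map(sprintf("a%d", 1:8), sprintf("b%d", 1:8))
  st <- score_all(pa, pb, map, q = 75, group_a = "A", group_b = "B")
  expect_equal(sort(st$score), as.numeric(1:8))
  expect_equal(unique(st$cutoff), 6.25)   # interpolated 75th percentile of 1..8
  expect_equal(sum(st$flagged), 2)
  expect_equal(st$feature_a[st$flagged], c("a8", "a7"))
  expect_equal(st$rank, 1:8)              # descending score, dense ranks
  expect_equal(st$score, rev(as.numeric(1:8)))

  # flagged fraction bound: within [q% - 1/n, q%] of pairs under strict >
  frac <- mean(st$flagged)
  expect_true(frac <= 0.25 && frac >= 0.25 - 1 / nrow(st))
})

test_that("degenerate score_all inputs behave per contract", {
  curves <- rbind(a1 = c(0, 1, 2))
  pa <- profiles_from_curves(curves, group = "A")
  pb <- profiles_from_curves(rbind(b1 = c(0, 2, 0)), group = "B")
  st <- score_all(pa, pb, ortholog_map("a1", "b1"), q = 75,
                  group_a = "A", group_b = "B")
  expect_equal(st$cutoff, st$score)  # single pair: cutoff is its own score
  expect_false(st$flagged)

  # identical curves across groups: every score 0, nothing flagged
  same <- rbind(x1 = c(0, 1, 2), x2 = c(0, -1, 1))
  sa <- same; rownames(sa) <- c("a1", "a2")
  sb <- same; rownames(sb) <- c("b1", "b2")
  st <- score_all(profiles_from_curves(sa, group = "A"),
                  profiles_from_curves(sb, group = "B"),
                  ortholog_map(c("a1", "a2"), c("b1", "b2")), q = 75,
                  group_a = "A", group_b = "B")
  expect_equal(st$score, c(0, 0))
  expect_equal(sum(st$flagged), 0)

  # incomplete pairs are skipped and counted, not fatal
  m <- matrix_from_curves(rbind(a1 = c(0, 1, 2), a2 = c(0, 1, 1)),
                          group = "A")
  m$values["a2", m$samples$sample_id[m$samples$time == 0][1]] <- 0
  pa2 <- normalize_to_baseline(m, pseudocount = 0)
  st <- score_all(pa2, pb, ortholog_map(c("a1", "a2"), c("b1", "b2")),
                  group_a = "A", group_b = "B")
  expect_equal(nrow(st), 1)
  expect_equal(attr(st, "n_skipped"), 1)

  expect_error(score_all(pa, pb, ortholog_map("zz", "yy"),
                         group_a = "A", group_b = "B"), "no mapped pair")
})

test_that("score vanishes exactly when |A| = 1 or B = 0", {
  x <- c(0, 0.5, 1.5, 1, 2)
  cases <- list(list(a = x, b = x),             # identical: A = 1, B = 0
                list(a = x, b = 2.5 * x),       # scaled: A = 1
                list(a = x, b = -x))            # flipped: A = -1
  for (cs in cases) {
    a <- pearson_shape(cs$a, cs$b)
    b <- integrated_difference(cs$a, cs$b, 0:4)
    expect_equal(divergence_score(a, b), 0)
  }
  # and a pair with |A| < 1, B > 0 scores strictly positive
  expect_gt(divergence_score(pearson_shape(c(0, 1, 0), c(0, 0, 1)),
                             integrated_difference(c(0, 1, 0), c(0, 0, 1),
                                                   0:2)), 0)
})
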