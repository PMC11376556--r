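make_de_matrix <- function(log2_rows_by_time, times = c(0, 1), n_reps = 3L) {
  # log2_rows_by_time: list(time -> feature x rep matrix of log2 values)
  sheet <- make_sheet(times = times, n_reps = n_reps)
  gsh <- sheet[sheet$group == "A", ]
  feat <- rownames(log2_rows_by_time[[1]])
  vals <- matrix(NA_real_, length(feat), nrow(gsh),
                 dimnames = list(feat, gsh$sample_id))
  for (i in seq_along(times)) {
    cols <- gsh$sample_id[gsh$time == times[i]]
    vals[, cols] <- 2^log2_rows_by_time[[i]]
  }
  tc_matrix(vals, sheet, "protein")
}

test_that("Welch test matches the closed-form worked example and t.test", {
  base <- rbind(f1 = c(0.9, 1.1, 1.0))
  t1 <- rbind(f1 = c(1.9, 2.1, 2.0))
  m <- make_de_matrix(list(base, t1))
  de <- per_timepoint_de(m, pseudocount = 0)
  expect_equal(de$effect, 1.0)
  expect_equal(de$statistic, 12.247, tolerance = 1e-4)
  expect_equal(de$df, 4)
  ref <- t.test(t1[1, ], base[1, ])
  expect_equal(de$statistic, unname(ref$statistic))
  expect_equal(de$p, ref$p.value)
})

test_that("identical replicate values give a null call; the variance floor rescues clean shifts", {
  base <- rbind(same = c(1, 1, 1), shift = c(1, 1, 1))
  t1 <- rbind(same = c(1, 1, 1), shift = c(3, 3, 3))
  de <- per_timepoint_de(make_de_matrix(list(base, t1)), pseudocount = 0)
  same <- de[de$feature_id == "same", ]
  expect_equal(same$effect, 0)
  expect_equal(same$statistic, 0)
  expect_equal(same$p, 1)
  expect_false(same$called)
  shift <- de[de$feature_id == "shift", ]
  expect_equal(shift$effect, 2)
  expect_true(shift$called)   # floored variance, huge statistic
})

test_that("features with missing replicates get NA rows, not a run failure", {
  base <- rbind(ok = c(1, 1.2, 0.8), thin = c(1, NA, NA))
  t1 <- rbind(ok = c(2, 2.1, 1.9), thin = c(2, 2.2, 1.8))
  de <- per_timepoint_de(make_de_matrix(list(base, t1)), pseudocount = 0)
  expect_true(is.na(de$p[de$feature_id == "thin"]))
  expect_false(de$called[de$feature_id == "thin"])
  expect_false(is.na(de$p[de$feature_id == "ok"]))
})

test_that("BH adjustment matches the worked cases and rejects bad input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(1.0), 1.0)
  expect_equal(bh_adjust(c(0.05, 0.05)), c(0.05, 0.05))
  expect_error(bh_adjust(c(0.5, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("BH equals the brute-force step-up definition on random vectors", {
  set.seed(123)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_identical(q, bh_brute(p))
    expect_true(all(q >= p))
    expect_true(all(diff(q[order(p)]) >= -1e-15))
  }
})

test_that("differential calls are anti-monotone in alpha", {
  sim <- simulate_timecourse(list(archetype_spec("divergent", 80)), seed = 9)
  de1 <- per_timepoint_de(sim$rna$A, fdr_alpha = 0.01)
  de2 <- per_timepoint_de(sim$rna$A, fdr_alpha = 0.10)
  key <- function(d) paste(d$feature_id, d$time)[d$called]
  expect_true(all(key(de1) %in% key(de2)))
})

test_that("profile clustering recovers planted archetypes exactly without noise", {
  up <- c(0, 0.5, 1, 1.5, 2)
  arch <- list(shared_up = cbind(up, up), shared_down = cbind(-up, -up),
               up_down = cbind(up, -up), down_up = cbind(-up, up))
  n_per <- 10
  ca <- NULL; cb <- NULL; truth <- NULL
  for (nm in names(arch)) for (i in seq_len(n_per)) {
    ca <- rbind(ca, arch[[nm]][, 1] * (1 + 0.05 * i))
    cb <- rbind(cb, arch[[nm]][, 2] * (1 + 0.05 * i))
    truth <- c(truth, nm)
  }
  ids_a <- sprintf("a%02d", seq_along(truth))
  ids_b <- sprintf("b%02d", seq_along(truth))
  rownames(ca) <- ids_a; rownames(cb) <- ids_b
  pa <- profiles_from_curves(ca, group = "A")
  pb <- profiles_from_curves(cb, group = "B")
  map <- ortholog_map(ids_a, ids_b)
  cl <- cluster_profiles(pa, pb, map, k = 4, group_a = "A", group_b = "B")
  expect_setequal(names(cl$labels), ids_a)
  expect_equal(mclust::adjustedRandIndex(cl$labels[ids_a], truth), 1.0)
  # deterministic labelling across repeated runs
  cl2 <- cluster_profiles(pa, pb, map, k = 4, group_a = "A", group_b = "B")
  expect_identical(cl$labels, cl2$labels)
})

test_that("clustering edge cases: duplicates co-cluster, k = 1, k too large", {
  curves <- rbind(a1 = c(0, 1, 2), a2 = c(0, 1, 2), a3 = c(0, -2, 1),
                  a4 = c(0, -2, 1))
  cb <- curves; rownames(cb) <- sub("a", "b", rownames(curves))
  pa <- profiles_from_curves(curves, group = "A")
  pb <- profiles_from_curves(cb, group = "B")
  map <- ortholog_map(rownames(curves), rownames(cb))
  cl <- cluster_profiles(pa, pb, map, k = 2, group_a = "A", group_b = "B")
  expect_equal(cl$labels[["a1"]], cl$labels[["a2"]])
  expect_equal(cl$labels[["a3"]], cl$labels[["a4"]])
  expect_false(cl$labels[["a1"]] == cl$labels[["a3"]])

  cl1 <- cluster_profiles(pa, pb, map, k = 1, group_a = "A", group_b = "B")
  expect_true(all(cl1$labels == "I"))
  expect_error(cluster_profiles(pa, pb, map, k = 5,
                                group_a = "A", group_b = "B"), "exceeds")
})

test_that("cross-layer overlap is the mapped intersection of called sets", {
  fake_de <- function(called_ids, all_ids, group = "A", time = 3) {
    data.frame(feature_id = all_ids, group = group, time = time,
               effect = 1, statistic = 1, df = 4, p = 0.01, q = 0.01,
               called = all_ids %in% called_ids, stringsAsFactors = FALSE)
  }
  ids <- paste0("g", 1:5)
  map <- ortholog_map(ids, ids)   # identity
  rna <- fake_de(c("g1", "g2", "g3"), ids)
  prot <- fake_de(c("g2", "g3", "g4"), ids)
  ov <- cross_layer_overlap(rna, prot, map, "A", 3)
  expect_equal(ov$pairs, c("g2", "g3"))
  expect_equal(ov$n_overlap, 2)
  expect_true(ov$n_overlap <= min(ov$n_rna, ov$n_protein))

  # permutation invariance in feature order
  ov2 <- cross_layer_overlap(rna[sample(1:5), ], prot[5:1, ], map, "A", 3)
  expect_equal(ov2$pairs, ov$pairs)

  ov0 <- cross_layer_overlap(rna, fake_de(character(), ids), map, "A", 3)
  expect_equal(ov0$n_overlap, 0)
  expect_equal(ov0$n_rna, 3)

  expect_error(cross_layer_overlap(rna, prot, map, "A", 99), "absent")
})

test_that("overlap translates protein ids through the ortholog map", {
  map <- ortholog_map(c("a1", "a2"), c("b1", "b2"))
  rna <- data.frame(feature_id = c("a1", "a2"), group = "B", time = 1,
                    effect = 1, statistic = 1, df = 4, p = 0.01, q = 0.01,
                    called = c(TRUE, TRUE))
  prot <- data.frame(feature_id = c("b1", "b2"), group = "B", time = 1,
                     effect = 1, statistic = 1, df = 4, p = 0.01, q = 0.01,
                     called = c(TRUE, FALSE))
  ov <- cross_layer_overlap(rna, prot, map, "B", 1)
  expect_equal(ov$pairs, "a1")
})
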