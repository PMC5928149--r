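test_that("low-read filter drops OTUs below the dataset-wide total", {
  m <- cbind(a = c(5L, 5L), b = c(24L, 25L), c = c(25L, 25L),
             d = c(400L, 100L), e = c(0L, 1L))
  rownames(m) <- c("s1", "s2")
  kept <- filter_low_read_otus(otu_table(m))
  expect_equal(kept$otu_ids, c("c", "d"))  # totals 10, 49, 50, 500, 1
  expect_equal(kept$sample_ids, c("s1", "s2"))
  ident <- filter_low_read_otus(otu_table(m), min_reads = 0)
  expect_equal(ident$otu_ids, colnames(m))
  expect_error(filter_low_read_otus(otu_table(m), min_reads = 1000), "every OTU")
})

test_that("rarefaction subsamples exactly, drops shallow samples, is seeded", {
  m <- rbind(deep = c(a = 6000L, b = 4000L, c = 0L),
             exact = c(a = 500L, b = 250L, c = 250L),
             shallow = c(a = 500L, b = 400L, c = 99L))
  tab <- otu_table(m)
  expect_warning(r <- rarefy(tab, depth = 1000, seed = 5), "shallow")
  expect_equal(rownames(r$counts), c("deep", "exact"))
  expect_true(all(rowSums(r$counts) == 1000))
  # a full draw returns the sample unchanged
  expect_equal(r$counts["exact", ], m["exact", ])
  expect_identical(suppressWarnings(rarefy(tab, 1000, seed = 5))$counts,
                   r$counts)
  # expected proportions preserved: hypergeometric mean depth * p
  draws <- withr::with_seed(11, {
    sapply(1:200, function(k) {
      rarefy(otu_table(m[1, , drop = FALSE]), 1000,
             seed = sample.int(1e6, 1))$counts[1, "a"]
    })
  })
  expect_lt(abs(mean(draws) - 600), 5)
  expect_error(rarefy(tab, depth = 1e7), "below the rarefaction depth")
})

test_that("Chao1 matches its closed form and dominates observed richness", {
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/6 = 12
  x <- c(rep(1L, 4), rep(2L, 2), rep(5L, 4))
  expect_equal(chao1(x), 12)
  # no singletons -> S_obs
  expect_equal(chao1(c(3L, 4L, 5L)), 3)
  expect_equal(chao1(rep(3L, 8)), 8)
  # monotone: adding a singleton species never decreases the estimate
  y <- c(x, 1L)
  expect_gte(chao1(y), chao1(x))
  expect_error(chao1(integer()), "empty")

  # rarefaction-averaged variant stays above rarefied richness and is seeded
  big <- as.integer(rmultinom(1, 5000, prob = c(rep(0.001, 100),
                                                rep(0.09, 10)))[, 1])
  v1 <- chao1(big, n_rarefaction_reps = 10, depth = 2000, seed = 3)
  v2 <- chao1(big, n_rarefaction_reps = 10, depth = 2000, seed = 3)
  expect_identical(v1, v2)
  expect_gte(v1, 10)
  expect_error(chao1(c(1L, 1L), depth = 100), "fewer reads")
})

test_that("alpha_diversity reports per-sample estimates with metadata", {
  sp <- basis_spec(40, seed = 23)
  ds <- simulate_staged_dataset(list(larva = sp), n_per_stage = 4, depth = 3000)
  out <- alpha_diversity(as_otu_table(ds), depth = 1000,
                         n_rarefaction_reps = 5, seed = 2)
  expect_equal(nrow(out), 4)
  expect_true(all(c("sample_id", "chao1", "stage") %in% names(out)))
  expect_true(all(out$chao1 >= 1))
})

test_that("Bray-Curtis hits hand values and metric properties", {
  m <- rbind(u = c(6L, 4L, 0L), v = c(2L, 4L, 4L), w = c(6L, 4L, 0L),
             z = c(0L, 0L, 7L))
  colnames(m) <- c("x", "y", "zz")
  d <- bray_curtis(otu_table(m))
  expect_equal(d["u", "v"], 0.4)          # (4+0+4)/(8+8+4)
  expect_equal(d["u", "w"], 0)            # identical samples
  expect_equal(d["u", "z"], 1)            # disjoint supports
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 4))
  expect_true(all(d >= 0 & d <= 1))
})

test_that("PCoA embeds two points at +/- d/2 and round-trips Euclidean data", {
  d2 <- matrix(c(0, 3, 3, 0), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  p2 <- pcoa(d2)
  expect_equal(ncol(p2$coordinates), 1)
  expect_equal(sort(p2$coordinates[, 1]), c(-1.5, 1.5), ignore_attr = TRUE)
  expect_equal(p2$explained, 1)

  pts <- withr::with_seed(31, matrix(rnorm(20), 10, 2))
  rownames(pts) <- paste0("s", 1:10)
  de <- as.matrix(dist(pts))
  pe <- pcoa(de)
  expect_true(all(diff(pe$explained) <= 1e-12))
  rec <- as.matrix(dist(pe$coordinates[, 1:2]))
  expect_equal(unname(rec), unname(de), tolerance = 1e-8)

  # three identical samples: no positive axes
  d0 <- matrix(0, 3, 3)
  expect_equal(ncol(pcoa(d0)$coordinates), 0)
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("PERMANOVA detects a planted group offset and degrades gracefully", {
  sp1 <- basis_spec(30, log_mean_range = c(1, 3), log_sd = 0.5, seed = 41)
  sp2 <- basis_spec(30, log_mean_range = c(3, 5), log_sd = 0.5, seed = 42)
  ds <- simulate_staged_dataset(list(a = sp1, b = sp2), n_per_stage = 10,
                                depth = 3000)
  tab <- as_otu_table(ds)
  d <- bray_curtis(tab)
  res <- permanova(d, ds$stage, n_perm = 999, seed = 43)
  expect_lte(res$p, 0.005)
  expect_gt(res$r2, 0.2)
  expect_identical(glance(res)$p, res$p)
  expect_identical(permanova(d, ds$stage, n_perm = 99, seed = 7)$p,
                   permanova(d, ds$stage, n_perm = 99, seed = 7)$p)
  expect_error(permanova(d, rep("a", 20)), "2 groups")

  # equidistant geometry: reports a baseline R2 without crashing
  deq <- matrix(1, 6, 6)
  diag(deq) <- 0
  eq <- permanova(deq, rep(c("g1", "g2"), 3), n_perm = 99, seed = 1)
  expect_gt(eq$p, 0.5)
})

test_that("fold change: identity, closed-form arithmetic, spiked recovery", {
  m <- toy_counts(n = 4, d = 6, seed = 51)
  tab <- otu_table(m)
  same <- fold_change(tab, tab, "OTU_2", depth = NULL)
  expect_equal(same$fc, 1)

  # rel. abundance 0.05 vs 0.005 at equal depths -> fc ~ 10 (pseudocount-shifted)
  t1 <- otu_table(cbind(f = 500L, rest = 9500L))
  t0 <- otu_table(cbind(f = 50L, rest = 9950L))
  fc <- fold_change(t1, t0, "f", depth = NULL)
  expect_equal(fc$fc, (501 / 10001) / (51 / 10001), tolerance = 1e-12)
  expect_gt(fc$fc, 9)

  expect_error(fold_change(t1, t0, "absent", depth = NULL), "absent")
})
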