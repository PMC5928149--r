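test_that("posterior fraction resamples live on the simplex and concentrate", {
  tab <- toy_table()
  fr <- estimate_fractions(tab, n_resamples = 5, seed = 1)
  expect_length(fr, 5)
  for (f in fr) expect_equal(rowSums(f), rep(1, nrow(f)),
                             tolerance = 1e-12, ignore_attr = TRUE)
  expect_identical(estimate_fractions(tab, 5, seed = 1),
                   estimate_fractions(tab, 5, seed = 1))

  # concentration: (0,0,0,N) with N large -> last fraction ~ 1
  m <- matrix(c(0L, 0L, 0L, 100000L), 1, 4)
  m <- rbind(m, m)  # two samples to satisfy the container
  rownames(m) <- c("a", "b")
  big <- estimate_fractions(otu_table(m), n_resamples = 50, seed = 2)
  expect_gt(mean(sapply(big, function(f) f[1, 4])), 0.99)

  # symmetric prior: two zero-count OTUs in a sample are exchangeable, so
  # their posterior mass splits 50:50 in expectation
  m0 <- matrix(c(10L, 0L, 0L), 2, 3, byrow = TRUE,
               dimnames = list(c("a", "b"), c("x", "y", "z")))
  fr0 <- estimate_fractions(otu_table(m0), 400, seed = 3)
  split_yz <- sapply(fr0, function(f) f[1, "y"] / (f[1, "y"] + f[1, "z"]))
  expect_equal(mean(split_yz), 0.5, tolerance = 0.05)
})

test_that("variation matrix matches hand-computed log-ratio variances", {
  # two samples with log-ratio {0, 2}: unbiased variance is 2
  f <- rbind(c(0.5, 0.5), c(exp(2) / (1 + exp(2)), 1 / (1 + exp(2))))
  t_mat <- variation_matrix(f)
  expect_equal(t_mat[1, 2], 2)
  expect_equal(diag(t_mat), c(0, 0), ignore_attr = TRUE)

  # proportional columns have zero variation
  f3 <- cbind(a = c(0.2, 0.4, 0.1), b = c(0.1, 0.2, 0.05))
  f3 <- cbind(f3, c = 1 - rowSums(f3))
  t3 <- variation_matrix(f3)
  expect_equal(t3["a", "b"], 0, tolerance = 1e-15)

  # order invariance and symmetry
  f4 <- matrix(runif(40, 0.01, 1), 10, 4)
  f4 <- f4 / rowSums(f4)
  expect_equal(variation_matrix(f4), variation_matrix(f4[10:1, ]))
  expect_true(isSymmetric(variation_matrix(f4)))
  expect_error(variation_matrix(f4 - 1), "positive")
})

test_that("basis-variance system solves the hand case and matches a
           least-squares oracle under exclusions", {
  d <- 5
  t_mat <- matrix(2, d, d)
  diag(t_mat) <- 0
  expect_equal(solve_basis_variances(t_mat), rep(1, d), tolerance = 1e-12)

  # all-zero variation floors at epsilon
  expect_equal(solve_basis_variances(matrix(0, 6, 6)), rep(1e-6, 6))
  expect_error(solve_basis_variances(matrix(0, 3, 3)), "at least 4")

  # exclusion: compare to an explicit least-squares oracle over the same
  # equations sum_{j in I_i} (omega_i + omega_j) = sum_{j in I_i} t_ij
  withr::with_seed(8, {
    f <- matrix(rgamma(300, 2), 50, 6)
    f <- f / rowSums(f)
  })
  tm <- variation_matrix(f)
  excl <- cbind(2L, 5L)
  got <- solve_basis_variances(tm, excluded = excl)
  d6 <- 6
  incl <- matrix(TRUE, d6, d6)
  diag(incl) <- FALSE
  incl[2, 5] <- incl[5, 2] <- FALSE
  m <- incl * 1
  diag(m) <- rowSums(incl)
  oracle <- qr.solve(m, rowSums(tm * incl))
  expect_equal(got, pmax(oracle, 1e-6), tolerance = 1e-8)
})

test_that("correlation back-transform hits its closed-form anchor points", {
  om <- c(1, 1, 2, 0.5)
  t_mat <- matrix(0, 4, 4)
  # t = 0 with equal variances -> rho = 1
  r0 <- correlations_from_basis(t_mat, om)
  expect_equal(r0[1, 2], 1)
  # t = omega_i + omega_j -> rho = 0
  t_mat[] <- outer(om, om, "+")
  diag(t_mat) <- 0
  expect_equal(correlations_from_basis(t_mat, om)[3, 4], 0)
  # t = 2(omega_i + omega_j) with equal omega -> clipped at -1
  t2 <- matrix(4, 2, 2)
  diag(t2) <- 0
  t2 <- rbind(cbind(t2, 4), 4)
  diag(t2) <- 0
  expect_equal(correlations_from_basis(t2[1:3, 1:3], c(1, 1, 1))[1, 2], -1)
})

test_that("inference recovers a planted edge, is symmetric, clipped and
           conformable under permutations", {
  sp <- basis_spec(50, tibble::tibble(i = 1, j = 2, rho = 0.8), seed = 1)
  tab <- as_otu_table(simulate_counts(sp, n_samples = 500, depth = 5000))
  fit <- sparcc(tab, seed = 1)
  expect_lt(abs(fit$rho[1, 2] - 0.8), 0.15)
  expect_true(isSymmetric(fit$rho))
  expect_true(all(abs(fit$rho) <= 1))
  expect_equal(unname(diag(fit$rho)), rep(1, 50))

  # sample reordering leaves rho unchanged and OTU reordering permutes it,
  # up to Dirichlet-resampling noise (the RNG stream maps to cells
  # differently after reordering)
  perm_s <- otu_table(tab$counts[rev(seq_len(500)), ])
  expect_lt(max(abs(sparcc(perm_s, seed = 1)$rho - fit$rho)), 0.05)
  ord <- c(3, 1, 2, 4:50)
  perm_o <- otu_table(tab$counts[, ord])
  expect_lt(max(abs(sparcc(perm_o, seed = 1)$rho - fit$rho[ord, ord])), 0.05)
})

test_that("a duplicated OTU column is inferred as near-perfectly correlated", {
  sp <- basis_spec(8, seed = 4)
  ds <- simulate_counts(sp, n_samples = 200, depth = 4000)
  m <- cbind(ds$counts, dup = ds$counts[, 1])
  fit <- sparcc(otu_table(m), seed = 4)
  expect_gte(fit$rho["OTU_1", "dup"], 0.95)
})

test_that("pseudo p-values: guard, planted-pair significance, determinism", {
  tab <- toy_table(n = 10, d = 5)
  fit <- sparcc(tab, seed = 1)
  expect_error(pseudo_pvalues(tab, fit, n_perm = 0), "n_perm")

  sp <- basis_spec(10, tibble::tibble(i = 1, j = 2, rho = 0.8), seed = 6)
  tab2 <- as_otu_table(simulate_counts(sp, n_samples = 500, depth = 5000))
  fit2 <- sparcc(tab2, seed = 6)
  pp <- pseudo_pvalues(tab2, fit2, n_perm = 100, seed = 7)
  expect_equal(pp$pvals[1, 2], 0)
  expect_true(all(pp$pvals >= 0 & pp$pvals <= 1))
  expect_true(isSymmetric(pp$pvals))
  pp2 <- pseudo_pvalues(tab2, fit2, n_perm = 100, seed = 7)
  expect_identical(pp$pvals, pp2$pvals)
})

test_that("tidy and glance views expose pairs and summary", {
  sp <- basis_spec(6, tibble::tibble(i = 1, j = 2, rho = 0.9), seed = 3)
  tab <- as_otu_table(simulate_counts(sp, 100, 2000))
  fit <- sparcc(tab, seed = 3)
  td <- tidy(fit)
  expect_equal(nrow(td), choose(6, 2))
  expect_equal(td$otu_a[1], "OTU_1")  # strongest pair sorts first
  expect_equal(td$otu_b[1], "OTU_2")
  g <- glance(fit)
  expect_equal(g$n_otus, 6)
  expect_equal(g$n_samples, 100)
  expect_gte(g$n_strong, 1)
})
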