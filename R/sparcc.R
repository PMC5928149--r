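#' Posterior fraction resamples for a count table
#'
#' Counts are converted to relative abundances by drawing, per sample, a
#' fraction vector from the Dirichlet posterior under a symmetric unit prior
#' (counts + 1). The prior guarantees strictly positive fractions, so
#' log-ratios are always defined; repeated resampling propagates the counting
#' uncertainty of sparse tables into the correlation estimates.
#'
#' @param table An [otu_table()].
#' @param n_resamples Number of posterior draws.
#' @param seed Integer seed.
#' @return A list of `n_resamples` samples x OTUs fraction matrices, each row
#'   summing to 1.
#' @export
estimate_fractions <- function(table, n_resamples = 20, seed = 1L) {
  assert_otu_table(table)
  stopifnot(n_resamples >= 1)
  counts <- table$counts
  withr::with_seed(seed, {
    lapply(seq_len(n_resamples), function(k) {
      g <- matrix(stats::rgamma(length(counts), shape = counts + 1, rate = 1),
                  nrow = nrow(counts))
      f <- g / rowSums(g)
      dimnames(f) <- dimnames(counts)
      f
    })
  })
}

#' Log-ratio variation matrix
#'
#' The core statistic of basis-correlation inference:
#' `t[i, j] = var(log(f_i / f_j))` across samples (unbiased, n - 1
#' denominator). Perfectly co-varying OTUs have `t = 0`; the matrix is
#' symmetric with zero diagonal.
#'
#' @param fractions A samples x OTUs matrix of strictly positive fractions.
#' @return A D x D variation matrix.
#' @export
variation_matrix <- function(fractions) {
  if (any(fractions <= 0)) stop("fractions must be strictly positive", call. = FALSE)
  lf <- log(fractions)
  v <- stats::cov(lf)                    # n-1 denominator
  d <- diag(v)
  t_mat <- outer(d, d, "+") - 2 * v
  t_mat <- (t_mat + t(t_mat)) / 2
  t_mat[t_mat < 0] <- 0                  # numerical negative zeros
  diag(t_mat) <- 0
  t_mat
}

#' Solve for basis variances under the sparsity approximation
#'
#' The variation matrix decomposes as
#' `t[i, j] = omega_i + omega_j - 2 rho_ij sqrt(omega_i omega_j)` where
#' `omega` are the variances of the unobserved basis log-abundances. Assuming
#' most correlations are near zero, the cross-terms drop and the row sums of
#' `t` over non-excluded pairs give a linear system in `omega`, solved here
#' exactly (least squares when exclusions make it inconsistent).
#'
#' @param t_mat A variation matrix.
#' @param excluded Optional 2-column matrix of OTU index pairs whose equations
#'   are dropped (iteratively excluded strong pairs).
#' @return Numeric vector `omega` of basis variances, floored at `1e-6`.
#' @details Requires D >= 4: with fewer OTUs the system is degenerate.
#' @export
solve_basis_variances <- function(t_mat, excluded = NULL) {
  d <- nrow(t_mat)
  if (d < 4) stop("basis-variance system needs at least 4 OTUs", call. = FALSE)
  incl <- matrix(TRUE, d, d)
  diag(incl) <- FALSE
  if (!is.null(excluded) && nrow(excluded)) {
    incl[excluded] <- FALSE
    incl[excluded[, c(2, 1), drop = FALSE]] <- FALSE
  }
  # row i: sum_{j included} t_ij = k_i omega_i + sum_{j included} omega_j
  m <- incl * 1
  diag(m) <- rowSums(incl)
  b <- rowSums(t_mat * incl)
  qr_m <- qr(m)
  if (qr_m$rank < d) {
    stop("basis-variance system is singular after exclusions", call. = FALSE)
  }
  pmax(as.numeric(qr.coef(qr_m, b)), 1e-6)
}

#' Correlations from a variation matrix and basis variances
#'
#' Inverts the variance decomposition:
#' `rho_ij = (omega_i + omega_j - t[i, j]) / (2 sqrt(omega_i omega_j))`,
#' clipped to `[-1, 1]` with unit diagonal.
#'
#' @param t_mat A variation matrix.
#' @param omega Positive basis variances.
#' @return A symmetric correlation matrix.
#' @export
correlations_from_basis <- function(t_mat, omega) {
  stopifnot(all(omega > 0), length(omega) == nrow(t_mat))
  so <- sqrt(omega)
  rho <- (outer(omega, omega, "+") - t_mat) / (2 * tcrossprod(so))
  rho <- pmin(pmax(rho, -1), 1)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  rho
}

# one resample: variation matrix -> iterative strong-pair exclusion -> rho
sparcc_one <- function(t_mat, exclusion_threshold, max_exclusions) {
  excluded <- matrix(integer(), 0, 2)
  omega <- solve_basis_variances(t_mat)
  rho <- correlations_from_basis(t_mat, omega)
  for (it in seq_len(max_exclusions)) {
    cand <- abs(rho)
    diag(cand) <- 0
    if (nrow(excluded)) {
      cand[excluded] <- 0
      cand[excluded[, c(2, 1), drop = FALSE]] <- 0
    }
    top <- which(cand == max(cand), arr.ind = TRUE)[1, , drop = FALSE]
    if (cand[top] <= exclusion_threshold) break
    excluded <- rbind(excluded, top)
    new_omega <- tryCatch(solve_basis_variances(t_mat, excluded),
                          error = function(e) NULL)
    if (is.null(new_omega)) break
    omega <- new_omega
    rho <- correlations_from_basis(t_mat, omega)
  }
  rho
}

# core used both on real tables and on permuted count matrices
sparcc_counts <- function(counts, n_resamples, exclusion_threshold,
                          max_exclusions, seed) {
  rhos <- withr::with_seed(seed, {
    lapply(seq_len(n_resamples), function(k) {
      g <- matrix(stats::rgamma(length(counts), shape = counts + 1, rate = 1),
                  nrow = nrow(counts))
      f <- g / rowSums(g)
      sparcc_one(variation_matrix(f), exclusion_threshold, max_exclusions)
    })
  })
  rho <- apply(simplify2array(rhos), c(1, 2), stats::median)
  rho <- (rho + t(rho)) / 2
  diag(rho) <- 1
  dimnames(rho) <- list(colnames(counts), colnames(counts))
  rho
}

#' Infer basis correlations from a compositional OTU table
#'
#' Full SparCC-style pipeline: Dirichlet-posterior fraction resamples, the
#' log-ratio variation matrix per resample, iterative exclusion of the single
#' strongest-correlated pair above the exclusion threshold (re-solving the
#' basis-variance system after each exclusion), and element-wise median
#' aggregation of the per-resample correlation matrices.
#'
#' @param table An [otu_table()] with at least 4 OTUs.
#' @param n_resamples Fraction resamples aggregated by the median (default 20).
#' @param exclusion_threshold Strong pairs with `|rho|` above this value are
#'   iteratively excluded from the sparsity system (default 0.1).
#' @param max_exclusions Cap on exclusion iterations (default 10).
#' @param seed Integer seed.
#' @return An object of class `sparcc_fit`: list with `rho` (symmetric,
#'   unit-diagonal matrix in `[-1, 1]`), `pvals` (`NULL` until
#'   [pseudo_pvalues()] is run), `otu_ids`, `n_samples`, and `params`.
#' @examples
#' spec <- basis_spec(10, seed = 7)
#' tab <- as_otu_table(simulate_counts(spec, n_samples = 50, depth = 2000))
#' fit <- sparcc(tab, seed = 7)
#' round(fit$rho[1:4, 1:4], 2)
#' @export
sparcc <- function(table, n_resamples = 20, exclusion_threshold = 0.1,
                   max_exclusions = 10, seed = 1L) {
  assert_otu_table(table)
  if (ncol(table$counts) < 4) stop("need at least 4 OTUs", call. = FALSE)
  rho <- sparcc_counts(table$counts, n_resamples, exclusion_threshold,
                       max_exclusions, seed)
  structure(
    list(rho = rho, pvals = NULL, otu_ids = table$otu_ids,
         n_samples = nrow(table$counts),
         params = list(n_resamples = n_resamples,
                       exclusion_threshold = exclusion_threshold,
                       max_exclusions = max_exclusions, seed = seed,
                       aggregation = "median",
                       permutation = "per-OTU independent shuffle")),
    class = "sparcc_fit"
  )
}

#' @rdname sparcc
#' @export
infer_correlations <- sparcc

#' Permutation pseudo p-values for inferred correlations
#'
#' Each permuted dataset shuffles every OTU's counts independently across
#' samples, destroying all between-OTU correlation while preserving marginal
#' abundance distributions; the full inference is re-run on each. The
#' two-sided pseudo p-value of a pair is the plain proportion of permutations
#' whose re-inferred `|rho|` is at least as extreme as the observed one
#' (`p = 0` is representable).
#'
#' @param table The [otu_table()] the fit was computed from.
#' @param fit A `sparcc_fit`.
#' @param n_perm Number of permuted datasets (>= 1; the network analyses here
#'   were designed around 1,000).
#' @param seed Integer seed for the permutation stream.
#' @return The `sparcc_fit` with its `pvals` matrix filled in.
#' @export
pseudo_pvalues <- function(table, fit, n_perm = 1000, seed = 1L) {
  assert_otu_table(table)
  stopifnot(inherits(fit, "sparcc_fit"), n_perm >= 1)
  counts <- table$counts
  n <- nrow(counts)
  obs <- abs(fit$rho)
  hits <- matrix(0, nrow(obs), ncol(obs))
  p <- fit$params
  perm_seeds <- withr::with_seed(seed, {
    sample.int(.Machine$integer.max - 1L, n_perm)
  })
  for (b in seq_len(n_perm)) {
    perm <- withr::with_seed(perm_seeds[b], {
      apply(counts, 2, function(col) col[sample.int(n)])
    })
    rho_p <- sparcc_counts(perm, p$n_resamples, p$exclusion_threshold,
                           p$max_exclusions, seed = perm_seeds[b])
    hits <- hits + (abs(rho_p) >= obs)
  }
  pv <- hits / n_perm
  pv <- (pv + t(pv)) / 2
  diag(pv) <- 1
  dimnames(pv) <- dimnames(fit$rho)
  fit$pvals <- pv
  fit$params$n_permutations <- n_perm
  fit
}

#' @export
print.sparcc_fit <- function(x, ...) {
  cat(sprintf("<sparcc_fit> %d OTUs, %d samples, %d resamples%s\n",
              length(x$otu_ids), x$n_samples, x$params$n_resamples,
              if (is.null(x$pvals)) "" else
                sprintf(", %d permutations", x$params$n_permutations)))
  invisible(x)
}

#' Tidy a correlation fit into a pair-wise tibble
#'
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return A tibble with one row per unordered OTU pair: `otu_a`, `otu_b`,
#'   `rho`, and `pval` when pseudo p-values have been computed.
#' @export
tidy.sparcc_fit <- function(x, ...) {
  d <- length(x$otu_ids)
  idx <- which(upper.tri(x$rho), arr.ind = TRUE)
  out <- tibble::tibble(
    otu_a = x$otu_ids[idx[, 1]],
    otu_b = x$otu_ids[idx[, 2]],
    rho = x$rho[idx]
  )
  if (!is.null(x$pvals)) out$pval <- x$pvals[idx]
  dplyr::arrange(out, dplyr::desc(abs(.data$rho)))
}

#' One-row summary of a correlation fit
#'
#' @param x A `sparcc_fit`.
#' @param ... Unused.
#' @return A one-row tibble: numbers of OTUs/samples, strongest absolute
#'   off-diagonal correlation, and count of strong (`|rho| > 0.5`) pairs.
#' @export
glance.sparcc_fit <- function(x, ...) {
  off <- x$rho[upper.tri(x$rho)]
  tibble::tibble(
    n_otus = length(x$otu_ids),
    n_samples = x$n_samples,
    n_resamples = x$params$n_resamples,
    max_abs_rho = max(abs(off)),
    n_strong = sum(abs(off) > 0.5)
  )
}
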