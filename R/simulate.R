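#' Specify a synthetic basis-correlation structure
#'
#' Defines the ground truth for the synthetic OTU-table generator: the number
#' of OTUs, a small set of planted strong pairwise correlations between their
#' (unobserved) basis abundances, and the log-scale location/spread of the
#' per-OTU mean abundances.
#'
#' @param n_otus Number of OTUs (D).
#' @param planted_edges Data frame with columns `i`, `j` (1-based OTU indices)
#'   and `rho` (target basis correlation). Targets must be strong
#'   (`abs(rho) >= 0.5`) and at most 1 in absolute value; weak targets are the
#'   regime the null already covers and are rejected.
#' @param log_mean_range Length-2 numeric: per-OTU log-scale means are drawn
#'   uniformly from this interval. Default `c(1, 4)` spans roughly a 20-fold
#'   abundance gradient, a modest version of real amplicon unevenness.
#' @param log_sd Common log-scale standard deviation of basis abundances
#'   (default 1).
#' @param seed Integer seed; every draw downstream of the spec is a pure
#'   function of it.
#'
#' @return An object of class `basis_spec`.
#' @seealso [make_basis_correlations()], [simulate_counts()]
#' @export
basis_spec <- function(n_otus, planted_edges = NULL,
                       log_mean_range = c(1, 4), log_sd = 1, seed = 1L) {
  stopifnot(n_otus >= 2, log_sd > 0, length(log_mean_range) == 2)
  if (is.null(planted_edges)) {
    planted_edges <- tibble::tibble(i = integer(), j = integer(), rho = numeric())
  }
  planted_edges <- tibble::as_tibble(planted_edges)
  stopifnot(all(c("i", "j", "rho") %in% names(planted_edges)))
  if (nrow(planted_edges)) {
    if (any(planted_edges$i == planted_edges$j)) {
      stop("a planted edge cannot join an OTU to itself", call. = FALSE)
    }
    if (any(planted_edges$i > n_otus | planted_edges$j > n_otus |
            planted_edges$i < 1 | planted_edges$j < 1)) {
      stop("planted edge indices must lie in 1..n_otus", call. = FALSE)
    }
    if (any(abs(planted_edges$rho) < 0.5 | abs(planted_edges$rho) > 1)) {
      stop("planted correlations must satisfy 0.5 <= |rho| <= 1", call. = FALSE)
    }
    key <- paste(pmin(planted_edges$i, planted_edges$j),
                 pmax(planted_edges$i, planted_edges$j))
    if (anyDuplicated(key)) stop("duplicate planted edges", call. = FALSE)
  }
  structure(
    list(n_otus = as.integer(n_otus), planted_edges = planted_edges,
         log_mean_range = as.numeric(log_mean_range),
         log_sd = as.numeric(log_sd), seed = as.integer(seed)),
    class = "basis_spec"
  )
}

#' Build the planted basis-correlation matrix
#'
#' Completes the planted edges with zeros off the edges and ones on the
#' diagonal, then repairs the result to the nearest positive semi-definite
#' matrix by clipping negative eigenvalues at zero and re-normalizing to unit
#' diagonal. If the repair moves any planted entry by more than 0.05 the spec
#' is over-constrained and an error is raised.
#'
#' @param spec A [basis_spec()].
#' @return A symmetric, unit-diagonal, positive semi-definite
#'   `n_otus x n_otus` correlation matrix.
#' @export
make_basis_correlations <- function(spec) {
  stopifnot(inherits(spec, "basis_spec"))
  d <- spec$n_otus
  r <- diag(d)
  pe <- spec$planted_edges
  for (k in seq_len(nrow(pe))) {
    r[pe$i[k], pe$j[k]] <- r[pe$j[k], pe$i[k]] <- pe$rho[k]
  }
  ev <- eigen(r, symmetric = TRUE)
  if (min(ev$values) < -1e-10) {
    vals <- pmax(ev$values, 0)
    r <- ev$vectors %*% diag(vals) %*% t(ev$vectors)
    s <- 1 / sqrt(diag(r))
    r <- r * tcrossprod(s)
    r <- (r + t(r)) / 2
    diag(r) <- 1
  }
  if (nrow(pe)) {
    got <- r[cbind(pe$i, pe$j)]
    if (any(abs(got - pe$rho) > 0.05)) {
      stop("planted correlations are jointly infeasible: PSD repair moved an ",
           "entry by more than 0.05", call. = FALSE)
    }
  }
  r
}

# multinomial count draw shared by simulate_counts and spike_isolate so that a
# fold = 1 respike with the same seed replays the identical counts
draw_counts <- function(fractions, depth, seed) {
  withr::with_seed(seed, {
    t(apply(fractions, 1, function(p) stats::rmultinom(1, depth, p)[, 1]))
  })
}

#' Simulate a compositional OTU count table with known correlation structure
#'
#' The generative model matches the assumptions under which log-ratio-variance
#' (SparCC-type) inference is derived: per-sample basis log-abundances are
#' multivariate normal with the spec's correlation structure, exponentiated and
#' closed to fractions, and reads are drawn multinomially at a fixed depth.
#'
#' @param spec A [basis_spec()].
#' @param n_samples Number of samples (>= 2).
#' @param depth Reads per sample (>= n_otus).
#' @return An object of class `simulated_dataset` with elements `counts`
#'   (samples x OTUs integers, every row summing to `depth`),
#'   `true_correlations`, `fractions` (pre-multinomial expected fractions),
#'   `log_abundances` (pre-closure basis draws, exposed for validation),
#'   `stage` (`NULL` here), `depth`, and `seed`.
#' @export
simulate_counts <- function(spec, n_samples, depth) {
  stopifnot(inherits(spec, "basis_spec"), n_samples >= 2, depth >= spec$n_otus)
  d <- spec$n_otus
  rho <- make_basis_correlations(spec)
  sigma <- spec$log_sd^2 * rho
  logs <- withr::with_seed(spec$seed, {
    mu <- stats::runif(d, spec$log_mean_range[1], spec$log_mean_range[2])
    MASS::mvrnorm(n_samples, mu = mu, Sigma = sigma)
  })
  if (is.null(dim(logs))) logs <- matrix(logs, nrow = n_samples)
  fracs <- exp(logs)
  fracs <- fracs / rowSums(fracs)
  counts <- draw_counts(fracs, depth, seed = spec$seed + 1L)
  dimnames(counts) <- list(paste0("S", seq_len(n_samples)),
                           paste0("OTU_", seq_len(d)))
  dimnames(fracs) <- dimnames(logs) <- dimnames(counts)
  structure(
    list(counts = counts, true_correlations = rho, fractions = fracs,
         log_abundances = logs, stage = NULL, depth = as.integer(depth),
         seed = spec$seed),
    class = "simulated_dataset"
  )
}

#' Simulate a stage-structured dataset
#'
#' Concatenates one simulated block per developmental stage (e.g. larva,
#' juvenile, adult), each with its own planted correlation structure, sharing
#' a common OTU set.
#'
#' @param specs Named list of [basis_spec()] objects, one per stage; all must
#'   share `n_otus`.
#' @param n_per_stage Samples per stage.
#' @param depth Reads per sample.
#' @return A `simulated_dataset` whose `stage` element labels each row and
#'   whose `true_correlations` is a named list of per-stage matrices.
#' @export
simulate_staged_dataset <- function(specs, n_per_stage, depth) {
  stopifnot(is.list(specs), length(specs) >= 1, !is.null(names(specs)))
  ds <- unique(vapply(specs, function(s) s$n_otus, integer(1)))
  if (length(ds) != 1) stop("all stages must share n_otus", call. = FALSE)
  blocks <- purrr::imap(specs, function(sp, st) simulate_counts(sp, n_per_stage, depth))
  counts <- do.call(rbind, purrr::map(blocks, "counts"))
  fracs <- do.call(rbind, purrr::map(blocks, "fractions"))
  logs <- do.call(rbind, purrr::map(blocks, "log_abundances"))
  stage <- rep(names(specs), each = n_per_stage)
  rownames(counts) <- rownames(fracs) <- rownames(logs) <-
    paste0(stage, "_", rep(seq_len(n_per_stage), times = length(specs)))
  structure(
    list(counts = counts,
         true_correlations = purrr::map(blocks, "true_correlations"),
         fractions = fracs, log_abundances = logs, stage = stage,
         depth = as.integer(depth), seed = specs[[1]]$seed),
    class = "simulated_dataset"
  )
}

#' Spike one OTU's expected abundance before re-drawing counts
#'
#' Emulates the experimental overrepresentation of a cultured isolate in a
#' recolonization inoculum: the chosen OTU's expected relative abundance is
#' multiplied by `fold`, the fraction vectors are re-closed to the simplex,
#' and counts are re-drawn multinomially at the original depth.
#'
#' @param dataset A `simulated_dataset`.
#' @param otu OTU index (1-based) or id.
#' @param fold Positive multiplier of the focal OTU's expected fraction.
#' @param seed Seed for the multinomial re-draw; defaults to the dataset's
#'   own count-draw seed, so `fold = 1` reproduces the original counts.
#' @return A `simulated_dataset` with updated `fractions` and `counts`.
#' @export
spike_isolate <- function(dataset, otu, fold, seed = dataset$seed + 1L) {
  stopifnot(inherits(dataset, "simulated_dataset"), fold > 0)
  if (is.character(otu)) otu <- match(otu, colnames(dataset$counts))
  stopifnot(!is.na(otu), otu >= 1, otu <= ncol(dataset$counts))
  fr <- dataset$fractions
  fr[, otu] <- fr[, otu] * fold
  fr <- fr / rowSums(fr)
  counts <- draw_counts(fr, dataset$depth, seed = seed)
  dimnames(counts) <- dimnames(dataset$counts)
  out <- dataset
  out$fractions <- fr
  out$counts <- counts
  out
}

#' Convert a simulated dataset to an OTU table
#'
#' @param dataset A `simulated_dataset`.
#' @return An [otu_table()] carrying the stage labels as metadata.
#' @export
as_otu_table <- function(dataset) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  md <- NULL
  if (!is.null(dataset$stage)) {
    md <- tibble::tibble(sample_id = rownames(dataset$counts),
                         stage = dataset$stage)
  }
  otu_table(dataset$counts, metadata = md)
}

#' @export
print.simulated_dataset <- function(x, ...) {
  cat(sprintf("<simulated_dataset> %d samples x %d OTUs at depth %d\n",
              nrow(x$counts), ncol(x$counts), x$depth))
  invisible(x)
}

#' Write a simulated dataset to plain-text files
#'
#' Writes the counts as a classic OTU-table TSV, the ground-truth correlation
#' matrix (or matrices, for staged datasets) as square TSV, and a `key=value`
#' manifest recording the generator settings.
#'
#' @param dataset A `simulated_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "simulated_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_otu_table(as_otu_table(dataset), file.path(dir, "counts.tsv"))
  write_square <- function(m, path) {
    utils::write.table(
      data.frame(otu_id = colnames(dataset$counts), m, check.names = FALSE),
      path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (is.list(dataset$true_correlations)) {
    for (st in names(dataset$true_correlations)) {
      write_square(dataset$true_correlations[[st]],
                   file.path(dir, paste0("truth_", st, ".tsv")))
    }
  } else {
    write_square(dataset$true_correlations, file.path(dir, "truth.tsv"))
  }
  writeLines(
    c(paste0("n_otus=", ncol(dataset$counts)),
      paste0("n_samples=", nrow(dataset$counts)),
      paste0("depth=", dataset$depth),
      paste0("seed=", dataset$seed)),
    file.path(dir, "manifest.txt"))
  invisible(dir)
}
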