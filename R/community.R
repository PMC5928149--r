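#' Drop low-read OTUs
#'
#' Removes OTUs whose total read count across the whole dataset is below
#' `min_reads` — the conventional guard against spurious OTUs arising from
#' sequencing error. The sample set is unchanged.
#'
#' @param table An [otu_table()].
#' @param min_reads Minimum total reads for an OTU to be kept (default 50;
#'   the rule is strict: a 49-read OTU is dropped, a 50-read OTU kept).
#' @return A filtered [otu_table()].
#' @export
filter_low_read_otus <- function(table, min_reads = 50) {
  assert_otu_table(table)
  keep <- colSums(table$counts) >= min_reads
  if (!any(keep)) stop("filtering removed every OTU", call. = FALSE)
  otu_table(table$counts[, keep, drop = FALSE], metadata = table$metadata)
}

#' Rarefy samples to a common depth
#'
#' Subsamples exactly `depth` reads per sample without replacement
#' (hypergeometric); samples with fewer than `depth` total reads are dropped
#' with a warning.
#'
#' @param table An [otu_table()].
#' @param depth Target reads per sample (default 10,000).
#' @param seed Integer seed.
#' @return A rarefied [otu_table()].
#' @export
rarefy <- function(table, depth = 10000, seed = 1L) {
  assert_otu_table(table)
  tot <- rowSums(table$counts)
  drop <- tot < depth
  if (all(drop)) stop("every sample is below the rarefaction depth", call. = FALSE)
  if (any(drop)) {
    warning(sprintf("dropping %d sample(s) below depth %d: %s",
                    sum(drop), depth,
                    paste(table$sample_ids[drop], collapse = ", ")),
            call. = FALSE)
  }
  m <- table$counts[!drop, , drop = FALSE]
  # vegan warns on perfectly valid small-count inputs; preconditions are ours
  r <- withr::with_seed(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  md <- table$metadata
  if (!is.null(md)) md <- md[!drop, , drop = FALSE]
  otu_table(r, metadata = md)
}

# bias-corrected Chao1 point estimate for one integer count vector
chao1_estimate <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts)) stop("empty sample", call. = FALSE)
  s_obs <- length(counts)
  f1 <- sum(counts == 1)
  f2 <- sum(counts == 2)
  s_obs + f1 * (f1 - 1) / (2 * (f2 + 1))
}

#' Rarefaction-averaged Chao1 richness of one sample
#'
#' Bias-corrected Chao1, `S_obs + F1 (F1 - 1) / (2 (F2 + 1))`, averaged over
#' independent rarefactions of the sample at a fixed depth (richness
#' estimates are depth-dependent, so per-sample rarefaction replicates put
#' samples of unequal depth on a common footing).
#'
#' @param sample_counts Non-negative integer vector for one sample.
#' @param n_rarefaction_reps Rarefaction replicates to average (default 10).
#' @param depth Subsampling depth; `NULL` (default) disables rarefaction and
#'   evaluates the estimator on the raw counts.
#' @param seed Integer seed.
#' @return The (averaged) Chao1 estimate, always at least the observed
#'   richness.
#' @export
chao1 <- function(sample_counts, n_rarefaction_reps = 10, depth = NULL,
                  seed = 1L) {
  stopifnot(all(sample_counts >= 0))
  if (is.null(depth)) return(chao1_estimate(sample_counts))
  if (sum(sample_counts) < depth) {
    stop("sample has fewer reads than the rarefaction depth", call. = FALSE)
  }
  reps <- withr::with_seed(seed, {
    vapply(seq_len(n_rarefaction_reps), function(k) {
      sub <- suppressWarnings(
        vegan::rrarefy(matrix(sample_counts, nrow = 1), depth))[1, ]
      # estimateR implements the same bias-corrected form; S.chao1 row
      unname(vegan::estimateR(sub)["S.chao1"])
    }, numeric(1))
  })
  mean(reps)
}

#' Per-sample alpha-diversity report
#'
#' @param table An [otu_table()].
#' @param depth Rarefaction depth per replicate (default 10,000); samples
#'   below it are dropped by [rarefy()]'s rule.
#' @param n_rarefaction_reps Replicates per sample (default 10).
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `chao1`, joined with sample metadata when
#'   present.
#' @export
alpha_diversity <- function(table, depth = 10000, n_rarefaction_reps = 10,
                            seed = 1L) {
  assert_otu_table(table)
  keep <- rowSums(table$counts) >= depth
  if (!any(keep)) stop("every sample is below the rarefaction depth", call. = FALSE)
  seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, sum(keep)))
  out <- tibble::tibble(
    sample_id = table$sample_ids[keep],
    chao1 = vapply(seq_len(sum(keep)), function(i) {
      chao1(table$counts[which(keep)[i], ], n_rarefaction_reps, depth, seeds[i])
    }, numeric(1))
  )
  if (!is.null(table$metadata)) {
    out <- dplyr::left_join(out, table$metadata, by = "sample_id")
  }
  out
}

#' Bray-Curtis dissimilarity matrix
#'
#' `BC(u, v) = sum |u_i - v_i| / sum (u_i + v_i)` on (typically rarefied)
#' counts; 0 for identical samples, 1 for disjoint supports.
#'
#' @param table An [otu_table()] with at least 2 samples.
#' @return A symmetric samples x samples matrix with zero diagonal.
#' @export
bray_curtis <- function(table) {
  assert_otu_table(table)
  if (nrow(table$counts) < 2) stop("need at least 2 samples", call. = FALSE)
  as.matrix(vegan::vegdist(table$counts, method = "bray"))
}

#' Principal coordinates analysis of a distance matrix
#'
#' Classical metric scaling: double-centering of squared distances followed
#' by eigen-decomposition. Coordinates are returned for positive eigenvalues
#' only, sorted by decreasing eigenvalue; the explained fraction of each axis
#' is its eigenvalue over the sum of positive eigenvalues.
#'
#' @param distances Symmetric zero-diagonal matrix (or `dist`).
#' @return An object of class `pcoa_result`: list with `coordinates`
#'   (samples x k matrix), `explained` (length-k fractions, non-increasing),
#'   `eigenvalues`.
#' @export
pcoa <- function(distances) {
  m <- as.matrix(distances)
  if (!isSymmetric(unname(m), tol = 1e-8)) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  n <- nrow(m)
  # cmdscale warns when trailing eigenvalues are non-positive; the positive
  # subset is selected explicitly below
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(m), k = n - 1, eig = TRUE))
  eig <- fit$eig
  pos <- which(eig > max(eig, 0) * 1e-8 & eig > 1e-12)
  coords <- fit$points[, pos, drop = FALSE]
  if (length(pos)) {
    colnames(coords) <- paste0("PCo", seq_along(pos))
  }
  structure(
    list(coordinates = coords,
         explained = if (length(pos)) eig[pos] / sum(eig[pos]) else numeric(),
         eigenvalues = eig),
    class = "pcoa_result"
  )
}

#' @export
print.pcoa_result <- function(x, ...) {
  cat(sprintf("<pcoa_result> %d samples, %d positive axes\n",
              nrow(x$coordinates), ncol(x$coordinates)))
  if (ncol(x$coordinates)) {
    cat("explained:", paste(sprintf("%.1f%%", 100 * x$explained[seq_len(min(3, length(x$explained)))]),
                            collapse = ", "), "...\n")
  }
  invisible(x)
}

#' Tidy PCoA coordinates
#'
#' @param x A `pcoa_result`.
#' @param ... Unused.
#' @return A tibble with `sample_id` and one column per retained axis.
#' @export
tidy.pcoa_result <- function(x, ...) {
  tibble::as_tibble(x$coordinates, rownames = "sample_id")
}

#' PERMANOVA (ADONIS) on a distance matrix
#'
#' Partitions the total sum of squared distances among and within groups and
#' tests the among-group fraction (`R^2`) by permuting group labels
#' (pseudo-F). Backed by the standard distance-based permutational ANOVA;
#' the p-value is `(k + 1) / (n_perm + 1)`.
#'
#' @param distances Symmetric distance matrix (or `dist`).
#' @param grouping Factor-like vector, one label per sample, at least 2
#'   groups.
#' @param n_perm Number of permutations (default 999).
#' @param seed Integer seed.
#' @return An object of class `permanova_result`: list with `r2`, `p`,
#'   `f`, `n_perm`, and the underlying ANOVA `table`.
#' @export
permanova <- function(distances, grouping, n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 1)
  grouping <- as.factor(grouping)
  if (nlevels(droplevels(grouping)) < 2) {
    stop("need at least 2 groups", call. = FALSE)
  }
  d <- stats::as.dist(as.matrix(distances))
  df <- data.frame(group = grouping)
  tab <- withr::with_seed(seed, {
    vegan::adonis2(d ~ group, data = df, permutations = n_perm)
  })
  structure(
    list(r2 = tab$R2[1], p = tab$`Pr(>F)`[1], f = tab$F[1],
         n_perm = n_perm, table = tab),
    class = "permanova_result"
  )
}

#' @export
print.permanova_result <- function(x, ...) {
  cat(sprintf("<permanova> R2 = %.3f, F = %.2f, p = %.4g (%d permutations)\n",
              x$r2, x$f, x$p, x$n_perm))
  invisible(x)
}

#' One-row PERMANOVA summary
#'
#' @param x A `permanova_result`.
#' @param ... Unused.
#' @return Tibble with `r2`, `f`, `p`, `n_perm`.
#' @export
glance.permanova_result <- function(x, ...) {
  tibble::tibble(r2 = x$r2, f = x$f, p = x$p, n_perm = x$n_perm)
}

#' Fold change of a focal OTU between two communities
#'
#' Mean relative abundance of the OTU in the treatment table divided by its
#' mean relative abundance in the control table, each computed after
#' rarefaction, with a 1-read pseudocount added to the focal OTU in every
#' sample before closure so the ratio is always finite.
#'
#' @param treatment,control [otu_table()] objects sharing the focal OTU (it
#'   must be present in at least one).
#' @param otu_id Focal OTU id.
#' @param depth Rarefaction depth (default 10,000); `NULL` skips rarefaction.
#' @param seed Integer seed for rarefaction.
#' @param timepoint_label Optional label (e.g. `"3dpr"`) carried through.
#' @return A one-row tibble: `otu_id`, `fc`, `timepoint_label`,
#'   `mean_treatment`, `mean_control`.
#' @export
fold_change <- function(treatment, control, otu_id, depth = 10000, seed = 1L,
                        timepoint_label = NA_character_) {
  assert_otu_table(treatment)
  assert_otu_table(control)
  if (!otu_id %in% c(treatment$otu_ids, control$otu_ids)) {
    stop("focal OTU absent from both tables", call. = FALSE)
  }
  mean_rel <- function(tab, s) {
    if (!is.null(depth)) tab <- rarefy(tab, depth, seed = s)
    m <- tab$counts
    focal <- if (otu_id %in% colnames(m)) m[, otu_id] else rep(0L, nrow(m))
    mean((focal + 1) / (rowSums(m) + 1))
  }
  mt <- mean_rel(treatment, seed)
  mc <- mean_rel(control, seed + 1L)
  tibble::tibble(otu_id = otu_id, fc = mt / mc,
                 timepoint_label = timepoint_label,
                 mean_treatment = mt, mean_control = mc)
}
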