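#' Construct an interaction network from an edge tibble
#'
#' Public constructor for building a signed network directly from a link
#' table — e.g. when importing edges produced elsewhere, or when writing
#' validation graphs with known structure. Links are canonicalized so the
#' lower-ordered node comes first, and a `sign` column is derived from the
#' strength.
#'
#' @param nodes Ordered character vector: the node universe (isolated nodes
#'   allowed).
#' @param links Data frame with columns `from`, `to`, `strength`.
#' @param stage Optional stage label.
#' @param annotations Optional per-node tibble (`otu_id`, `lineage`,
#'   `median_reads`).
#' @return An `interaction_network`.
#' @examples
#' interaction_network(c("a", "b", "c"),
#'   tibble::tibble(from = "a", to = "b", strength = 0.7))
#' @export
interaction_network <- function(nodes, links, stage = NULL, annotations = NULL) {
  new_network(nodes, links, stage = stage, annotations = annotations)
}

#' Deterministic benchmark network with prescribed descriptors
#'
#' Builds a concrete signed graph realizing a prescribed descriptor profile:
#' total nodes `n`, `n_connected` linked nodes split into `n_sub` components,
#' `l_pos` positive links of common strength `m_pos` and `l_neg` negative
#' links of common strength `m_neg`. Useful for checking descriptor
#' arithmetic (density, signed proportions, mean degree, mean-correlation
#' identities) against published summary rows: the constructed network's
#' descriptor suite reproduces the prescription exactly.
#'
#' All but the first component are single links between node pairs; the first
#' component is a path over the remaining connected nodes plus deterministic
#' chords up to the prescribed link count.
#'
#' @param n Total nodes in the universe.
#' @param n_connected Number of nodes with at least one link.
#' @param n_sub Number of connected components with links.
#' @param l_pos,l_neg Counts of positive / negative links.
#' @param m_pos,m_neg Common strength of positive / negative links
#'   (defaults 0.6 / -0.6).
#' @return An `interaction_network` with `N = n`, `L = l_pos + l_neg`,
#'   `N_C = n_connected`, `n_sub` subnetworks, and the prescribed signed
#'   link counts and means.
#' @export
synthetic_benchmark_network <- function(n, n_connected, n_sub, l_pos, l_neg,
                                        m_pos = 0.6, m_neg = -0.6) {
  l <- l_pos + l_neg
  stopifnot(n_sub >= 1, n_connected >= 2 * n_sub, n >= n_connected, l >= n_sub)
  n1 <- n_connected - 2L * (n_sub - 1L)
  l1 <- l - (n_sub - 1L)
  if (l1 < n1 - 1 || l1 > n1 * (n1 - 1) / 2) {
    stop("prescription is not realizable by this constructor", call. = FALSE)
  }
  nodes <- sprintf("n%02d", seq_len(n))
  big <- nodes[seq_len(n1)]
  edges <- data.frame(from = big[-n1], to = big[-1])         # path
  extra <- l1 - (n1 - 1)
  if (extra > 0) {
    # chords in a fixed scan order, skipping path edges
    cand <- which(upper.tri(matrix(0, n1, n1)), arr.ind = TRUE)
    cand <- cand[cand[, 2] - cand[, 1] > 1, , drop = FALSE]
    stopifnot(nrow(cand) >= extra)
    edges <- rbind(edges, data.frame(from = big[cand[seq_len(extra), 1]],
                                     to = big[cand[seq_len(extra), 2]]))
  }
  for (k in seq_len(n_sub - 1)) {
    pair <- nodes[n1 + 2 * k - c(1, 0)]
    edges <- rbind(edges, data.frame(from = pair[1], to = pair[2]))
  }
  stopifnot(nrow(edges) == l)
  edges$strength <- c(rep(m_pos, l_pos), rep(m_neg, l_neg))
  interaction_network(nodes, edges)
}

#' Benchmark network realizing prescribed signed node degrees
#'
#' Builds a graph in which each focal node has exactly the requested numbers
#' of positive and negative links, attached to fresh auxiliary leaf nodes —
#' the minimal structure for validating role classification against a
#' published table of per-isolate link counts.
#'
#' @param role_spec Data frame with columns `otu_id`, `pos`, `neg`.
#' @param strength_pos,strength_neg Link strengths used (defaults 0.6 / -0.6).
#' @return An `interaction_network` whose focal nodes carry the prescribed
#'   signed degrees.
#' @export
synthetic_role_network <- function(role_spec, strength_pos = 0.6,
                                   strength_neg = -0.6) {
  role_spec <- tibble::as_tibble(role_spec)
  stopifnot(all(c("otu_id", "pos", "neg") %in% names(role_spec)))
  links <- NULL
  aux <- character()
  k <- 0L
  for (i in seq_len(nrow(role_spec))) {
    for (s in c("pos", "neg")) {
      cnt <- role_spec[[s]][i]
      if (cnt > 0) {
        leaves <- sprintf("aux%03d", k + seq_len(cnt))
        k <- k + cnt
        aux <- c(aux, leaves)
        links <- rbind(links, data.frame(
          from = role_spec$otu_id[i], to = leaves,
          strength = if (s == "pos") strength_pos else strength_neg))
      }
    }
  }
  interaction_network(c(role_spec$otu_id, aux),
                      links %||% tibble::tibble(from = character(),
                                                to = character(),
                                                strength = numeric()))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
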