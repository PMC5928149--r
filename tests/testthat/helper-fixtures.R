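# small deterministic fixtures shared across test files

toy_counts <- function(n = 4, d = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n * d, 60), n, d,
                dimnames = list(paste0("S", seq_len(n)),
                                paste0("OTU_", seq_len(d))))
    m
  })
}

toy_table <- function(...) otu_table(toy_counts(...))

# independent brute-force descriptor oracle: plain loops, no igraph
oracle_descriptors <- function(nodes, links) {
  n <- length(nodes)
  l <- nrow(links)
  deg <- setNames(numeric(n), nodes)
  for (k in seq_len(l)) {
    deg[links$from[k]] <- deg[links$from[k]] + 1
    deg[links$to[k]] <- deg[links$to[k]] + 1
  }
  # connected components by label propagation over the edge list
  comp <- setNames(seq_len(n), nodes)
  repeat {
    changed <- FALSE
    for (k in seq_len(l)) {
      a <- links$from[k]; b <- links$to[k]
      m <- min(comp[a], comp[b])
      if (comp[a] != m || comp[b] != m) {
        comp[a] <- comp[b] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  sizes <- table(comp)
  pos <- links$strength > 0
  list(
    n_nodes = n,
    n_links = l,
    n_connected = sum(deg > 0),
    l_max = n * (n - 1) / 2,
    density = if (n > 1) l / (n * (n - 1) / 2) else 0,
    n_pos = sum(pos),
    n_neg = sum(!pos),
    prop_pos = if (l > 0) sum(pos) / l else NA_real_,
    prop_neg = if (l > 0) sum(!pos) / l else NA_real_,
    mean_total = if (l > 0) mean(links$strength) else NA_real_,
    mean_pos = if (any(pos)) mean(links$strength[pos]) else NA_real_,
    mean_neg = if (any(!pos)) mean(links$strength[!pos]) else NA_real_,
    n_subnetworks = sum(sizes >= 2),
    mean_degree = if (any(deg > 0)) 2 * l / sum(deg > 0) else 0,
    max_degree = if (any(deg > 0)) max(deg) else 0,
    max_degree_nodes = if (any(deg > 0)) sort(names(deg)[deg == max(deg)])
                       else character()
  )
}

random_signed_graph <- function(seed, max_nodes = 12) {
  withr::with_seed(seed, {
    n <- sample(2:max_nodes, 1)
    nodes <- sprintf("v%02d", seq_len(n))
    pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    l <- sample(0:nrow(pairs), 1)
    take <- if (l > 0) sample(nrow(pairs), l) else integer()
    links <- tibble::tibble(
      from = nodes[pairs[take, 1]],
      to = nodes[pairs[take, 2]],
      strength = round(runif(l, -1, 1), 3)
    )
    links <- links[links$strength != 0, ]
    list(nodes = nodes, links = links)
  })
}
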