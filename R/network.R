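#' Build a signed interaction network from a correlation fit
#'
#' A pair becomes a link iff its pseudo p-value is at most `p_threshold`
#' (inclusive) and its absolute correlation strictly exceeds `r_threshold`.
#' The node universe is preserved even for isolated nodes, so per-stage
#' networks built on a shared universe are directly comparable.
#'
#' @param fit A `sparcc_fit` with pseudo p-values ([pseudo_pvalues()]).
#' @param p_threshold Significance cut-off, inclusive (default 0.05).
#' @param r_threshold Strength cut-off on `|rho|`, strict (default 0.5).
#' @param nodes Optional fixed node universe (character); defaults to the
#'   fit's OTU ids. Must contain every OTU of the fit.
#' @param stage Optional stage label carried on the network.
#' @param annotations Optional tibble with columns `otu_id` and any of
#'   `lineage`, `median_reads`, attached per node.
#' @return An object of class `interaction_network`: list with `nodes`
#'   (ordered character vector), `links` (tibble `from`, `to`, `strength`,
#'   `sign`, with `from < to` in node order), `stage`, `annotations`.
#' @export
build_network <- function(fit, p_threshold = 0.05, r_threshold = 0.5,
                          nodes = NULL, stage = NULL, annotations = NULL) {
  stopifnot(inherits(fit, "sparcc_fit"))
  if (is.null(fit$pvals)) {
    stop("fit has no pseudo p-values; run pseudo_pvalues() first", call. = FALSE)
  }
  ids <- fit$otu_ids
  if (is.null(nodes)) nodes <- ids
  if (!all(ids %in% nodes)) stop("node universe must contain all fitted OTUs",
                                 call. = FALSE)
  idx <- which(upper.tri(fit$rho), arr.ind = TRUE)
  keep <- fit$pvals[idx] <= p_threshold & abs(fit$rho[idx]) > r_threshold
  links <- tibble::tibble(
    from = ids[idx[keep, 1]],
    to = ids[idx[keep, 2]],
    strength = fit$rho[idx[keep, , drop = FALSE]]
  )
  new_network(nodes, links, stage = stage, annotations = annotations)
}

# canonicalizes links (from < to in node order, sign column) and validates
new_network <- function(nodes, links, stage = NULL, annotations = NULL) {
  nodes <- as.character(nodes)
  if (anyDuplicated(nodes)) stop("duplicate nodes in universe", call. = FALSE)
  links <- tibble::as_tibble(links)
  if (nrow(links)) {
    if (!all(c(links$from, links$to) %in% nodes)) {
      stop("link endpoint outside the node universe", call. = FALSE)
    }
    if (any(links$from == links$to)) stop("self-links are not allowed", call. = FALSE)
    oi <- match(links$from, nodes)
    oj <- match(links$to, nodes)
    swap <- oi > oj
    tmp <- links$from[swap]
    links$from[swap] <- links$to[swap]
    links$to[swap] <- tmp
    links <- dplyr::arrange(links, match(.data$from, nodes), match(.data$to, nodes))
    if (anyDuplicated(paste(links$from, links$to))) {
      stop("duplicate links", call. = FALSE)
    }
    links$sign <- ifelse(links$strength > 0, "positive", "negative")
  } else {
    links <- tibble::tibble(from = character(), to = character(),
                            strength = numeric(), sign = character())
  }
  if (!is.null(annotations)) {
    annotations <- tibble::as_tibble(annotations)
    stopifnot("otu_id" %in% names(annotations))
  }
  structure(
    list(nodes = nodes, links = links, stage = stage, annotations = annotations),
    class = "interaction_network"
  )
}

#' @export
print.interaction_network <- function(x, ...) {
  cat(sprintf(
    "<interaction_network%s> N = %d nodes, L = %d links (%d +, %d -)\n",
    if (is.null(x$stage)) "" else paste0(": ", x$stage),
    length(x$nodes), nrow(x$links),
    sum(x$links$sign == "positive"), sum(x$links$sign == "negative")))
  invisible(x)
}

#' Union node set of several networks
#'
#' Collects every OTU incident to at least one link in any of the input
#' networks — the shared universe on which comparable per-stage networks are
#' drawn. With annotations the ordering is by taxonomy then descending median
#' reads (ties broken by OTU id); otherwise lexicographic.
#'
#' @param networks List of `interaction_network` objects.
#' @param annotations Optional tibble (`otu_id`, `lineage`, `median_reads`)
#'   used for ordering.
#' @return Ordered character vector of OTU ids.
#' @export
union_node_set <- function(networks, annotations = NULL) {
  stopifnot(length(networks) >= 1)
  linked <- unique(unlist(lapply(networks, function(nw) {
    c(nw$links$from, nw$links$to)
  })))
  if (is.null(annotations)) return(sort(linked))
  ann <- tibble::as_tibble(annotations)
  ann <- ann[match(linked, ann$otu_id), ]
  lin <- if ("lineage" %in% names(ann)) ann$lineage else ""
  reads <- if ("median_reads" %in% names(ann)) ann$median_reads else 0
  linked[order(lin, -xtfrm(reads), linked)]
}

#' Re-express a network on a fixed node universe
#'
#' Replaces the node list by `universe` (adding isolated nodes, never dropping
#' links) so that stage-specific networks share an identical, ordered node
#' set.
#'
#' @param network An `interaction_network`.
#' @param universe Character vector containing every linked node of `network`.
#' @return An `interaction_network` on `universe`.
#' @export
restrict_to_universe <- function(network, universe) {
  linked <- unique(c(network$links$from, network$links$to))
  if (!all(linked %in% universe)) {
    stop("universe is missing linked nodes", call. = FALSE)
  }
  new_network(universe, network$links, stage = network$stage,
              annotations = network$annotations)
}

#' Links shared between stage networks
#'
#' @param networks Named list of `interaction_network` objects on a common
#'   universe.
#' @return A tibble of links present in at least two networks: `from`, `to`,
#'   `stages` (comma-separated), `n_stages`.
#' @export
shared_links <- function(networks) {
  stopifnot(length(networks) >= 2, !is.null(names(networks)))
  uni <- networks[[1]]$nodes
  if (!all(vapply(networks, function(nw) identical(nw$nodes, uni), logical(1)))) {
    stop("networks must share a node universe", call. = FALSE)
  }
  all_links <- purrr::imap_dfr(networks, function(nw, st) {
    dplyr::mutate(nw$links[c("from", "to")], stage = st)
  })
  out <- all_links |>
    dplyr::group_by(.data$from, .data$to) |>
    dplyr::summarise(stages = paste(.data$stage, collapse = ","),
                     n_stages = dplyr::n(), .groups = "drop") |>
    dplyr::filter(.data$n_stages >= 2)
  out
}

#' Convert a network to an igraph object
#'
#' @param network An `interaction_network`.
#' @return An undirected [igraph::graph] with `strength` and `sign` edge
#'   attributes; isolated nodes retained.
#' @export
as_igraph <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  igraph::graph_from_data_frame(
    as.data.frame(network$links),
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
}

#' Read / write a network edge list
#'
#' The TSV edge-list dialect has columns `source`, `target`, `strength`,
#' `sign`; a companion node-table TSV (`write_node_table()`) records the full
#' universe so isolated nodes survive a round trip.
#'
#' @param network An `interaction_network`.
#' @param path File path.
#' @return `write_edge_list()` returns `path` invisibly; `read_edge_list()`
#'   returns an `interaction_network`.
#' @export
write_edge_list <- function(network, path) {
  df <- data.frame(source = network$links$from, target = network$links$to,
                   strength = format(network$links$strength, digits = 17),
                   sign = network$links$sign)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @param nodes Optional universe for the read-back network; defaults to the
#'   nodes present in the edge list.
#' @export
read_edge_list <- function(path, nodes = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c(source = "character",
                                         target = "character",
                                         strength = "character",
                                         sign = "character"))
  links <- tibble::tibble(from = df$source, to = df$target,
                          strength = as.numeric(df$strength))
  if (is.null(nodes)) nodes <- sort(unique(c(links$from, links$to)))
  new_network(nodes, links)
}

#' @rdname write_edge_list
#' @export
write_node_table <- function(network, path) {
  deg <- node_degrees(network)
  df <- data.frame(id = network$nodes, degree = deg$degree,
                   stage = if (is.null(network$stage)) NA else network$stage)
  if (!is.null(network$annotations)) {
    df <- merge(df, as.data.frame(network$annotations),
                by.x = "id", by.y = "otu_id", all.x = TRUE, sort = FALSE)
    df <- df[match(network$nodes, df$id), ]
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(network, path) {
  g <- as_igraph(network)
  if (!is.null(network$annotations)) {
    ann <- network$annotations[match(network$nodes, network$annotations$otu_id), ]
    for (col in setdiff(names(ann), "otu_id")) {
      g <- igraph::set_vertex_attr(g, col, value = ann[[col]])
    }
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Link counts across a sweep of strength cut-offs
#'
#' Sensitivity helper: the subnetwork structure of thresholded co-occurrence
#' graphs can be an artifact of the chosen cut-off, so this reports how the
#' link count decays as the threshold rises.
#'
#' @param fit A `sparcc_fit` with p-values.
#' @param r_thresholds Numeric vector of strength cut-offs.
#' @param p_threshold Significance cut-off (default 0.05).
#' @return A tibble with `r_threshold`, `n_links`, `n_pos`, `n_neg`.
#' @export
threshold_sweep <- function(fit, r_thresholds = seq(0.3, 0.8, by = 0.05),
                            p_threshold = 0.05) {
  purrr::map_dfr(r_thresholds, function(r) {
    nw <- build_network(fit, p_threshold = p_threshold, r_threshold = r)
    tibble::tibble(r_threshold = r, n_links = nrow(nw$links),
                   n_pos = sum(nw$links$sign == "positive"),
                   n_neg = sum(nw$links$sign == "negative"))
  })
}

#' Tidy a network into its link tibble
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return The links tibble (`from`, `to`, `strength`, `sign`).
#' @export
tidy.interaction_network <- function(x, ...) x$links
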