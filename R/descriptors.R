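# signed degrees per node, in universe order
node_degrees <- function(network) {
  nodes <- network$nodes
  pos <- neg <- stats::setNames(integer(length(nodes)), nodes)
  lk <- network$links
  if (nrow(lk)) {
    for (s in c("positive", "negative")) {
      ends <- c(lk$from[lk$sign == s], lk$to[lk$sign == s])
      tb <- table(factor(ends, levels = nodes))
      if (s == "positive") pos <- pos + as.integer(tb) else neg <- neg + as.integer(tb)
    }
  }
  tibble::tibble(otu_id = nodes, degree_pos = as.integer(pos),
                 degree_neg = as.integer(neg),
                 degree = as.integer(pos + neg))
}

#' Compute the descriptor suite of a signed network
#'
#' All classical descriptors of a thresholded co-occurrence graph: size `N`,
#' links `L`, connected nodes `N_C`, density `D = L / (N (N - 1) / 2)`,
#' signed link counts and proportions (`L_P`, `L_N`, `%L_P`, `%L_N`), mean
#' correlation over all / positive / negative links (`m_t`, `m_p`, `m_n`),
#' number of subnetworks (connected components with at least one link),
#' mean degree over connected nodes (`2 L / N_C`), and the maximum degree
#' with the node(s) attaining it.
#'
#' @param network An `interaction_network`.
#' @return An object of class `network_descriptors` (a named list, full
#'   precision); see [tidy.network_descriptors()] for the tabular form.
#' @details `m_p` / `m_n` are `NA` when the corresponding link class is
#'   empty. Mean degree uses connected nodes as the denominator — the only
#'   reading consistent with reporting both a fixed universe `N` and a
#'   per-stage `N_C`. Isolated nodes are not subnetworks.
#' @examples
#' nw <- microcooc:::new_network(
#'   letters[1:5],
#'   tibble::tibble(from = c("a", "b"), to = c("b", "c"),
#'                  strength = c(0.7, -0.6)))
#' tidy(compute_descriptors(nw))
#' @export
compute_descriptors <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  n <- length(network$nodes)
  lk <- network$links
  l <- nrow(lk)
  deg <- node_degrees(network)
  n_c <- sum(deg$degree > 0)
  l_max <- n * (n - 1) / 2
  l_p <- sum(lk$sign == "positive")
  l_n <- sum(lk$sign == "negative")
  g <- as_igraph(network)
  comp <- igraph::components(g)
  n_sub <- sum(comp$csize >= 2)
  d_max <- if (n_c > 0) max(deg$degree) else 0L
  structure(
    list(
      n_nodes = n, n_links = l, n_connected = n_c, l_max = l_max,
      density = if (l_max > 0) l / l_max else 0,
      n_pos = l_p, n_neg = l_n,
      prop_pos = if (l > 0) l_p / l else NA_real_,
      prop_neg = if (l > 0) l_n / l else NA_real_,
      mean_total = if (l > 0) mean(lk$strength) else NA_real_,
      mean_pos = if (l_p > 0) mean(lk$strength[lk$sign == "positive"]) else NA_real_,
      mean_neg = if (l_n > 0) mean(lk$strength[lk$sign == "negative"]) else NA_real_,
      n_subnetworks = n_sub,
      mean_degree = if (n_c > 0) 2 * l / n_c else 0,
      max_degree = d_max,
      max_degree_nodes = if (d_max > 0) deg$otu_id[deg$degree == d_max] else character()
    ),
    class = "network_descriptors"
  )
}

#' @export
print.network_descriptors <- function(x, ...) {
  print(tidy(x), n = Inf)
  invisible(x)
}

# presentation rounding: half away from zero at `digits` decimals
round_half_up <- function(x, digits = 3) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

descriptor_order <- c(
  "n_nodes", "n_links", "n_connected", "l_max", "density", "n_pos", "n_neg",
  "prop_pos", "prop_neg", "mean_total", "mean_pos", "mean_neg",
  "n_subnetworks", "mean_degree", "max_degree", "max_degree_nodes"
)

#' Tidy network descriptors
#'
#' @param x A `network_descriptors` object.
#' @param ... Unused.
#' @return A tibble with columns `descriptor` and `value` (full precision;
#'   `max_degree_nodes` collapsed to a comma-separated string in a separate
#'   `label` column).
#' @export
tidy.network_descriptors <- function(x, ...) {
  vals <- vapply(descriptor_order[descriptor_order != "max_degree_nodes"],
                 function(k) as.numeric(x[[k]]), numeric(1))
  tibble::tibble(
    descriptor = c(names(vals), "max_degree_nodes"),
    value = c(unname(vals), NA_real_),
    label = c(rep(NA_character_, length(vals)),
              paste(x$max_degree_nodes, collapse = ", "))
  )
}

#' One-row descriptor summary of a network
#'
#' @param x An `interaction_network`.
#' @param ... Unused.
#' @return A one-row tibble of the numeric descriptors.
#' @export
glance.interaction_network <- function(x, ...) {
  d <- compute_descriptors(x)
  tibble::as_tibble(d[descriptor_order[descriptor_order != "max_degree_nodes"]])
}

#' Side-by-side descriptor report for several networks
#'
#' @param networks Named list of `interaction_network` objects (e.g. whole
#'   development plus the three stages).
#' @param digits Decimal places for real-valued rows (default 3, half away
#'   from zero, presentation only).
#' @return A tibble with a `descriptor` column and one character column per
#'   network, rows in the canonical report order.
#' @export
descriptor_table <- function(networks, digits = 3) {
  stopifnot(length(networks) >= 1, !is.null(names(networks)))
  cols <- purrr::map(networks, function(nw) {
    d <- compute_descriptors(nw)
    unname(vapply(descriptor_order, function(k) {
      v <- d[[k]]
      if (k == "max_degree_nodes") return(paste(v, collapse = ", "))
      if (is.na(v)) return("-")
      if (k %in% c("density", "prop_pos", "prop_neg", "mean_total",
                   "mean_pos", "mean_neg", "mean_degree")) {
        return(formatC(round_half_up(v, digits), format = "f", digits = digits))
      }
      format(v)
    }, character(1)))
  })
  dplyr::bind_cols(tibble::tibble(descriptor = descriptor_order),
                   tibble::as_tibble(cols))
}

#' Classify nodes into ecological roles
#'
#' A node with mostly negative links is a candidate competitor, one with
#' mostly positive links a cooperator; unlinked nodes are neutral and exact
#' sign ties are labelled mixed rather than silently resolved. Hubs are the
#' nodes attaining the maximum degree (ties allowed).
#'
#' @param network An `interaction_network`.
#' @return A tibble with one row per node: `otu_id`, `degree`, `degree_pos`,
#'   `degree_neg`, `role` (one of `"competitive"`, `"cooperative"`,
#'   `"mixed"`, `"neutral"`), `is_hub`.
#' @export
classify_roles <- function(network) {
  stopifnot(inherits(network, "interaction_network"))
  deg <- node_degrees(network)
  d_max <- if (nrow(deg)) max(deg$degree) else 0L
  deg |>
    dplyr::mutate(
      role = dplyr::case_when(
        .data$degree == 0L ~ "neutral",
        .data$degree_neg > .data$degree_pos ~ "competitive",
        .data$degree_pos > .data$degree_neg ~ "cooperative",
        TRUE ~ "mixed"
      ),
      is_hub = .data$degree == d_max & d_max > 0L
    )
}
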