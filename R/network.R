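#' Build the unweighted, unipartite co-occurrence network
#'
#' One node per species appearing in any co-occurring pair, one edge per
#' pair; the graph is simple (duplicate pairs in either order collapse to a
#' single edge, self-pairs are rejected). Species present in the occurrence
#' matrix but sharing no site with any other species are recorded as
#' isolated: they take no part in module detection and are excluded (with an
#' audit trail) from partition comparisons.
#'
#' @param edges Edge tibble from [build_edge_list()] (or any data frame whose
#'   first two columns are species ids).
#' @param species Optional full species list; entries absent from `edges`
#'   are recorded as isolated.
#' @return A `poolnet_network`: list with `graph` (an [igraph][igraph::igraph-package]
#'   object) and `isolated` (character vector).
#' @export
build_network <- function(edges, species = NULL) {
  if (!is.data.frame(edges) || nrow(edges) == 0L) {
    stop_degenerate("empty edge list: cannot build a network")
  }
  a <- as.character(edges[[1L]])
  b <- as.character(edges[[2L]])
  if (any(a == b)) stop_domain("self-pairs are not allowed in a co-occurrence network")
  g <- igraph::graph_from_data_frame(data.frame(a, b), directed = FALSE)
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  isolated <- character(0)
  if (!is.null(species)) {
    isolated <- setdiff(species, igraph::V(g)$name)
  }
  structure(list(graph = g, isolated = isolated), class = "poolnet_network")
}

#' @export
print.poolnet_network <- function(x, ...) {
  cat(sprintf(
    "<poolnet_network: %d species, %d edges, %d isolated>\n",
    igraph::vcount(x$graph), igraph::ecount(x$graph), length(x$isolated)
  ))
  invisible(x)
}

as_igraph <- function(net) {
  if (inherits(net, "poolnet_network")) net$graph else net
}

#' Newman-Girvan modularity of a partition
#'
#' \deqn{Q = \sum_c \left[ L_c/m - (D_c/2m)^2 \right]}
#' where `m` is the total edge count, `L_c` the number of edges inside group
#' `c` and `D_c` the summed degree of its members. `Q = 0` for the trivial
#' single-group partition; `Q` is invariant to group relabelling.
#'
#' @param net A `poolnet_network` or igraph graph.
#' @param partition A partition covering every node of the graph (see
#'   [as_partition()]).
#' @return Modularity score in `[-0.5, 1]`.
#' @export
#'
#' @examples
#' el <- data.frame(a = c("A", "B", "C"), b = c("B", "C", "A"))
#' net <- build_network(el)
#' modularity_score(net, c(A = 1, B = 1, C = 1))  # 0
modularity_score <- function(net, partition) {
  g <- as_igraph(net)
  p <- as_partition(partition)
  nodes <- igraph::V(g)$name
  if (!all(nodes %in% names(p))) {
    stop_domain(sprintf(
      "partition misses %d network node(s): %s",
      sum(!nodes %in% names(p)),
      paste(head(setdiff(nodes, names(p)), 5L), collapse = ", ")
    ))
  }
  m <- igraph::ecount(g)
  if (m == 0L) stop_degenerate("graph has no edges")
  labels <- unclass(p)[nodes]
  ends <- igraph::ends(g, igraph::E(g), names = TRUE)
  within <- labels[ends[, 1L]] == labels[ends[, 2L]]
  deg <- igraph::degree(g)
  l_c <- tapply(rep(1L, m)[within], labels[ends[within, 1L]], sum)
  d_c <- tapply(deg, labels, sum)
  l_full <- stats::setNames(numeric(length(d_c)), names(d_c))
  l_full[names(l_c)] <- l_c
  sum(l_full / m - (d_c / (2 * m))^2)
}

#' Detect network modules by simulated annealing
#'
#' Partitions the network into modules by a spin-glass simulated-annealing
#' search that maximises Newman-Girvan modularity (Potts model at
#' `gamma = 1`, no negative-link term, matching the unweighted co-occurrence
#' graphs this package builds). Defaults follow common practice for fish
#' co-occurrence networks: 100 spins, start temperature 1, stop temperature
#' 0.01, cooling factor 0.99. The annealing search is stochastic; the result
#' is deterministic given `seed`. Optionally the search is restarted
#' `restarts` times and the highest-modularity solution kept.
#'
#' Spin-glass annealing requires a connected graph; disconnected networks
#' are handled by running the search per connected component and offsetting
#' the labels, so every (non-isolated) species receives exactly one label.
#'
#' @param net A `poolnet_network` or igraph graph.
#' @param spins Maximum number of modules the search may use.
#' @param start_temp,stop_temp,cooling Annealing schedule.
#' @param gamma Resolution parameter of the Potts Hamiltonian.
#' @param restarts Number of annealing runs; the best modularity wins.
#' @param seed Integer seed making the run reproducible (`NULL` leaves the
#'   RNG state alone).
#' @return A `poolnet_modules` object: list with `partition` (source
#'   `"module"`), `q` (modularity of the returned partition on the full
#'   graph), `k`, `n_components`, `params` and `seed`.
#' @export
detect_modules <- function(net, spins = 100, start_temp = 1, stop_temp = 0.01,
                           cooling = 0.99, gamma = 1, restarts = 1, seed = NULL) {
  g <- as_igraph(net)
  if (igraph::vcount(g) == 0L) stop_degenerate("empty network")
  restarts <- check_count(restarts, "restarts", min = 1L)
  with_seed(seed, {
    comps <- igraph::components(g)
    membership <- integer(igraph::vcount(g))
    names(membership) <- igraph::V(g)$name
    offset <- 0L
    for (comp in seq_len(comps$no)) {
      nodes <- names(comps$membership)[comps$membership == comp]
      sub <- igraph::induced_subgraph(g, nodes)
      if (length(nodes) == 1L || igraph::ecount(sub) == 0L) {
        membership[nodes] <- offset + 1L
        offset <- offset + 1L
        next
      }
      best <- NULL
      for (r in seq_len(restarts)) {
        sg <- igraph::cluster_spinglass(
          sub,
          spins = spins, start.temp = start_temp, stop.temp = stop_temp,
          cool.fact = cooling, gamma = gamma, update.rule = "config"
        )
        if (is.null(best) || sg$modularity > best$modularity) best <- sg
      }
      memb <- igraph::membership(best)
      memb <- as.integer(factor(memb))  # compact labels 1..k_comp
      membership[nodes] <- offset + memb
      offset <- offset + max(memb)
    }
    partition <- as_partition(membership, source = "module")
    structure(list(
      partition = partition,
      q = modularity_score(g, partition),
      k = n_groups(partition),
      n_components = as.integer(comps$no),
      params = list(
        spins = spins, start_temp = start_temp, stop_temp = stop_temp,
        cooling = cooling, gamma = gamma, restarts = restarts
      ),
      seed = seed
    ), class = "poolnet_modules")
  })
}

#' @export
print.poolnet_modules <- function(x, ...) {
  cat(sprintf(
    "<poolnet_modules: %d modules over %d species, Q = %.4f (%d component(s))>\n",
    x$k, length(x$partition), x$q, x$n_components
  ))
  invisible(x)
}

#' @describeIn detect_modules Per-species module membership as a tibble.
#' @param x A `poolnet_modules` object.
#' @param ... Unused.
#' @export
tidy.poolnet_modules <- function(x, ...) tidy(x$partition)

#' @describeIn detect_modules One-row summary (k, Q, components, seed).
#' @export
glance.poolnet_modules <- function(x, ...) {
  tibble::tibble(
    k = x$k, q = x$q, n_species = length(x$partition),
    n_components = x$n_components, seed = x$seed %||% NA_integer_
  )
}

#' Export a network to GraphML or edge-list CSV
#'
#' @param net A `poolnet_network`.
#' @param path Output path.
#' @param format `"graphml"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, format = c("graphml", "csv")) {
  format <- match.arg(format)
  g <- as_igraph(net)
  if (format == "graphml") {
    igraph::write_graph(g, path, format = "graphml")
  } else {
    ends <- igraph::as_data_frame(g, what = "edges")
    readr::write_csv(tibble::as_tibble(ends), path)
  }
  invisible(path)
}
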