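#' Declare a host + associate complex
#'
#' A nest-associate complex is a host species (e.g. a nest-building chub)
#' plus the associate species known to spawn in its nests. The complex is an
#' empirical benchmark: if network modules (or clusters) capture positive
#' interspecific relationships, the complex should end up in a single group
#' with its host.
#'
#' @param host Host species id.
#' @param associates Character vector of associate species ids (>= 1).
#' @return A `poolnet_complex` object.
#' @export
#'
#' @examples
#' nest_complex("bluehead_chub", c("rosyside_dace", "white_shiner"))
nest_complex <- function(host, associates) {
  if (length(host) != 1L || !nzchar(host)) stop_domain("`host` must be a single species id")
  if (length(associates) < 1L) stop_domain("at least one associate is required")
  if (anyDuplicated(associates)) stop_domain("duplicate associate ids")
  if (host %in% associates) stop_domain("the host cannot be its own associate")
  structure(list(host = host, associates = as.character(associates)),
            class = "poolnet_complex")
}

#' @export
print.poolnet_complex <- function(x, ...) {
  cat(sprintf("<poolnet_complex: host %s + %d associates>\n",
              x$host, length(x$associates)))
  invisible(x)
}

#' Completeness of a complex under a partition
#'
#' The proportion of a host's associates assigned to the same group as the
#' host. Associates absent from the partition (e.g. isolated network nodes)
#' count as not co-grouped; associates absent from the species `pool`
#' altogether (never observed in the basin) are dropped from the denominator
#' when a `pool` is supplied, since the complex can only be evaluated over
#' species the basin contains.
#'
#' @param partition A partition containing the host.
#' @param complex A [nest_complex()].
#' @param pool Optional character vector of all species observed in the
#'   basin (e.g. `species_ids(occ)`).
#' @return Completeness in `[0, 1]` with attributes `n_present` and
#'   `n_associates`.
#' @export
completeness <- function(partition, complex, pool = NULL) {
  p <- as_partition(partition)
  if (!inherits(complex, "poolnet_complex")) stop_domain("`complex` must be a nest_complex()")
  if (!complex$host %in% names(p)) {
    stop_domain(sprintf("host '%s' is not in the partition", complex$host))
  }
  assoc <- complex$associates
  if (!is.null(pool)) {
    absent <- setdiff(assoc, pool)
    if (length(absent) > 0L) {
      rlang::inform(sprintf("%d associate(s) absent from the species pool dropped from the denominator: %s",
                            length(absent), paste(absent, collapse = ", ")))
      assoc <- intersect(assoc, pool)
    }
    if (length(assoc) == 0L) stop_domain("no associates present in the species pool")
  }
  unpartitioned <- setdiff(assoc, names(p))
  if (length(unpartitioned) > 0L) {
    rlang::inform(sprintf("%d associate(s) not in the partition count as not co-grouped: %s",
                          length(unpartitioned), paste(unpartitioned, collapse = ", ")))
  }
  host_group <- unclass(p)[[complex$host]]
  in_group <- assoc[assoc %in% names(p)]
  n_present <- sum(unclass(p)[in_group] == host_group)
  structure(n_present / length(assoc),
            n_present = n_present, n_associates = length(assoc))
}

#' Contrast complex effect sizes with network-wide effect sizes
#'
#' Summarises the probabilistic co-occurrence effect sizes over four pair
#' sets: the host-associate pairs of the complex, all within-group pairs,
#' all among-group pairs, and all pairs of the network. Within- and
#' among-group pairs partition the network's pair set. Standard deviations
#' use the sample (n-1) form.
#'
#' @param effects Effect table from [effect_size_table()].
#' @param net A `poolnet_network` (defines the node set).
#' @param partition A partition covering the network's nodes.
#' @param complex A [nest_complex()].
#' @return A `poolnet_contrast` object: tibble with one row per pair set
#'   (`pair_set`, `n_pairs`, `mean_effect`, `sd_effect`).
#' @export
effect_contrast <- function(effects, net, partition, complex) {
  p <- as_partition(partition)
  nodes <- igraph::V(as_igraph(net))$name
  if (!all(nodes %in% names(p))) stop_domain("partition must cover all network nodes")
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  eff <- effects[effects$species_a %in% nodes & effects$species_b %in% nodes, ]
  if (nrow(eff) < choose(length(nodes), 2L)) {
    stop_domain("effect table does not cover all pairs of the network's nodes")
  }
  same <- unclass(p)[eff$species_a] == unclass(p)[eff$species_b]

  complex_keys <- key(complex$host, complex$associates)
  is_complex <- key(eff$species_a, eff$species_b) %in% complex_keys
  if (sum(is_complex) < length(complex$associates)) {
    rlang::inform(sprintf("only %d of %d host-associate pairs present in the network",
                          sum(is_complex), length(complex$associates)))
  }
  summarise_set <- function(x) {
    tibble::tibble(n_pairs = length(x),
                   mean_effect = mean(x),
                   sd_effect = if (length(x) > 1L) sd(x) else NA_real_)
  }
  out <- dplyr::bind_rows(
    complex = summarise_set(eff$effect[is_complex]),
    within_group = summarise_set(eff$effect[same]),
    among_group = summarise_set(eff$effect[!same]),
    all_pairs = summarise_set(eff$effect),
    .id = "pair_set"
  )
  structure(out, class = c("poolnet_contrast", class(out)))
}

#' @describeIn effect_contrast The contrast table is already tidy.
#' @param x A `poolnet_contrast` object.
#' @param ... Unused.
#' @export
tidy.poolnet_contrast <- function(x, ...) tibble::as_tibble(x)
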