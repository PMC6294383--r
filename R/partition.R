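#' Species partitions
#'
#' A partition assigns every species to exactly one group. Partitions are the
#' shared currency of the package: network modules, PAM clusters and planted
#' (ground-truth) groupings are all represented the same way, so the
#' congruence, spatial-clustering and nest-associate analyses can consume any
#' of them interchangeably. Group labels are arbitrary: every consumer in the
#' package is invariant to relabelling.
#'
#' @param x A named vector of group labels (names are species ids), a factor
#'   with names, or a data frame whose first two columns are species id and
#'   group label.
#' @param source Provenance tag: `"module"`, `"cluster"`, `"planted"` or any
#'   short string.
#'
#' @return A `poolnet_partition`: a named integer vector with labels compacted
#'   to `1..k` (attribute `source` records provenance, `levels` the original
#'   labels).
#' @export
#'
#' @examples
#' as_partition(c(a = 1, b = 1, c = 2))
#' as_partition(data.frame(species = c("a", "b", "c"), group = c("x", "x", "y")))
as_partition <- function(x, source = "unknown") {
  if (inherits(x, "poolnet_partition")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) < 2L) stop_domain("a partition data frame needs species and group columns")
    labels <- x[[2L]]
    names(labels) <- as.character(x[[1L]])
    x <- labels
  }
  if (is.null(names(x)) || anyNA(names(x)) || any(names(x) == "")) {
    stop_domain("partition labels must be named by species id")
  }
  if (anyDuplicated(names(x))) stop_domain("duplicate species ids in partition")
  if (anyNA(x)) stop_domain("NA group labels in partition")
  f <- factor(x)
  out <- as.integer(f)
  names(out) <- names(x)
  structure(out,
    levels = levels(f), source = source,
    class = "poolnet_partition"
  )
}

n_groups <- function(p) max(unclass(p))

#' @export
print.poolnet_partition <- function(x, ...) {
  cat(sprintf(
    "<poolnet_partition: %d species in %d groups (source: %s)>\n",
    length(x), n_groups(x), attr(x, "source") %||% "unknown"
  ))
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' @describeIn as_partition Tidy a partition into a `species`/`group` tibble.
#' @export
tidy.poolnet_partition <- function(x, ...) {
  tibble::tibble(
    species = names(x),
    group = as.integer(x),
    source = attr(x, "source") %||% "unknown"
  )
}

# Restrict two partitions to their common species, preserving class/source.
align_partitions <- function(a, b) {
  a <- as_partition(a, attr(a, "source") %||% "a")
  b <- as_partition(b, attr(b, "source") %||% "b")
  shared <- intersect(names(a), names(b))
  if (length(shared) == 0L) stop_domain("partitions share no species")
  excluded <- union(setdiff(names(a), shared), setdiff(names(b), shared))
  list(
    a = as_partition(unclass(a)[shared], attr(a, "source")),
    b = as_partition(unclass(b)[shared], attr(b, "source")),
    excluded = excluded
  )
}
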