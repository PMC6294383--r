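# Internal condition helpers. Every recoverable failure is signalled with a
# poolnet_* condition class so callers (and the pipeline) can distinguish,
# e.g., a malformed file from a basin that is simply under-sampled.

stop_poolnet <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "poolnet_error"), ...)
}

stop_parse <- function(message, ...) stop_poolnet(message, "poolnet_parse_error", ...)
stop_domain <- function(message, ...) stop_poolnet(message, "poolnet_domain_error", ...)
stop_degenerate <- function(message, ...) stop_poolnet(message, "poolnet_degenerate_error", ...)
stop_insufficient <- function(message, ...) stop_poolnet(message, "poolnet_insufficient_samples", ...)
stop_single_group <- function(message, ...) stop_poolnet(message, "poolnet_single_group", ...)

check_count <- function(x, name, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != floor(x) || x < min) {
    stop_domain(sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}

check_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_domain(sprintf("`%s` must be a single probability in [0, 1]", name))
  }
  as.numeric(x)
}

# Derive a stream of per-stage seeds from one master seed, so that pipeline
# stages can be re-run in isolation yet the end-to-end run stays reproducible.
derive_seeds <- function(seed, n) {
  if (is.null(seed)) return(rep(list(NULL), n))
  seed <- check_count(seed, "seed")
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  as.list(sample.int(.Machine$integer.max - 1L, n))
}

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  force(code)
}
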