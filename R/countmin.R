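# Count-min sketch: fixed-memory approximate frequency counting.
#
# Counters are real-valued so that uniform decay scaling composes cleanly
# with increments.  Each of the `depth` tables hashes a key with its own
# seed derived from the master seed.

#' Derive count-min sketch dimensions from accuracy parameters
#'
#' Frequency estimates are within a factor `epsilon` of the total added mass
#' with probability `delta`.  The dimensions follow
#' `depth = ceiling(log(1 - delta) / log(0.5))` and
#' `width = ceiling(2 / epsilon)`; at the defaults
#' (`epsilon = 1e-4`, `delta = 0.9`) this gives 4 tables of 20,000 counters.
#'
#' @param epsilon relative-accuracy factor in (0, 1).
#' @param delta confidence in (0, 1).
#' @return named integer vector `c(depth =, width =)`.
#' @examples
#' derive_cms_dimensions(0.0001, 0.9)  # depth 4, width 20000
#' @export
derive_cms_dimensions <- function(epsilon, delta) {
  assert_scalar_number(epsilon, "epsilon", 0, 1, open_lower = TRUE,
                       open_upper = TRUE)
  assert_scalar_number(delta, "delta", 0, 1, open_lower = TRUE,
                       open_upper = TRUE)
  c(depth = as.integer(ceiling(log(1 - delta) / log(0.5))),
    width = as.integer(ceiling(2 / epsilon)))
}

#' Create an empty count-min sketch
#'
#' @inheritParams derive_cms_dimensions
#' @param master_seed integer seed from which the per-table hash seeds are
#'   derived.
#' @return an object of class `count_min_sketch`.
#' @seealso [cms_add()], [cms_estimate()], [cms_scale()]
#' @export
count_min_sketch <- function(epsilon = 1e-4, delta = 0.9, master_seed = 1L) {
  dims <- derive_cms_dimensions(epsilon, delta)
  structure(list(epsilon = epsilon, delta = delta,
                 depth = dims[["depth"]], width = dims[["width"]],
                 master_seed = as.integer(master_seed),
                 counters = matrix(0, dims[["depth"]], dims[["width"]])),
            class = "count_min_sketch")
}

#' @export
print.count_min_sketch <- function(x, ...) {
  cat(sprintf("<count_min_sketch> %d x %d (epsilon = %g, delta = %g), mass %g\n",
              x$depth, x$width, x$epsilon, x$delta, sum(x$counters) / x$depth))
  invisible(x)
}

#' Add weighted keys to a count-min sketch
#'
#' @param cms a [count_min_sketch()].
#' @param keys vector of non-negative integer keys (may repeat).
#' @param amounts positive amounts, recycled along `keys`.
#' @return the updated `count_min_sketch`.
#' @export
cms_add <- function(cms, keys, amounts = 1) {
  if (any(amounts <= 0)) stopf("amounts must be > 0")
  amounts <- rep_len(as.numeric(amounts), length(keys))
  cols <- cpp_cms_cols(as.numeric(keys), cms$depth, cms$width, cms$master_seed)
  for (t in seq_len(cms$depth)) {
    acc <- rowsum(amounts, cols[t, ])         # accumulate duplicate columns
    idx <- as.integer(rownames(acc))
    cms$counters[t, idx] <- cms$counters[t, idx] + acc[, 1L]
  }
  cms
}

#' Estimate frequencies from a count-min sketch
#'
#' Returns, for each key, the minimum over tables of the addressed counter.
#' Estimates never underestimate the true added mass of a key; they
#' overestimate by at most `epsilon` times the total mass with probability
#' `delta`.
#'
#' @inheritParams cms_add
#' @return numeric vector of estimates (0 for never-seen keys).
#' @export
cms_estimate <- function(cms, keys) {
  cols <- cpp_cms_cols(as.numeric(keys), cms$depth, cms$width, cms$master_seed)
  est <- rep(Inf, length(keys))
  for (t in seq_len(cms$depth))
    est <- pmin(est, cms$counters[t, cols[t, ]])
  est
}

#' Uniformly scale all counters
#'
#' Supports gradual forgetting: every counter is multiplied by `factor`.
#'
#' @param cms a [count_min_sketch()].
#' @param factor scaling factor in (0, 1].
#' @return the scaled `count_min_sketch`.
#' @export
cms_scale <- function(cms, factor) {
  assert_scalar_number(factor, "factor", 0, 1, open_lower = TRUE)
  if (factor < 1) cms$counters <- cms$counters * factor
  cms
}
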