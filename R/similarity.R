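# Sketch-level similarity/distance estimation and all-vs-all matrices.

# per-slot weight surrogate: the stored minimal CWS hash A_j is inversely
# monotone in the underlying bin weight, so 1/A_j serves as the slot's
# weight.  Empty slots (A = +Inf) get weight 0.
slot_weights <- function(hs) {
  w <- 1 / hs$A
  w[!is.finite(hs$A)] <- 0
  w
}

#' Jaccard similarity between two histosketches
#'
#' The fraction of slots whose selected bin identifiers agree; an unbiased
#' estimator of the weighted Jaccard similarity of the underlying spectra.
#'
#' @param a,b comparable `histosketch` objects (same k, Z, X and seed).
#' @return similarity in \[0, 1\].
#' @export
jaccard_similarity <- function(a, b) {
  assert_comparable(a$config, b$config)
  mean(!is.na(a$S) & !is.na(b$S) & a$S == b$S)
}

#' Weighted Jaccard distance between two histosketches
#'
#' One minus the ratio of slot-wise minimum to maximum weight, computed on
#' the per-slot weight surrogates `1/A`.  Slots whose bin identifiers
#' disagree share no mass, so their minimum term is 0; the union term runs
#' over all slots.
#'
#' @inheritParams jaccard_similarity
#' @return distance in \[0, 1\].
#' @export
weighted_jaccard_distance <- function(a, b) {
  assert_comparable(a$config, b$config)
  u <- slot_weights(a)
  v <- slot_weights(b)
  num <- sum(ifelse(!is.na(a$S) & !is.na(b$S) & a$S == b$S, pmin(u, v), 0))
  den <- sum(pmax(u, v))
  if (den == 0) return(0)
  1 - num / den
}

#' Bray-Curtis or Euclidean distance between two histosketches
#'
#' Standard vector metrics over the per-slot weight surrogates `1/A`.
#'
#' @inheritParams jaccard_similarity
#' @param metric `"bray-curtis"` or `"euclidean"`.
#' @return non-negative distance.
#' @export
vector_distance <- function(a, b, metric = c("bray-curtis", "euclidean")) {
  metric <- match.arg(metric)
  assert_comparable(a$config, b$config)
  u <- slot_weights(a)
  v <- slot_weights(b)
  switch(metric,
         "bray-curtis" = {
           den <- sum(u) + sum(v)
           if (den == 0) 0 else sum(abs(u - v)) / den
         },
         "euclidean" = sqrt(sum((u - v)^2)))
}

#' All-vs-all distance or similarity matrix
#'
#' @param sketches list of comparable `histosketch` objects.
#' @param labels sample names (defaults to `names(sketches)`).
#' @param metric one of `"jaccard"` (similarity, diagonal 1),
#'   `"weighted-jaccard"`, `"bray-curtis"` or `"euclidean"` (distances,
#'   diagonal 0).
#' @return symmetric numeric matrix with `labels` as dimnames.
#' @export
pairwise_matrix <- function(sketches, labels = names(sketches),
                            metric = c("jaccard", "weighted-jaccard",
                                       "bray-curtis", "euclidean")) {
  metric <- match.arg(metric)
  n <- length(sketches)
  if (n < 2L) stopf("need >= 2 sketches")
  if (is.null(labels)) labels <- paste0("sample_", seq_len(n))
  if (length(labels) != n) stopf("need one label per sketch")
  fn <- switch(metric,
               "jaccard" = jaccard_similarity,
               "weighted-jaccard" = weighted_jaccard_distance,
               function(a, b) vector_distance(a, b, metric))
  m <- diag(if (metric == "jaccard") 1 else 0, n)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      v <- tryCatch(fn(sketches[[i]], sketches[[j]]), error = function(e)
        stopf("pair (%s, %s): %s", labels[i], labels[j], conditionMessage(e)))
      m[i, j] <- m[j, i] <- v
    }
  }
  dimnames(m) <- list(labels, labels)
  m
}

#' Write a distance/similarity matrix as CSV
#'
#' Labels form the header row and first column.
#'
#' @param m matrix from [pairwise_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(m, path) {
  write.csv(m, path, row.names = TRUE)
  invisible(path)
}
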