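# LSH-forest style self-tuning index over histosketches.
#
# A sketch's S-vector (bin identifiers only, never the hash values A) is
# split into L chunks of K slots; each chunk is serialized to a key and
# stored in its table.  A query collides with an entry if any chunk key
# matches; candidates are post-filtered by exact slot-Jaccard against the
# stored S-vectors.

# chunk keys: K bin identifiers serialized little-endian (least significant
# byte of the first slot first)
chunk_keys <- function(S, K, L) {
  vapply(seq_len(L), function(l) {
    vals <- S[((l - 1L) * K + 1L):(l * K)]
    paste(vapply(vals, function(v) {
      paste(bitwAnd(bitwShiftR(v, c(0L, 8L, 16L, 24L)), 255L), collapse = ".")
    }, character(1)), collapse = "|")
  }, character(1))
}

# collision probability of the banding scheme at similarity s
lsh_collision_prob <- function(s, K, L) 1 - (1 - s^K)^L

#' Tune LSH forest parameters
#'
#' Evaluates every `(K, L)` pair whose product `K * L` divides the sketch
#' size under the banding collision model `p(s) = 1 - (1 - s^K)^L`: the
#' false-negative rate is `1 - p(threshold)` and the false-positive rate is
#' `p(threshold - margin)`.  Among pairs meeting `max_fp`/`max_fn`, the pair
#' minimizing `fp + fn` is returned; ties prefer larger `K`.
#'
#' @param sketch_size number of sketch slots Z.
#' @param threshold Jaccard similarity cutoff in (0, 1).
#' @param max_fp,max_fn admissible false-positive / false-negative rates
#'   (default 1 = unconstrained, pure `fp + fn` minimization).
#' @param margin similarity gap below `threshold` at which false positives
#'   are evaluated (default 0.05).
#' @return list with `K`, `L`, `fn` and `fp` (the modelled rates).
#' @export
tune_lsh_parameters <- function(sketch_size, threshold, max_fp = 1,
                                max_fn = 1, margin = 0.05) {
  sketch_size <- assert_count(sketch_size, "sketch_size")
  assert_scalar_number(threshold, "threshold", 0, 1, open_lower = TRUE,
                       open_upper = TRUE)
  divisors <- which(sketch_size %% seq_len(sketch_size) == 0L)
  cand <- do.call(rbind, lapply(divisors, function(p) {
    kk <- which(p %% seq_len(p) == 0L)
    cbind(K = kk, L = p %/% kk)
  }))
  cand <- unique(cand)
  fn <- 1 - lsh_collision_prob(threshold, cand[, "K"], cand[, "L"])
  fp <- lsh_collision_prob(max(threshold - margin, 0), cand[, "K"],
                           cand[, "L"])
  ok <- fn <= max_fn & fp <= max_fp
  if (!any(ok))
    stopf(paste0("no (K, L) pair meets max_fp = %g / max_fn = %g at ",
                 "threshold %g; try a larger sketch size"),
          max_fp, max_fn, threshold)
  score <- fp + fn
  score[!ok] <- Inf
  best <- which(score == min(score))
  best <- best[which.max(cand[best, "K"])]
  list(K = unname(cand[best, "K"]), L = unname(cand[best, "L"]),
       fn = unname(fn[best]), fp = unname(fp[best]))
}

sketch_S_or_die <- function(sketch, label) {
  if (anyNA(sketch$S))
    stopf("sketch '%s' has empty slots and cannot be indexed", label)
  sketch$S
}

#' Create an LSH forest index over histosketches
#'
#' @param sketches list of comparable `histosketch` objects.
#' @param labels unique sample labels (defaults to `names(sketches)`).
#' @param threshold Jaccard similarity cutoff for searches.
#' @param max_fp,max_fn,margin tuning constraints; see
#'   [tune_lsh_parameters()].
#' @return an object of class `lsh_forest`.
#' @export
lsh_index_create <- function(sketches, labels = names(sketches),
                             threshold = 0.9, max_fp = 1, max_fn = 1,
                             margin = 0.05) {
  if (length(sketches) == 0L) stopf("need >= 1 sketch")
  if (is.null(labels)) labels <- paste0("sketch_", seq_along(sketches))
  if (anyDuplicated(labels)) stopf("duplicate label: %s",
                                   labels[anyDuplicated(labels)])
  cfg <- sketches[[1L]]$config
  tuned <- tune_lsh_parameters(cfg$sketch_size, threshold, max_fp, max_fn,
                               margin)
  index <- structure(list(K = tuned$K, L = tuned$L, threshold = threshold,
                          fn = tuned$fn, fp = tuned$fp,
                          header = cfg[comparability_fields],
                          tables = lapply(seq_len(tuned$L),
                                          function(l) list()),
                          entries = list()),
                     class = "lsh_forest")
  for (i in seq_along(sketches))
    index <- lsh_index_add(index, sketches[[i]], labels[i])
  index
}

#' Add a histosketch to an existing LSH forest index
#'
#' Reuses the stored `(K, L, threshold)` parameters.
#'
#' @param index an `lsh_forest`.
#' @param sketch a `histosketch` comparable with the indexed ones.
#' @param label unique sample label.
#' @return the updated `lsh_forest`.
#' @export
lsh_index_add <- function(index, sketch, label) {
  assert_comparable(index$header, sketch$config, what = "index and sketch")
  if (label %in% names(index$entries)) stopf("duplicate label: %s", label)
  S <- sketch_S_or_die(sketch, label)
  keys <- chunk_keys(S, index$K, index$L)
  for (l in seq_len(index$L)) {
    key <- keys[l]
    index$tables[[l]][[key]] <- c(index$tables[[l]][[key]], label)
  }
  index$entries[[label]] <- S
  index
}

#' Search an LSH forest index
#'
#' Candidates are the entries colliding with the query in at least one
#' chunk; by default they are post-filtered so that every returned label has
#' exact slot-Jaccard similarity with the query at or above the index
#' threshold.
#'
#' @param index an `lsh_forest`.
#' @param query a comparable `histosketch`.
#' @param filter post-filter candidates by exact similarity (default
#'   `TRUE`); `FALSE` returns the raw collision candidates.
#' @return sorted character vector of matching labels (possibly empty).
#' @export
lsh_index_search <- function(index, query, filter = TRUE) {
  assert_comparable(index$header, query$config, what = "index and query")
  if (length(index$entries) == 0L) return(character(0))
  S <- sketch_S_or_die(query, "query")
  keys <- chunk_keys(S, index$K, index$L)
  cand <- unique(unlist(lapply(seq_len(index$L), function(l)
    index$tables[[l]][[keys[l]]])))
  if (is.null(cand)) return(character(0))
  if (filter) {
    sim <- vapply(cand, function(lbl)
      mean(index$entries[[lbl]] == S), numeric(1))
    cand <- cand[sim >= index$threshold]
  }
  sort(cand)
}

#' @export
print.lsh_forest <- function(x, ...) {
  cat(sprintf(
    "<lsh_forest> %d entries, K=%d, L=%d, threshold=%g (fn~%.3g, fp~%.3g)\n",
    length(x$entries), x$K, x$L, x$threshold, x$fn, x$fp))
  invisible(x)
}

#' Save / load an LSH forest index
#'
#' JSON serialization of the full index (parameters, comparability header,
#' tables and stored S-vectors); searches are identical after a round trip.
#'
#' @param index an `lsh_forest`.
#' @param path file path.
#' @return `path` invisibly (save) or the restored `lsh_forest` (load).
#' @export
save_lsh_index <- function(index, path) {
  obj <- list(magic = "HSLF", version = 1L, K = index$K, L = index$L,
              threshold = index$threshold, fn = index$fn, fp = index$fp,
              header = index$header,
              labels = names(index$entries),
              entries = unname(index$entries),
              tables = lapply(index$tables, function(tab)
                list(keys = names(tab), labels = unname(tab))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_lsh_index
#' @export
load_lsh_index <- function(path) {
  obj <- jsonlite::read_json(path)    # no simplification: exact structure
  if (!identical(obj$magic, "HSLF"))
    stopf("not an LSH forest index file: %s", path)
  as_chr <- function(x) vapply(as.list(x), as.character, character(1))
  tables <- lapply(obj$tables, function(tab) {
    labs <- lapply(as.list(tab$labels), as_chr)
    names(labs) <- as_chr(tab$keys)
    labs
  })
  entries <- lapply(obj$entries, function(e)
    vapply(as.list(e), as.integer, integer(1)))
  names(entries) <- as_chr(obj$labels)
  header <- lapply(obj$header, as.integer)
  structure(list(K = as.integer(obj$K), L = as.integer(obj$L),
                 threshold = obj$threshold, fn = obj$fn, fp = obj$fp,
                 header = header, tables = tables, entries = entries),
            class = "lsh_forest")
}
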