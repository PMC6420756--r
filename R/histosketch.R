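# The core method: map the streaming k-mer spectrum to histogram bins, hash
# bins by consistent weighted sampling (CWS), and maintain the Z-slot
# minimal-hash histosketch with incremental updates and optional
# concept-drift decay.

#' Sketching configuration
#'
#' Bundles every parameter that determines a histosketch.  Two sketches are
#' comparable if and only if their `(k, sketch_size, num_bins, master_seed)`
#' agree.
#'
#' @param k k-mer size (default 21).
#' @param sketch_size number of sketch slots Z (default 512).
#' @param num_bins number of histogram bins X the k-mer space is hashed
#'   into; defaults to `depth * width` of the count-min sketch at
#'   (`epsilon`, `delta`), i.e. 80,000 at the defaults, honouring the
#'   fixed-counter budget.
#' @param epsilon,delta count-min sketch accuracy parameters (defaults
#'   1e-4 and 0.9, giving 4 x 20,000 counters).
#' @param decay_ratio gradual-forgetting parameter in \[0, 1); 0 disables
#'   concept-drift decay.
#' @param interval reads consumed per counting worker between flushes to the
#'   sketcher; 0 sketches the whole input in one flush.
#' @param master_seed integer seed for every hash family (bin assignment,
#'   count-min tables, CWS draws).
#' @param num_counters number of independent counting workers; with decay
#'   off the result is identical for any value.
#' @return an object of class `sketch_config`.
#' @export
sketch_config <- function(k = 21L, sketch_size = 512L, num_bins = NULL,
                          epsilon = 1e-4, delta = 0.9, decay_ratio = 0,
                          interval = 0L, master_seed = 1L,
                          num_counters = 1L) {
  k <- assert_count(k, "k")
  if (k > 31L) stopf("k must be <= 31")
  sketch_size <- assert_count(sketch_size, "sketch_size")
  dims <- derive_cms_dimensions(epsilon, delta)
  if (is.null(num_bins)) num_bins <- dims[["depth"]] * dims[["width"]]
  num_bins <- assert_count(num_bins, "num_bins")
  assert_scalar_number(decay_ratio, "decay_ratio", 0, 1, open_upper = TRUE)
  interval <- assert_count(interval, "interval", lower = 0L)
  num_counters <- assert_count(num_counters, "num_counters")
  structure(list(k = k, sketch_size = sketch_size, num_bins = num_bins,
                 epsilon = epsilon, delta = delta,
                 depth = dims[["depth"]], width = dims[["width"]],
                 decay_ratio = decay_ratio, interval = interval,
                 master_seed = as.integer(master_seed),
                 num_counters = num_counters),
            class = "sketch_config")
}

#' @export
print.sketch_config <- function(x, ...) {
  cat(sprintf(
    "<sketch_config> k=%d Z=%d X=%d cms=%dx%d decay=%g interval=%d seed=%d\n",
    x$k, x$sketch_size, x$num_bins, x$depth, x$width, x$decay_ratio,
    x$interval, x$master_seed))
  invisible(x)
}

# comparability: sketches (and indexes/models built from them) may only be
# compared when these four parameters agree
comparability_fields <- c("k", "sketch_size", "num_bins", "master_seed")

assert_comparable <- function(a, b, what = "sketches") {
  for (f in comparability_fields) {
    if (!identical(a[[f]], b[[f]]))
      stopf("incomparable %s: '%s' differs (%s vs %s)", what, f,
            format(a[[f]]), format(b[[f]]))
  }
  invisible(TRUE)
}

#' Construct a k-mer spectrum
#'
#' The histogram being sketched: `num_bins` bins with non-negative
#' frequencies.
#'
#' @param weights numeric vector of bin frequencies (dense, length
#'   `num_bins`).
#' @param num_bins number of bins (defaults to `length(weights)`).
#' @return an object of class `kmer_spectrum` with fields `num_bins`,
#'   `weights` and `total_mass`.
#' @export
kmer_spectrum <- function(weights, num_bins = length(weights)) {
  num_bins <- assert_count(num_bins, "num_bins")
  if (length(weights) != num_bins)
    stopf("weights has length %d but num_bins is %d", length(weights),
          num_bins)
  if (any(weights < 0)) stopf("bin frequencies must be >= 0")
  structure(list(num_bins = num_bins, weights = as.numeric(weights),
                 total_mass = sum(weights)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat(sprintf("<kmer_spectrum> %d bins, %d occupied, total mass %g\n",
              x$num_bins, sum(x$weights > 0), x$total_mass))
  invisible(x)
}

#' Assign k-mers to histogram bins
#'
#' Deterministic uniform mapping of encoded canonical k-mers onto
#' `1..num_bins` via a seeded 64-bit mix hash.
#'
#' @param kmers numeric vector of encoded k-mers (see
#'   [encode_canonical_kmers()]).
#' @param num_bins number of histogram bins X.
#' @param master_seed integer seed.
#' @return integer vector of bin indices in `1..num_bins`.
#' @export
assign_bin <- function(kmers, num_bins, master_seed = 1L) {
  num_bins <- assert_count(num_bins, "num_bins")
  cpp_assign_bin(as.numeric(kmers), num_bins, as.integer(master_seed))
}

#' Consistent weighted sampling draws
#'
#' The CWS variables for histogram bin `i` and sketch slot `j`:
#' `r ~ Gamma(shape = 2, scale = 1)`, `c ~ Gamma(shape = 2, scale = 1)` and
#' `beta ~ Uniform(0, 1)`.  Draws are a pure function of
#' `(i, j, master_seed)` (counter-based hashing, nothing precomputed), so
#' they are identical across calls, processes and samples.
#'
#' @param i bin index (vectorized).
#' @param j slot index (vectorized, recycled against `i`).
#' @param master_seed integer seed.
#' @return list with numeric components `r`, `c`, `beta`.
#' @export
cws_draw <- function(i, j, master_seed = 1L) {
  n <- max(length(i), length(j))
  cpp_cws_draw(rep_len(as.integer(i), n), rep_len(as.integer(j), n),
               as.integer(master_seed))
}

#' CWS hash of a weighted bin
#'
#' Given a bin frequency `weight` and a CWS draw, computes the scaled weight
#' `y = exp(log(weight) - r * beta)` and the hash `a = c / (y * exp(r))`.
#' Over random draws, the bin attaining the minimal `a` across a weighted
#' set is selected with probability proportional to its weight.
#'
#' @param weight positive bin frequency (vectorized).
#' @param draw a draw from [cws_draw()] (components recycled).
#' @return list with numeric components `y` and `a`.
#' @export
cws_hash <- function(weight, draw) {
  if (any(weight <= 0)) stopf("weight must be > 0")
  y <- exp(log(weight) - draw$r * draw$beta)
  a <- draw$c / (y * exp(draw$r))
  list(y = y, a = a)
}

# internal constructor; S uses NA for never-filled slots
new_histosketch <- function(config, S, A, reads_consumed = 0) {
  structure(list(config = config, S = as.integer(S), A = as.numeric(A),
                 reads_consumed = reads_consumed),
            class = "histosketch")
}

#' @export
print.histosketch <- function(x, ...) {
  cat(sprintf(
    "<histosketch> Z=%d (k=%d, X=%d, seed=%d), %d slots filled, %s reads\n",
    x$config$sketch_size, x$config$k, x$config$num_bins,
    x$config$master_seed, sum(!is.na(x$S)),
    format(x$reads_consumed, big.mark = ",")))
  invisible(x)
}

#' Create a histosketch from a k-mer spectrum
#'
#' One-shot sketching: for each of the Z slots, every occupied bin is hashed
#' with [cws_hash()] under that slot's draws, and the bin with the minimal
#' hash is kept (`S`) together with the hash value itself (`A`).  Ties keep
#' the lower bin index.
#'
#' @param spectrum a [kmer_spectrum()] with at least one occupied bin.
#' @param config a [sketch_config()] with `num_bins` matching the spectrum.
#' @return an object of class `histosketch`.
#' @export
create_histosketch <- function(spectrum, config) {
  if (!inherits(spectrum, "kmer_spectrum")) stopf("not a kmer_spectrum")
  if (spectrum$num_bins != config$num_bins)
    stopf("spectrum has %d bins but config expects %d", spectrum$num_bins,
          config$num_bins)
  nz <- which(spectrum$weights > 0)
  if (length(nz) == 0L) stopf("empty spectrum")
  res <- cpp_create_sketch(nz, spectrum$weights[nz], config$sketch_size,
                           config$master_seed)
  new_histosketch(config, res$S, res$A)
}

#' Incrementally update a histosketch with one histogram bin
#'
#' The bin's cumulative frequency is estimated from the persistent count-min
#' sketch (which must already be credited with the increment); the bin is
#' hashed against every slot and replaces the slot's entry whenever its hash
#' is a strict improvement.
#'
#' @param hs a [create_histosketch()] result, or an empty sketch from
#'   [empty_histosketch()].
#' @param bin histogram bin index in `1..num_bins`.
#' @param cms the persistent [count_min_sketch()] tracking cumulative bin
#'   frequencies; its `master_seed` must match the sketch's.
#' @return the updated `histosketch`.
#' @export
update_histosketch <- function(hs, bin, cms) {
  if (!identical(cms$master_seed, hs$config$master_seed))
    stopf("incomparable sketches: 'master_seed' differs (%d vs %d)",
          cms$master_seed, hs$config$master_seed)
  bin <- assert_count(bin, "bin")
  if (bin > hs$config$num_bins) stopf("bin %d out of range", bin)
  f <- cms_estimate(cms, bin)
  if (f <= 0) stopf("count-min sketch holds no mass for bin %d", bin)
  res <- cpp_update_slots(hs$S, hs$A, bin, f, hs$config$master_seed)
  new_histosketch(hs$config, res$S, res$A, hs$reads_consumed)
}

#' An empty histosketch
#'
#' Slots start at `A = +Inf` with undefined bins, so the first update fills
#' every slot.
#'
#' @param config a [sketch_config()].
#' @return a `histosketch` with all slots empty.
#' @export
empty_histosketch <- function(config) {
  new_histosketch(config, rep(NA_integer_, config$sketch_size),
                  rep(Inf, config$sketch_size))
}

#' Apply concept-drift decay
#'
#' Gradual forgetting with weight `w = 1 - decay_ratio`: the persistent
#' count-min counters are uniformly scaled by `w` and every stored sketch
#' hash is divided by `w`, so old minima become easier to displace by
#' incoming elements.
#'
#' @param hs a `histosketch`.
#' @param cms the persistent [count_min_sketch()].
#' @param decay_ratio forgetting parameter in \[0, 1).
#' @return list with components `sketch` and `cms`.
#' @export
apply_decay <- function(hs, cms, decay_ratio) {
  assert_scalar_number(decay_ratio, "decay_ratio", 0, 1, open_upper = TRUE)
  if (decay_ratio == 0) return(list(sketch = hs, cms = cms))
  w <- 1 - decay_ratio
  cms <- cms_scale(cms, w)
  hs$A <- hs$A / w
  list(sketch = hs, cms = cms)
}

#' Sketch a pre-binned element stream incrementally
#'
#' Replays a stream of `(bin, amount)` arrivals: each is credited to a
#' persistent count-min sketch and the slots are re-evaluated at the bin's
#' cumulative frequency estimate.  With exact count-min estimates the result
#' is identical to [create_histosketch()] on the final spectrum, for any
#' ordering or partition of the stream.
#'
#' @param bins integer vector of bin indices, one per arriving element.
#' @param amounts positive amounts, recycled along `bins`.
#' @param config a [sketch_config()].
#' @return list with components `sketch` (`histosketch`) and `cms` (the
#'   persistent `count_min_sketch`).
#' @export
sketch_bin_stream <- function(bins, amounts = 1, config) {
  if (length(bins) == 0L) stopf("nothing to sketch")
  amounts <- rep_len(as.numeric(amounts), length(bins))
  if (any(amounts <= 0)) stopf("amounts must be > 0")
  res <- cpp_sketch_bin_stream(as.integer(bins), amounts,
                               config$sketch_size, config$depth,
                               config$width, config$master_seed)
  cms <- count_min_sketch(config$epsilon, config$delta, config$master_seed)
  cms$counters <- res$counters
  list(sketch = new_histosketch(config, res$S, res$A), cms = cms)
}

#' Histosketch a FASTQ read stream
#'
#' The streaming front end: reads are dealt round-robin to
#' `config$num_counters` counting workers, each decomposing its reads into
#' canonical k-mers, assigning them to histogram bins and counting bins in a
#' local count-min sketch.  Every `config$interval` reads a worker flushes
#' its touched `(bin, estimate)` elements (ascending bin order) to the
#' single sketching process, which credits a persistent count-min sketch,
#' applies decay once per flush when `decay_ratio > 0`, updates the sketch
#' slots at the cumulative estimates, wipes the worker's store, and emits a
#' snapshot.  A final snapshot is always emitted at end of stream.
#'
#' With `decay_ratio = 0` the final sketch is a pure function of the
#' multiset of reads: identical for any `interval`, `num_counters` or read
#' order.
#'
#' @param input FASTQ file path, `"-"`/connection (see [read_fastq()]), a
#'   character vector of read sequences, or a list of [sequence_record()]s.
#' @param config a [sketch_config()].
#' @param min_quality optional 3' quality-trimming threshold applied per
#'   read before counting (0 = off); see [trim_quality()].
#' @return list of `histosketch` snapshots, one per interval flush plus the
#'   final state (a single final snapshot when `interval = 0`).
#' @seealso [classify_stream()] for consuming snapshots as they arrive.
#' @export
sketch_stream <- function(input, config, min_quality = 0) {
  ptr <- cpp_sketcher_new(config$k, config$sketch_size, config$num_bins,
                          config$depth, config$width, config$master_seed,
                          config$interval, config$num_counters,
                          config$decay_ratio)
  snapshots <- list()
  wrap <- function(snap)
    new_histosketch(config, snap$S, snap$A, snap$reads_consumed)
  feed <- function(bases) {
    for (snap in cpp_sketcher_add(ptr, bases))
      snapshots[[length(snapshots) + 1L]] <<- wrap(snap)
  }
  record_bases <- function(records) {
    if (min_quality > 0)
      records <- lapply(records, trim_quality, min_quality = min_quality)
    vapply(records, `[[`, character(1), "bases")
  }
  if (is.character(input) && length(input) > 1L) {
    feed(input)                                   # raw sequences
  } else if (is.list(input) && !inherits(input, "connection")) {
    feed(record_bases(input))                     # sequence_record list
  } else if (is.character(input) && !file.exists(input) &&
             !identical(input, "-") && grepl("^[ACGTNacgtn]+$", input)) {
    feed(input)                                   # a single raw sequence
  } else {
    read_fastq(input, callback = function(records) feed(record_bases(records)),
               chunk_size = 5000L)
  }
  if (cpp_sketcher_kmers(ptr) == 0) stopf("nothing to sketch")
  snapshots[[length(snapshots) + 1L]] <- wrap(cpp_sketcher_finalize(ptr))
  snapshots
}

# ---------------------------------------------------------------------------
# Sketch serialization: little-endian binary with a versioned header, plus a
# JSON mirror for interoperability.
# ---------------------------------------------------------------------------

sketch_magic <- "HSKT"
sketch_format_version <- 1L

#' Save a histosketch to a binary file
#'
#' Little-endian, versioned: magic `"HSKT"`, version, the comparability
#' header (`k`, `Z`, `X`, `master_seed`, plus `epsilon`, `delta`,
#' `decay_ratio`, `reads_consumed`), then the Z bin identifiers and Z hash
#' values.
#'
#' @param hs a `histosketch`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
save_sketch <- function(hs, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  cfg <- hs$config
  writeBin(charToRaw(sketch_magic), con)
  writeBin(c(sketch_format_version, cfg$k, cfg$sketch_size, cfg$num_bins,
             cfg$master_seed),
           con, size = 4L, endian = "little")
  writeBin(c(cfg$epsilon, cfg$delta, cfg$decay_ratio,
             as.numeric(hs$reads_consumed)),
           con, size = 8L, endian = "little")
  writeBin(hs$S, con, size = 4L, endian = "little")
  writeBin(hs$A, con, size = 8L, endian = "little")
  invisible(path)
}

#' Load a histosketch from a binary file
#'
#' @param path a file written by [save_sketch()].
#' @return a `histosketch`.
#' @export
load_sketch <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 4L))
  if (!identical(magic, sketch_magic))
    stopf("not a histosketch file (bad magic in %s)", path)
  hdr <- readBin(con, "integer", 5L, size = 4L, endian = "little")
  if (length(hdr) < 5L) stopf("truncated histosketch file: %s", path)
  if (hdr[1L] != sketch_format_version)
    stopf("unsupported histosketch format version %d", hdr[1L])
  dbl <- readBin(con, "double", 4L, size = 8L, endian = "little")
  if (length(dbl) < 4L) stopf("truncated histosketch file: %s", path)
  S <- readBin(con, "integer", hdr[3L], size = 4L, endian = "little")
  A <- readBin(con, "double", hdr[3L], size = 8L, endian = "little")
  if (length(S) < hdr[3L] || length(A) < hdr[3L])
    stopf("truncated histosketch file: %s", path)
  config <- sketch_config(k = hdr[2L], sketch_size = hdr[3L],
                          num_bins = hdr[4L], epsilon = dbl[1L],
                          delta = dbl[2L], decay_ratio = dbl[3L],
                          master_seed = hdr[5L])
  new_histosketch(config, S, A, dbl[4L])
}

#' Export a histosketch as JSON
#'
#' A plain-text mirror of the binary format (same fields) for
#' interoperability.
#'
#' @param hs a `histosketch`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return `path` (invisibly) or a JSON string.
#' @export
export_sketch_json <- function(hs, path = NULL) {
  cfg <- hs$config
  obj <- list(magic = sketch_magic, version = sketch_format_version,
              k = cfg$k, sketch_size = cfg$sketch_size,
              num_bins = cfg$num_bins, master_seed = cfg$master_seed,
              epsilon = cfg$epsilon, delta = cfg$delta,
              decay_ratio = cfg$decay_ratio,
              reads_consumed = hs$reads_consumed,
              S = hs$S, A = hs$A)
  if (is.null(path))
    return(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
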