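# FASTQ parsing, quality trimming and canonical k-mer encoding.

#' Construct a sequence record
#'
#' A minimal container for one sequencing read: an identifier, its bases and
#' per-base Phred quality scores.
#'
#' @param identifier read name (the FASTQ header without the leading `@`).
#' @param bases character scalar of bases (alphabet `{A,C,G,T,N,...}`).
#' @param qualities integer vector of Phred scores, one per base.
#' @return an object of class `sequence_record`.
#' @export
sequence_record <- function(identifier, bases, qualities) {
  if (nchar(bases) != length(qualities))
    stopf("bases (%d) and qualities (%d) differ in length",
          nchar(bases), length(qualities))
  if (any(qualities < 0)) stopf("qualities must be >= 0")
  structure(list(identifier = identifier, bases = bases,
                 qualities = as.integer(qualities)),
            class = "sequence_record")
}

#' @export
print.sequence_record <- function(x, ...) {
  cat(sprintf("<sequence_record> %s: %d bp\n", x$identifier, nchar(x$bases)))
  invisible(x)
}

# open a text connection for FASTQ input; gzfile() transparently handles both
# plain and gzip-compressed files.  Returns list(con, owned).
open_fastq_connection <- function(input, gzipped = NA) {
  if (inherits(input, "connection")) {
    con <- if (isTRUE(gzipped)) gzcon(input) else input
    owned <- isTRUE(gzipped)
    if (!isOpen(con)) {
      open(con, "rt")
      owned <- TRUE
    }
    return(list(con = con, owned = owned))
  }
  if (!is.character(input) || length(input) != 1L)
    stopf("input must be a file path or a connection")
  if (identical(input, "-")) return(list(con = file("stdin", "rt"), owned = TRUE))
  if (!file.exists(input)) stopf("FASTQ file not found: %s", input)
  list(con = gzfile(input, "rt"), owned = TRUE)
}

# parse one chunk of 4-line records; `offset` = records already consumed.
# Returns list of sequence_record.
parse_fastq_lines <- function(lines, offset = 0L, decode_qualities = TRUE) {
  n <- length(lines)
  if (n %% 4L != 0L)
    stopf("malformed FASTQ: truncated record %d (line count not divisible by 4)",
          offset + n %/% 4L + 1L)
  nrec <- n %/% 4L
  if (nrec == 0L) return(list())
  heads <- lines[seq(1L, n, by = 4L)]
  seqs <- lines[seq(2L, n, by = 4L)]
  plus <- lines[seq(3L, n, by = 4L)]
  quals <- lines[seq(4L, n, by = 4L)]
  bad <- which(!startsWith(heads, "@"))
  if (length(bad))
    stopf("malformed FASTQ: record %d does not start with '@'", offset + bad[1L])
  bad <- which(!startsWith(plus, "+"))
  if (length(bad))
    stopf("malformed FASTQ: record %d is missing the '+' line", offset + bad[1L])
  bad <- which(nchar(seqs) != nchar(quals))
  if (length(bad))
    stopf("malformed FASTQ: record %d has mismatched sequence/quality lengths",
          offset + bad[1L])
  ids <- sub("^@", "", heads)
  lapply(seq_len(nrec), function(i) {
    q <- if (decode_qualities) utf8ToInt(quals[i]) - 33L else integer(0)
    structure(list(identifier = ids[i], bases = seqs[i],
                   qualities = if (decode_qualities) q else
                     rep(0L, nchar(seqs[i]))),
              class = "sequence_record")
  })
}

#' Read a FASTQ stream
#'
#' Parses 4-line FASTQ records (Phred+33) from a file path, `"-"` (standard
#' input) or a connection.  Gzip-compressed files are decompressed
#' transparently; for an already-open connection carrying gzip bytes, set
#' `gzipped = TRUE`.
#'
#' Records are parsed in chunks, so arbitrarily large files can be consumed
#' via the `callback` interface without materializing them; without a
#' callback all records are returned as a list.
#'
#' @param input file path, `"-"`, or a connection.
#' @param gzipped force gzip decompression of a connection (`NA` =
#'   auto-handle file paths).
#' @param n maximum number of records to read (`Inf` = all).
#' @param callback optional `function(records)` invoked per chunk; when
#'   supplied, records are not accumulated and the record count is returned.
#' @param chunk_size records per parsed chunk.
#' @return list of [sequence_record()] objects (or the record count when
#'   `callback` is used).
#' @examples
#' fq <- tempfile(fileext = ".fastq")
#' writeLines(c("@r1", "ACGT", "+", "IIII"), fq)
#' read_fastq(fq)[[1]]
#' @export
read_fastq <- function(input, gzipped = NA, n = Inf, callback = NULL,
                       chunk_size = 10000L) {
  oc <- open_fastq_connection(input, gzipped)
  if (oc$owned) on.exit(close(oc$con))
  out <- list()
  consumed <- 0L
  repeat {
    want <- min(chunk_size, n - consumed)
    if (want <= 0) break
    lines <- readLines(oc$con, n = 4L * want)
    if (length(lines) == 0L) break
    recs <- parse_fastq_lines(lines, offset = consumed)
    consumed <- consumed + length(recs)
    if (is.null(callback)) out <- c(out, recs) else callback(recs)
    if (length(lines) < 4L * want) break
  }
  if (is.null(callback)) out else consumed
}

#' Quality-trim the 3' end of a read
#'
#' BWA-style trimming: over all cut points `c` (keeping bases `1..c`), the
#' running sum of `min_quality - q_i` over the discarded suffix is maximized;
#' ties keep the longer read.  `min_quality = 0` disables trimming.
#'
#' @param record a [sequence_record()].
#' @param min_quality Phred threshold (integer >= 0).
#' @return the trimmed [sequence_record()].
#' @examples
#' r <- sequence_record("r1", "ACGTT", c(40L, 40L, 2L, 2L, 2L))
#' trim_quality(r, 20)$bases  # "AC"
#' @export
trim_quality <- function(record, min_quality) {
  assert_scalar_number(min_quality, "min_quality", lower = 0)
  if (min_quality == 0) return(record)
  q <- record$qualities
  L <- length(q)
  if (L == 0L || all(q >= min_quality)) return(record)
  # suffix sums s[i] = sum_{i..L} (min_quality - q_i); score(c) = s[c + 1]
  s <- rev(cumsum(rev(min_quality - q)))
  scores <- c(s, 0)                      # score(c) for c = 0..L
  keep <- max(which(scores == max(scores))) - 1L
  structure(list(identifier = record$identifier,
                 bases = substr(record$bases, 1L, keep),
                 qualities = q[seq_len(keep)]),
            class = "sequence_record")
}

#' Encode canonical k-mers as packed integers
#'
#' Decomposes a sequence into its length-`k` windows, skipping any window
#' containing a non-`ACGT` symbol, and encodes each window 2 bits per base
#' (`A=0, C=1, G=2, T=3`, first base most significant).  The canonical value
#' is the numeric minimum of the forward and reverse-complement encodings.
#'
#' Values are returned as doubles; they are exact integers for `k <= 26`
#' (the default pipeline uses `k = 21`).  The internal streaming pipeline
#' carries 64-bit integers natively for any `k <= 31`.
#'
#' @param bases character scalar.
#' @param k k-mer length (1..31).
#' @return numeric vector of canonical k-mer encodings, each `< 4^k`.
#' @examples
#' encode_canonical_kmers("ACG", 3)  # 6: min(ACG = 6, CGT = 27)
#' @export
encode_canonical_kmers <- function(bases, k) {
  k <- assert_count(k, "k")
  if (k > 31L) stopf("k must be <= 31")
  if (!is.character(bases) || length(bases) != 1L)
    stopf("'bases' must be a single character string")
  cpp_encode_canonical(bases, k)
}
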