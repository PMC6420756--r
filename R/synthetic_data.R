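# Synthetic microbial communities and FASTQ read streams with exact-spectrum
# oracles.  Genomes are i.i.d. uniform ACGT, so at the default k = 21
# cross-taxon k-mer collisions are negligible and community overlap is
# controlled purely by shared taxa and abundances, making planted
# similarities analytically predictable.

random_genome <- function(length) {
  paste(sample(c("A", "C", "G", "T"), length, replace = TRUE), collapse = "")
}

#' Generate a synthetic microbial community
#'
#' A set of random "genomes" with a relative-abundance vector, deterministic
#' under `seed`.
#'
#' @param n_taxa number of taxa (>= 1).
#' @param genome_length length of each genome in bp.
#' @param abundance_profile `"uniform"`, `"lognormal"` (sdlog 1, normalized)
#'   or `"explicit"` (supply `abundances`).
#' @param seed RNG seed.
#' @param abundances explicit relative abundances (length `n_taxa`; they are
#'   normalized to sum to 1).
#' @return an object of class `synthetic_community`.
#' @export
make_community <- function(n_taxa, genome_length,
                           abundance_profile = c("uniform", "lognormal",
                                                 "explicit"),
                           seed = 1L, abundances = NULL) {
  abundance_profile <- match.arg(abundance_profile)
  n_taxa <- assert_count(n_taxa, "n_taxa")
  genome_length <- assert_count(genome_length, "genome_length")
  with_seed(seed, {
    taxa <- vapply(seq_len(n_taxa), function(i) random_genome(genome_length),
                   character(1))
    ab <- switch(abundance_profile,
                 uniform = rep(1, n_taxa),
                 lognormal = rlnorm(n_taxa, meanlog = 0, sdlog = 1),
                 explicit = {
                   if (is.null(abundances) || length(abundances) != n_taxa)
                     stopf("explicit profile needs %d abundances", n_taxa)
                   if (any(abundances < 0) || sum(abundances) <= 0)
                     stopf("abundances must be >= 0 with positive sum")
                   as.numeric(abundances)
                 })
    structure(list(taxa = taxa, abundances = ab / sum(ab),
                   n_taxa = n_taxa, genome_length = genome_length,
                   seed = as.integer(seed)),
              class = "synthetic_community")
  })
}

#' @export
print.synthetic_community <- function(x, ...) {
  cat(sprintf("<synthetic_community> %d taxa x %d bp (seed %d)\n",
              x$n_taxa, x$genome_length, x$seed))
  invisible(x)
}

#' Perturb a community's composition
#'
#' Emulates ecological shifts: `"abundance-shift"` redistributes `shift` of
#' the total relative-abundance mass onto a random composition;
#' `"taxon-swap"` replaces `ceiling(shift * n_taxa)` genomes with fresh
#' random genomes (abundances unchanged).  `shift = 0` returns the base
#' community unchanged.
#'
#' @param base a [make_community()] result.
#' @param shift fraction in \[0, 1\].
#' @param mode `"abundance-shift"` or `"taxon-swap"`.
#' @param seed RNG seed for the perturbation.
#' @return a `synthetic_community`.
#' @export
perturb_community <- function(base, shift,
                              mode = c("abundance-shift", "taxon-swap"),
                              seed = 1L) {
  mode <- match.arg(mode)
  assert_scalar_number(shift, "shift", 0, 1)
  if (shift == 0) return(base)
  out <- base
  with_seed(seed, {
    if (mode == "abundance-shift") {
      target <- rexp(base$n_taxa)
      target <- target / sum(target)
      out$abundances <- (1 - shift) * base$abundances + shift * target
    } else {
      n_swap <- ceiling(shift * base$n_taxa)
      swap <- sample(base$n_taxa, n_swap)
      out$taxa[swap] <- vapply(seq_len(n_swap), function(i)
        random_genome(base$genome_length), character(1))
    }
  })
  out
}

#' Generate a FASTQ read stream from a community
#'
#' Reads are drawn from taxa proportional to abundances, with uniform start
#' positions and strands, independent per-base substitution errors at
#' `error_rate`, and constant Phred-40 qualities.  Returns the 4-line FASTQ
#' records as a character vector (`4 * n_reads` lines); see [write_fastq()].
#'
#' @param community a [make_community()] result.
#' @param n_reads number of reads.
#' @param read_length read length (<= genome length).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @return character vector of FASTQ lines, with the source taxon of each
#'   read recorded in the header.
#' @export
generate_reads <- function(community, n_reads, read_length, error_rate = 0,
                           seed = 1L) {
  n_reads <- assert_count(n_reads, "n_reads")
  read_length <- assert_count(read_length, "read_length")
  if (read_length > community$genome_length)
    stopf("read_length %d exceeds genome_length %d", read_length,
          community$genome_length)
  assert_scalar_number(error_rate, "error_rate", 0, 1)
  bases_tab <- c("A", "C", "G", "T")
  with_seed(seed, {
    taxon <- sample.int(community$n_taxa, n_reads, replace = TRUE,
                        prob = community$abundances)
    start <- sample.int(community$genome_length - read_length + 1L, n_reads,
                        replace = TRUE)
    fwd <- runif(n_reads) < 0.5
    reads <- substring(community$taxa[taxon], start,
                       start + read_length - 1L)
    if (any(!fwd)) reads[!fwd] <- reverse_complement(reads[!fwd])
    if (error_rate > 0) {
      nerr <- rbinom(n_reads, read_length, error_rate)
      for (i in which(nerr > 0L)) {
        pos <- sample.int(read_length, nerr[i])
        chars <- strsplit(reads[i], "")[[1L]]
        chars[pos] <- vapply(chars[pos], function(b)
          sample(setdiff(bases_tab, b), 1L), character(1))
        reads[i] <- paste(chars, collapse = "")
      }
    }
    qual <- strrep("I", read_length)
    as.vector(rbind(
      sprintf("@read_%d taxon=%d pos=%d strand=%s", seq_len(n_reads), taxon,
              start, ifelse(fwd, "+", "-")),
      reads, "+", qual))
  })
}

#' Write FASTQ lines to a file
#'
#' @param lines character vector from [generate_reads()].
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(lines, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wt") else file(path, "wt")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Exact binned k-mer spectrum (the brute-force oracle)
#'
#' Counts canonical k-mers exactly and maps them through [assign_bin()] --
#' the ground truth against which the count-min and histosketch
#' approximations are validated.  For a community, each genome's k-mer
#' counts are weighted by its relative abundance (the expected read-derived
#' spectrum up to edge effects); for sequences or a FASTQ file, plain window
#' counts are used.
#'
#' @param x a `synthetic_community`, a character vector of sequences, or a
#'   FASTQ file path.
#' @param k k-mer size.
#' @param num_bins number of histogram bins X.
#' @param master_seed integer seed (must match the sketching configuration).
#' @return a [kmer_spectrum()].
#' @export
exact_spectrum <- function(x, k, num_bins, master_seed = 1L) {
  k <- assert_count(k, "k")
  num_bins <- assert_count(num_bins, "num_bins")
  W <- numeric(num_bins)
  if (inherits(x, "synthetic_community")) {
    for (i in seq_len(x$n_taxa)) {
      bins <- cpp_seqs_to_bins(x$taxa[i], k, num_bins,
                               as.integer(master_seed))
      if (length(bins))
        W <- W + x$abundances[i] * tabulate(bins, num_bins)
    }
  } else if (is.character(x) && length(x) == 1L && file.exists(x)) {
    read_fastq(x, callback = function(records) {
      seqs <- vapply(records, `[[`, character(1), "bases")
      bins <- cpp_seqs_to_bins(seqs, k, num_bins, as.integer(master_seed))
      if (length(bins)) W <<- W + tabulate(bins, num_bins)
    })
  } else if (is.character(x)) {
    bins <- cpp_seqs_to_bins(x, k, num_bins, as.integer(master_seed))
    if (length(bins)) W <- W + tabulate(bins, num_bins)
  } else {
    stopf("cannot compute a spectrum from class '%s'", class(x)[1L])
  }
  kmer_spectrum(W, num_bins)
}

#' Exact weighted Jaccard similarity between two spectra
#'
#' `sum(pmin(W1, W2)) / sum(pmax(W1, W2))`: the closed-form oracle that
#' histosketch slot-match rates estimate.
#'
#' @param s1,s2 [kmer_spectrum()] objects over the same bins.
#' @return similarity in \[0, 1\].
#' @export
weighted_jaccard_spectra <- function(s1, s2) {
  if (s1$num_bins != s2$num_bins)
    stopf("spectra have different bin counts (%d vs %d)", s1$num_bins,
          s2$num_bins)
  den <- sum(pmax(s1$weights, s2$weights))
  if (den == 0) return(1)
  sum(pmin(s1$weights, s2$weights)) / den
}

#' Serialize / restore a community description as JSON
#'
#' @param community a `synthetic_community`.
#' @param path file path.
#' @return `path` invisibly (save) or the restored community (load).
#' @export
save_community_json <- function(community, path) {
  jsonlite::write_json(unclass(community), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname save_community_json
#' @export
load_community_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(taxa = as.character(obj$taxa),
                 abundances = as.numeric(obj$abundances),
                 n_taxa = as.integer(obj$n_taxa),
                 genome_length = as.integer(obj$genome_length),
                 seed = as.integer(obj$seed)),
            class = "synthetic_community")
}
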