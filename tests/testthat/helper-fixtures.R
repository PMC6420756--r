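# shared fixtures: all built in code at test time

# plant a histosketch directly from S (and optionally A) under a config;
# used to test similarity metrics and indexing against hand-chosen slots
planted_sketch <- function(S, config, A = NULL) {
  if (is.null(A)) A <- rep(1, length(S))
  histosketchr:::new_histosketch(config, S, A)
}

# random integer-valued sparse spectrum (counts, so streaming sums are exact)
random_count_spectrum <- function(num_bins, occupancy = 0.5, max_count = 50,
                                  seed = 1) {
  histosketchr:::with_seed(seed, {
    W <- numeric(num_bins)
    occ <- sample(num_bins, ceiling(occupancy * num_bins))
    W[occ] <- sample.int(max_count, length(occ), replace = TRUE)
    kmer_spectrum(W, num_bins)
  })
}

# brute-force window scan: number of length-k windows containing only ACGT
count_acgt_windows <- function(bases, k) {
  chars <- strsplit(bases, "")[[1]]
  ok <- chars %in% c("A", "C", "G", "T")
  n <- length(chars) - k + 1
  if (n < 1) return(0L)
  sum(vapply(seq_len(n), function(i) all(ok[i:(i + k - 1)]), logical(1)))
}

# a pair of communities with a planted taxon overlap; J of their exact
# spectra is computable with weighted_jaccard_spectra
community_pair <- function(n_taxa, genome_length, swap_shift, seed) {
  base <- make_community(n_taxa, genome_length, seed = seed)
  list(a = base,
       b = perturb_community(base, swap_shift, "taxon-swap",
                             seed = seed + 1000L))
}

tmp_path <- function(ext = "") tempfile(fileext = ext)
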