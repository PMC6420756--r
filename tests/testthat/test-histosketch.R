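test_that("bin assignment is deterministic and uniform-ish", {
  expect_true(all(assign_bin(c(0, 5, 999), 1, 7) == 1))
  kmers <- histosketchr:::with_seed(1, sample.int(4^10, 1000))
  expect_identical(assign_bin(kmers, 64, 5), assign_bin(kmers, 64, 5))
  expect_false(identical(assign_bin(kmers, 64, 5), assign_bin(kmers, 64, 6)))
  bins <- assign_bin(histosketchr:::with_seed(2, sample.int(2^40, 1e5)),
                     100, 9)
  expect_true(all(bins >= 1 & bins <= 100))
  p <- chisq.test(tabulate(bins, 100))$p.value
  expect_gt(p, 0.001)
})

test_that("CWS draws are pure functions with the stated distributions", {
  d1 <- cws_draw(3, 7, 42)
  d2 <- cws_draw(3, 7, 42)
  expect_identical(d1, d2)
  expect_false(identical(d1, cws_draw(3, 8, 42)))
  expect_false(identical(d1, cws_draw(3, 7, 43)))
  # Gamma(shape 2, scale 1): mean 2, variance 2
  n <- 1e5
  d <- cws_draw(seq_len(n), 1, 13)
  se <- sqrt(2 / n)
  expect_lt(abs(mean(d$r) - 2), 3 * se)
  expect_lt(abs(mean(d$c) - 2), 3 * se)
  expect_true(all(d$beta >= 0 & d$beta <= 1))
  expect_lt(abs(mean(d$beta) - 0.5), 3 * sqrt(1 / 12 / n))
  # draws at adjacent slots look independent
  da <- cws_draw(seq_len(1e4), 1, 13)
  db <- cws_draw(seq_len(1e4), 2, 13)
  expect_lt(abs(cor(da$r, db$r)), 0.05)
})

test_that("the CWS hash matches the closed form and is monotone in weight", {
  h <- cws_hash(1, list(r = 1, c = 1, beta = 0))
  expect_equal(h$y, 1)
  expect_equal(h$a, exp(-1))
  # symbolic simplification: beta = 1, r = log(W), c = 1 gives y = 1, a = 1/W
  W <- 7.5
  h2 <- cws_hash(W, list(r = log(W), c = 1, beta = 1))
  expect_equal(h2$y, 1)
  expect_equal(h2$a, 1 / W)
  d <- cws_draw(5, 9, 1)
  expect_gt(cws_hash(4, d)$y, cws_hash(2, d)$y)
  expect_lt(cws_hash(4, d)$a, cws_hash(2, d)$a)
  expect_error(cws_hash(0, d), "weight")
})

test_that("one-shot creation selects minimal-hash bins per slot", {
  cfg <- sketch_config(k = 21, sketch_size = 16, num_bins = 8,
                       master_seed = 4)
  # single occupied bin is the only candidate everywhere
  hs <- create_histosketch(kmer_spectrum(c(0, 0, 5, 0, 0, 0, 0, 0), 8), cfg)
  expect_true(all(hs$S == 3))
  expect_error(create_histosketch(kmer_spectrum(numeric(8), 8), cfg),
               "empty spectrum")
  # brute-force oracle: independent R loop over all (bin, slot) pairs
  W <- c(2, 0, 1.5, 8, 0, 0.3, 4, 1)
  hs <- create_histosketch(kmer_spectrum(W, 8), cfg)
  for (j in seq_len(cfg$sketch_size)) {
    a <- rep(Inf, 8)
    for (i in which(W > 0))
      a[i] <- cws_hash(W[i], cws_draw(i, j, cfg$master_seed))$a
    expect_equal(hs$S[j], which.min(a))
    expect_equal(hs$A[j], min(a))
  }
  # selection probability tracks weight: a 10^6:1 imbalance dominates
  cfg2 <- sketch_config(sketch_size = 512, num_bins = 2, master_seed = 6)
  hs2 <- create_histosketch(kmer_spectrum(c(1, 1e6), 2), cfg2)
  expect_gt(mean(hs2$S == 2), 0.95)
})

test_that("CWS sampling selects bins proportional to their weights", {
  W <- c(1, 2, 3, 4, 10)
  cfg <- sketch_config(sketch_size = 2000, num_bins = 5, master_seed = 17)
  hs <- create_histosketch(kmer_spectrum(W, 5), cfg)
  counts <- tabulate(hs$S, 5)
  p <- chisq.test(counts, p = W / sum(W))$p.value
  expect_gt(p, 0.001)
})

test_that("incremental updates reproduce one-shot creation", {
  cfg <- sketch_config(sketch_size = 64, num_bins = 500, epsilon = 1e-5,
                       master_seed = 21)
  sp <- random_count_spectrum(500, occupancy = 0.4, seed = 3)
  batch <- create_histosketch(sp, cfg)
  nz <- which(sp$weights > 0)

  # empty sketch updated once: every slot adopts the bin
  cms <- count_min_sketch(cfg$epsilon, cfg$delta, cfg$master_seed)
  cms <- cms_add(cms, nz[1], sp$weights[nz[1]])
  one <- update_histosketch(empty_histosketch(cfg), nz[1], cms)
  expect_true(all(one$S == nz[1]))
  expect_true(all(is.finite(one$A)))

  # element-by-element replay: whole weights in order, then two shuffled
  # half-weight partitions
  for (variant in 1:3) {
    elems <- histosketchr:::with_seed(variant, {
      if (variant == 1) {
        data.frame(bin = nz, amt = sp$weights[nz])
      } else {
        w <- sp$weights[nz]
        df <- data.frame(bin = c(nz, nz), amt = c(floor(w / 2),
                                                  w - floor(w / 2)))
        df <- df[df$amt > 0, ]
        df[sample(nrow(df)), ]
      }
    })
    res <- sketch_bin_stream(elems$bin, elems$amt, cfg)
    expect_identical(res$sketch$S, batch$S)
    expect_identical(res$sketch$A, batch$A)
  }

  # re-updating an already-counted bin at its current estimate is a no-op
  # (ties never displace the incumbent)
  res <- sketch_bin_stream(nz, sp$weights[nz], cfg)
  again <- update_histosketch(res$sketch, nz[5], res$cms)
  expect_identical(again$S, res$sketch$S)
  expect_identical(again$A, res$sketch$A)

  # incompatible seeds are refused
  other <- count_min_sketch(cfg$epsilon, cfg$delta, master_seed = 99)
  expect_error(update_histosketch(batch, nz[1], other), "master_seed")
})

test_that("decay rescales hashes and counters for gradual forgetting", {
  cfg <- sketch_config(sketch_size = 8, num_bins = 16, master_seed = 2)
  sp <- random_count_spectrum(16, seed = 5)
  res <- sketch_bin_stream(which(sp$weights > 0),
                           sp$weights[sp$weights > 0], cfg)
  # decay 0 is the identity
  d0 <- apply_decay(res$sketch, res$cms, 0)
  expect_identical(d0$sketch, res$sketch)
  expect_identical(d0$cms, res$cms)
  # decay 0.02: hashes divided by 0.98, counters multiplied by 0.98
  d <- apply_decay(res$sketch, res$cms, 0.02)
  expect_equal(d$sketch$A, res$sketch$A / 0.98)
  expect_equal(d$cms$counters, res$cms$counters * 0.98)
  # repeated decay: S untouched, A strictly increasing
  d2 <- apply_decay(d$sketch, d$cms, 0.02)
  expect_identical(d2$sketch$S, res$sketch$S)
  expect_true(all(d2$sketch$A > d$sketch$A))
})

test_that("the streaming front end matches one-shot sketching of the reads", {
  comm <- make_community(5, 300, seed = 8)
  fq <- tmp_path(".fastq")
  write_fastq(generate_reads(comm, 400, 80, error_rate = 0.002, seed = 3), fq)
  cfg <- sketch_config(sketch_size = 64, epsilon = 1e-5, master_seed = 31)
  snaps <- sketch_stream(fq, cfg)
  expect_length(snaps, 1)  # interval 0: final snapshot only
  batch <- create_histosketch(exact_spectrum(fq, cfg$k, cfg$num_bins,
                                             cfg$master_seed), cfg)
  expect_identical(snaps[[1]]$S, batch$S)
  expect_identical(snaps[[1]]$A, batch$A)
  expect_equal(snaps[[1]]$reads_consumed, 400)

  # interval flushes: one snapshot per flush plus the final state
  cfg_i <- sketch_config(sketch_size = 64, epsilon = 1e-5, master_seed = 31,
                         interval = 100L)
  snaps_i <- sketch_stream(fq, cfg_i)
  expect_length(snaps_i, 5)
  expect_identical(snaps_i[[5]]$S, batch$S)

  # worker count never changes the result (decay off)
  cfg_p <- sketch_config(sketch_size = 64, epsilon = 1e-5, master_seed = 31,
                         interval = 100L, num_counters = 4L)
  snaps_p <- sketch_stream(fq, cfg_p)
  fin <- snaps_p[[length(snaps_p)]]
  expect_identical(fin$S, batch$S)
  expect_identical(fin$A, batch$A)

  # a stream with no usable k-mers errors
  bad <- tmp_path(".fastq")
  writeLines(c("@r1", "NNNNN", "+", "IIIII"), bad)
  expect_error(sketch_stream(bad, cfg), "nothing to sketch")
})

test_that("sketch files round-trip and refuse foreign content", {
  cfg <- sketch_config(sketch_size = 32, num_bins = 100, master_seed = 12)
  hs <- create_histosketch(random_count_spectrum(100, seed = 4), cfg)
  hs$reads_consumed <- 123
  p <- tmp_path(".sketch")
  save_sketch(hs, p)
  back <- load_sketch(p)
  expect_identical(back$S, hs$S)
  expect_identical(back$A, hs$A)
  expect_identical(back$config, hs$config)
  expect_equal(back$reads_consumed, 123)

  # truncation and bad magic are format errors
  bytes <- readBin(p, "raw", file.size(p))
  trunc <- tmp_path(".sketch")
  writeBin(bytes[1:30], trunc)
  expect_error(load_sketch(trunc), "truncated")
  notsk <- tmp_path(".sketch")
  writeBin(as.raw(1:64), notsk)
  expect_error(load_sketch(notsk), "magic")

  # a sketch from a different k cannot be compared downstream
  cfg2 <- sketch_config(k = 15, sketch_size = 32, num_bins = 100,
                        master_seed = 12)
  hs2 <- create_histosketch(random_count_spectrum(100, seed = 4), cfg2)
  expect_error(jaccard_similarity(hs, hs2), "'k'")

  # JSON export mirrors the same fields
  js <- jsonlite::fromJSON(export_sketch_json(hs))
  expect_equal(js$k, cfg$k)
  expect_equal(js$S, hs$S)
  expect_equal(js$A, hs$A)
})
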