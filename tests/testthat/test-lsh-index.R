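# helper: planted sketch set with a known similarity structure: `n_base`
# random base sketches, each with `n_copy` near-duplicates made by redrawing
# `mut` slots, under one shared config
planted_sketch_set <- function(cfg, n_base, n_copy, mut_range, seed) {
  histosketchr:::with_seed(seed, {
    Z <- cfg$sketch_size
    out <- list()
    for (b in seq_len(n_base)) {
      base <- sample.int(cfg$num_bins, Z, TRUE)
      out[[sprintf("b%d", b)]] <- planted_sketch(base, cfg)
      for (c in seq_len(n_copy)) {
        mut <- sample(mut_range, 1)
        S <- base
        idx <- sample(Z, mut)
        S[idx] <- sample.int(cfg$num_bins, mut, TRUE)
        out[[sprintf("b%d_c%d", b, c)]] <- planted_sketch(S, cfg)
      }
    }
    out
  })
}

brute_force_neighbours <- function(sketches, threshold) {
  labs <- names(sketches)
  lapply(stats::setNames(labs, labs), function(q) {
    sims <- vapply(labs, function(e)
      jaccard_similarity(sketches[[q]], sketches[[e]]), numeric(1))
    labs[sims >= threshold & labs != q]
  })
}

test_that("parameter tuning matches exhaustive evaluation of the model", {
  # independent enumeration for Z = 4: the six divisor pairs
  pairs <- list(c(1, 1), c(1, 2), c(2, 1), c(1, 4), c(2, 2), c(4, 1))
  for (thr in c(0.5, 0.7, 0.9)) {
    scores <- vapply(pairs, function(kl) {
      p_t <- 1 - (1 - thr^kl[1])^kl[2]
      (1 - p_t) + (1 - (1 - (thr - 0.05)^kl[1])^kl[2])
    }, numeric(1))
    best <- pairs[scores == min(scores)]
    bestK <- max(vapply(best, `[`, numeric(1), 1))
    tuned <- tune_lsh_parameters(4, thr)
    expect_equal(tuned$K, bestK)
    expect_equal(tuned$K * tuned$L <= 4, TRUE)
  }
  # Z = 512: the returned pair is optimal among all divisor pairs
  tuned <- tune_lsh_parameters(512, 0.9)
  expect_true(512 %% (tuned$K * tuned$L) == 0)
  for (K in c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512)) {
    for (L in c(1, 2, 4, 8, 16, 32, 64, 128, 256, 512)) {
      if (512 %% (K * L) != 0 || K * L > 512) next
      fn <- (1 - 0.9^K)^L
      fp <- 1 - (1 - 0.85^K)^L
      expect_gte(fn + fp + 1e-12, tuned$fn + tuned$fp)
    }
  }
  # perfect similarity always collides under the model, for any (K, L)
  for (kl in pairs)
    expect_equal(histosketchr:::lsh_collision_prob(1, kl[1], kl[2]), 1)
  # unmeetable constraints are refused with advice
  expect_error(tune_lsh_parameters(2, 0.5, max_fn = 1e-6), "larger sketch")
})

test_that("create, add and search behave on degenerate cases", {
  cfg <- sketch_config(sketch_size = 16, num_bins = 1000, master_seed = 2)
  s1 <- planted_sketch(histosketchr:::with_seed(1, sample.int(1000, 16, TRUE)),
                       cfg)
  idx <- lsh_index_create(list(s1), "one", threshold = 0.9)
  # one sketch indexed: its key appears in every table
  expect_equal(length(idx$tables), idx$L)
  expect_true(all(vapply(idx$tables, function(t) "one" %in% unlist(t),
                         logical(1))))
  # querying an indexed sketch returns its label
  expect_equal(lsh_index_search(idx, s1), "one")
  # identical sketches under different labels share all chunk keys
  idx2 <- lsh_index_create(list(s1, s1), c("a", "b"), threshold = 0.9)
  expect_setequal(lsh_index_search(idx2, s1), c("a", "b"))
  # disjoint query finds nothing
  s2 <- planted_sketch(rep(999L, 16), cfg)
  expect_equal(lsh_index_search(idx, s2), character(0))
  # duplicate labels and incomparable sketches are refused
  expect_error(lsh_index_create(list(s1, s1), c("a", "a")), "duplicate")
  foreign <- planted_sketch(1:16, sketch_config(sketch_size = 16,
                                                num_bins = 1000,
                                                master_seed = 3))
  expect_error(lsh_index_add(idx, foreign, "f"), "master_seed")
  expect_error(lsh_index_search(idx, foreign), "master_seed")
})

test_that("search equals brute force up to the tuned miss rate", {
  cfg <- sketch_config(sketch_size = 128, num_bins = 10000, master_seed = 5)
  thr <- 0.9
  missed <- 0L
  total <- 0L
  fn_bound <- tune_lsh_parameters(cfg$sketch_size, thr)$fn
  for (seed in 1:3) {
    sketches <- planted_sketch_set(cfg, n_base = 5, n_copy = 3,
                                   mut_range = 2:10, seed = seed)
    idx <- lsh_index_create(sketches, threshold = thr)
    truth <- brute_force_neighbours(sketches, thr)
    for (q in names(sketches)) {
      hits <- lsh_index_search(idx, sketches[[q]])
      hits <- setdiff(hits, q)
      # no false positives after filtering
      expect_true(all(hits %in% truth[[q]]))
      missed <- missed + sum(!truth[[q]] %in% hits)
      total <- total + length(truth[[q]])
    }
  }
  expect_gt(total, 20)
  se <- sqrt(fn_bound * (1 - fn_bound) / total)
  expect_lte(missed / total, fn_bound + 3 * se + 1e-9)
})

test_that("indexes survive save/load and are insertion-order invariant", {
  cfg <- sketch_config(sketch_size = 32, num_bins = 500, master_seed = 7)
  sketches <- planted_sketch_set(cfg, n_base = 3, n_copy = 2,
                                 mut_range = 1:3, seed = 9)
  idx <- lsh_index_create(sketches, threshold = 0.9)
  p <- tmp_path(".json")
  save_lsh_index(idx, p)
  back <- load_lsh_index(p)
  shuffled <- sketches[rev(seq_along(sketches))]
  idx_rev <- lsh_index_create(shuffled, threshold = 0.9)
  for (q in names(sketches)) {
    ref <- lsh_index_search(idx, sketches[[q]])
    expect_identical(lsh_index_search(back, sketches[[q]]), ref)
    expect_identical(lsh_index_search(idx_rev, sketches[[q]]), ref)
  }
  # add-then-search equals create-with-all
  grown <- lsh_index_create(sketches[1:3], threshold = 0.9)
  for (i in 4:length(sketches))
    grown <- lsh_index_add(grown, sketches[[i]], names(sketches)[i])
  for (q in names(sketches))
    expect_identical(lsh_index_search(grown, sketches[[q]]),
                     lsh_index_search(idx, sketches[[q]]))
  expect_error(load_lsh_index(export_sketch_json(sketches[[1]],
                                                 tmp_path(".json"))),
               "not an LSH")
})
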