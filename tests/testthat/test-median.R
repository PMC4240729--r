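test_that("weighted genome sets collapse equivalent entries", {
  A <- genome_set(list(1:4, c(4, 3, 2, 1), c(2, 1, 4, 3)))
  expect_identical(nrow(A), 2L)
  expect_identical(A$weight[A$representative == "1 2 3 4"], 2L)
  expect_error(genome_set(list(1:4), weight = 0L), class = "bpmedian_input_error")
  expect_error(total_distance(1:4, list()), class = "bpmedian_input_error")
})

test_that("total distance is the weighted sum of member distances", {
  expect_identical(total_distance(1:5, genome_set(list(1:5))), 0L)
  X <- max_distant_set(7, 3, seed = 21)
  # each member sits at (k-1)(n-1) from the set
  for (g in X$genome) expect_identical(total_distance(g, X), 12L)
  # doubling one member's weight adds its distance once more
  q <- c(2L, 3L, 1L, 4L, 5L, 6L, 7L)
  A1 <- genome_set(X$genome)
  A2 <- genome_set(X$genome, weight = c(2L, 1L, 1L))
  expect_identical(total_distance(q, A2),
                   total_distance(q, A1) + bp_distance(q, X$genome[[1L]]))
})

test_that("total distance and medians are invariant under reversing inputs", {
  withr::with_seed(81, {
    for (rep in 1:20) {
      gs <- lapply(1:3, function(i) sample.int(5))
      flip <- lapply(gs, function(g) if (runif(1) < .5) rev(g) else g)
      q <- sample.int(5)
      expect_identical(total_distance(q, genome_set(gs)),
                       total_distance(rev(q), genome_set(flip)))
      m1 <- median_bruteforce(gs)
      m2 <- median_bruteforce(flip)
      expect_identical(m1$value, m2$value)
      expect_identical(keyset(m1$medians), keyset(m2$medians))
    }
  })
})

test_that("brute-force medians match the exhaustive oracle", {
  # singleton: the input is its own unique median
  m <- median_bruteforce(list(c(3, 1, 2, 4)))
  expect_identical(m$value, 0L)
  expect_identical(keyset(m$medians), key_of(c(3, 1, 2, 4)))
  withr::with_seed(82, {
    for (rep in 1:10) {
      gs <- lapply(1:3, function(i) sample.int(5))
      w <- sample(1:3, 3, replace = TRUE)
      got <- median_bruteforce(genome_set(gs, weight = w))
      want <- brute_median(gs, weight = w)
      expect_identical(as.numeric(got$value), want$value)
      expect_identical(keyset(got$medians), want$keys)
    }
  })
})

test_that("the median set of two genomes is their patch union set", {
  withr::with_seed(83, {
    for (rep in 1:10) {
      x <- sample.int(6); y <- sample.int(6)
      m <- median_bruteforce(list(x, y))
      expect_identical(m$value, bp_distance(x, y))
      expect_identical(keyset(m$medians),
                       sort(patch_union_set(x, y)$representative))
    }
  })
})

test_that("maximally-distant sets attain median value (k-1)(n-1) with the characterized median set", {
  for (nk in list(c(5, 2), c(6, 2), c(6, 3), c(7, 3))) {
    n <- nk[1L]; k <- nk[2L]
    X <- max_distant_set(n, k, seed = 100L + n * 10L + k)
    bf <- median_bruteforce(X)
    expect_identical(bf$value, as.integer((k - 1) * (n - 1)))
    ms <- median_set_maxdist(X)
    expect_identical(ms$value, bf$value)
    expect_identical(keyset(ms$medians), keyset(bf$medians))
    # the inputs themselves are medians
    expect_true(all(X$representative %in% keyset(ms$medians)))
  }
})

test_that("the adjacency-inclusion median test agrees with brute-force membership", {
  # k = 2 keeps the union graph a strict subset of K_6, so non-medians exist
  X <- max_distant_set(6, 2, seed = 31)
  bf <- median_bruteforce(X)
  med_keys <- keyset(bf$medians)
  cl <- enumerate_classes(6)
  for (i in seq_len(nrow(cl))) {
    expect_identical(is_median_maxdist(cl[i, ], X),
                     key_of(cl[i, ]) %in% med_keys)
  }
  # inputs are medians; precondition is enforced
  for (g in X$genome) expect_true(is_median_maxdist(g, X))
  expect_error(is_median_maxdist(1:4, list(1:4, c(2, 1, 3, 4))),
               class = "bpmedian_precondition_error")
  # a genome with an adjacency outside the union is strictly worse
  out <- cl[!vapply(seq_len(nrow(cl)), function(i) is_median_maxdist(cl[i, ], X), TRUE), , drop = FALSE]
  expect_gt(nrow(out), 0L)
  expect_gt(total_distance(out[1L, ], X), bf$value)
})

test_that("one-step accessibility contains the seed set and its pairwise patches", {
  X <- max_distant_set(6, 2, seed = 41)
  z1 <- one_step_accessible(X)
  expect_true(all(X$representative %in% z1$representative))
  pw <- patch_union_set(X$genome[[1L]], X$genome[[2L]])
  expect_true(all(pw$representative %in% z1$representative))
  # a singleton reaches only itself
  solo <- one_step_accessible(list(c(2, 1, 3, 4, 5)))
  expect_identical(solo$representative, "2 1 3 4 5")
})

test_that("the accessibility closure is a monotone idempotent fixed point", {
  sets <- list(
    max_distant_set(6, 3, seed = 42)$genome,
    withr::with_seed(43, lapply(1:3, function(i) sample_class(6))))
  for (gs in sets) {
    z1 <- one_step_accessible(gs)
    zb <- accessible_closure(gs)
    expect_true(all(vapply(gs, key_of, "") %in% zb$representative))
    expect_true(all(z1$representative %in% zb$representative)) # monotone
    again <- one_step_accessible(zb)
    expect_identical(sort(again$representative), sort(zb$representative))
  }
  expect_error(accessible_closure(list(sample.int(9))),
               class = "bpmedian_cap_error")
})

test_that("accessible genomes are medians when inputs are maximally distant", {
  for (nk in list(c(6, 2), c(6, 3))) {
    X <- max_distant_set(nk[1L], nk[2L], seed = 44)
    zb <- accessible_closure(X)
    med <- keyset(median_bruteforce(X)$medians)
    expect_true(all(zb$representative %in% med))
  }
})

test_that("patches between medians stay inside the median set", {
  X <- max_distant_set(6, 3, seed = 45)
  bf <- median_bruteforce(X)
  med_keys <- keyset(bf$medians)
  withr::with_seed(46, {
    for (rep in 1:10) {
      pick <- sample(length(bf$medians), 2L)
      pw <- patch_union_set(bf$medians[[pick[1L]]], bf$medians[[pick[2L]]])
      expect_true(all(pw$representative %in% med_keys))
    }
  })
})

test_that("the accessibility report is internally consistent", {
  # k = 2: the median set is exactly the patch, and it is fully accessible
  X2 <- max_distant_set(6, 2, seed = 47)
  rep2 <- conjecture_report(X2)
  expect_true(rep2$equal)
  expect_identical(rep2$n_medians,
                   nrow(patch_union_set(X2$genome[[1L]], X2$genome[[2L]])))
  # k = 3 diagnostic: containment always holds, sizes add up
  X3 <- max_distant_set(6, 3, seed = 48)
  rep3 <- conjecture_report(X3)
  expect_lte(rep3$n_accessible, rep3$n_medians)
  expect_identical(rep3$n_medians,
                   rep3$n_accessible + nrow(rep3$not_accessible))
  expect_identical(rep3$median_value, 10L)
})
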