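test_that("patch membership agrees with the worked chain and rejects off-patch points", {
  expect_true(on_patch(c(2, 1, 3, 4, 5, 6), eq6_x, eq6_y))
  expect_true(on_patch(eq6_x, eq6_x, eq6_y)) # endpoints are always members
  expect_true(on_patch(eq6_y, eq6_x, eq6_y))
  # 3 2 1 4 5 6 shares 4 adjacencies with id but none with the other end:
  # the distance sum is 1 + 5 > 5, so it lies on no patch
  expect_false(on_patch(c(3, 2, 1, 4, 5, 6), eq6_x, eq6_y))
  expect_error(on_patch(1:5, eq6_x, eq6_y), class = "bpmedian_input_error")
})

test_that("the additivity and adjacency-inclusion criteria coincide", {
  # exhaustive over all class triples for n = 4
  cl <- enumerate_classes(4)
  for (ix in seq_len(nrow(cl))) {
    for (iy in seq_len(nrow(cl))) {
      for (iz in seq_len(nrow(cl))) {
        expect_identical(
          on_patch(cl[iz, ], cl[ix, ], cl[iy, ], criterion = "additivity"),
          on_patch(cl[iz, ], cl[ix, ], cl[iy, ], criterion = "adjacency"))
      }
    }
  }
  # randomized at n = 6, 7
  withr::with_seed(74, {
    for (rep in 1:400) {
      n <- sample(6:7, 1L)
      x <- sample.int(n); y <- sample.int(n); z <- sample.int(n)
      expect_identical(on_patch(z, x, y, criterion = "additivity"),
                       on_patch(z, x, y, criterion = "adjacency"))
    }
  })
})

test_that("patch union sets match the exhaustive additivity oracle", {
  # degenerate pair: a point is its own patch
  p <- patch_union_set(1:5, c(5, 4, 3, 2, 1))
  expect_identical(p$representative, "1 2 3 4 5")
  # frozen worked case: exactly the two endpoint classes
  expect_identical(sort(patch_union_set(1:4, c(2, 1, 4, 3))$representative),
                   c("1 2 3 4", "2 1 4 3"))
  # all class pairs at n = 4 against the oracle
  cl <- enumerate_classes(4)
  for (ix in seq_len(nrow(cl))) {
    for (iy in seq_len(nrow(cl))) {
      got <- sort(patch_union_set(cl[ix, ], cl[iy, ])$representative)
      expect_identical(got, brute_patch_keys(cl[ix, ], cl[iy, ]))
    }
  }
  # sampled pairs at n = 6, plus symmetry and endpoint membership
  withr::with_seed(75, {
    for (rep in 1:25) {
      x <- sample.int(6); y <- sample.int(6)
      got <- patch_union_set(x, y)
      expect_identical(sort(got$representative), brute_patch_keys(x, y))
      expect_identical(sort(got$representative),
                       sort(patch_union_set(y, x)$representative))
      expect_true(all(c(key_of(x), key_of(y)) %in% got$representative))
      expect_true(all(vapply(got$genome, on_patch, TRUE, x = x, y = y)))
    }
  })
})

test_that("hamiltonian-path and oracle engines enumerate identical patch sets", {
  for (n in 4:5) {
    cl <- enumerate_classes(n)
    idx <- seq_len(nrow(cl))
    for (ix in idx) {
      for (iy in idx[idx >= ix]) {
        expect_identical(
          sort(patch_union_set(cl[ix, ], cl[iy, ], method = "hampath")$representative),
          sort(patch_union_set(cl[ix, ], cl[iy, ], method = "oracle")$representative))
      }
    }
  }
  withr::with_seed(76, {
    for (rep in 1:40) {
      x <- sample.int(6); y <- sample.int(6)
      expect_identical(
        sort(patch_union_set(x, y, method = "hampath")$representative),
        sort(patch_union_set(x, y, method = "oracle")$representative))
    }
  })
})

test_that("hamiltonian path enumeration honors edge and required-edge constraints", {
  # a path graph has exactly one Hamiltonian path class
  hp <- hamiltonian_paths(4, cbind(1:3, 2:4))
  expect_length(hp, 1L)
  expect_identical(hp[[1L]], 1:4)
  # required edges forming a 3-cycle can lie on no path: empty result
  edges <- rbind(cbind(1:3, 2:4), c(1L, 3L))
  expect_length(
    hamiltonian_paths(4, edges,
                      required = rbind(c(1L, 2L), c(2L, 3L), c(1L, 3L))),
    0L)
  # a usable required edge restricts the enumeration
  expect_identical(
    keyset(hamiltonian_paths(4, edges, required = cbind(1L, 3L))),
    "2 1 3 4")
  # required edges must come from `edges`
  expect_error(hamiltonian_paths(4, cbind(1:3, 2:4), required = cbind(1L, 4L)),
               class = "bpmedian_input_error")
  # union graph of the worked pair reproduces its patch set
  ux <- adjacency_set(eq6_x); uy <- adjacency_set(eq6_y)
  edges6 <- unique(rbind(as.matrix(ux), as.matrix(uy)))
  got <- hamiltonian_paths(6, edges6)
  expect_identical(keyset(got), brute_patch_keys(eq6_x, eq6_y))
  expect_length(got, 28L)
})

test_that("a maximal geodesic exists for the worked pair and is verified stepwise", {
  chain <- find_geodesic(eq6_x, eq6_y)
  expect_length(chain, 6L)
  expect_true(is_valid_geodesic(chain))
  expect_identical(chain[[1L]], eq6_x)
  expect_identical(chain[[6L]], eq6_y)
  # determinism
  expect_identical(find_geodesic(eq6_x, eq6_y), chain)
  # trivial chains
  expect_identical(find_geodesic(1:5, 1:5), list(1:5))
  expect_length(find_geodesic(1:5, c(2, 1, 3, 4, 5)), 2L)
})

test_that("the non-geodesic family admits no geodesic, exhaustively over middles", {
  for (n in 6:7) {
    mids <- e1071::permutations(n - 4L) + 2L
    for (i in seq_len(nrow(mids))) {
      mid <- as.integer(mids[i, ])
      if (all(mid == sort(mid))) next # identity middle excluded by the family
      pr <- nongeodesic_pair(n, mid)
      expect_null(find_geodesic(pr$x, pr$y))
    }
  }
})

test_that("found geodesics are always valid chains on random pairs", {
  withr::with_seed(77, {
    found <- 0L
    for (rep in 1:60) {
      x <- sample.int(6); y <- sample.int(6)
      chain <- find_geodesic(x, y)
      if (!is.null(chain)) {
        found <- found + 1L
        expect_length(chain, bp_distance(x, y) + 1L)
        expect_true(is_valid_geodesic(chain))
      }
    }
    expect_gt(found, 0L)
  })
})

test_that("patch members of a maximally-distant pair stay maximal to a third", {
  X <- max_distant_set(7, 3, seed = 11)
  gs <- X$genome
  p12 <- patch_union_set(gs[[1L]], gs[[2L]])
  for (w in p12$genome) {
    expect_identical(bp_distance(w, gs[[3L]]), 6L)
  }
})
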