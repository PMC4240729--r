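# Independent brute-force oracles used across the suite. These deliberately
# go through nothing but bp_distance()/adjacency_set() and exhaustive
# enumeration, so they stay independent of the solver paths they check.

key_of <- function(p) paste(bpmedian::class_of(p), collapse = " ")

keyset <- function(gs) sort(vapply(gs, key_of, ""))

# all genomes of length n as a list (both orientations)
all_perms <- function(n) {
  m <- e1071::permutations(n)
  lapply(seq_len(nrow(m)), function(i) as.integer(m[i, ]))
}

# patch membership by the additivity definition, filtered over all classes
brute_patch_keys <- function(x, y) {
  cl <- enumerate_classes(length(x))
  d <- bp_distance(x, y)
  keep <- vapply(seq_len(nrow(cl)), function(i) {
    bp_distance(x, cl[i, ]) + bp_distance(cl[i, ], y) == d
  }, TRUE)
  sort(apply(cl[keep, , drop = FALSE], 1L, paste, collapse = " "))
}

# exact median value and median keys by an explicit double loop
brute_median <- function(genomes, weight = NULL) {
  gs <- lapply(genomes, as_genome)
  w <- rep_len(weight %||% 1L, length(gs))
  cl <- enumerate_classes(length(gs[[1L]]))
  td <- vapply(seq_len(nrow(cl)), function(i) {
    sum(w * vapply(gs, function(g) bp_distance(cl[i, ], g), 0L))
  }, 0)
  list(value = min(td),
       keys = sort(apply(cl[td == min(td), , drop = FALSE], 1L,
                         paste, collapse = " ")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# distance matrix over the enumerated classes, by pairwise bp_distance
brute_distance_matrix <- function(n) {
  cl <- enumerate_classes(n)
  m <- nrow(cl)
  D <- matrix(0L, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) D[i, j] <- bp_distance(cl[i, ], cl[j, ])
  }
  D
}

# a maximally-distant pair used in many fixtures
eq6_x <- 1:6
eq6_y <- c(1L, 3L, 5L, 2L, 4L, 6L)
# the six chain classes between them, canonical representatives
eq6_chain <- list(
  c(1L, 2L, 3L, 4L, 5L, 6L),
  c(2L, 1L, 3L, 4L, 5L, 6L),
  c(3L, 1L, 2L, 4L, 5L, 6L),
  c(4L, 2L, 1L, 3L, 5L, 6L),
  c(5L, 3L, 1L, 2L, 4L, 6L),
  c(1L, 3L, 5L, 2L, 4L, 6L)
)

# is a chain a genuine geodesic (pairwise isometric to 0..D)?
is_valid_geodesic <- function(chain) {
  D <- length(chain) - 1L
  for (i in seq_along(chain)) {
    for (j in seq_along(chain)) {
      if (bp_distance(chain[[i]], chain[[j]]) != abs(i - j)) return(FALSE)
    }
  }
  TRUE
}
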