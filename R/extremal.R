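# Constructions of the special inputs the theory is about: k genomes
# pairwise at maximum distance (edge-disjoint Hamiltonian paths of K_n),
# and the family of pairs with no geodesic between them.

#' Construct k pairwise maximally-distant genome classes
#'
#' Finds `k` genome classes of length `n` whose adjacency sets are pairwise
#' disjoint, i.e. pairwise at bp distance `n - 1`. Such a set corresponds
#' to `k` edge-disjoint Hamiltonian paths of the complete graph `K_n`,
#' which exist iff `k <= floor(n/2)` (K_n decomposes into exactly
#' `floor(n/2)` Hamiltonian paths), so larger `k` is rejected up front.
#'
#' The search is randomized backtracking: each path is grown gene by gene,
#' shuffling candidate next genes with a seeded RNG and backtracking when a
#' path or the whole set gets stuck. Identical `(n, k, seed)` always yields
#' the identical set, and the pairwise-distance postcondition is verified
#' before returning.
#'
#' @param n Number of genes (`n >= 2`).
#' @param k Number of genomes (`1 <= k <= floor(n/2)`).
#' @param seed Integer seed driving the randomized search.
#' @param max_restarts Restarts of the whole construction before giving up.
#' @return A tibble with columns `representative` and `genome`, `k` rows,
#'   with attributes `n`, `k`, `seed`.
#' @examples
#' max_distant_set(7, 3, seed = 1)
#' @export
max_distant_set <- function(n, k, seed, max_restarts = 200L) {
  n <- as.integer(n); k <- as.integer(k)
  if (n < 2L || k < 1L) {
    abort("need n >= 2 and k >= 1", class = "bpmedian_input_error")
  }
  if (k > n %/% 2L) {
    abort(sprintf(
      "k = %d infeasible for n = %d: k(n-1) edge-disjoint adjacencies cannot exceed the n(n-1)/2 edges of K_n, so k <= floor(n/2) = %d",
      k, n, n %/% 2L), class = "bpmedian_input_error")
  }
  genomes <- withr::with_seed(seed, {
    res <- NULL
    for (attempt in seq_len(max_restarts)) {
      res <- try_edge_disjoint_paths(n, k)
      if (!is.null(res)) break
    }
    res
  })
  if (is.null(genomes)) {
    abort(sprintf(
      "randomized search failed to find %d edge-disjoint Hamiltonian paths of K_%d after %d restarts",
      k, n, max_restarts), class = "bpmedian_search_error")
  }
  gs <- lapply(genomes, class_of)
  check_pairwise_maxdist(gs)
  out <- class_tibble(gs)
  attr(out, "n") <- n; attr(out, "k") <- k; attr(out, "seed") <- seed
  out
}

# one attempt: build the k paths greedily with in-path backtracking,
# restarting the attempt if some path cannot be completed
try_edge_disjoint_paths <- function(n, k) {
  used <- matrix(FALSE, n, n) # symmetric edge-used marker
  paths <- vector("list", k)
  for (i in seq_len(k)) {
    p <- random_path_avoiding(n, used)
    if (is.null(p)) return(NULL)
    paths[[i]] <- p
    for (j in seq_len(n - 1L)) {
      used[p[j], p[j + 1L]] <- TRUE
      used[p[j + 1L], p[j]] <- TRUE
    }
  }
  paths
}

# Hamiltonian path of K_n avoiding used edges, by randomized DFS
random_path_avoiding <- function(n, used) {
  visited <- logical(n)
  path <- integer(n)
  dfs <- function(u, depth) {
    if (depth == n) return(TRUE)
    cand <- which(!visited & !used[u, ])
    if (!length(cand)) return(FALSE)
    for (v in cand[sample.int(length(cand))]) {
      visited[v] <<- TRUE
      path[depth + 1L] <<- v
      if (dfs(v, depth + 1L)) return(TRUE)
      visited[v] <<- FALSE
    }
    FALSE
  }
  for (s in sample.int(n)) {
    visited[] <- FALSE
    visited[s] <- TRUE
    path[1L] <- s
    if (dfs(s, 1L)) return(path)
  }
  NULL
}

#' A pair of genomes with no geodesic between them
#'
#' Builds the pair `(id_n, 1 2 m_1 ... m_{n-4} n-1 n)` where
#' `m_1 ... m_{n-4}` is a non-identity arrangement of `{3, ..., n-2}`. No
#' chain between the two realizes every intermediate distance, so
#' [find_geodesic()] returns `NULL` on every such pair — the witness that
#' the bp space is not geodesic.
#'
#' @param n Number of genes (`n >= 6`).
#' @param middle Integer vector: a non-identity arrangement of
#'   `{3, ..., n-2}`.
#' @return A list with genomes `x` (the identity) and `y`.
#' @examples
#' nongeodesic_pair(7, c(4, 3, 5))
#' @export
nongeodesic_pair <- function(n, middle) {
  n <- as.integer(n)
  if (n < 6L) {
    abort("the non-geodesic family needs n >= 6", class = "bpmedian_input_error")
  }
  middle <- as.integer(middle)
  want <- 3:(n - 2L)
  if (length(middle) != length(want) || !setequal(middle, want)) {
    abort(sprintf("`middle` must arrange {3, ..., %d}", n - 2L),
          class = "bpmedian_input_error")
  }
  if (all(middle == want)) {
    abort("`middle` must not be the identity arrangement (the pair would be geodesically connected)",
          class = "bpmedian_input_error")
  }
  list(x = seq_len(n), y = c(1L, 2L, middle, n - 1L, n))
}
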