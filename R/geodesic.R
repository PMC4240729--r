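# Geodesic patches in the space of genome classes.
#
# The bp space is not geodesic: between some pairs of genomes no chain
# realizing every intermediate distance exists. The union of all geodesic
# patches between x and y, written [x,y] with an overline in the field's
# notation, admits a purely adjacency-level characterization:
#   z lies on a patch  <=>  A_xy ⊆ A_z ⊆ A_x ∪ A_y
# which is equivalent to the additivity criterion d(x,z) + d(z,y) = d(x,y).

#' Is a genome on a geodesic patch between two others?
#'
#' Tests whether `z` lies on some geodesic patch between `x` and `y`. Two
#' equivalent criteria are implemented: `"additivity"` checks
#' `d(x,z) + d(z,y) = d(x,y)`; `"adjacency"` checks
#' `A_xy ⊆ A_z ⊆ A_x ∪ A_y`. They always agree (their equivalence is a
#' theorem about the bp space, and a property test of this package).
#'
#' @param z,x,y Genomes of the same length.
#' @param criterion Which characterization to evaluate.
#' @return Logical scalar.
#' @examples
#' on_patch(c(2, 1, 3, 4, 5, 6), 1:6, c(1, 3, 5, 2, 4, 6)) # TRUE
#' @export
on_patch <- function(z, x, y, criterion = c("additivity", "adjacency")) {
  criterion <- match.arg(criterion)
  z <- as_genome(z); x <- as_genome(x); y <- as_genome(y)
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    abort("genomes must have the same number of genes",
          class = "bpmedian_input_error")
  }
  if (criterion == "additivity") {
    bp_distance(x, z) + bp_distance(z, y) == bp_distance(x, y)
  } else {
    az <- adj_codes(z)
    required <- intersect(adj_codes(x), adj_codes(y))
    allowed <- union(adj_codes(x), adj_codes(y))
    all(required %in% az) && all(az %in% allowed)
  }
}

# ---- Hamiltonian path enumeration ------------------------------------------

#' Enumerate Hamiltonian paths with required edges
#'
#' Enumerates every linear gene order on `1..n` whose adjacency set is
#' contained in `edges` and contains `required`, one canonical
#' representative per genome class. This realizes the adjacency
#' characterization of patch membership constructively: candidate members
#' are exactly the Hamiltonian paths of the graph `(1..n, A_x ∪ A_y)` using
#' every edge of `A_xy`.
#'
#' The search is a depth-first walk with required-edge pruning: once a
#' vertex becomes interior to the partial path, all its required edges must
#' already lie on the path, so any branch violating that is cut.
#'
#' @param n Number of vertices (gene labels `1..n`).
#' @param edges Two-column matrix or data frame of available adjacencies.
#' @param required Optional two-column matrix or data frame of adjacencies
#'   every path must use; must be a subset of `edges`.
#' @return A list of canonical genomes (possibly empty), sorted by their
#'   representative string.
#' @examples
#' hamiltonian_paths(4, cbind(1:3, 2:4)) # only the identity class
#' @export
hamiltonian_paths <- function(n, edges, required = NULL) {
  n <- as.integer(n)
  e <- as_edge_matrix(edges, n)
  r <- as_edge_matrix(required, n)
  ecodes <- pair_code(e[, 1L], e[, 2L], n)
  rcodes <- if (nrow(r)) pair_code(r[, 1L], r[, 2L], n) else integer(0)
  if (!all(rcodes %in% ecodes)) {
    abort("`required` must be a subset of `edges`",
          class = "bpmedian_input_error")
  }
  nbrs <- vector("list", n)
  req_nbrs <- vector("list", n)
  for (v in seq_len(n)) nbrs[[v]] <- req_nbrs[[v]] <- integer(0)
  for (i in seq_len(nrow(e))) {
    a <- e[i, 1L]; b <- e[i, 2L]
    nbrs[[a]] <- c(nbrs[[a]], b)
    nbrs[[b]] <- c(nbrs[[b]], a)
  }
  for (i in seq_len(nrow(r))) {
    a <- r[i, 1L]; b <- r[i, 2L]
    req_nbrs[[a]] <- c(req_nbrs[[a]], b)
    req_nbrs[[b]] <- c(req_nbrs[[b]], a)
  }
  found <- new.env(parent = emptyenv())
  visited <- logical(n)
  path <- integer(n)

  extend <- function(u, prev, depth) {
    if (depth == n) {
      # endpoint: its required edges must all have been used (== go to prev)
      ru <- req_nbrs[[u]]
      if (length(ru) && !all(ru == prev)) return(invisible())
      key <- paste(class_of(path), collapse = " ")
      if (is.null(found[[key]])) found[[key]] <- path
      return(invisible())
    }
    ru <- req_nbrs[[u]]
    for (v in nbrs[[u]]) {
      if (visited[v]) next
      # leaving u via v makes u interior: required edges at u must be
      # exactly among {prev, v}
      if (length(ru) && !all(ru == prev | ru == v)) next
      visited[v] <<- TRUE
      path[depth + 1L] <<- v
      extend(v, u, depth + 1L)
      visited[v] <<- FALSE
    }
    invisible()
  }

  for (s in seq_len(n)) {
    visited[] <- FALSE
    visited[s] <- TRUE
    path[1L] <- s
    extend(s, 0L, 1L)
  }
  keys <- ls(found)
  lapply(keys[order(keys)], function(k) class_of(found[[k]]))
}

as_edge_matrix <- function(edges, n) {
  if (is.null(edges)) return(matrix(integer(0), 0L, 2L))
  if (is.data.frame(edges)) edges <- as.matrix(edges)
  if (!is.matrix(edges) || ncol(edges) != 2L) {
    abort("edges must be a two-column matrix or data frame",
          class = "bpmedian_input_error")
  }
  storage.mode(edges) <- "integer"
  if (nrow(edges) && (any(edges < 1L | edges > n) ||
                      any(edges[, 1L] == edges[, 2L]))) {
    abort("edges must join two distinct labels in 1..n",
          class = "bpmedian_input_error")
  }
  edges
}

# ---- the union-of-patches set ---------------------------------------------

# internal: row indices (into class_space(n)$classes) of [x,y].
# With the cached pairwise eps matrix this is the additivity criterion
# |A_zx| + |A_zy| = (n-1) + |A_xy| as one vectorized comparison; otherwise
# the adjacency-inclusion criterion as two incidence mat-vecs.
patch_rows <- function(xi, yi, sp) {
  E <- space_eps(sp)
  if (!is.null(E)) {
    return(which(E[, xi] + E[, yi] == (sp$n - 1) + E[xi, yi]))
  }
  ax <- sp$L[xi, ]; ay <- sp$L[yi, ]
  allowed <- pmax(ax, ay)
  required <- ax * ay
  bad <- as.vector(sp$L %*% (1 - allowed))
  hits <- as.vector(sp$L %*% required)
  which(bad == 0 & hits == sum(required))
}

#' All genomes on geodesic patches between two genomes
#'
#' Computes the full set of genome classes lying on some geodesic patch
#' between `x` and `y`, i.e. all `z` with `A_xy ⊆ A_z ⊆ A_x ∪ A_y`. Two
#' independent engines are provided: `"oracle"` filters the exhaustive class
#' enumeration (requires `n <= cap`); `"hampath"` enumerates Hamiltonian
#' paths of the graph with edge set `A_x ∪ A_y` that use every edge of
#' `A_xy`, and works for any `n` the search can handle (the union graph has
#' maximum degree 4). The engines return identical sets.
#'
#' @param x,y Genomes of the same length.
#' @param method Computation engine.
#' @param cap Enumeration cap for the oracle engine.
#' @return A tibble with a `representative` string column and a `genome`
#'   list-column, one row per member class; always contains `x` and `y`.
#' @examples
#' patch_union_set(1:4, c(2, 1, 4, 3))
#' @export
patch_union_set <- function(x, y, method = c("oracle", "hampath"),
                            cap = bp_enum_cap()) {
  method <- match.arg(method)
  x <- as_genome(x); y <- as_genome(y)
  n <- length(x)
  if (length(y) != n) {
    abort("genomes must have the same number of genes",
          class = "bpmedian_input_error")
  }
  if (method == "oracle") {
    check_cap(n, cap)
    sp <- class_space(n)
    rows <- patch_rows(class_row(x, sp), class_row(y, sp), sp)
    members <- lapply(rows, function(i) sp$classes[i, ])
  } else {
    allowed <- codes_to_pairs(union(adj_codes(x), adj_codes(y)), n)
    required <- codes_to_pairs(intersect(adj_codes(x), adj_codes(y)), n)
    members <- hamiltonian_paths(n, allowed, required)
  }
  class_tibble(members)
}

# ---- geodesic search -------------------------------------------------------

#' Find a geodesic between two genomes, if one exists
#'
#' Searches for a chain `z_0 = x, z_1, ..., z_D = y` (`D = d(x,y)`) that is
#' isometric to the full integer segment `0..D`, i.e.
#' `d(z_i, z_j) = |i - j|` for all `i, j`. The bp space is not geodesic, so
#' the search may legitimately fail; candidates are restricted to the
#' patch-union set (any geodesic point satisfies the additivity criterion)
#' and explored depth-first by level, tie-broken by the lexicographic order
#' of canonical representatives, so the result is deterministic.
#'
#' @param x,y Genomes of the same length, `n <= cap`.
#' @param cap Enumeration cap.
#' @return A list of canonical genomes forming the chain from `x` to `y`,
#'   or `NULL` when no geodesic exists.
#' @examples
#' length(find_geodesic(1:6, c(1, 3, 5, 2, 4, 6))) # 6: a maximal geodesic
#' @export
find_geodesic <- function(x, y, cap = bp_enum_cap()) {
  x <- as_genome(x); y <- as_genome(y)
  n <- length(x)
  if (length(y) != n) {
    abort("genomes must have the same number of genes",
          class = "bpmedian_input_error")
  }
  check_cap(n, cap)
  d <- bp_distance(x, y)
  if (d == 0L) return(list(class_of(x)))
  sp <- class_space(n)
  xi <- class_row(x, sp); yi <- class_row(y, sp)
  rows <- patch_rows(xi, yi, sp)
  Lm <- sp$L[rows, , drop = FALSE]
  Dm <- (n - 1) - tcrossprod(Lm)
  ix <- match(xi, rows); iy <- match(yi, rows)
  lev_x <- Dm[, ix]; lev_y <- Dm[, iy]
  # candidates per interior level, already in lex order (rows are sorted)
  cand <- lapply(seq_len(d - 1L), function(i) which(lev_x == i & lev_y == d - i))
  chosen <- integer(d - 1L)

  dfs <- function(level) {
    if (level == d) return(TRUE)
    for (c in cand[[level]]) {
      ok <- TRUE
      if (level > 1L) {
        prev <- chosen[seq_len(level - 1L)]
        if (!all(Dm[c, prev] == level - seq_len(level - 1L))) ok <- FALSE
      }
      if (ok) {
        chosen[level] <<- c
        if (dfs(level + 1L)) return(TRUE)
      }
    }
    FALSE
  }

  if (!dfs(1L)) return(NULL)
  idx <- c(ix, chosen[seq_len(d - 1L)], iy)
  lapply(rows[idx], function(i) sp$classes[i, ])
}
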