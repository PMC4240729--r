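# Total distance, exact medians, and the accessibility closure.
#
# The median of a genome set is any genome minimizing total bp distance to
# the set; the minimum is the median value. For k genomes pairwise at the
# maximum distance n-1 the median value is (k-1)(n-1) and a genome m is a
# median iff its adjacency set lies inside the union of the inputs'
# adjacency sets — which turns median enumeration into Hamiltonian-path
# enumeration on the union graph.

#' Build a weighted genome-class set
#'
#' Canonicalizes the inputs to genome classes and collapses equivalent
#' entries, summing their multiplicities: a genome and its reversal are the
#' same class, so their weights merge. Total distances and medians are
#' invariant under replacing any entry by its reversal.
#'
#' @param genomes A list of genomes, a tibble with a `genome` list-column,
#'   or a matrix with genomes as rows.
#' @param weight Optional positive integer multiplicities, recycled to the
#'   number of input genomes; default 1.
#' @return A tibble with columns `representative`, `genome` (list-column of
#'   canonical genomes) and `weight`, one row per class.
#' @examples
#' genome_set(list(1:4, c(4, 3, 2, 1)))$weight # collapses to weight 2
#' @export
genome_set <- function(genomes, weight = NULL) {
  gs <- lapply(as_genome_list(genomes), class_of)
  w <- weight %||% 1L
  if (any(w < 1 | w != as.integer(w))) {
    abort("weights must be positive integers", class = "bpmedian_input_error")
  }
  w <- rep_len(as.integer(w), length(gs))
  keys <- vapply(gs, paste, "", collapse = " ")
  agg <- rowsum(w, keys)
  first <- !duplicated(keys)
  out <- class_tibble(gs[first])
  out$weight <- as.integer(agg[out$representative, 1L])
  out
}

#' Total breakpoint distance from a genome to a weighted set
#'
#' The multiplicity-weighted sum of bp distances from `q` to every class in
#' `A`.
#'
#' @param q A genome.
#' @param A A weighted genome set (see [genome_set()]); plain lists/tibbles
#'   of genomes are accepted and given weight 1.
#' @return Non-negative integer.
#' @export
total_distance <- function(q, A) {
  q <- as_genome(q)
  A <- as_weighted_set(A)
  sum(A$weight * vapply(A$genome, bp_distance, 0L, y = q))
}

as_weighted_set <- function(A) {
  if (is.data.frame(A) && all(c("genome", "weight") %in% names(A))) {
    if (nrow(A) == 0L) {
      abort("the genome set must be nonempty", class = "bpmedian_input_error")
    }
    return(A)
  }
  gs <- as_genome_list(A, allow_empty = TRUE)
  if (length(gs) == 0L) {
    abort("the genome set must be nonempty", class = "bpmedian_input_error")
  }
  genome_set(gs)
}

new_bp_median <- function(value, medians, method, n, A) {
  structure(
    list(value = as.integer(value), medians = medians, method = method,
         n = n, k = sum(A$weight), input = A),
    class = "bp_median")
}

#' @export
print.bp_median <- function(x, ...) {
  cat(sprintf(
    "<bp_median> n = %d, k = %d (method: %s)\n  median value: %d\n  medians: %d classes\n",
    x$n, x$k, x$method, x$value, length(x$medians)))
  invisible(x)
}

#' Exact median by exhaustive search
#'
#' Minimizes the weighted total bp distance over all n!/2 genome classes
#' and returns the full argmin set (the object of interest is the median
#' SET; no arbitrary single median is ever picked).
#'
#' @param A A weighted genome set or anything [genome_set()] accepts.
#' @param cap Enumeration cap, see [bp_enum_cap()].
#' @return A `bp_median` object with fields `value` (median value),
#'   `medians` (list of canonical genomes), `method`, `n`, `k`. Use
#'   [tidy()] / [glance()] for tibble views.
#' @examples
#' median_bruteforce(list(1:4, c(2, 1, 4, 3)))
#' @export
median_bruteforce <- function(A, cap = bp_enum_cap()) {
  A <- as_weighted_set(A)
  n <- length(A$genome[[1L]])
  check_cap(n, cap)
  sp <- class_space(n)
  # total distance to every class in one mat-vec:
  # td = (sum w)(n-1) - L (sum_x w_x a_x)
  acc <- numeric(length(sp$codes))
  for (i in seq_len(nrow(A))) {
    acc <- acc + A$weight[i] * adj_incidence(A$genome[[i]], sp)
  }
  td <- sum(A$weight) * (n - 1) - as.vector(sp$L %*% acc)
  value <- min(td)
  rows <- which(td == value)
  medians <- lapply(rows, function(i) sp$classes[i, ])
  new_bp_median(value, medians, "bruteforce", n, A)
}

# ---- maximally-distant inputs ---------------------------------------------

check_pairwise_maxdist <- function(gs) {
  n <- length(gs[[1L]])
  k <- length(gs)
  if (k >= 2L) {
    for (i in seq_len(k - 1L)) {
      for (j in (i + 1L):k) {
        if (bp_distance(gs[[i]], gs[[j]]) != n - 1L) {
          abort(sprintf(
            "input genomes %d and %d are at distance < n-1; this operation requires pairwise maximally-distant inputs",
            i, j), class = "bpmedian_precondition_error")
        }
      }
    }
  }
  invisible(gs)
}

#' Median test for maximally-distant inputs
#'
#' For a set `X` of genomes pairwise at distance `n-1`, a genome `m` is a
#' median of `X` exactly when every adjacency of `m` appears in some member
#' of `X` (`A_m ⊆ ∪ A_xi`). This predicate checks that characterization
#' directly, without enumerating anything.
#'
#' @param m Candidate genome.
#' @param X List (or tibble/matrix) of genomes pairwise at distance `n-1`;
#'   violation of that precondition is an error.
#' @return Logical scalar.
#' @export
is_median_maxdist <- function(m, X) {
  m <- as_genome(m)
  gs <- check_pairwise_maxdist(as_class_list(X))
  allowed <- unique(unlist(lapply(gs, adj_codes)))
  all(adj_codes(m) %in% allowed)
}

#' Full median set for maximally-distant inputs
#'
#' Enumerates every genome class whose adjacency set lies inside the union
#' graph of the inputs' adjacencies, via Hamiltonian-path enumeration on
#' that union graph. For pairwise maximally-distant inputs this is exactly
#' the median set and the median value is `(k-1)(n-1)`.
#'
#' @inheritParams is_median_maxdist
#' @param cap Passed through to the postcondition cross-check; the
#'   Hamiltonian-path engine itself is not capped.
#' @return A `bp_median` object with `method = "maxdist_hampath"`.
#' @export
median_set_maxdist <- function(X, cap = bp_enum_cap()) {
  gs <- check_pairwise_maxdist(as_class_list(X))
  n <- length(gs[[1L]])
  k <- length(gs)
  allowed <- codes_to_pairs(unique(unlist(lapply(gs, adj_codes))), n)
  medians <- hamiltonian_paths(n, allowed)
  new_bp_median((k - 1L) * (n - 1L), medians, "maxdist_hampath", n,
                genome_set(gs))
}

# ---- accessibility ---------------------------------------------------------

# internal: 1-accessible closure over row indices; anchors ys stay fixed.
# Grows the reachable set by patch steps towards anchors until stable.
one_step_rows <- function(start_rows, anchor_rows, sp) {
  m <- nrow(sp$L)
  in_reach <- logical(m)
  in_reach[start_rows] <- TRUE
  pending <- unique(start_rows)
  while (length(pending)) {
    z <- pending[[1L]]
    pending <- pending[-1L]
    for (y in anchor_rows) {
      new <- patch_rows(z, y, sp)
      new <- new[!in_reach[new]]
      if (length(new)) {
        in_reach[new] <- TRUE
        pending <- c(pending, new)
      }
    }
  }
  which(in_reach)
}

# internal: full accessibility closure = smallest superset of `start_rows`
# closed under taking the patch of any two members (iterating the
# 1-accessible step with growing anchors reaches exactly this set, since a
# chain step towards an already-reached genome is a member-pair patch).
# Processes every unordered member pair once, batched per new member.
closure_rows <- function(start_rows, sp) {
  start_rows <- unique(start_rows)
  n1 <- sp$n - 1
  # every patch member keeps its adjacencies inside the union of its
  # endpoints' adjacency sets, so (inductively) the whole closure lives in
  # {v : A_v ⊆ union of the starting adjacency sets} — restrict to it
  allowed <- apply(sp$L[start_rows, , drop = FALSE], 2L, max)
  cand <- which(as.vector(sp$L %*% (1 - allowed)) == 0)
  mc <- length(cand)
  E <- space_eps(sp)
  Esub <- if (!is.null(E)) E[cand, cand, drop = FALSE]
  loc <- match(start_rows, cand) # local indices within cand
  in_reach <- logical(mc)
  in_reach[loc] <- TRUE
  pending <- loc
  while (length(pending)) {
    z <- pending[[1L]]
    pending <- pending[-1L]
    members <- which(in_reach)
    if (!is.null(Esub)) {
      # all patches (z, w), w a member, in one vectorized comparison
      hit <- (Esub[, members, drop = FALSE] + Esub[, z]) ==
        rep(n1 + Esub[z, members], each = mc)
      new <- which(rowSums(hit) > 0 & !in_reach)
    } else {
      Lw <- sp$L[cand, , drop = FALSE]
      new <- integer(0)
      for (w in members) {
        az <- Lw[z, ]; aw <- Lw[w, ]
        ok <- as.vector(Lw %*% (1 - pmax(az, aw))) == 0 &
          as.vector(Lw %*% (az * aw)) == sum(az * aw)
        pr <- which(ok)
        new <- c(new, pr[!in_reach[pr]])
      }
      new <- unique(new)
    }
    if (length(new)) {
      in_reach[new] <- TRUE
      pending <- c(pending, new)
    }
  }
  cand[in_reach]
}

rows_from_classes <- function(X, sp) {
  gs <- as_class_list(X)
  vapply(gs, class_row, 0L, sp = sp)
}

#' One-accessibility step
#'
#' The set of genomes reachable from `X` by a chain that starts at a member
#' of `X` and repeatedly hops onto a geodesic patch towards another member
#' of `X`. Computed as a fixed-point closure (chain concatenation and
#' iterated closure steps reach the same set). Always contains `X`.
#'
#' @param X List/tibble/matrix of genomes, `n <= cap`.
#' @param cap Enumeration cap.
#' @return A tibble of member classes as in [patch_union_set()].
#' @export
one_step_accessible <- function(X, cap = bp_enum_cap()) {
  gs <- as_class_list(X)
  n <- length(gs[[1L]])
  check_cap(n, cap)
  sp <- class_space(n)
  anchors <- rows_from_classes(gs, sp)
  rows <- one_step_rows(anchors, anchors, sp)
  class_tibble(lapply(rows, function(i) sp$classes[i, ]))
}

#' Accessibility closure
#'
#' Iterates the one-accessibility step, each round allowing hops towards
#' any already-reached genome, until a fixed point: the set of all genomes
#' accessible from `X` in any finite number of rounds. The closure is
#' idempotent (one more step changes nothing), and for pairwise
#' maximally-distant `X` it is contained in the median set of `X`.
#'
#' @inheritParams one_step_accessible
#' @return A tibble of member classes.
#' @export
accessible_closure <- function(X, cap = bp_enum_cap()) {
  gs <- as_class_list(X)
  n <- length(gs[[1L]])
  check_cap(n, cap)
  sp <- class_space(n)
  reach <- closure_rows(sort(rows_from_classes(gs, sp)), sp)
  class_tibble(lapply(reach, function(i) sp$classes[i, ]))
}

#' Median accessibility report
#'
#' For pairwise maximally-distant `X`, computes both the exact median set
#' `M(X)` (brute force) and the accessibility closure, and reports whether
#' every median is accessible. Containment of the closure in `M(X)` is a
#' theorem; equality is an open conjecture, so this is a diagnostic report,
#' not an assertion.
#'
#' @inheritParams one_step_accessible
#' @return A list of class `bp_conjecture_report`: sizes of both sets, the
#'   one-sided difference `M(X) \ closure` (tibble), and a logical `equal`.
#' @export
conjecture_report <- function(X, cap = bp_enum_cap()) {
  gs <- check_pairwise_maxdist(as_class_list(X))
  med <- median_bruteforce(genome_set(gs), cap = cap)
  acc <- accessible_closure(gs, cap = cap)
  med_keys <- vapply(med$medians, paste, "", collapse = " ")
  missing <- setdiff(med_keys, acc$representative)
  if (length(setdiff(acc$representative, med_keys))) {
    abort("internal error: closure not contained in the median set",
          class = "bpmedian_internal_error")
  }
  structure(
    list(
      n = med$n, k = length(gs),
      median_value = med$value,
      n_medians = length(med$medians),
      n_accessible = nrow(acc),
      equal = length(missing) == 0L,
      not_accessible = class_tibble(
        lapply(strsplit(missing, " ", fixed = TRUE), as.integer))
    ),
    class = "bp_conjecture_report")
}

#' @export
print.bp_conjecture_report <- function(x, ...) {
  cat(sprintf(
    "<bp_conjecture_report> n = %d, k = %d\n  median value %d; |M(X)| = %d, |closure| = %d\n  every median accessible: %s (%d not accessible)\n",
    x$n, x$k, x$median_value, x$n_medians, x$n_accessible,
    x$equal, nrow(x$not_accessible)))
  invisible(x)
}
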