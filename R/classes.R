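# Exhaustive enumeration of genome classes and the cached incidence
# structures used by the exact solvers.

#' Default cap on exhaustive enumeration
#'
#' Exhaustive operations (class enumeration, brute-force medians, oracle
#' patch computation) walk all n!/2 genome classes; the cap keeps that below
#' 8!/2 = 20160 classes by default.
#' @export
bp_enum_cap <- function() 8L

check_cap <- function(n, cap) {
  if (n > cap) {
    abort(sprintf(
      "n = %d exceeds the exhaustive-enumeration cap (%d); raise `cap` only if you accept n!/2 = %.3g classes",
      n, cap, factorial(n) / 2),
      class = "bpmedian_cap_error")
  }
}

#' Enumerate all genome classes of length n
#'
#' Yields one canonical representative per class; there are n!/2 classes
#' (each unordered pair \{genome, reversal\} counted once).
#'
#' @param n Number of genes (`2 <= n <= cap`).
#' @param cap Enumeration cap, see [bp_enum_cap()].
#' @return An integer matrix with n!/2 rows (canonical representatives,
#'   lexicographically sorted) and n columns.
#' @examples
#' nrow(enumerate_classes(4)) # 12
#' @export
enumerate_classes <- function(n, cap = bp_enum_cap()) {
  n <- as.integer(n)
  if (n < 2L) abort("n must be at least 2", class = "bpmedian_input_error")
  check_cap(n, cap)
  class_space(n)$classes
}

# Cached per-n structures:
#   classes  : (n!/2) x n matrix of canonical representatives, lex-sorted
#   codes    : all C(n,2) pair codes, sorted
#   L        : (n!/2) x C(n,2) 0/1 incidence matrix, L[i,j] = 1 iff class i
#              contains the adjacency coded by codes[j]
#   key      : named integer vector mapping genome_key -> row index
class_space <- function(n) {
  key <- as.character(n)
  if (!is.null(.bp_cache[[key]])) return(.bp_cache[[key]])
  perms <- e1071::permutations(n)
  storage.mode(perms) <- "integer"
  # canonical orientation iff first gene < last gene (labels are distinct)
  canon <- perms[perms[, 1L] < perms[, n], , drop = FALSE]
  canon <- canon[do.call(order, as.data.frame(canon)), , drop = FALSE]
  m <- nrow(canon)
  codes <- sort(pair_code(
    rep(seq_len(n - 1L), times = (n - 1L):1L),
    unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n)),
    n))
  adj <- matrix(0L, m, n - 1L)
  for (j in seq_len(n - 1L)) {
    adj[, j] <- pair_code(canon[, j], canon[, j + 1L], n)
  }
  col <- matrix(match(adj, codes), m, n - 1L)
  L <- matrix(0, m, length(codes))
  L[cbind(rep(seq_len(m), n - 1L), as.vector(col))] <- 1
  rownames_key <- apply(canon, 1L, paste, collapse = " ")
  sp <- list(
    n = n, classes = canon, codes = codes, L = L,
    key = setNames(seq_len(m), rownames_key)
  )
  .bp_cache[[key]] <- sp
  sp
}

# row index of a class in the enumerated space
class_row <- function(p, sp) {
  i <- sp$key[[paste(class_of(p), collapse = " ")]]
  if (is.null(i)) abort("genome not found in class space (wrong n?)",
                        class = "bpmedian_internal_error")
  i
}

# 0/1 incidence vector over sp$codes for one genome
adj_incidence <- function(p, sp) {
  v <- numeric(length(sp$codes))
  v[match(adj_codes(p, sp$n), sp$codes)] <- 1
  v
}

# distances from one genome to every enumerated class: one mat-vec,
# d = (n-1) - L a_x since |A_i ∩ A_x| = L a_x
dist_to_all <- function(p, sp) {
  as.vector((sp$n - 1) - sp$L %*% adj_incidence(p, sp))
}

# full (n!/2)^2 distance matrix of the class space
class_distance_matrix <- function(n, cap = bp_enum_cap()) {
  check_cap(n, cap)
  sp <- class_space(n)
  (n - 1) - space_eps(sp)
}

# cached (n!/2)^2 matrix of pairwise shared-adjacency counts |A_i ∩ A_j|;
# kept only up to n = 7 (2520^2 doubles); larger spaces use mat-vec paths
space_eps <- function(sp) {
  if (nrow(sp$L) > 2520L) return(NULL)
  key <- sprintf("E%d", sp$n)
  E <- .bp_cache[[key]]
  if (is.null(E)) {
    E <- tcrossprod(sp$L)
    .bp_cache[[key]] <- E
  }
  E
}
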