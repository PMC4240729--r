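# Unsigned linear genomes as permutations of gene labels 1..n.
#
# A genome is an integer vector holding each label in 1..n exactly once.
# A genome and its full reversal carry the same adjacency information, so
# they form one genome class; the canonical representative of a class is the
# lexicographically smaller of the two orientations (equivalently, the
# orientation whose first gene is smaller than its last).

#' Validate and coerce a gene order
#'
#' A genome is a permutation of the consecutive integer labels `1..n`
#' (`n >= 2`). Anything else — gaps, repeats, labels outside `1..n` — is
#' rejected.
#'
#' @param x Numeric or integer vector of gene labels.
#' @return An integer vector of length `n`.
#' @examples
#' as_genome(c(1, 3, 5, 2, 4, 6))
#' @export
as_genome <- function(x) {
  if (is.list(x) || !is.numeric(x)) {
    abort("a genome must be a numeric vector of gene labels",
          class = "bpmedian_input_error")
  }
  if (anyNA(x) || any(x != as.integer(x))) {
    abort("gene labels must be integers without NA",
          class = "bpmedian_input_error")
  }
  p <- as.integer(x)
  n <- length(p)
  if (n < 2L) {
    abort("a genome needs at least 2 genes", class = "bpmedian_input_error")
  }
  seen <- logical(n)
  if (any(p < 1L | p > n)) {
    abort(sprintf("gene labels must be exactly 1..%d", n),
          class = "bpmedian_input_error")
  }
  seen[p] <- TRUE
  if (!all(seen)) {
    abort(sprintf("gene labels must be exactly 1..%d with no repeats", n),
          class = "bpmedian_input_error")
  }
  p
}

#' Canonical representative of a genome class
#'
#' The class of a genome contains the genome and its full reversal; the
#' canonical representative is the lexicographically smaller of the two.
#' Since all labels are distinct this is decided by comparing the first and
#' last gene.
#'
#' @param x A genome (see [as_genome()]).
#' @return The canonical orientation, an integer vector.
#' @examples
#' class_of(c(4, 3, 2, 1)) # 1 2 3 4
#' @export
class_of <- function(x) {
  p <- as_genome(x)
  if (p[1L] < p[length(p)]) p else rev(p)
}

#' @rdname class_of
#' @export
genome_key <- function(x) paste(class_of(x), collapse = " ")

# ---- adjacency machinery ---------------------------------------------------

# integer code of the unordered pair {a, b} with labels in 1..n
pair_code <- function(a, b, n) {
  pmin(a, b) * (n + 1L) + pmax(a, b)
}

# adjacency codes of a genome (length n-1, distinct)
adj_codes <- function(p, n = length(p)) {
  a <- p[-n]
  b <- p[-1L]
  pair_code(a, b, n)
}

codes_to_pairs <- function(codes, n) {
  codes <- sort(unique(as.integer(codes)))
  tibble(gene1 = codes %/% (n + 1L), gene2 = codes %% (n + 1L))
}

#' Adjacency set of a genome
#'
#' The adjacencies of a genome are the unordered pairs of genes occupying
#' consecutive positions; a genome of `n` genes has exactly `n - 1`. The
#' adjacency set is identical for a genome and its reversal.
#'
#' @param x A genome.
#' @return A tibble with integer columns `gene1 < gene2`, one row per
#'   adjacency, sorted.
#' @examples
#' adjacency_set(c(1, 3, 5, 2, 4, 6))
#' @export
adjacency_set <- function(x) {
  p <- as_genome(x)
  codes_to_pairs(adj_codes(p), length(p))
}

#' Common adjacencies of a collection of genomes
#'
#' Intersects the adjacency sets of the given genomes. By convention the
#' empty collection yields the set of all unordered pairs of labels, so `n`
#' must then be supplied.
#'
#' @param genomes A list of genomes, a tibble with a `genome` list-column
#'   (as returned by [read_genomes()]), or a single genome vector.
#' @param n Number of genes; only needed when `genomes` is empty.
#' @return A tibble as in [adjacency_set()].
#' @examples
#' common_adjacencies(list(c(1, 2, 3, 4), c(2, 1, 4, 3)))
#' @export
common_adjacencies <- function(genomes, n = NULL) {
  gs <- as_genome_list(genomes, allow_empty = TRUE)
  if (length(gs) == 0L) {
    if (is.null(n)) {
      abort("`n` is required for an empty collection",
            class = "bpmedian_input_error")
    }
    prs <- which(upper.tri(matrix(0L, n, n)), arr.ind = TRUE)
    return(tibble(gene1 = as.integer(prs[, 1L]),
                  gene2 = as.integer(prs[, 2L]))[order(prs[, 1L], prs[, 2L]), ])
  }
  n <- length(gs[[1L]])
  codes <- Reduce(intersect, lapply(gs, adj_codes))
  codes_to_pairs(codes, n)
}

# internal: common adjacency codes (fast path)
common_adj_codes <- function(gs) {
  Reduce(intersect, lapply(gs, adj_codes))
}

#' Breakpoint distance between two genomes
#'
#' `d(x, y) = n - 1 - |A_xy|` where `A_xy` is the set of adjacencies the two
#' genomes share. The distance is a pseudometric on gene orders (a genome is
#' at distance 0 from its reversal) and a metric on genome classes. It
#' ranges from 0 to `n - 1`, the maximum being attained exactly when the
#' genomes share no adjacency.
#'
#' @param x,y Genomes of the same length.
#' @return A non-negative integer.
#' @examples
#' bp_distance(1:6, c(1, 3, 5, 2, 4, 6)) # 5, the maximum for n = 6
#' @export
bp_distance <- function(x, y) {
  p <- as_genome(x)
  q <- as_genome(y)
  n <- length(p)
  if (length(q) != n) {
    abort("genomes must have the same number of genes",
          class = "bpmedian_input_error")
  }
  pos <- integer(n)
  pos[p] <- seq_len(n)
  a <- pos[q[-n]]
  b <- pos[q[-1L]]
  (n - 1L) - sum(abs(a - b) == 1L)
}

# shared-adjacency count, no validation (hot loop use)
eps_fast <- function(p, q, n) {
  pos <- integer(n)
  pos[p] <- seq_len(n)
  sum(abs(pos[q[-n]] - pos[q[-1L]]) == 1L)
}

# ---- coercion helpers ------------------------------------------------------

# Accepts a list of genomes, a tibble with a `genome` column, a matrix with
# genomes as rows, or a single genome vector. Returns a list of validated
# integer vectors, all of the same length.
as_genome_list <- function(x, allow_empty = FALSE) {
  gs <-
    if (is.data.frame(x)) {
      if (!"genome" %in% names(x)) {
        abort("data frame input needs a `genome` list-column",
              class = "bpmedian_input_error")
      }
      x$genome
    } else if (is.matrix(x)) {
      lapply(seq_len(nrow(x)), function(i) x[i, ])
    } else if (is.list(x)) {
      x
    } else {
      list(x)
    }
  gs <- lapply(gs, as_genome)
  if (length(gs) == 0L) {
    if (!allow_empty) {
      abort("empty genome collection", class = "bpmedian_input_error")
    }
    return(gs)
  }
  ns <- lengths(gs)
  if (length(unique(ns)) != 1L) {
    abort("all genomes must have the same number of genes",
          class = "bpmedian_input_error")
  }
  gs
}

# canonicalize a list of genomes and drop duplicate classes (stable order)
as_class_list <- function(x, allow_empty = FALSE) {
  gs <- lapply(as_genome_list(x, allow_empty = allow_empty), class_of)
  keys <- vapply(gs, paste, "", collapse = " ")
  gs[!duplicated(keys)]
}

# tibble view of a list of classes
class_tibble <- function(gs) {
  tibble(
    representative = vapply(gs, paste, "", collapse = " "),
    genome = gs
  )
}
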