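# Monte-Carlo experiments on uniformly random genomes.
#
# For two independent uniform genomes the number of shared adjacencies
# eps = |A_xy| has mean and variance both close to 2 for large n, so the bp
# distance concentrates near its maximum n-1, and eps/a_n -> 0 in
# probability for any divergent sequence a_n. The median value of k random
# genomes consequently sits within C(k,2) * max-pairwise-eps of the maximal
# value (k-1)(n-1) on every draw, a deterministic per-replicate bound.

#' Sample a uniform genome or genome class
#'
#' `sample_genome()` draws a uniformly random gene order of length `n`;
#' `sample_class()` canonicalizes it. Since every class contains exactly two
#' gene orders, the push-forward of the uniform measure on gene orders is
#' the uniform measure on classes. Both use R's current RNG stream; seed
#' with [withr::with_seed()] or `set.seed()` for reproducibility.
#'
#' @param n Number of genes.
#' @return An integer vector.
#' @export
sample_genome <- function(n) sample.int(n)

#' @rdname sample_genome
#' @export
sample_class <- function(n) class_of(sample.int(n))

#' Divergent rescaling sequences
#'
#' Named choices for the sequence `a_n` used to rescale eps: `"sqrt"`
#' (`sqrt(n)`), `"log"` (`log(n + 1)`), `"linear"` (`n`). A custom function
#' is accepted if it is positive and diverges (checked on a probe grid);
#' bounded sequences are rejected since the convergence statements require
#' `a_n -> Inf`.
#'
#' @param a_n A name above or a function of `n`.
#' @return A function of `n`.
#' @export
make_an <- function(a_n = c("sqrt", "log", "linear")) {
  if (is.character(a_n)) {
    a_n <- match.arg(a_n)
    f <- switch(a_n,
      sqrt = function(n) sqrt(n),
      log = function(n) log(n + 1),
      linear = function(n) as.numeric(n))
    return(f)
  }
  if (!is.function(a_n)) {
    abort("`a_n` must be a known name or a function",
          class = "bpmedian_input_error")
  }
  probe <- a_n(c(10, 1e3, 1e5, 1e7))
  if (anyNA(probe) || any(probe <= 0) || any(diff(probe) <= 0) ||
      probe[4] <= 5 * probe[1]) {
    abort("`a_n` must be positive and diverge to +Inf",
          class = "bpmedian_input_error")
  }
  a_n
}

new_bp_sim <- function(experiment, config, replicates, summary, ...) {
  structure(
    c(list(experiment = experiment, config = config,
           replicates = replicates, summary = summary), list(...)),
    class = "bp_sim")
}

#' @export
print.bp_sim <- function(x, ...) {
  cfg <- paste(sprintf("%s = %s", names(x$config),
                       vapply(x$config, format, "")), collapse = ", ")
  cat(sprintf("<bp_sim: %s> %s\n", x$experiment, cfg))
  s <- unlist(x$summary)
  cat(sprintf("  %s = %.6g\n", names(s), s), sep = "")
  invisible(x)
}

# per-replicate seed streams from one root seed (kept below 2^31)
replicate_seeds <- function(seed, reps) {
  withr::with_seed(seed, sample.int(.Machine$integer.max - 1L, reps))
}

#' Moments of the shared-adjacency count of random genomes
#'
#' Draws `reps` independent pairs and records `eps = |A_xy|` (the number of
#' shared adjacencies) and the bp distance `d = n - 1 - eps`. For large `n`
#' the sample mean and variance of eps are both close to 2. With
#' `reference = "identity"` one genome of each pair is fixed at the
#' identity, which leaves the distribution unchanged (the distance is
#' invariant under relabeling) and halves the sampling cost.
#'
#' @param n Number of genes.
#' @param reps Number of replicate pairs.
#' @param seed Root seed; each replicate gets its own derived stream.
#' @param reference `"random"` (two random genomes) or `"identity"`.
#' @return A `bp_sim` object; `tidy()` gives per-replicate records,
#'   `glance()` the summary (mean/variance of eps and d).
#' @examples
#' glance(distance_moments(100, reps = 500, seed = 1))
#' @export
distance_moments <- function(n, reps, seed,
                             reference = c("random", "identity")) {
  reference <- match.arg(reference)
  n <- as.integer(n)
  if (reps < 2L) abort("need reps >= 2", class = "bpmedian_input_error")
  seeds <- replicate_seeds(seed, reps)
  eps <- integer(reps)
  for (i in seq_len(reps)) {
    eps[i] <- withr::with_seed(seeds[i], {
      if (reference == "identity") {
        x <- sample.int(n)
        sum(abs(diff(x)) == 1L)
      } else {
        eps_fast(sample.int(n), sample.int(n), n)
      }
    })
  }
  d <- (n - 1L) - eps
  new_bp_sim(
    "distance_moments",
    list(n = n, reps = reps, seed = seed, reference = reference),
    tibble(rep = seq_len(reps), eps = eps, d = d),
    list(mean_eps = mean(eps), var_eps = var(eps),
         mean_d = mean(d), var_d = var(d)))
}

# exact moments of eps by exhaustive enumeration of class pairs (oracle
# for small n): averages |A_x ∩ A_y| over the full product space
exact_eps_moments <- function(n, cap = bp_enum_cap()) {
  check_cap(n, cap)
  sp <- class_space(n)
  E <- tcrossprod(sp$L) # eps for every ordered class pair
  list(mean_eps = mean(E), var_eps = mean(E^2) - mean(E)^2)
}

#' Convergence of the rescaled shared-adjacency count
#'
#' For each `n` in `n_grid`, draws `reps` independent pairs of random
#' genomes and estimates the tail probability `P(eps / a_n > delta)` for
#' each threshold in `delta`. For any divergent `a_n` these probabilities
#' vanish as `n` grows (Chebyshev: about `2 / (delta * a_n)^2`).
#'
#' @param n_grid Increasing vector of genome lengths.
#' @param reps Replicates per grid point.
#' @param a_n Rescaling sequence, see [make_an()].
#' @param delta Tail thresholds.
#' @param seed Root seed.
#' @return A `bp_sim` object; the `tail` field (also `tidy(x, "tail")`)
#'   holds one row per `(n, delta)` with the estimated tail probability.
#' @export
epsilon_convergence <- function(n_grid, reps, a_n = "sqrt",
                                delta = c(0.5, 0.1), seed = 1L) {
  f <- make_an(a_n)
  n_grid <- as.integer(n_grid)
  seeds <- replicate_seeds(seed, length(n_grid))
  rec <- vector("list", length(n_grid))
  for (g in seq_along(n_grid)) {
    n <- n_grid[g]
    eps <- withr::with_seed(seeds[g], {
      vapply(seq_len(reps),
             function(i) eps_fast(sample.int(n), sample.int(n), n), 0L)
    })
    rec[[g]] <- tibble(n = n, rep = seq_len(reps), eps = eps,
                       ratio = eps / f(n))
  }
  replicates <- dplyr::bind_rows(rec)
  tail_tbl <- dplyr::bind_rows(lapply(delta, function(dl) {
    dplyr::summarise(dplyr::group_by(replicates, .data$n),
                     delta = dl,
                     tail_prob = mean(.data$ratio > dl),
                     .groups = "drop")
  }))
  new_bp_sim(
    "epsilon_convergence",
    list(reps = reps, seed = seed,
         a_n = if (is.character(a_n)) a_n else "custom"),
    replicates,
    list(first_tail = tail_tbl$tail_prob[tail_tbl$n == n_grid[1L]][1L],
         last_tail = tail_tbl$tail_prob[tail_tbl$n == n_grid[length(n_grid)]][1L]),
    tail = tail_tbl)
}

#' Median-value gap of k random genomes
#'
#' Per replicate, samples `k` independent uniform genome classes, computes
#' the exact median value by brute force, and records the gap
#' `e* = (k-1)(n-1) - median value` together with `alpha = ` the maximum
#' pairwise shared-adjacency count. The bound `0 <= e* <= C(k,2) * alpha`
#' holds deterministically on every replicate (and `e* = 0` whenever
#' `alpha = 0`, the pairwise maximally-distant case); violations are
#' counted, never expected.
#'
#' @param n Number of genes (`n <= cap`; the median is exact).
#' @param k Number of genomes per replicate.
#' @param reps Number of replicates.
#' @param seed Root seed.
#' @param cap Enumeration cap.
#' @return A `bp_sim` object with per-replicate `e_star`, `alpha`, `bound`,
#'   `bound_ok`.
#' @export
median_gap_experiment <- function(n, k, reps, seed, cap = bp_enum_cap()) {
  n <- as.integer(n); k <- as.integer(k)
  check_cap(n, cap)
  sp <- class_space(n)
  seeds <- replicate_seeds(seed, reps)
  kk <- choose(k, 2)
  out <- vector("list", reps)
  for (i in seq_len(reps)) {
    gs <- withr::with_seed(seeds[i],
                           lapply(seq_len(k), function(j) sample_class(n)))
    acc <- numeric(length(sp$codes))
    for (g in gs) acc <- acc + adj_incidence(g, sp)
    value <- min(k * (n - 1) - as.vector(sp$L %*% acc))
    alpha <- 0L
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        alpha <- max(alpha, eps_fast(gs[[a]], gs[[b]], n))
      }
    }
    e_star <- (k - 1L) * (n - 1L) - value
    out[[i]] <- tibble(
      rep = i, e_star = e_star, alpha = alpha, bound = kk * alpha,
      bound_ok = e_star >= 0 && e_star <= kk * alpha)
  }
  replicates <- dplyr::bind_rows(out)
  new_bp_sim(
    "median_gap",
    list(n = n, k = k, reps = reps, seed = seed),
    replicates,
    list(mean_e_star = mean(replicates$e_star),
         max_e_star = max(replicates$e_star),
         mean_alpha = mean(replicates$alpha),
         violations = sum(!replicates$bound_ok)))
}

#' Total distance of accessible genomes to k random genomes
#'
#' Per replicate, samples `k` uniform genome classes `X`, computes the full
#' accessibility closure of `X` (patch steps use the general adjacency
#' characterization), and records the extremes over the closure of the gap
#' `(k-1)(n-1) - d(z, X)`. Every accessible `z` keeps its adjacencies
#' inside the union of the inputs' adjacency sets, so the gap lies in
#' `[0, C(k,2) * alpha]` on every replicate. The median-pair property is
#' checked too: for the two lexicographically first medians `m1, m2`, every
#' member of their patch has total distance within `C(k,2) * alpha` of the
#' median value.
#'
#' @inheritParams median_gap_experiment
#' @return A `bp_sim` object with per-replicate closure size, gap extremes
#'   and bound checks.
#' @export
accessible_distance_experiment <- function(n = 6, k = 3, reps = 20, seed = 1L,
                                           cap = bp_enum_cap()) {
  n <- as.integer(n); k <- as.integer(k)
  check_cap(n, cap)
  sp <- class_space(n)
  seeds <- replicate_seeds(seed, reps)
  kk <- choose(k, 2)
  out <- vector("list", reps)
  for (i in seq_len(reps)) {
    gs <- withr::with_seed(seeds[i],
                           lapply(seq_len(k), function(j) sample_class(n)))
    alpha <- 0L
    for (a in seq_len(k - 1L)) {
      for (b in (a + 1L):k) {
        alpha <- max(alpha, eps_fast(gs[[a]], gs[[b]], n))
      }
    }
    # total distance to X for every enumerated class, one mat-vec
    acc <- numeric(length(sp$codes))
    for (g in gs) acc <- acc + adj_incidence(g, sp)
    td <- k * (n - 1) - as.vector(sp$L %*% acc)
    value <- min(td)
    closure <- accessible_closure(gs, cap = cap)
    rows <- vapply(closure$genome, class_row, 0L, sp = sp)
    gap <- (k - 1L) * (n - 1L) - td[rows]
    # patch between the two lex-first medians stays near the median value
    med_rows <- which(td == value)
    pair_ok <- TRUE
    if (length(med_rows) >= 2L) {
      pr <- patch_rows(med_rows[1L], med_rows[2L], sp)
      pair_ok <- all(abs(td[pr] - value) <= kk * alpha)
    }
    out[[i]] <- tibble(
      rep = i, n_accessible = nrow(closure), alpha = alpha,
      max_gap = max(gap), min_gap = min(gap),
      bound = kk * alpha,
      bound_ok = min(gap) >= 0 && max(gap) <= kk * alpha,
      median_pair_ok = pair_ok)
  }
  replicates <- dplyr::bind_rows(out)
  new_bp_sim(
    "accessible_distance",
    list(n = n, k = k, reps = reps, seed = seed),
    replicates,
    list(mean_closure = mean(replicates$n_accessible),
         max_gap = max(replicates$max_gap),
         violations = sum(!replicates$bound_ok) +
           sum(!replicates$median_pair_ok)))
}
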