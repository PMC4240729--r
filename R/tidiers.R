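# broom-style views of fitted/median objects and sim reports

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a median result
#'
#' One row per median class, with its total distance to the input set
#' (equal to the median value for every row, by construction).
#'
#' @param x A `bp_median` object.
#' @param ... Unused.
#' @return A tibble with columns `representative`, `genome`,
#'   `total_distance`.
#' @method tidy bp_median
#' @export
tidy.bp_median <- function(x, ...) {
  out <- class_tibble(x$medians)
  out$total_distance <- x$value
  out
}

#' @rdname tidy.bp_median
#' @method glance bp_median
#' @export
glance.bp_median <- function(x, ...) {
  tibble(median_value = x$value, n_medians = length(x$medians),
         n = x$n, k = x$k, method = x$method)
}

#' Tidy a simulation report
#'
#' @param x A `bp_sim` object.
#' @param which `"replicates"` (default) or, for the convergence
#'   experiment, `"tail"` for the per-(n, delta) tail probabilities.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy bp_sim
#' @export
tidy.bp_sim <- function(x, which = c("replicates", "tail"), ...) {
  which <- match.arg(which)
  if (which == "tail") {
    if (is.null(x$tail)) {
      abort("this experiment has no tail table", class = "bpmedian_input_error")
    }
    return(x$tail)
  }
  x$replicates
}

#' @rdname tidy.bp_sim
#' @method glance bp_sim
#' @export
glance.bp_sim <- function(x, ...) {
  cfg <- x$config[vapply(x$config, function(v) is.atomic(v) && length(v) == 1L,
                         TRUE)]
  as_tibble(c(list(experiment = x$experiment), cfg, x$summary))
}

#' Plot a simulation report
#'
#' For the moments experiment, a histogram of the shared-adjacency count
#' with its sample mean marked; for the convergence experiment, tail
#' probability against genome length on a log-x scale; for the median-gap
#' and accessibility experiments, the per-replicate gap against its
#' deterministic bound.
#'
#' @param object A `bp_sim` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bp_sim
#' @export
autoplot.bp_sim <- function(object, ...) {
  reps <- object$replicates
  switch(object$experiment,
    distance_moments =
      ggplot2::ggplot(reps, ggplot2::aes(x = .data$eps)) +
      ggplot2::geom_bar() +
      ggplot2::geom_vline(xintercept = mean(reps$eps), linetype = 2) +
      ggplot2::labs(x = "shared adjacencies ε", y = "replicates"),
    epsilon_convergence =
      ggplot2::ggplot(object$tail,
                      ggplot2::aes(x = .data$n, y = .data$tail_prob,
                                   colour = factor(.data$delta))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::scale_x_log10() +
      ggplot2::labs(x = "genes n", y = "P(ε / a_n > δ)",
                    colour = "δ"),
    # median_gap / accessible_distance share a gap-vs-bound view
    {
      gap_col <- if ("e_star" %in% names(reps)) "e_star" else "max_gap"
      ggplot2::ggplot(reps, ggplot2::aes(x = .data$bound,
                                         y = .data[[gap_col]])) +
        ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
        ggplot2::geom_jitter(width = 0.15, height = 0.15, alpha = 0.6) +
        ggplot2::labs(x = "bound C(k,2) · α", y = "observed gap")
    })
}

#' @importFrom rlang .data
NULL
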