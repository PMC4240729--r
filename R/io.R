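# Plain-text genome I/O and machine-readable reports.
#
# Dialect: one genome per line, whitespace-separated integer gene labels;
# '#' starts a comment line; a '>' line names the genome that follows
# (GRIMM-like, single linear unsigned chromosome). The writer emits the
# same dialect and round-trips exactly.

#' Read genomes from a text file
#'
#' @param path Path to a genome text file.
#' @return A tibble with columns `name` (character; auto-numbered when no
#'   '>' header precedes a genome) and `genome` (list-column of integer
#'   vectors, all the same length).
#' @export
read_genomes <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("no such file: %s", path), class = "bpmedian_io_error")
  }
  lines <- readLines(path, warn = FALSE)
  names_out <- character(0)
  genomes <- list()
  pending <- NULL
  for (ln in seq_along(lines)) {
    raw <- trimws(lines[ln])
    if (raw == "" || startsWith(raw, "#")) next
    if (startsWith(raw, ">")) {
      pending <- trimws(sub("^>", "", raw))
      next
    }
    toks <- strsplit(raw, "\\s+")[[1L]]
    vals <- suppressWarnings(as.integer(toks))
    if (anyNA(vals)) {
      abort(sprintf("line %d: non-integer token '%s'",
                    ln, toks[which(is.na(vals))[1L]]),
            class = "bpmedian_parse_error")
    }
    g <- tryCatch(as_genome(vals), error = function(e) {
      abort(sprintf("line %d: %s", ln, conditionMessage(e)),
            class = "bpmedian_parse_error")
    })
    genomes <- c(genomes, list(g))
    names_out <- c(names_out,
                   pending %||% sprintf("genome%d", length(genomes)))
    pending <- NULL
  }
  if (length(genomes) == 0L) {
    abort("no genomes in file", class = "bpmedian_parse_error")
  }
  if (length(unique(lengths(genomes))) != 1L) {
    abort("file mixes genomes of different lengths",
          class = "bpmedian_parse_error")
  }
  tibble(name = names_out, genome = genomes)
}

#' Write genomes to a text file
#'
#' @param x A tibble with `genome` (and optionally `name`) columns, a list
#'   of genomes, or a single genome.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genomes <- function(x, path) {
  gs <- as_genome_list(x)
  nms <- if (is.data.frame(x) && "name" %in% names(x)) {
    x$name
  } else {
    sprintf("genome%d", seq_along(gs))
  }
  lines <- unlist(lapply(seq_along(gs), function(i) {
    c(paste0(">", nms[i]), paste(gs[[i]], collapse = " "))
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Write a result as JSON or TSV
#'
#' JSON output serializes medians as representative strings and carries the
#' configuration (including the seed) of sim reports; TSV output writes the
#' per-replicate table of a sim report, or the median table.
#'
#' @param x A `bp_median`, `bp_sim` or `bp_conjecture_report` object.
#' @param path Output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(x, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  if (format == "tsv") {
    tbl <- if (inherits(x, "bp_sim")) {
      x$replicates
    } else if (inherits(x, "bp_median")) {
      tidy(x)[, c("representative", "total_distance")]
    } else {
      abort("no TSV form for this object", class = "bpmedian_input_error")
    }
    utils::write.table(tbl, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(path))
  }
  obj <- report_list(x)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

report_list <- function(x) {
  if (inherits(x, "bp_median")) {
    list(type = "median", method = x$method, n = x$n, k = x$k,
         median_value = x$value,
         n_medians = length(x$medians),
         medians = vapply(x$medians, paste, "", collapse = " "))
  } else if (inherits(x, "bp_sim")) {
    list(type = "simulation", experiment = x$experiment,
         config = x$config, summary = x$summary)
  } else if (inherits(x, "bp_conjecture_report")) {
    list(type = "conjecture_report", n = x$n, k = x$k,
         median_value = x$median_value,
         n_medians = x$n_medians, n_accessible = x$n_accessible,
         equal = x$equal,
         not_accessible = x$not_accessible$representative)
  } else {
    abort("unsupported report object", class = "bpmedian_input_error")
  }
}

#' Read back a JSON report
#'
#' @param path A file written by [write_report()] with `format = "json"`.
#' @return A list.
#' @export
read_report <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Generate the worked-example fixtures
#'
#' Writes small genome files used throughout the documentation and tests:
#' the maximally-distant pair of length 6 together with a geodesic chain
#' between its ends, a length-7 pair with no geodesic, a maximally-distant
#' triple of length 7, and a few seeded random genome sets.
#'
#' @param outdir Output directory (created if needed).
#' @param seed Seed for the randomized constructions.
#' @return Tibble of written paths, invisibly.
#' @export
make_fixtures <- function(outdir, seed = 1L) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  emit <- function(x, file) {
    p <- file.path(outdir, file)
    write_genomes(x, p)
    paths <<- c(paths, p)
  }
  pair6 <- list(1:6, c(1L, 3L, 5L, 2L, 4L, 6L))
  emit(tibble(name = c("id6", "alt6"), genome = pair6), "maxpair_n6.txt")
  chain <- find_geodesic(pair6[[1L]], pair6[[2L]])
  emit(tibble(name = sprintf("step%d", seq_along(chain) - 1L),
              genome = chain), "geodesic_chain_n6.txt")
  ng <- nongeodesic_pair(7, c(4L, 3L, 5L))
  emit(tibble(name = c("id7", "nongeo7"), genome = list(ng$x, ng$y)),
       "nongeodesic_n7.txt")
  emit(max_distant_set(7, 3, seed = seed), "maxdistant_n7_k3.txt")
  rnd <- withr::with_seed(seed, lapply(1:4, function(i) sample_class(6L)))
  emit(tibble(name = sprintf("rand%d", 1:4), genome = rnd),
       "random_n6_k4.txt")
  invisible(tibble(path = paths))
}
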