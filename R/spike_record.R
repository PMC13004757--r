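#' Construct a spike record
#'
#' The universal simulation output: one row per spike with its time,
#' population label and neuron index within that population. Spike times
#' are timestamped at the end of the threshold-crossing step.
#'
#' @param time_ms spike times (ms).
#' @param population population label per spike.
#' @param neuron_index 1-based neuron index within its population.
#' @param t_end end of the simulated interval (ms).
#' @param dt integration step used (ms).
#' @param seed noise seed used.
#' @param pop_sizes named integer vector of population sizes.
#' @return A data frame of class `"spike_record"` with attributes
#'   `t_end`, `dt`, `seed` and `pop_sizes`.
#' @export
spike_record <- function(time_ms, population, neuron_index, t_end,
                         dt = NA_real_, seed = NA_integer_,
                         pop_sizes = NULL) {
  stopifnot(length(time_ms) == length(population),
            length(time_ms) == length(neuron_index))
  if (length(time_ms) && (min(time_ms) < 0 || max(time_ms) > t_end))
    stop("spike times must lie in [0, t_end]", call. = FALSE)
  df <- data.frame(time_ms = as.numeric(time_ms),
                   population = as.character(population),
                   neuron_index = as.integer(neuron_index))
  structure(df, t_end = as.numeric(t_end), dt = dt, seed = seed,
            pop_sizes = pop_sizes,
            class = c("spike_record", "data.frame"))
}

#' @export
print.spike_record <- function(x, ...) {
  cat("<spike_record> ", nrow(x), " spikes over ", attr(x, "t_end"),
      " ms\n", sep = "")
  if (nrow(x)) {
    tab <- table(x$population)
    cat("  per population:",
        paste0(names(tab), "=", as.integer(tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Extract the spikes of one population
#'
#' @param record a [spike_record()].
#' @param population population label.
#' @return A `spike_record` restricted to that population.
#' @export
population_spikes <- function(record, population) {
  keep <- record$population == population
  out <- record[keep, , drop = FALSE]
  attributes(out)[c("t_end", "dt", "seed", "pop_sizes")] <-
    attributes(record)[c("t_end", "dt", "seed", "pop_sizes")]
  class(out) <- c("spike_record", "data.frame")
  out
}

#' Write / read a spike record as delimited text
#'
#' The record itself is a tab-separated file (columns `time_ms`,
#' `population`, `neuron_index`); simulation metadata (`t_end`, `dt`,
#' `seed`, population sizes and a content hash) go to a JSON sidecar
#' `<path>.json`.
#'
#' @param record a [spike_record()].
#' @param path file path for the delimited text.
#' @return `write_spike_record` returns `path` invisibly;
#'   `read_spike_record` returns the reconstructed [spike_record()].
#' @export
write_spike_record <- function(record, path) {
  utils::write.table(as.data.frame(record), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  ps <- attr(record, "pop_sizes")
  meta <- list(t_end = attr(record, "t_end"), dt = attr(record, "dt"),
               seed = attr(record, "seed"),
               pop_sizes = as.list(ps),
               n_spikes = nrow(record),
               md5 = unname(tools::md5sum(path)))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_spike_record
#' @export
read_spike_record <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          colClasses = c("numeric", "character", "integer"))
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  ps <- unlist(meta$pop_sizes)
  spike_record(df$time_ms, df$population, df$neuron_index,
               t_end = meta$t_end, dt = meta$dt, seed = meta$seed,
               pop_sizes = if (length(ps)) ps else NULL)
}
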