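#' Full-factorial parameter grid
#'
#' @param axes named list of parameter value vectors; names must match
#'   [mmn_params()] arguments when used with [run_grid()].
#' @return An object of class `"grid_spec"`.
#' @export
grid_spec <- function(axes) {
  stopifnot(is.list(axes), length(axes) >= 1, !is.null(names(axes)))
  if (any(!vapply(axes, length, 1L)))
    stop("every axis needs at least one value", call. = FALSE)
  structure(list(axes = axes), class = "grid_spec")
}

#' The default eight-axis search grid
#'
#' Eight axes with 5 x 5 x 5 x 7 x 2 x 6 x 2 x 2 = 42,000 combinations:
#' stimulus amplitude, tone-to-output conductance, pacemaker-to-output
#' conductance, delayed-to-output conductance, NMDA/AMPA ratio,
#' inhibitory conductance, depression strength, and the capacitance of
#' the delayed-activating populations. Ranges were chosen by coarse
#' pre-calibration around the regime in which the network discriminates
#' deviants (see the package vignette); the [mmn_params()] defaults are
#' one of the grid points.
#'
#' @return A [grid_spec()].
#' @export
default_grid_spec <- function() {
  grid_spec(list(
    stim_amplitude = c(0.30, 0.35, 0.40, 0.45, 0.50),
    g_tone_eo = c(8, 11, 14, 17, 20),
    g_phase_eo = c(12, 16, 20, 24, 28),
    g_delayed_eo = c(12, 16, 20, 24, 28, 32, 36),
    nmda_ratio = c(0.1, 0.3),
    g_inh = c(1, 2, 3, 4, 5, 6),
    pv = c(0.35, 0.5),
    cm_delayed = c(1000, 1100)))
}

#' Enumerate all parameter sets of a grid
#'
#' Deterministic lexicographic enumeration: the first axis varies
#' slowest, the last fastest. The number of rows is the product of the
#' axis lengths (42,000 for [default_grid_spec()]).
#'
#' @param spec a [grid_spec()].
#' @return A data frame with one row per parameter set and a `set_id`
#'   column (1-based row index).
#' @export
enumerate_grid <- function(spec) {
  stopifnot(inherits(spec, "grid_spec"))
  rev_axes <- rev(spec$axes)
  df <- expand.grid(rev_axes, KEEP.OUT.ATTRS = FALSE)
  df <- df[, rev(seq_along(rev_axes)), drop = FALSE]
  df <- cbind(set_id = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Run the grid search with acceptance filtering
#'
#' Simulates every requested parameter set under every protocol,
#' applies the acceptance criterion and reports the per-protocol
#' accepted sets and their intersection. One fixed connectivity /
#' heterogeneity seed is used across the grid so that parameter
#' effects, not realization effects, drive acceptance.
#'
#' @param spec a [grid_spec()] (axis names must be [mmn_params()]
#'   arguments).
#' @param protocols character vector of protocol kinds (default: the
#'   four fitted protocols).
#' @param set_ids optional subset of parameter-set ids to run (e.g. a
#'   subsample of the full grid).
#' @param base_params an [mmn_params()] supplying values for parameters
#'   not on the grid.
#' @param n neurons per population.
#' @param network_seed fixed structural seed.
#' @param noise_seed noise seed per run.
#' @param checkpoint optional CSV path; finished rows are appended as
#'   they complete and already-present rows are skipped on resume.
#' @param verbose print progress.
#' @return A list with `results` (one row per set x protocol:
#'   acceptance flag, deviance-index fields, error messages),
#'   `accepted` (list of accepted `set_id`s per protocol) and
#'   `intersection`.
#' @export
run_grid <- function(spec, protocols = c("frequency_deviant", "omission",
                                         "duration_deviant",
                                         "inverse_duration_deviant"),
                     set_ids = NULL, base_params = mmn_params(), n = 40,
                     network_seed = 1, noise_seed = 1, checkpoint = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(spec, "grid_spec"), length(protocols) >= 1)
  grid <- enumerate_grid(spec)
  if (!is.null(set_ids)) grid <- grid[grid$set_id %in% set_ids, , drop = FALSE]
  prots <- lapply(protocols, make_stimulus_sequence)
  names(prots) <- protocols

  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, stringsAsFactors = FALSE)
  }
  rows <- list()
  for (i in seq_len(nrow(grid))) {
    sid <- grid$set_id[i]
    pars <- do.call(mmn_params,
                    modifyList(unclass(base_params),
                               as.list(grid[i, -1, drop = FALSE])))
    net <- tryCatch(build_mmn_network(pars, n = n, seed = network_seed),
                    error = function(e) e)
    for (pk in protocols) {
      if (!is.null(done) &&
          any(done$set_id == sid & done$protocol == pk)) next
      row <- data.frame(set_id = sid, protocol = pk, accepted = NA,
                        f_deviant = NA_real_, f_standard = NA_real_,
                        f_dd = NA_real_, frac_firing = NA_real_,
                        ratio = NA_real_, error = "",
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        if (inherits(net, "error")) stop(conditionMessage(net))
        rec <- run_protocol(net, prots[[pk]], seed = noise_seed)
        acc <- acceptance_test(rec, prots[[pk]])
        row$accepted <- acc$accepted
        row$f_deviant <- acc$deviance$f_deviant
        row$f_standard <- acc$deviance$f_standard
        row$f_dd <- acc$deviance$f_dd
        row$frac_firing <- acc$frac_firing
        row$ratio <- acc$ratio
        row
      }, error = function(e) {
        row$error <- conditionMessage(e)
        row
      })
      rows[[length(rows) + 1L]] <- res
      if (!is.null(checkpoint))
        utils::write.table(res, checkpoint, sep = ",", append = file.exists(checkpoint),
                           col.names = !file.exists(checkpoint),
                           row.names = FALSE, qmethod = "double")
    }
    if (verbose && i %% 10 == 0)
      message("grid: ", i, "/", nrow(grid), " parameter sets done")
  }
  results <- if (length(rows)) do.call(rbind, rows) else done
  if (!is.null(done) && length(rows)) results <- rbind(done, results)
  accepted <- lapply(protocols, function(pk)
    sort(results$set_id[results$protocol == pk &
                          results$accepted %in% TRUE]))
  names(accepted) <- protocols
  list(results = results, accepted = accepted,
       intersection = Reduce(intersect, accepted))
}
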