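#' Bernoulli (Erdos-Renyi) connectivity between two populations
#'
#' Draws each ordered (pre, post) pair independently with probability
#' `p`. Reproducible: the same `seed` always yields the same adjacency.
#'
#' @param n_pre,n_post population sizes (non-negative integers).
#' @param p connection probability in \[0, 1\]; the network default is
#'   0.5.
#' @param seed integer seed.
#' @param allow_self keep self-connections when the two populations are
#'   the same index space; default TRUE (the populations here are always
#'   distinct, so this rarely matters).
#' @return A two-column integer matrix with columns `pre` and `post`
#'   (1-based indices), ordered by `pre` then `post`.
#' @export
bernoulli_connect <- function(n_pre, n_post, p = 0.5, seed = 1,
                              allow_self = TRUE) {
  if (n_pre < 0 || n_post < 0) stop("counts must be non-negative", call. = FALSE)
  if (p < 0 || p > 1) stop("p must be in [0, 1]", call. = FALSE)
  if (n_pre == 0 || n_post == 0 || p == 0)
    return(cbind(pre = integer(), post = integer()))
  keep <- with_seed(seed, runif(n_pre * n_post) < p)
  idx <- which(keep) - 1L
  m <- cbind(pre = idx %/% n_post + 1L, post = idx %% n_post + 1L)
  if (!allow_self) m <- m[m[, 1] != m[, 2], , drop = FALSE]
  m
}

#' Sample heterogeneous positive parameter values
#'
#' Draws `n` values from a normal distribution with mean `mean` and
#' standard deviation `rel_sd * mean`, redrawing any non-positive values
#' (so the output is strictly positive). Used for the 30 percent
#' membrane-capacitance heterogeneity of the network populations.
#'
#' @param mean distribution mean, > 0.
#' @param rel_sd relative standard deviation (fraction of the mean),
#'   >= 0.
#' @param n number of samples.
#' @param seed integer seed.
#' @return Numeric vector of `n` positive values.
#' @export
sample_heterogeneous <- function(mean, rel_sd, n, seed = 1) {
  stopifnot(mean > 0, rel_sd >= 0, n >= 0)
  if (rel_sd == 0) return(rep(mean, n))
  with_seed(seed, {
    x <- rnorm(n, mean, rel_sd * mean)
    bad <- which(x <= 0)
    while (length(bad)) {
      x[bad] <- rnorm(length(bad), mean, rel_sd * mean)
      bad <- which(x <= 0)
    }
    x
  })
}
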