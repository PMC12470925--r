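# Exact conjugate beta-binomial posteriors for stratum event probabilities.
#
# Deaths in a stratum are binomial(n, PO) and PO carries a beta(a, b) prior,
# so the posterior is beta(a + r, b + n - r) in closed form. All posterior
# quantities are therefore sampled directly (no MCMC): independent draws
# from the exact posterior are the stationary distribution the equivalent
# Gibbs-free sampler would converge to.

#' Beta prior specification
#'
#' The default, `beta_prior(1, 10)`, is weakly informative toward small
#' probabilities, appropriate for rare events such as infant mortality;
#' `uniform_prior()` is the flat beta(1, 1) alternative used in prior
#' sensitivity analysis.
#'
#' @param a,b positive shape parameters.
#' @return object of class `prior_spec`.
#' @export
beta_prior <- function(a = 1, b = 10) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L ||
      is.na(a) || is.na(b) || a <= 0 || b <= 0)
    stop("prior shapes a and b must be positive scalars")
  structure(list(a = as.numeric(a), b = as.numeric(b)), class = "prior_spec")
}

#' @rdname beta_prior
#' @export
uniform_prior <- function() beta_prior(1, 1)

#' @export
print.prior_spec <- function(x, ...) {
  cat(sprintf("beta(%g, %g) prior\n", x$a, x$b))
  invisible(x)
}

posterior_shapes <- function(r, n, prior) {
  stopifnot(inherits(prior, "prior_spec"))
  if (any(is.na(r)) || any(is.na(n)) || any(r < 0) || any(n < 0))
    stop("counts must be nonnegative")
  if (any(r > n)) stop("deaths exceed births")
  list(shape1 = prior$a + r, shape2 = prior$b + n - r)
}

#' Monte-Carlo draws from the conjugate posterior of an event probability
#'
#' With `r` events among `n` trials and a `beta(a, b)` prior, returns
#' independent draws from `beta(a + r, b + n - r)`. With `r = n = 0` the
#' draws follow the prior.
#'
#' @param r number of events (deaths).
#' @param n number of trials (births), `r <= n`.
#' @param prior a [beta_prior()].
#' @param n_draws number of Monte-Carlo draws (default 10000).
#' @param seed optional integer seed; when `NULL` the current RNG stream is
#'   used (callers managing drawwise alignment seed once themselves).
#' @param label optional label attached to the draws.
#' @return numeric vector of class `po_draws`.
#' @export
posterior_draws <- function(r, n, prior = beta_prior(), n_draws = 10000,
                            seed = NULL, label = NULL) {
  stopifnot(length(r) == 1L, length(n) == 1L, n_draws >= 1)
  sh <- posterior_shapes(r, n, prior)
  if (!is.null(seed)) set.seed(seed)
  structure(stats::rbeta(n_draws, sh$shape1, sh$shape2),
            class = "po_draws", label = label)
}

#' Exact posterior quantile
#'
#' Closed-form quantile of the conjugate posterior; the analytic oracle for
#' the Monte-Carlo summaries.
#'
#' @inheritParams posterior_draws
#' @param q probability (or vector of probabilities) in (0, 1).
#' @return numeric vector of quantiles.
#' @export
posterior_quantile <- function(r, n, prior = beta_prior(), q = 0.5) {
  stopifnot(all(q > 0), all(q < 1))
  sh <- posterior_shapes(r, n, prior)
  stats::qbeta(q, sh$shape1, sh$shape2)
}

#' Posterior draws of a race-marginal event probability
#'
#' The marginal probability for a race group pools that group's deaths and
#' births across all strata (the race totals).
#'
#' @param counts a [strata_counts()] object.
#' @param race `"Black"` or `"nonBlack"`.
#' @inheritParams posterior_draws
#' @export
race_marginal_po <- function(counts, race = c("Black", "nonBlack"),
                             prior = beta_prior(), n_draws = 10000,
                             seed = NULL) {
  stopifnot(inherits(counts, "strata_counts"))
  race <- match.arg(race)
  posterior_draws(counts$r_race[race], counts$n_race[race], prior,
                  n_draws = n_draws, seed = seed,
                  label = paste0("marginal PO [", race, "]"))
}

#' Median and 95% credibility interval of a draw vector
#'
#' The empirical 2.5th, 50th and 97.5th percentiles (linear interpolation
#' between order statistics).
#'
#' @param draws numeric vector of Monte-Carlo draws.
#' @return one-row data.frame with columns `median`, `lo2_5`, `hi97_5`.
#' @export
summarize_draws <- function(draws) {
  draws <- as.numeric(draws)
  draws <- draws[!is.na(draws)]
  if (!length(draws)) stop("cannot summarize an empty draw vector")
  qs <- stats::quantile(draws, c(0.5, 0.025, 0.975), names = FALSE, type = 7)
  data.frame(median = qs[1], lo2_5 = qs[2], hi97_5 = qs[3])
}

#' @export
print.po_draws <- function(x, ...) {
  lab <- attr(x, "label")
  s <- summarize_draws(x)
  cat(sprintf("%s%d posterior draws: median %.4g (95%% CrI %.4g, %.4g)\n",
              if (is.null(lab)) "" else paste0(lab, ": "),
              length(x), s$median, s$lo2_5, s$hi97_5))
  invisible(x)
}
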