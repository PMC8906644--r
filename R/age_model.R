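#' Parameters of the heuristic steady-state age model
#'
#' A single exponentially growing population with gamma-distributed
#' generation times of mean \code{tau} and coefficient of variation
#' \code{CV}.  Derived quantities: growth rate \eqn{k = \ln 2 / \tau}, gamma
#' shape \eqn{\alpha = 1/CV^2}, scale \eqn{\beta = \tau/\alpha} (so the gamma
#' mean is \eqn{\tau} and its standard deviation \eqn{CV\,\tau}).
#'
#' @param tau Mean generation time (any time unit; all model outputs use the
#'   same unit).
#' @param CV Coefficient of variation of generation times, \code{>= 0};
#'   \code{CV = 0} selects the degenerate (identical generation times)
#'   branch of the model.
#' @return Object of class \code{age_model_params} with fields \code{tau},
#'   \code{CV}, \code{k}, \code{alpha}, \code{beta}, \code{sigma}.
#' @examples
#' age_model_params(200, 0.1)  # alpha = 100, beta = 2
#' @export
age_model_params <- function(tau, CV) {
  stopifnot(tau > 0, CV >= 0)
  if (CV > 0) {
    alpha <- 1 / CV^2
    beta <- tau / alpha
  } else {
    alpha <- Inf
    beta <- 0
  }
  structure(list(tau = tau, CV = CV, k = log(2) / tau,
                 alpha = alpha, beta = beta, sigma = CV * tau),
            class = "age_model_params")
}

#' @export
print.age_model_params <- function(x, ...) {
  cat(sprintf("Age model: tau = %g, CV = %g  (k = %.5g, alpha = %.5g, beta = %.5g)\n",
              x$tau, x$CV, x$k, x$alpha, x$beta))
  invisible(x)
}

#' Generation-time density
#'
#' The gamma density of generation times implied by
#' \code{\link{age_model_params}} (mean \code{tau}, sd \code{CV * tau}).
#'
#' @param a Generation times (same unit as \code{tau}).
#' @param p An \code{age_model_params} with \code{CV > 0}.
#' @return Density values.
#' @export
gen_time_pdf <- function(a, p) {
  stopifnot(inherits(p, "age_model_params"))
  if (p$CV == 0)
    stop("CV = 0 has no density; use the degenerate branch of age_density_single")
  stats::dgamma(a, shape = p$alpha, scale = p$beta)
}

#' Steady-state cell-age density of a single population
#'
#' The age density of an exponentially growing, symmetric-dividing,
#' death-free population at steady state:
#' \deqn{u(a) = 2 k e^{-k a} S(a)}
#' where \eqn{S(a)} is the survival function of the generation-time
#' distribution.  For \code{CV > 0}, \eqn{S} is the gamma survival function;
#' in the degenerate limit \code{CV = 0} the survival function is a step at
#' \eqn{\tau}, giving \eqn{u(a) = 2 k e^{-k a}} for \eqn{a < \tau} and 0 for
#' \eqn{a > \tau} (the value at \eqn{a = \tau} is taken as the left limit).
#' At \eqn{a = 0} the density is \eqn{2k} for every CV.
#'
#' @param a Ages, \code{>= 0}.
#' @param p An \code{\link{age_model_params}}.
#' @return Density values \code{u(a)}.
#' @examples
#' p <- age_model_params(200, 0.1)
#' age_density_single(0, p) / p$k  # = 2
#' @export
age_density_single <- function(a, p) {
  stopifnot(inherits(p, "age_model_params"))
  if (any(a < 0)) stop("ages must be non-negative")
  base <- 2 * p$k * exp(-p$k * a)
  if (p$CV == 0) {
    surv <- as.numeric(a <= p$tau)
  } else {
    surv <- stats::pgamma(a, shape = p$alpha, scale = p$beta,
                          lower.tail = FALSE)
  }
  base * surv
}

#' Total mass of the single-population age density
#'
#' Closed form of \eqn{\int_0^\infty u(a)\,da}: the Laplace transform of the
#' gamma survival function gives \eqn{2(1 - (1+\beta k)^{-\alpha})}, which
#' tends to 1 as \eqn{CV \to 0} (where the density integrates to exactly 1).
#'
#' @param p An \code{\link{age_model_params}}.
#' @return The integral value.
#' @export
age_density_mass <- function(p) {
  stopifnot(inherits(p, "age_model_params"))
  if (p$CV == 0) return(2 * (1 - exp(-p$k * p$tau))) # = 1 since k*tau = ln 2
  2 * (1 - (1 + p$beta * p$k)^(-p$alpha))
}

#' Growth-rate grid for community mixtures
#'
#' Log-spaced growth rates between a division once a year and one every
#' 30 minutes (the span used for the community age-density integration).
#'
#' @param n Number of grid points (default 400).
#' @param k_min,k_max Grid ends, 1/h.
#' @return Strictly increasing numeric vector.
#' @export
make_k_grid <- function(n = 400, k_min = log(2) / (365.25 * 24),
                        k_max = log(2) / 0.5) {
  stopifnot(n >= 1, k_min > 0, k_max > k_min)
  exp(seq(log(k_min), log(k_max), length.out = n))
}

#' Lognormal growth-rate weight regimes
#'
#' Weight profiles over a growth-rate grid representing different community
#' growth regimes: lognormal densities whose medians sit at the 10th, 50th
#' and 90th geometric quantiles of the grid span (slow / intermediate /
#' fast), all with log-sd 1, plus a homogeneous regime of equal weights.
#' Weights are the density values at the grid points, normalized to sum 1.
#'
#' @param k_grid Strictly increasing growth-rate grid.
#' @param regime \code{"homogeneous"}, \code{"slow"}, \code{"intermediate"}
#'   or \code{"fast"}.
#' @param log_sd Log-space standard deviation of the lognormal profiles.
#' @return Object of class \code{growth_rate_weights}: list with
#'   \code{k_grid}, \code{weights} (sum 1), \code{regime}.
#' @examples
#' w <- lognormal_weights(make_k_grid(100), "slow")
#' sum(w$weights)
#' @export
lognormal_weights <- function(k_grid,
                              regime = c("homogeneous", "slow",
                                         "intermediate", "fast"),
                              log_sd = 1.0) {
  regime <- match.arg(regime)
  stopifnot(length(k_grid) >= 1, all(diff(k_grid) > 0), all(k_grid > 0))
  if (regime == "homogeneous") {
    w <- rep(1 / length(k_grid), length(k_grid))
  } else {
    q <- switch(regime, slow = 0.1, intermediate = 0.5, fast = 0.9)
    lmin <- log(min(k_grid)); lmax <- log(max(k_grid))
    med <- lmin + q * (lmax - lmin)
    w <- stats::dlnorm(k_grid, meanlog = med, sdlog = log_sd)
    w <- w / sum(w)
  }
  structure(list(k_grid = k_grid, weights = w, regime = regime),
            class = "growth_rate_weights")
}

#' Community cell-age density
#'
#' Mixes the single-population age density over a spectrum of growth rates:
#' \deqn{\bar u(a) = \int u(a \mid k) \, w(k) \, dk}
#' evaluated as a trapezoidal quadrature over the weight object's grid (the
#' stored weights are density values at the grid points; the quadrature
#' measure \eqn{dk} is applied internally and the mixture renormalized, so a
#' homogeneous regime corresponds to growth rates uniformly present in
#' \eqn{k}).  Each population's mean generation time follows its growth rate
#' via \eqn{\tau = \ln 2 / k}.  With homogeneous weights and \code{CV = 0}
#' the result is the classic power-law community age distribution with
#' log-log slope \eqn{-2} over the intermediate age window.
#'
#' @param a_grid Ages at which to evaluate (> 0 recommended).
#' @param w A \code{\link{growth_rate_weights}}.
#' @param CV Coefficient of variation shared by all populations.
#' @return Numeric vector \eqn{\bar u} on \code{a_grid}.
#' @export
community_age_density <- function(a_grid, w, CV = 0.1) {
  stopifnot(inherits(w, "growth_rate_weights"), CV >= 0,
            length(w$weights) == length(w$k_grid))
  k <- w$k_grid
  nk <- length(k)
  if (nk == 1) {
    p <- age_model_params(log(2) / k, CV)
    return(age_density_single(a_grid, p))
  }
  # trapezoidal dk quadrature weights
  dk <- c(diff(k)[1] / 2,
          (k[-(1:2)] - k[-c(nk - 1, nk)]) / 2,
          diff(k)[nk - 1] / 2)
  W <- w$weights * dk
  W <- W / sum(W)
  out <- numeric(length(a_grid))
  for (j in seq_len(nk)) {
    p <- age_model_params(log(2) / k[j], CV)
    out <- out + W[j] * age_density_single(a_grid, p)
  }
  out
}

#' Untruncated power-law limit of the community age density
#'
#' The closed form obtained by integrating \eqn{2 k e^{-k a}} over all
#' growth rates \eqn{k \in (0, \infty)} without survival truncation:
#' \eqn{\bar u(a) = 2/a^2}.  This is the dashed reference line against which
#' numerically integrated community densities are compared.
#'
#' @param a Ages, strictly positive.
#' @return \code{2 / a^2}.
#' @examples
#' power_law_limit(1) # 2
#' @export
power_law_limit <- function(a) {
  if (any(a <= 0)) stop("ages must be strictly positive")
  2 / a^2
}

#' Log-log slope of a density over an age window
#'
#' Least-squares slope of \code{log(u)} against \code{log(a)} over
#' \code{[a_lo, a_hi]}; utility for the power-law checks on community
#' densities.
#'
#' @param a_grid,u Density tabulation.
#' @param a_lo,a_hi Window ends.
#' @return The fitted slope.
#' @export
loglog_slope <- function(a_grid, u, a_lo, a_hi) {
  sel <- a_grid >= a_lo & a_grid <= a_hi & u > 0
  if (sum(sel) < 3) stop("too few points in the slope window")
  stats::coef(stats::lm(log(u[sel]) ~ log(a_grid[sel])))[[2]]
}
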