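#' Maximum-likelihood fit of a heavy-tailed family to a sample tail
#'
#' Continuous MLE on the tail \code{x >= x_min} for one of five candidate
#' families of generation-time distributions:
#' \describe{
#'   \item{power_law}{\eqn{p(x) \propto x^{-\alpha}} with the closed-form
#'     Hill estimator \eqn{\hat\alpha = 1 + n / \sum \ln(x/x_{min})}.}
#'   \item{trunc_power_law}{\eqn{p(x) \propto x^{-\alpha} e^{-\lambda x}},
#'     by numerical likelihood maximization (normalizer by quadrature).}
#'   \item{exponential}{shifted exponential, \eqn{\hat\lambda = 1/\overline{(x - x_{min})}}.}
#'   \item{gamma, lognormal}{truncated-likelihood MLE via \code{optim}
#'     (reduces to the standard MLE when \code{x_min} is at the support
#'     edge).}
#' }
#'
#' @param sample Positive sample values.
#' @param family One of \code{"power_law"}, \code{"trunc_power_law"},
#'   \code{"exponential"}, \code{"gamma"}, \code{"lognormal"}.
#' @param x_min Lower tail cutoff; default the sample median.  At least 10
#'   values must lie at or above it.
#' @return Object of class \code{tail_fit}: list with \code{family},
#'   \code{params}, \code{x_min}, \code{n_tail}, \code{log_likelihood},
#'   \code{AIC}, \code{converged}.
#' @examples
#' x <- rexp(500)
#' fit_tail(x, "exponential", x_min = 0)
#' @export
fit_tail <- function(sample,
                     family = c("power_law", "trunc_power_law",
                                "exponential", "gamma", "lognormal"),
                     x_min = NULL) {
  family <- match.arg(family)
  stopifnot(all(sample > 0) || family == "exponential")
  if (is.null(x_min)) x_min <- stats::median(sample)
  tail <- sample[sample >= x_min]
  n <- length(tail)
  if (n < 10)
    stop("tail too small: ", n, " values >= x_min = ", format(x_min))
  converged <- TRUE
  if (family == "power_law") {
    alpha <- 1 + n / sum(log(tail / x_min))
    ll <- n * log((alpha - 1) / x_min) - alpha * sum(log(tail / x_min))
    params <- c(alpha = alpha)
  } else if (family == "exponential") {
    lambda <- 1 / mean(tail - x_min)
    ll <- n * log(lambda) - lambda * sum(tail - x_min)
    params <- c(lambda = lambda)
  } else if (family == "trunc_power_law") {
    nll <- function(par) {
      a <- par[1]; lam <- exp(par[2])
      lz <- .tpl_log_norm(a, lam, x_min)
      if (!is.finite(lz)) return(1e12)
      -(-n * lz - a * sum(log(tail)) - lam * sum(tail))
    }
    a0 <- 1 + n / sum(log(tail / x_min))
    opt <- stats::optim(c(max(a0, 1.01), log(1 / mean(tail))), nll,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    converged <- opt$convergence == 0
    params <- c(alpha = opt$par[1], lambda = exp(opt$par[2]))
    ll <- -opt$value
  } else if (family == "gamma") {
    nll <- function(par) {
      sh <- exp(par[1]); rate <- exp(par[2])
      lt <- stats::pgamma(x_min, sh, rate, lower.tail = FALSE, log.p = TRUE)
      -sum(stats::dgamma(tail, sh, rate, log = TRUE) - lt)
    }
    m <- mean(tail); v <- stats::var(tail)
    opt <- stats::optim(log(c(max(m^2 / v, 0.1), max(m / v, 1e-8))), nll,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    converged <- opt$convergence == 0
    params <- c(shape = exp(opt$par[1]), rate = exp(opt$par[2]))
    ll <- -opt$value
  } else { # lognormal
    nll <- function(par) {
      mu <- par[1]; s <- exp(par[2])
      lt <- stats::plnorm(x_min, mu, s, lower.tail = FALSE, log.p = TRUE)
      -sum(stats::dlnorm(tail, mu, s, log = TRUE) - lt)
    }
    lx <- log(tail)
    opt <- stats::optim(c(mean(lx), log(max(stats::sd(lx), 1e-3))), nll,
                        method = "Nelder-Mead",
                        control = list(maxit = 500, reltol = 1e-10))
    converged <- opt$convergence == 0
    params <- c(meanlog = opt$par[1], sdlog = exp(opt$par[2]))
    ll <- -opt$value
  }
  k <- length(params)
  structure(list(family = family, params = params, x_min = x_min,
                 n_tail = n, log_likelihood = ll, AIC = 2 * k - 2 * ll,
                 converged = converged),
            class = "tail_fit")
}

# log normalizing constant of x^-a e^(-lam x) on [x_min, Inf)
.tpl_log_norm <- function(a, lam, x_min) {
  if (lam < 0 || (lam == 0 && a <= 1)) return(NA_real_)
  if (lam == 0) return((1 - a) * log(x_min) - log(a - 1))
  # integrate in a numerically safe scaled form
  f <- function(x) exp(-a * log(x) - lam * x + a * log(x_min) + lam * x_min)
  val <- tryCatch(stats::integrate(f, x_min, Inf, rel.tol = 1e-9)$value,
                  error = function(e) NA_real_)
  if (!is.finite(val) || val <= 0) return(NA_real_)
  log(val) - a * log(x_min) - lam * x_min
}

#' Tail density of a fitted family
#'
#' Normalized density on \code{[x_min, Inf)} implied by a \code{tail_fit};
#' used for overlays and the quadrature normalization checks.
#'
#' @param fit A \code{tail_fit}.
#' @param x Evaluation points.
#' @return Density values (0 below \code{x_min}).
#' @export
tail_density <- function(fit, x) {
  stopifnot(inherits(fit, "tail_fit"))
  p <- fit$params; xm <- fit$x_min
  d <- switch(fit$family,
    power_law = (p["alpha"] - 1) / xm * (x / xm)^(-p["alpha"]),
    exponential = p["lambda"] * exp(-p["lambda"] * (x - xm)),
    trunc_power_law = exp(-p["alpha"] * log(x) - p["lambda"] * x -
                            .tpl_log_norm(p["alpha"], p["lambda"], xm)),
    gamma = stats::dgamma(x, p["shape"], p["rate"]) /
      stats::pgamma(xm, p["shape"], p["rate"], lower.tail = FALSE),
    lognormal = stats::dlnorm(x, p["meanlog"], p["sdlog"]) /
      stats::plnorm(xm, p["meanlog"], p["sdlog"], lower.tail = FALSE))
  d <- as.numeric(d)
  d[x < xm] <- 0
  d
}

#' @export
print.tail_fit <- function(x, ...) {
  cat(sprintf("Tail fit: %s (n_tail = %d, x_min = %.4g)%s\n", x$family,
              x$n_tail, x$x_min,
              if (x$converged) "" else "  [did not converge]"))
  cat("  ", paste(sprintf("%s = %.5g", names(x$params), x$params),
                  collapse = ", "), "\n", sep = "")
  cat(sprintf("  logLik = %.4f, AIC = %.4f\n", x$log_likelihood, x$AIC))
  invisible(x)
}

#' @export
coef.tail_fit <- function(object, ...) object$params

#' @export
logLik.tail_fit <- function(object, ...) {
  structure(object$log_likelihood, df = length(object$params),
            nobs = object$n_tail, class = "logLik")
}

#' @export
AIC.tail_fit <- function(object, ..., k = 2) object$AIC

#' Fit and rank several tail families
#'
#' Fits all requested families on a common tail and ranks them by AIC
#' (ties break alphabetically by family name); also reports pairwise
#' log-likelihood ratios.  Families whose fit errors out are dropped with a
#' warning and the rest are ranked.
#'
#' @param sample Positive sample values.
#' @param families Character vector of family names (>= 2, or 1 for a
#'   trivial ranking).
#' @param x_min Common lower cutoff (default: sample median).
#' @return Object of class \code{tail_fit_ranking}: list with \code{fits}
#'   (named list of \code{tail_fit}), \code{ranking} (data.frame: family,
#'   AIC, logLik, delta_AIC), \code{llr} (pairwise log-likelihood-ratio
#'   matrix), \code{best}.
#' @export
compare_tail_fits <- function(sample,
                              families = c("power_law", "trunc_power_law"),
                              x_min = NULL) {
  stopifnot(length(families) >= 1)
  if (is.null(x_min)) x_min <- stats::median(sample)
  fits <- list()
  for (fam in families) {
    f <- tryCatch(fit_tail(sample, fam, x_min), error = function(e) {
      warning("family ", fam, " failed: ", conditionMessage(e))
      NULL
    })
    if (!is.null(f)) fits[[fam]] <- f
  }
  if (length(fits) == 0) stop("no family could be fitted")
  aic <- vapply(fits, function(f) f$AIC, numeric(1))
  ll <- vapply(fits, function(f) f$log_likelihood, numeric(1))
  ord <- order(aic, names(fits))
  ranking <- data.frame(family = names(fits)[ord], AIC = aic[ord],
                        logLik = ll[ord], delta_AIC = aic[ord] - min(aic),
                        row.names = NULL)
  llr <- outer(ll, ll, "-")
  dimnames(llr) <- list(names(fits), names(fits))
  structure(list(fits = fits, ranking = ranking, llr = llr,
                 best = ranking$family[1], x_min = x_min),
            class = "tail_fit_ranking")
}

#' @export
print.tail_fit_ranking <- function(x, ...) {
  cat(sprintf("Tail model comparison at x_min = %.4g (best: %s)\n",
              x$x_min, x$best))
  print(x$ranking, row.names = FALSE)
  invisible(x)
}

#' Log-log overlay of sample tail and fitted families
#'
#' Empirical complementary CDF of the tail on log-log axes with the fitted
#' families' tail CCDFs overlaid (numerically integrated from the fitted
#' densities).
#'
#' @param x A \code{tail_fit_ranking}.
#' @param sample The sample used for fitting.
#' @param ... Passed to \code{plot}.
#' @return Invisibly, \code{NULL}.
#' @export
plot.tail_fit_ranking <- function(x, sample, ...) {
  tail <- sort(sample[sample >= x$x_min])
  n <- length(tail)
  ccdf <- 1 - (seq_len(n) - 1) / n
  graphics::plot(tail, ccdf, log = "xy", xlab = "generation time",
                 ylab = "P(X > x)", pch = 16, cex = 0.4, ...)
  cols <- seq_along(x$fits) + 1
  xs <- exp(seq(log(min(tail)), log(max(tail)), length.out = 200))
  for (i in seq_along(x$fits)) {
    f <- x$fits[[i]]
    cc <- vapply(xs, function(v)
      tryCatch(stats::integrate(function(u) tail_density(f, u), v, Inf,
                                rel.tol = 1e-8)$value,
               error = function(e) NA_real_), numeric(1))
    graphics::lines(xs, cc, col = cols[i])
  }
  graphics::legend("bottomleft", legend = names(x$fits), col = cols, lty = 1,
                   bty = "n")
  invisible(NULL)
}

#' Write a model-comparison result as JSON
#'
#' One entry per family: parameters, log-likelihood, AIC, cutoff and tail
#' size, ready for downstream plotting.
#'
#' @param cmp A \code{tail_fit_ranking}.
#' @param path Output file (conventionally \code{fits.json}).
#' @return \code{path}, invisibly.
#' @export
write_tail_fits <- function(cmp, path) {
  stopifnot(inherits(cmp, "tail_fit_ranking"))
  out <- lapply(cmp$fits, function(f)
    list(params = as.list(f$params), log_likelihood = f$log_likelihood,
         AIC = f$AIC, x_min = f$x_min, n_tail = f$n_tail,
         converged = f$converged))
  out$best <- cmp$best
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
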