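# Local linear model on the current subinterval (v0, v1]:
#   F(x) = alpha + beta (x - theta) = rho0 + (rho1 - rho0) (x - v0) / (v1 - v0)
# with rho0 = F(v0), rho1 = F(v1), prior 2 I(0 < rho0 < rho1 < 1), and theta
# the dose at which the line crosses the target rate alpha.

#' Value of the local line segment
#'
#' Evaluates the local linear dose-toxicity approximation parameterized by its
#' endpoint values \code{rho0 = F(v0)} and \code{rho1 = F(v1)}.  Equivalent to
#' the slope/quantile parameterization with
#' \code{beta = (rho1 - rho0)/(v1 - v0)} and
#' \code{theta = v0 + (alpha - rho0)/(rho1 - rho0) * (v1 - v0)}.
#'
#' @param rho0,rho1 Toxicity rates at the subinterval endpoints,
#'   \code{0 < rho0 < rho1 < 1}.
#' @param x Dose(s) at which to evaluate, in \code{[v0, v1]}.
#' @param v0,v1 Subinterval endpoints.
#' @return Toxicity rate(s) \code{F(x)}.
#' @export
line_value <- function(rho0, rho1, x, v0, v1) {
  if (any(rho0 >= rho1)) stop("monotonicity violated: need rho0 < rho1")
  stopifnot(v0 < v1)
  rho0 + (rho1 - rho0) * (x - v0) / (v1 - v0)
}

#' Log-likelihood of binary toxicity outcomes under the local line
#'
#' Sum of Bernoulli log-likelihood contributions \code{y log F(x) +
#' (1-y) log(1 - F(x))} for observations inside one subinterval.  A rate of
#' exactly 0 or 1 with a contradictory outcome yields \code{-Inf}.
#'
#' @inheritParams line_value
#' @param x,y Vectors of scaled doses and binary outcomes (1 = dose-limiting
#'   toxicity).
#' @return Scalar log-likelihood (0 for empty data).
#' @export
local_loglik <- function(rho0, rho1, x, y, v0, v1) {
  stopifnot(length(x) == length(y), all(y %in% c(0, 1)))
  if (length(x) == 0L) return(0)
  Fx <- line_value(rho0, rho1, x, v0, v1)
  if (any(Fx < 0 | Fx > 1)) return(-Inf)
  ll <- sum(ifelse(y == 1, log(Fx), log1p(-Fx)))
  if (is.nan(ll)) -Inf else ll
}

# Largest admissible slope at a given theta: the steepest line through
# (theta, alpha) whose endpoint values stay inside (0, 1).
.bmax <- function(theta, v0, v1, alpha) {
  b <- rep(Inf, length(theta))
  up <- theta > v0            # rho0 = alpha - beta (theta - v0) > 0
  b[up] <- pmin(b[up], alpha / (theta[up] - v0))
  lo <- theta < v1            # rho1 = alpha + beta (v1 - theta) < 1
  b[lo] <- pmin(b[lo], (1 - alpha) / (v1 - theta[lo]))
  hi <- theta > v1            # rho1 > 0 when theta beyond the subinterval
  b[hi] <- pmin(b[hi], alpha / (theta[hi] - v1))
  b
}

# Per-observation predictive toxicity rate given theta, with the slope
# integrated against its conditional prior induced by 2 I(0<rho0<rho1<1):
# p(beta | theta) = 2 beta / bmax(theta)^2, so E[beta | theta] = 2 bmax / 3.
.pred_rate <- function(x, theta, bm, alpha) {
  pmin(pmax(alpha + (2 / 3) * bm * (x - theta), 0), 1)
}

#' Posterior of the target quantile on the current subinterval
#'
#' Computes the marginal posterior density and mean of \code{theta}, the dose
#' at which the local line crosses the target rate \code{alpha}, from the
#' observations whose scaled doses lie in the subinterval \code{(v0, v1]}.
#' The endpoint rates carry the noninformative order prior
#' \code{2 I(0 < rho0 < rho1 < 1)}; \code{theta} is supported on the dose
#' domain \code{(0, 1]}.
#'
#' Two numerical schemes are available.  The default \code{"sequential"}
#' scheme updates the \code{theta} marginal one observation at a time, each
#' time integrating the slope against its conditional prior given
#' \code{theta}; this is the recursion that drives the design's transition
#' decisions.  The \code{"joint"} scheme integrates the full joint posterior
#' of (slope, \code{theta}) numerically (equivalently, the (rho0, rho1)
#' triangle with the order prior) and marginalizes; it serves as the directly
#' integrated reference.  With no data both return the prior push-forward.
#'
#' @param x,y Scaled doses and binary outcomes of the eligible observations
#'   (may be empty).
#' @param v0,v1 Subinterval endpoints, \code{0 <= v0 < v1 <= 1}.
#' @param alpha Target toxicity rate in \code{(0, 1)}.
#' @param resolution Number of grid points for \code{theta} (and for the
#'   inner slope integral of the joint scheme); at least 32.
#' @param method \code{"sequential"} (default) or \code{"joint"}.
#' @return An object of class \code{"bsa_posterior"}: list with \code{grid}
#'   (theta support points), \code{density} (normalized so the trapezoid
#'   integral is 1), \code{theta_mean}, \code{log_norm}, \code{v0},
#'   \code{v1}, \code{alpha}, \code{method}, \code{n} (number of
#'   observations used).
#' @examples
#' # after the first toxicity in a trial targeting alpha = 0.2 on (2/3, 1]:
#' post <- local_posterior(x = c(rep(0.75, 3), rep(0.96, 3)),
#'                         y = c(0, 0, 0, 0, 0, 1),
#'                         v0 = 2/3, v1 = 1, alpha = 0.2)
#' post$theta_mean
#' @export
local_posterior <- function(x, y, v0, v1, alpha, resolution = 400L,
                            method = c("sequential", "joint")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), v0 < v1, v0 >= 0, v1 <= 1,
            alpha > 0, alpha < 1)
  if (resolution < 32L) stop("'resolution' must be at least 32")
  if (length(x) > 0L) {
    if (any(x <= v0 | x > v1)) {
      stop("all doses must lie in the subinterval (v0, v1]")
    }
    if (!all(y %in% c(0, 1))) stop("outcomes must be binary 0/1")
  }
  M <- as.integer(resolution)
  th <- (seq_len(M) - 0.5) / M                 # midpoint grid on (0, 1]
  bm <- .bmax(th, v0, v1, alpha)

  # collapse to unique (dose, outcome) with counts
  if (length(x) > 0L) {
    key <- paste(x, y)
    agg <- do.call(rbind, lapply(split(seq_along(x), key), function(i) {
      c(x[i[1L]], y[i[1L]], length(i))
    }))
  } else {
    agg <- matrix(numeric(0), ncol = 3L)
  }

  logh <- 2 * log(bm)                           # induced prior marginal of theta
  if (method == "sequential") {
    for (r in seq_len(nrow(agg))) {
      p1 <- .pred_rate(agg[r, 1L], th, bm, alpha)
      f <- if (agg[r, 2L] == 1) p1 else 1 - p1
      logh <- logh + agg[r, 3L] * log(f)
    }
  } else {
    nb <- M
    bfrac <- (seq_len(nb) - 0.5) / nb
    logh <- vapply(seq_len(M), function(j) {
      b <- bm[j] * bfrac
      # joint prior in (beta, theta) coordinates is proportional to beta;
      # the marginal is the midpoint integral bmax * mean(beta * L)
      lw <- log(2) + log(b)
      for (r in seq_len(nrow(agg))) {
        Fx <- pmin(pmax(alpha + b * (agg[r, 1L] - th[j]), 0), 1)
        f <- if (agg[r, 2L] == 1) Fx else 1 - Fx
        lw <- lw + agg[r, 3L] * log(f)
      }
      m <- max(lw)
      if (!is.finite(m)) return(-Inf)
      m + log(mean(exp(lw - m)))
    }, numeric(1)) + log(bm)
  }

  m <- max(logh)
  if (!is.finite(m)) stop("posterior has no support: degenerate data")
  h <- exp(logh - m)
  z <- .trapz(th, h)
  dens <- h / z
  structure(
    list(grid = th, density = dens,
         theta_mean = .trapz(th, th * dens),
         log_norm = m + log(z) - log(M),
         v0 = v0, v1 = v1, alpha = alpha, method = method,
         n = length(x)),
    class = "bsa_posterior")
}

.trapz <- function(x, y) {
  n <- length(x)
  sum((y[-1] + y[-n]) * diff(x)) / 2
}

#' @export
print.bsa_posterior <- function(x, ...) {
  cat(sprintf(
    "Local posterior of theta on (%.3f, %.3f], alpha = %g (%s scheme)\n",
    x$v0, x$v1, x$alpha, x$method))
  cat(sprintf("  observations: %d   posterior mean: %.4f\n", x$n, x$theta_mean))
  invisible(x)
}

#' @export
plot.bsa_posterior <- function(x, ...) {
  graphics::plot(x$grid, x$density, type = "l", xlab = "theta",
                 ylab = "posterior density", ...)
  graphics::abline(v = c(x$v0, x$v1), lty = 3)
  graphics::abline(v = x$theta_mean, col = 2)
  invisible(x)
}

#' Serialize a local posterior to JSON
#'
#' @param post A \code{bsa_posterior}.
#' @param path Optional file path; when omitted the JSON string is returned.
#' @return JSON string (invisibly when written to file).
#' @export
posterior_json <- function(post, path = NULL) {
  stopifnot(inherits(post, "bsa_posterior"))
  j <- jsonlite::toJSON(
    list(grid = post$grid, density = post$density,
         theta_mean = post$theta_mean, v0 = post$v0, v1 = post$v1,
         alpha = post$alpha, method = post$method, n = post$n),
    auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(j)
}
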