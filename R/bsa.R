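#' Fit the dose-finding design state to an accumulated trial history
#'
#' The central modelling function: takes the cohort-level history of a
#' running (or completed) phase I trial, computes per-dose summaries, the
#' local posterior of the target quantile on the current subinterval, and
#' the next-dose decision under the full transition policy.
#'
#' @param history Data frame with columns \code{cohort}, \code{dose_index},
#'   \code{n_patients}, \code{n_dlt}; zero rows (or \code{NULL}) for a trial
#'   about to start.
#' @param grid A [dose_grid()].
#' @param config A [bsa_config()]; defaults to the grid's \code{alpha} and
#'   \code{s} with standard settings.
#' @param historical Optional [build_pseudo_data()] prior.
#' @return An object of class \code{"bsa"}: list with the inputs, per-dose
#'   counts \code{m} and \code{t}, observed and monotonicity-adjusted
#'   frequencies, the current dose, the local \code{posterior} (when the
#'   history is non-empty), and the \code{decision}.
#' @examples
#' g <- dose_grid(1:5, alpha = 0.3)
#' h <- data.frame(cohort = 1:2, dose_index = 1:2,
#'                 n_patients = 3, n_dlt = 0)
#' fit <- bsa(h, g)
#' fit$decision
#' @export
bsa <- function(history, grid, config = NULL, historical = NULL) {
  stopifnot(inherits(grid, "bsa_grid"))
  if (is.null(config)) config <- bsa_config(alpha = grid$alpha, s = grid$s)
  stopifnot(inherits(config, "bsa_config"))
  if (!is.null(historical)) {
    stopifnot(inherits(historical, "bsa_prior"))
    if (length(historical$a) != grid$K) {
      stop("historical prior length must match the number of doses")
    }
  }
  history <- .as_history(history)
  state <- .state_from_history(history, grid)

  posterior <- NULL
  if (nrow(history) > 0L) {
    sub <- subinterval_of(grid$scaled_levels[state$current_k], config$s)
    dat <- .local_data(state, grid, sub$v0, sub$v1, historical)
    posterior <- local_posterior(dat$x, dat$y, sub$v0, sub$v1, config$alpha,
                                 resolution = config$resolution)
  }
  decision <- next_dose(history, grid, config, historical)

  phat <- ifelse(state$m > 0, state$t / pmax(state$m, 1L), NA_real_)
  structure(
    list(history = history, grid = grid, config = config,
         historical = historical,
         m = state$m, t = state$t, phat = phat,
         phat_adjusted = pava_adjust(phat, state$m),
         current_k = state$current_k, any_dlt = state$any_dlt,
         enrolled = state$enrolled,
         posterior = posterior, decision = decision),
    class = "bsa")
}

#' @export
print.bsa <- function(x, ...) {
  cat(sprintf("Dose-finding design state: %d patients in %d cohorts, %d DLTs\n",
              x$enrolled, nrow(x$history), sum(x$t)))
  if (!is.na(x$current_k)) {
    cat(sprintf("  current dose: %d (scaled %.3f)\n", x$current_k,
                x$grid$scaled_levels[x$current_k]))
  }
  print(x$decision)
  invisible(x)
}

#' @describeIn bsa Per-dose table with counts, frequencies and the decision.
#' @param object,x A \code{bsa} object.
#' @param ... Unused.
#' @export
summary.bsa <- function(object, ...) {
  tab <- data.frame(
    dose = seq_len(object$grid$K),
    scaled = round(object$grid$scaled_levels, 4),
    n = object$m, dlt = object$t,
    phat = round(object$phat, 3),
    phat_adj = round(object$phat_adjusted, 3))
  out <- list(table = tab, decision = object$decision,
              enrolled = object$enrolled,
              theta_mean = if (!is.null(object$posterior))
                object$posterior$theta_mean else NULL)
  class(out) <- "summary.bsa"
  out
}

#' @export
print.summary.bsa <- function(x, ...) {
  cat("Per-dose summary:\n")
  print(x$table, row.names = FALSE)
  if (!is.null(x$theta_mean)) {
    cat(sprintf("Posterior mean of theta on the current subinterval: %.4f\n",
                x$theta_mean))
  }
  print(x$decision)
  invisible(x)
}

#' @describeIn bsa Posterior mean of the target quantile (\code{NA} before
#'   any data).
#' @export
coef.bsa <- function(object, ...) {
  c(theta = if (is.null(object$posterior)) NA_real_
    else object$posterior$theta_mean)
}

#' @describeIn bsa Plot the local posterior density with the dose positions.
#' @export
plot.bsa <- function(x, ...) {
  if (is.null(x$posterior)) stop("no posterior yet: the trial has no data")
  plot(x$posterior, ...)
  graphics::points(x$grid$scaled_levels,
                   rep(0, x$grid$K), pch = 3)
  invisible(x)
}

#' @describeIn bsa Decision tree for the next \code{depth} cohorts (see
#'   [decision_tree()]).
#' @param depth Cohorts to look ahead.
#' @export
predict.bsa <- function(object, depth = 3L, ...) {
  decision_tree(object$history, object$grid, object$config,
                object$historical, depth = depth)
}
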