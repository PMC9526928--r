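#' Design configuration
#'
#' Collects the tuning parameters of the design.  Defaults follow common
#' phase I practice: a maximum of 30 patients in cohorts of three, quick-action
#' threshold \code{m0 = 12} patients at one dose, and a 90\% Wald interval
#' (\code{xi = 0.05}).
#'
#' @param alpha Target toxicity rate in \code{(0, 1)} (required).
#' @param s Number of subintervals for local modelling (default 3).
#' @param m0 Patient count at one dose that activates the Wald-type quick
#'   action (default 12).
#' @param xi Tail probability of the Wald interval, in \code{(0, 0.5)}
#'   (default 0.05, a 90\% interval).
#' @param max_n Maximum sample size (default 30).
#' @param cohort_size A single integer (default 3), an integer schedule
#'   vector, or \code{"random"} for sizes drawn uniformly from \{1, 2, 3\}.
#' @param resolution Grid size for the posterior computation (default 400).
#' @param wald Logical; set \code{FALSE} to disable the Wald-type quick
#'   action (fast escalation is always active).
#' @param seed Optional integer seed recorded for random cohort sizes.
#' @return An object of class \code{"bsa_config"}.
#' @export
bsa_config <- function(alpha, s = 3L, m0 = 12L, xi = 0.05, max_n = 30L,
                       cohort_size = 3L, resolution = 400L, wald = TRUE,
                       seed = NULL) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (xi <= 0 || xi >= 0.5) stop("'xi' must lie in (0, 0.5)")
  if (m0 < 1) stop("'m0' must be at least 1")
  if (max_n < 1) stop("'max_n' must be at least 1")
  if (s < 1 || s != as.integer(s)) stop("'s' must be a positive integer")
  if (!(identical(cohort_size, "random") ||
        (is.numeric(cohort_size) && all(cohort_size >= 1) &&
         all(cohort_size == as.integer(cohort_size))))) {
    stop("'cohort_size' must be a positive integer, a schedule, or \"random\"")
  }
  structure(
    list(alpha = alpha, s = as.integer(s), m0 = as.integer(m0), xi = xi,
         max_n = as.integer(max_n), cohort_size = cohort_size,
         resolution = as.integer(resolution), wald = isTRUE(wald),
         seed = seed),
    class = "bsa_config")
}

#' @export
print.bsa_config <- function(x, ...) {
  cs <- if (identical(x$cohort_size, "random")) "random in {1,2,3}"
        else paste(x$cohort_size, collapse = ",")
  cat(sprintf(paste0(
    "Design configuration: alpha = %g, s = %d, m0 = %d, xi = %g,\n",
    "  max_n = %d, cohort size %s, wald quick action %s\n"),
    x$alpha, x$s, x$m0, x$xi, x$max_n, cs,
    if (x$wald) "on" else "off"))
  invisible(x)
}

# ---- trial state -----------------------------------------------------------

# Cohort-level history -> per-dose counts and flags.
# history: data.frame(cohort, dose_index, n_patients, n_dlt)
.state_from_history <- function(history, grid) {
  K <- grid$K
  m <- integer(K); t <- integer(K)
  if (nrow(history) > 0L) {
    if (any(history$dose_index < 1 | history$dose_index > K)) {
      stop("dose_index out of range for this grid")
    }
    if (any(history$n_dlt > history$n_patients) || any(history$n_patients < 1)) {
      stop("invalid cohort record: need 0 <= n_dlt <= n_patients, n_patients >= 1")
    }
    for (i in seq_len(nrow(history))) {
      k <- history$dose_index[i]
      m[k] <- m[k] + history$n_patients[i]
      t[k] <- t[k] + history$n_dlt[i]
    }
  }
  list(m = m, t = t,
       current_k = if (nrow(history)) history$dose_index[nrow(history)] else NA_integer_,
       any_dlt = sum(t) > 0L,
       enrolled = sum(m))
}

# Patient-level (x, y) expansion of all observations in subinterval (v0, v1],
# optionally augmented with historical pseudo-observations.
.local_data <- function(state, grid, v0, v1, historical = NULL) {
  d <- grid$scaled_levels
  x <- numeric(0); y <- numeric(0)
  for (k in seq_len(grid$K)) {
    inside <- d[k] > v0 & d[k] <= v1
    if (!inside) next
    a <- 0L; b <- 0L
    if (!is.null(historical)) {
      a <- historical$a[k]; b <- historical$b[k]
    }
    n1 <- state$t[k] + a
    n0 <- state$m[k] - state$t[k] + b
    x <- c(x, rep(d[k], n1 + n0))
    y <- c(y, rep(1, n1), rep(0, n0))
  }
  list(x = x, y = y)
}

# ---- frequentist pieces ----------------------------------------------------

#' Monotonicity adjustment of observed toxicity frequencies
#'
#' Restores monotonicity of the per-dose DLT frequencies by the two-point
#' pool-adjacent-violators rule: whenever the frequency at a dose falls below
#' the frequency at the previous observed dose, both are replaced by their
#' average.  Doses without patients are skipped (returned as \code{NA}).
#'
#' @param phat Per-dose DLT frequencies (may contain \code{NA} for untried
#'   doses).
#' @param m Per-dose patient counts.
#' @return Adjusted frequency vector, \code{NA} where \code{m == 0}.
#' @examples
#' pava_adjust(c(0.0, 0.5, 0.2, 0.6), c(3, 6, 5, 5))
#' @export
pava_adjust <- function(phat, m) {
  stopifnot(length(phat) == length(m))
  out <- ifelse(m > 0, phat, NA_real_)
  idx <- which(m > 0)
  if (length(idx) >= 2L) {
    for (j in 2:length(idx)) {
      a <- idx[j - 1L]; b <- idx[j]
      if (!is.na(out[a]) && !is.na(out[b]) && out[b] < out[a]) {
        avg <- (out[a] + out[b]) / 2
        out[a] <- avg; out[b] <- avg
      }
    }
  }
  out
}

#' Wald-type interval for the observed toxicity frequency
#'
#' The logit of the observed frequency at a dose with \code{m_k} patients is
#' asymptotically normal with variance \code{1 / (m_k p (1-p))}.  Centering at
#' the target rate gives the interval
#' \code{logit(alpha) +/- z_xi / sqrt(m_k alpha (1-alpha))}, mapped back to
#' the probability scale by the inverse logit.
#'
#' @param alpha Target toxicity rate.
#' @param m_k Number of patients at the dose (at least 1).
#' @param xi Tail probability (0.05 gives a 90\% interval).
#' @return Named vector \code{c(lower, upper)} on the probability scale.
#' @examples
#' wald_bounds(0.3, 12, 0.05)   # approximately (0.132, 0.547)
#' @export
wald_bounds <- function(alpha, m_k, xi = 0.05) {
  stopifnot(m_k >= 1, alpha > 0, alpha < 1, xi > 0, xi < 1)
  z <- stats::qnorm(1 - xi)
  half <- z / sqrt(m_k * alpha * (1 - alpha))
  c1 <- stats::qlogis(alpha) - half
  c2 <- stats::qlogis(alpha) + half
  c(lower = stats::plogis(c1), upper = stats::plogis(c2))
}

.decision <- function(action, next_k, rationale, theta_mean = NULL) {
  structure(list(action = action, next_k = next_k, rationale = rationale,
                 theta_mean = theta_mean),
            class = "bsa_decision")
}

#' @export
print.bsa_decision <- function(x, ...) {
  cat(sprintf("Decision: %s", x$action))
  if (!is.na(x$next_k)) cat(sprintf(" -> dose %d", x$next_k))
  cat(sprintf("  [%s", x$rationale))
  if (!is.null(x$theta_mean)) cat(sprintf(", E(theta|D) = %.4f", x$theta_mean))
  cat("]\n")
  invisible(x)
}

# Quick actions: fast escalation before any DLT, then the Wald interval check
# once m_k >= m0 at the current dose. Returns NULL when neither fires.
.quick_action <- function(state, grid, cfg) {
  k <- state$current_k
  K <- grid$K
  if (!state$any_dlt) {
    if (k < K) return(.decision("escalate", k + 1L, "fast-escalation"))
    return(NULL)                       # at top dose: defer to the Bayesian step
  }
  if (cfg$wald && state$m[k] >= cfg$m0) {
    phat <- ifelse(state$m > 0, state$t / pmax(state$m, 1L), NA_real_)
    adj <- pava_adjust(phat, state$m)
    wb <- wald_bounds(cfg$alpha, state$m[k], cfg$xi)
    if (adj[k] < wb["lower"]) {
      return(.decision("escalate", min(k + 1L, K), "wald-escalate"))
    }
    if (adj[k] > wb["upper"]) {
      if (k == 1L) {
        return(.decision("terminate-toxicity", NA_integer_, "wald-terminate"))
      }
      return(.decision("de-escalate", k - 1L, "wald-deescalate"))
    }
  }
  NULL
}

# Bayesian neighborhood rule: the next dose is the neighbor of the current
# dose closest to the posterior mean of theta; ties break toward the lower
# dose.
.bayes_step <- function(state, grid, cfg, historical = NULL) {
  k <- state$current_k
  sub <- subinterval_of(grid$scaled_levels[k], cfg$s)
  dat <- .local_data(state, grid, sub$v0, sub$v1, historical)
  post <- local_posterior(dat$x, dat$y, sub$v0, sub$v1, cfg$alpha,
                          resolution = cfg$resolution)
  cand <- sort(unique(c(max(k - 1L, 1L), k, min(k + 1L, grid$K))))
  dist <- abs(grid$scaled_levels[cand] - post$theta_mean)
  a <- cand[which.min(dist)]           # which.min takes the first (lower) tie
  action <- if (a > k) "escalate" else if (a < k) "de-escalate" else "stay"
  .decision(action, a, "bayes", theta_mean = post$theta_mean)
}

#' Next-dose decision
#'
#' Applies the full transition policy to an accumulated trial history: the
#' first cohort is always treated at the lowest dose; thereafter quick
#' actions are tried first (fast escalation while no DLT has occurred, then
#' the Wald-interval move/termination once \code{m0} patients have
#' accumulated at the current dose), and otherwise the Bayesian neighborhood
#' rule decides.  Dose skipping is never allowed.
#'
#' @param history Cohort-level data frame with columns \code{cohort},
#'   \code{dose_index}, \code{n_patients}, \code{n_dlt} (zero rows for a new
#'   trial).
#' @param grid A [dose_grid()].
#' @param config A [bsa_config()]; defaults to the grid's \code{alpha} and
#'   \code{s} with standard settings.
#' @param historical Optional [build_pseudo_data()] prior for historical
#'   borrowing.
#' @return A \code{bsa_decision}: list with \code{action}, \code{next_k},
#'   \code{rationale} and (for Bayesian decisions) \code{theta_mean}.
#' @export
next_dose <- function(history, grid, config = NULL, historical = NULL) {
  stopifnot(inherits(grid, "bsa_grid"))
  if (is.null(config)) config <- bsa_config(alpha = grid$alpha, s = grid$s)
  history <- .as_history(history)
  state <- .state_from_history(history, grid)
  if (nrow(history) == 0L) {
    return(.decision("escalate", 1L, "first-cohort"))
  }
  d <- .quick_action(state, grid, config)
  if (is.null(d)) d <- .bayes_step(state, grid, config, historical)
  d <- .coherence_guard(d, history, state$current_k)
  if (!is.na(d$next_k) && abs(d$next_k - state$current_k) > 1L) {
    stop("internal error: dose skipping")   # contract, should be unreachable
  }
  d
}

# Coherence restriction: a cohort with toxicity in every patient never leads
# to escalation, and a toxicity-free cohort never leads to de-escalation;
# the offending move is capped at the current dose.  Mixed cohorts are
# unrestricted.  Toxicity termination is a safety stop on cumulative
# evidence and is not capped.
.coherence_guard <- function(d, history, current_k) {
  last <- history[nrow(history), ]
  all_dlt <- last$n_dlt == last$n_patients
  none_dlt <- last$n_dlt == 0L
  if ((all_dlt && d$action == "escalate") ||
      (none_dlt && d$action == "de-escalate")) {
    return(.decision("stay", current_k, d$rationale, theta_mean = d$theta_mean))
  }
  d
}

.as_history <- function(history) {
  if (is.null(history)) {
    history <- data.frame(cohort = integer(0), dose_index = integer(0),
                          n_patients = integer(0), n_dlt = integer(0))
  }
  need <- c("dose_index", "n_patients", "n_dlt")
  if (!all(need %in% names(history))) {
    stop("history needs columns dose_index, n_patients, n_dlt")
  }
  if (!"cohort" %in% names(history)) history$cohort <- seq_len(nrow(history))
  history
}

#' Maximum tolerated dose recommendation
#'
#' Once the sample size is exhausted, the recommended next dose under the
#' Bayesian neighborhood rule is the MTD estimate.  A trial terminated for
#' toxicity yields no MTD.  The in-trial quick actions are accelerations of
#' the search and play no part in the final selection.
#'
#' @inheritParams next_dose
#' @param terminated Logical; \code{TRUE} when the trial was stopped by the
#'   toxicity rule.
#' @return Integer dose index, or \code{NA} when terminated.
#' @export
select_mtd <- function(history, grid, config = NULL, historical = NULL,
                       terminated = FALSE) {
  if (terminated) return(NA_integer_)
  if (is.null(config)) config <- bsa_config(alpha = grid$alpha, s = grid$s)
  history <- .as_history(history)
  if (nrow(history) == 0L) stop("cannot select an MTD from an empty trial")
  if (grid$K == 1L) return(1L)
  state <- .state_from_history(history, grid)
  if (!state$any_dlt) {
    # no toxicity ever observed: the search never left fast escalation, the
    # highest explored neighbor is recommended
    return(min(state$current_k + 1L, grid$K))
  }
  .bayes_step(state, grid, config, historical)$next_k
}

# ---- historical information ------------------------------------------------

#' Pseudo-observations from historical information
#'
#' Converts an elicited skeleton of prior toxicity probabilities \code{q_k}
#' and per-dose prior effective sample sizes \code{n_0k} into pseudo-counts:
#' \code{a_k} DLT and \code{b_k} non-DLT pre-existing observations at dose
#' \code{d_k}, the nearest integers to \code{n_0k q_k} and
#' \code{n_0k (1 - q_k)}.  These enter the local likelihood exactly like real
#' observations.
#'
#' @param skeleton Prior toxicity probabilities, strictly increasing in
#'   \code{(0, 1)}.
#' @param pess Prior effective sample sizes (non-negative integers), one per
#'   dose.
#' @return An object of class \code{"bsa_prior"}: list with \code{skeleton},
#'   \code{pess}, \code{a}, \code{b}.
#' @examples
#' build_pseudo_data(skeleton = c(0.1, 0.2, 0.3), pess = c(3, 3, 3))
#' @export
build_pseudo_data <- function(skeleton, pess) {
  stopifnot(length(skeleton) == length(pess))
  if (any(skeleton <= 0 | skeleton >= 1) || any(diff(skeleton) <= 0)) {
    stop("skeleton must be strictly increasing within (0, 1)")
  }
  if (any(pess < 0) || any(pess != as.integer(pess))) {
    stop("prior effective sample sizes must be non-negative integers")
  }
  a <- as.integer(round(pess * skeleton))
  b <- as.integer(round(pess * (1 - skeleton)))
  structure(list(skeleton = skeleton, pess = as.integer(pess), a = a, b = b),
            class = "bsa_prior")
}

#' @export
print.bsa_prior <- function(x, ...) {
  cat("Historical prior (pseudo-observations per dose):\n")
  print(data.frame(dose = seq_along(x$skeleton), q = x$skeleton,
                   n0 = x$pess, dlt = x$a, no_dlt = x$b), row.names = FALSE)
  invisible(x)
}

#' Default prior effective sample size for a vague prior
#'
#' For a vague historical prior the per-dose effective sample size is taken
#' as an integer in \code{[N/(3K), N/(2K)]}, where \code{N} is the maximum
#' sample size and \code{K} the number of doses.
#'
#' @param N Maximum sample size.
#' @param K Number of doses.
#' @param rule \code{"largest"} (default) or \code{"smallest"} integer in the
#'   interval.
#' @return A single integer.
#' @examples
#' pess_default(30, 5)  # 3
#' pess_default(30, 6)  # 2
#' @export
pess_default <- function(N, K, rule = c("largest", "smallest")) {
  rule <- match.arg(rule)
  stopifnot(N >= 1, K >= 1)
  lo <- ceiling(N / (3 * K)); hi <- floor(N / (2 * K))
  if (lo > hi) {
    stop(sprintf(
      "no integer lies in [N/(3K), N/(2K)] = [%.3g, %.3g]; choose n0 manually",
      N / (3 * K), N / (2 * K)))
  }
  as.integer(if (rule == "largest") hi else lo)
}

# ---- decision tree ---------------------------------------------------------

#' Pre-printed decision tree for the coming cohorts
#'
#' Enumerates every possible DLT count of the next \code{depth} cohorts and
#' tabulates the dose decision on each branch, so the transitions can be
#' looked up without computation during the trial.
#'
#' @inheritParams next_dose
#' @param depth Number of cohorts to look ahead (default 3).
#' @param cohort_size Patients per future cohort (default from
#'   \code{config}, or 3).
#' @return An object of class \code{"bsa_tree"}: nested list in which each
#'   node holds the dose treated, the branch DLT count, the decision, and
#'   its children.
#' @export
decision_tree <- function(history, grid, config = NULL, historical = NULL,
                          depth = 3L, cohort_size = NULL) {
  if (is.null(config)) config <- bsa_config(alpha = grid$alpha, s = grid$s)
  if (is.null(cohort_size)) {
    cohort_size <- if (is.numeric(config$cohort_size)) config$cohort_size[1L] else 3L
  }
  stopifnot(depth >= 1L, cohort_size >= 1L)
  history <- .as_history(history)
  grow <- function(hist, lvl) {
    dec <- next_dose(hist, grid, config, historical)
    node <- list(decision = dec, children = NULL)
    if (lvl < depth && !dec$action %in% "terminate-toxicity") {
      node$children <- lapply(0:cohort_size, function(tdlt) {
        nh <- rbind(hist, data.frame(cohort = nrow(hist) + 1L,
                                     dose_index = dec$next_k,
                                     n_patients = cohort_size,
                                     n_dlt = tdlt))
        ch <- grow(nh, lvl + 1L)
        ch$n_dlt <- tdlt
        ch
      })
    }
    node
  }
  structure(c(grow(history, 0L), list(cohort_size = cohort_size, depth = depth)),
            class = "bsa_tree")
}

#' @export
print.bsa_tree <- function(x, ...) {
  rec <- function(node, indent, label) {
    d <- node$decision
    tm <- if (!is.null(d$theta_mean)) sprintf(" E=%.3f", d$theta_mean) else ""
    cat(sprintf("%s%s%s dose %s (%s%s)\n", strrep("  ", indent), label,
                if (nzchar(label)) " ->" else "next:",
                if (is.na(d$next_k)) "none" else d$next_k, d$rationale, tm))
    for (ch in node$children) {
      rec(ch, indent + 1L, sprintf("%d/%d DLT", ch$n_dlt, x$cohort_size))
    }
  }
  rec(x, 0L, "")
  invisible(x)
}

#' Convert a decision tree to JSON
#'
#' @param tree A \code{bsa_tree}.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
tree_json <- function(tree, path = NULL) {
  strip <- function(node) {
    out <- list(next_k = node$decision$next_k,
                action = node$decision$action,
                rationale = node$decision$rationale)
    if (!is.null(node$decision$theta_mean)) out$theta_mean <- node$decision$theta_mean
    if (!is.null(node$n_dlt)) out$n_dlt <- node$n_dlt
    if (!is.null(node$children)) out$children <- lapply(node$children, strip)
    out
  }
  j <- jsonlite::toJSON(strip(tree), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(j)
}
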