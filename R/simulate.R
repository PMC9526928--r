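#' Toxicity scenario
#'
#' A scenario pairs a dose grid with the true per-dose toxicity
#' probabilities; the true MTD is the dose whose toxicity probability is
#' closest to the target rate (ties toward the lower dose).
#'
#' @param grid A [dose_grid()].
#' @param p True toxicity probabilities, strictly increasing in
#'   \code{(0, 1)}, one per dose.
#' @return An object of class \code{"bsa_scenario"} with \code{grid},
#'   \code{p}, \code{mtd_index}.
#' @export
scenario <- function(grid, p) {
  stopifnot(inherits(grid, "bsa_grid"), length(p) == grid$K)
  if (any(p <= 0 | p >= 1) || any(diff(p) <= 0)) {
    stop("'p' must be strictly increasing within (0, 1)")
  }
  structure(list(grid = grid, p = as.numeric(p),
                 mtd_index = which.min(abs(p - grid$alpha))),
            class = "bsa_scenario")
}

#' @export
print.bsa_scenario <- function(x, ...) {
  cat(sprintf("Toxicity scenario (alpha = %g, true MTD = dose %d):\n",
              x$grid$alpha, x$mtd_index))
  print(data.frame(dose = seq_len(x$grid$K),
                   scaled = round(x$grid$scaled_levels, 3),
                   true_p = round(x$p, 3)), row.names = FALSE)
  invisible(x)
}

#' Hyperbolic-tangent dose-toxicity scenario
#'
#' The classical smooth dose-toxicity curve
#' \code{Pr(y = 1) = (((tanh(x) + 1) / 2))^2} evaluated at the original
#' (untransformed) dose values.
#'
#' @param original_doses Doses on the original scale.
#' @param grid A [dose_grid()] for the same doses.
#' @return A [scenario()].
#' @examples
#' g <- dose_grid(c(-1.47, -1.1, -0.69, -0.42, 0, 0.42), alpha = 0.2,
#'                scaled = c(0.015, 0.20, 0.405, 0.54, 0.75, 0.96))
#' tanh_scenario(g$original_levels, g)$p   # 0.002 0.01 0.04 0.09 0.24 0.49
#' @export
tanh_scenario <- function(original_doses, grid) {
  p <- ((tanh(original_doses) + 1) / 2)^2
  scenario(grid, p)
}

#' Random toxicity scenario with a prescribed MTD position
#'
#' Generates a strictly increasing toxicity-probability vector whose MTD sits
#' at a given position, with the gaps to the adjacent doses constrained to
#' \code{gap_bounds}.  The probability at the MTD is drawn uniformly within
#' 0.05 of the target rate, the adjacent gaps uniformly from
#' \code{gap_bounds}, and the remaining doses extend outward with increasing
#' uniform increments; draws violating the constraints (after clipping to
#' \code{(0, 1)}) are rejected and resampled.
#'
#' @param grid A [dose_grid()].
#' @param mtd_position Target MTD index in \code{1..K}.
#' @param gap_bounds Bounds for the toxicity gap between the MTD and its
#'   neighbors (default \code{c(0.05, 0.3)}).
#' @param seed Optional seed for reproducibility.
#' @param max_tries Resampling cap before an error.
#' @return A [scenario()].
#' @export
random_scenario <- function(grid, mtd_position, gap_bounds = c(0.05, 0.3),
                            seed = NULL, max_tries = 1000L) {
  K <- grid$K
  alpha <- grid$alpha
  stopifnot(mtd_position >= 1L, mtd_position <= K)
  if (!is.null(seed)) set.seed(seed)
  for (try in seq_len(max_tries)) {
    p <- numeric(K)
    p[mtd_position] <- stats::runif(1, max(alpha - 0.05, 0.01),
                                    min(alpha + 0.05, 0.99))
    if (mtd_position > 1L) {
      p[mtd_position - 1L] <- p[mtd_position] -
        stats::runif(1, gap_bounds[1L], gap_bounds[2L])
      k <- mtd_position - 1L
      while (k > 1L) {
        p[k - 1L] <- p[k] - stats::runif(1, 0.01, 0.25)
        k <- k - 1L
      }
    }
    if (mtd_position < K) {
      p[mtd_position + 1L] <- p[mtd_position] +
        stats::runif(1, gap_bounds[1L], gap_bounds[2L])
      k <- mtd_position + 1L
      while (k < K) {
        p[k + 1L] <- p[k] + stats::runif(1, 0.01, 0.25)
        k <- k + 1L
      }
    }
    p <- pmin(pmax(p, 1e-4), 1 - 1e-4)
    ok <- all(diff(p) > 0) &&
      which.min(abs(p - alpha)) == mtd_position &&
      (mtd_position == 1L ||
         abs(p[mtd_position] - p[mtd_position - 1L]) >= gap_bounds[1L]) &&
      (mtd_position == K ||
         abs(p[mtd_position + 1L] - p[mtd_position]) >= gap_bounds[1L])
    if (ok) return(scenario(grid, p))
  }
  stop("could not generate a scenario satisfying the gap constraints")
}

#' Random dose grid with the MTD at an early, middle or late position
#'
#' Places the scaled MTD dose at 0.3, 0.5 or 0.7 and draws the remaining
#' doses uniformly below and above it, keeping the vicinity of width 0.05 on
#' each side of the MTD free so it stays distinguishable.
#'
#' @param K Number of doses.
#' @param mtd_position MTD index in \code{1..K}.
#' @param location \code{"early"}, \code{"middle"} or \code{"late"} (scaled
#'   MTD dose 0.3, 0.5, 0.7).
#' @param alpha Target rate stored in the returned grid.
#' @param s Partition count stored in the returned grid.
#' @param seed Optional seed.
#' @return A [dose_grid()] whose scaled levels are the generated doses.
#' @export
random_exact_doses <- function(K, mtd_position, location = c("early", "middle", "late"),
                               alpha = 0.3, s = 3L, seed = NULL) {
  location <- match.arg(location)
  stopifnot(mtd_position >= 1L, mtd_position <= K)
  if (!is.null(seed)) set.seed(seed)
  dk <- c(early = 0.3, middle = 0.5, late = 0.7)[[location]]
  lower <- if (mtd_position > 1L) {
    sort(stats::runif(mtd_position - 1L, 0.01, dk - 0.05))
  } else numeric(0)
  upper <- if (mtd_position < K) {
    sort(stats::runif(K - mtd_position, dk + 0.05, 1))
  } else numeric(0)
  d <- c(lower, dk, upper)
  dose_grid(seq_len(K), alpha = alpha, s = s, scaled = d)
}

#' Simulate one virtual trial
#'
#' Runs the full sequential design against a toxicity scenario: the first
#' cohort at the lowest dose, per-patient Bernoulli toxicity outcomes, the
#' transition policy after every cohort, stopping at the maximum sample size
#' or on toxicity termination, and final MTD selection.
#'
#' @param scn A [scenario()].
#' @param config A [bsa_config()] (defaults from the scenario's grid).
#' @param historical Optional [build_pseudo_data()] prior.
#' @param seed Integer seed; a fixed seed reproduces the trial exactly.
#' @return An object of class \code{"bsa_trial"}: list with \code{selected}
#'   (MTD index or \code{NA}), \code{path} (dose per cohort),
#'   \code{allocations} (patients per dose), \code{n_dlt}, \code{enrolled},
#'   \code{terminated}, and \code{quick_counts} (fires of fast escalation
#'   and Wald actions).
#' @export
run_trial <- function(scn, config = NULL, historical = NULL, seed = NULL) {
  stopifnot(inherits(scn, "bsa_scenario"))
  grid <- scn$grid
  if (is.null(config)) config <- bsa_config(alpha = grid$alpha, s = grid$s)
  if (!is.null(seed)) set.seed(seed)
  history <- .as_history(NULL)
  quick <- c(`fast-escalation` = 0L, wald = 0L)
  terminated <- FALSE
  k <- 1L                                    # first cohort at the lowest dose
  sched <- config$cohort_size
  cohort_no <- 0L
  enrolled <- 0L
  repeat {
    cohort_no <- cohort_no + 1L
    size <- if (identical(sched, "random")) {
      sample(1:3, 1L)
    } else if (length(sched) > 1L) {
      sched[min(cohort_no, length(sched))]
    } else sched
    size <- min(size, config$max_n - enrolled)
    ndlt <- stats::rbinom(1L, size, scn$p[k])
    history <- rbind(history,
                     data.frame(cohort = cohort_no, dose_index = k,
                                n_patients = size, n_dlt = ndlt))
    enrolled <- enrolled + size
    if (enrolled >= config$max_n) break
    dec <- next_dose(history, grid, config, historical)
    if (dec$action == "terminate-toxicity") { terminated <- TRUE; break }
    if (dec$rationale == "fast-escalation") {
      quick["fast-escalation"] <- quick["fast-escalation"] + 1L
    } else if (startsWith(dec$rationale, "wald")) {
      quick["wald"] <- quick["wald"] + 1L
    }
    k <- dec$next_k
  }
  state <- .state_from_history(history, grid)
  selected <- select_mtd(history, grid, config, historical,
                         terminated = terminated)
  structure(
    list(selected = selected, path = history$dose_index,
         allocations = state$m, n_dlt = sum(state$t),
         enrolled = enrolled, terminated = terminated,
         quick_counts = quick, history = history),
    class = "bsa_trial")
}

#' @export
print.bsa_trial <- function(x, ...) {
  cat(sprintf("Simulated trial: %d patients, %d DLTs, path %s\n",
              x$enrolled, x$n_dlt, paste(x$path, collapse = "-")))
  cat(if (x$terminated) "  terminated for toxicity (no MTD)\n"
      else sprintf("  selected MTD: dose %d\n", x$selected))
  invisible(x)
}

#' Replicate virtual trials
#'
#' Runs [run_trial()] repeatedly with one reproducible random stream per
#' replicate (root seed plus replicate index).
#'
#' @inheritParams run_trial
#' @param reps Number of replicates.
#' @param seed Root seed.
#' @return A list of \code{bsa_trial} objects with class
#'   \code{"bsa_sims"}.
#' @export
simulate_trials <- function(scn, config = NULL, reps = 100L, seed = 1L,
                            historical = NULL) {
  stopifnot(reps >= 1L)
  out <- lapply(seq_len(reps), function(i) {
    run_trial(scn, config, historical, seed = seed + i - 1L)
  })
  structure(out, class = "bsa_sims", scenario = scn)
}

#' Operating characteristics of replicated trials
#'
#' Tabulates the four standard metrics over a set of simulated trials:
#' the percentage of replicates selecting the true MTD (PCS), the average
#' percentage of patients allocated to the MTD, the average percentage of
#' patients treated above the MTD, and the mean number of observed DLTs.
#' Toxicity-terminated replicates count as incorrect selections and
#' contribute their enrolled patients to the allocation metrics.
#'
#' @param results A \code{bsa_sims} list (or plain list of
#'   \code{bsa_trial}).
#' @param scn The [scenario()] the trials were run against (defaults to the
#'   one attached to \code{results}).
#' @return An object of class \code{"bsa_oc"}: list with \code{pcs},
#'   \code{mtd_pct}, \code{above_mtd_pct}, \code{avg_dlt}, \code{reps},
#'   \code{terminated_pct}.
#' @export
operating_characteristics <- function(results, scn = NULL) {
  if (is.null(scn)) scn <- attr(results, "scenario")
  stopifnot(inherits(scn, "bsa_scenario"), length(results) >= 1L)
  mtd <- scn$mtd_index
  sel <- vapply(results, function(r) {
    !r$terminated && !is.na(r$selected) && r$selected == mtd
  }, logical(1))
  at <- vapply(results, function(r) r$allocations[mtd] / r$enrolled, numeric(1))
  above <- vapply(results, function(r) {
    if (mtd >= length(r$allocations)) 0
    else sum(r$allocations[(mtd + 1L):length(r$allocations)]) / r$enrolled
  }, numeric(1))
  structure(
    list(pcs = 100 * mean(sel),
         mtd_pct = 100 * mean(at),
         above_mtd_pct = 100 * mean(above),
         avg_dlt = mean(vapply(results, function(r) r$n_dlt, numeric(1))),
         reps = length(results),
         terminated_pct = 100 * mean(vapply(results, function(r) r$terminated,
                                            logical(1)))),
    class = "bsa_oc")
}

#' @export
print.bsa_oc <- function(x, ...) {
  cat(sprintf(paste0(
    "Operating characteristics over %d replicates:\n",
    "  correct selection (PCS): %.1f%%\n",
    "  patients at MTD:         %.1f%%\n",
    "  patients above MTD:      %.1f%%\n",
    "  average DLT count:       %.2f\n",
    "  terminated for toxicity: %.1f%%\n"),
    x$reps, x$pcs, x$mtd_pct, x$above_mtd_pct, x$avg_dlt, x$terminated_pct))
  invisible(x)
}

#' @export
plot.bsa_oc <- function(x, ...) {
  graphics::barplot(
    c(PCS = x$pcs, `MTD%` = x$mtd_pct, `above-MTD%` = x$above_mtd_pct),
    ylab = "percent", ...)
  invisible(x)
}
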