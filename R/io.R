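# File interfaces: YAML run configuration, CSV trial histories and
# scenarios, JSON decisions, and the human-readable trial report.

#' Load a run configuration from a YAML file
#'
#' Recognized keys: \code{alpha} (required), \code{doses} or
#' \code{scaled_doses}, \code{s}, \code{m0}, \code{xi}, \code{max_n},
#' \code{cohort_size}, \code{resolution}, \code{wald}, \code{seed},
#' \code{skeleton}, \code{pess}, \code{reps}, \code{scenario},
#' \code{history}, \code{out}.  Unknown keys raise an error; omitted design
#' parameters take the standard defaults (\code{s = 3}, \code{m0 = 12},
#' \code{xi = 0.05}, \code{max_n = 30}, cohorts of 3).
#'
#' @param path Path to a YAML file.
#' @return A list with elements \code{config} (a [bsa_config()]),
#'   \code{grid} (a [dose_grid()] or \code{NULL}), \code{historical}
#'   (a [build_pseudo_data()] prior or \code{NULL}), and the remaining
#'   run-level entries (\code{reps}, \code{scenario}, \code{history},
#'   \code{out}).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  raw <- yaml::read_yaml(path)
  known <- c("alpha", "doses", "scaled_doses", "s", "m0", "xi", "max_n",
             "cohort_size", "resolution", "wald", "seed", "skeleton",
             "pess", "reps", "scenario", "history", "out")
  unknown <- setdiff(names(raw), known)
  if (length(unknown)) {
    stop(sprintf("unknown configuration key(s): %s",
                 paste(unknown, collapse = ", ")))
  }
  if (is.null(raw[["alpha"]])) stop("configuration must specify 'alpha'")
  cfg <- bsa_config(
    alpha = raw[["alpha"]],
    s = raw[["s"]] %||% 3L,
    m0 = raw[["m0"]] %||% 12L,
    xi = raw[["xi"]] %||% 0.05,
    max_n = raw[["max_n"]] %||% 30L,
    cohort_size = raw[["cohort_size"]] %||% 3L,
    resolution = raw[["resolution"]] %||% 400L,
    wald = raw[["wald"]] %||% TRUE,
    seed = raw[["seed"]])
  grid <- NULL
  if (!is.null(raw[["doses"]])) {
    grid <- dose_grid(raw[["doses"]], alpha = cfg$alpha, s = cfg$s,
                      scaled = raw[["scaled_doses"]])
  } else if (!is.null(raw[["scaled_doses"]])) {
    grid <- dose_grid(seq_along(raw[["scaled_doses"]]), alpha = cfg$alpha,
                      s = cfg$s, scaled = raw[["scaled_doses"]])
  }
  historical <- NULL
  if (!is.null(raw[["skeleton"]])) {
    pess <- raw[["pess"]]
    if (is.null(pess)) {
      if (is.null(grid)) stop("'skeleton' given without 'pess' or doses")
      pess <- rep(pess_default(cfg$max_n, grid$K), grid$K)
    } else if (length(pess) == 1L) {
      pess <- rep(pess, length(raw[["skeleton"]]))
    }
    historical <- build_pseudo_data(raw[["skeleton"]], pess)
  }
  list(config = cfg, grid = grid, historical = historical,
       reps = raw[["reps"]], scenario = raw[["scenario"]], history = raw[["history"]],
       out = raw[["out"]])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read or write a cohort-level trial history as CSV
#'
#' Columns: \code{cohort}, \code{dose_index}, \code{n_patients},
#' \code{n_dlt} (an optional \code{scaled_dose} column is accepted and
#' ignored on reading, and written when a grid is supplied).
#'
#' @param history A history data frame.
#' @param path File path.
#' @param grid Optional [dose_grid()] used to add the \code{scaled_dose}
#'   column on writing.
#' @return \code{read_history} returns the history data frame.
#' @export
write_history <- function(history, path, grid = NULL) {
  history <- .as_history(history)
  out <- history
  if (!is.null(grid)) out$scaled_dose <- grid$scaled_levels[out$dose_index]
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_history
#' @export
read_history <- function(path) {
  d <- utils::read.csv(path)
  .as_history(d)[, c("cohort", "dose_index", "n_patients", "n_dlt")]
}

#' Read or write a toxicity scenario as CSV
#'
#' Columns: \code{dose_index}, \code{scaled_dose}, \code{true_p}.
#'
#' @param scn A [scenario()].
#' @param path File path.
#' @param alpha,s Target rate and partition count applied on reading.
#' @return \code{read_scenario} returns a [scenario()].
#' @export
write_scenario <- function(scn, path) {
  stopifnot(inherits(scn, "bsa_scenario"))
  utils::write.csv(
    data.frame(dose_index = seq_len(scn$grid$K),
               scaled_dose = scn$grid$scaled_levels,
               true_p = scn$p),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scenario
#' @export
read_scenario <- function(path, alpha, s = 3L) {
  d <- utils::read.csv(path)
  need <- c("dose_index", "scaled_dose", "true_p")
  if (!all(need %in% names(d))) {
    stop("scenario file must have columns dose_index, scaled_dose, true_p")
  }
  d <- d[order(d$dose_index), ]
  g <- dose_grid(seq_len(nrow(d)), alpha = alpha, s = s,
                 scaled = d$scaled_dose)
  scenario(g, d$true_p)
}

#' Write a decision as JSON
#'
#' @param decision A \code{bsa_decision}.
#' @param path Optional output file.
#' @return JSON string (invisibly when written to file).
#' @export
decision_json <- function(decision, path = NULL) {
  stopifnot(inherits(decision, "bsa_decision"))
  j <- jsonlite::toJSON(
    list(action = decision$action,
         next_k = if (is.na(decision$next_k)) NULL else decision$next_k,
         rationale = decision$rationale,
         theta_mean = decision$theta_mean),
    auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(j)
  writeLines(j, path)
  invisible(j)
}

#' Human-readable trial report
#'
#' Prints the per-dose summary table, the current decision with its
#' rationale, and the posterior mean of the target quantile when the
#' decision is Bayesian.  The same content is returned invisibly as a list
#' (the machine twin of the printed report).
#'
#' @param fit A [bsa()] object.
#' @return Invisibly, a list with \code{table}, \code{decision},
#'   \code{theta_mean}.
#' @export
report_trial <- function(fit) {
  stopifnot(inherits(fit, "bsa"))
  s <- summary(fit)
  if (nrow(fit$history) == 0L) {
    cat("New trial: start at dose 1 (first cohort at the lowest dose)\n")
  } else if (fit$decision$action == "terminate-toxicity") {
    cat("Trial terminated for toxicity: the lowest dose is too toxic\n")
    print(s$table, row.names = FALSE)
  } else {
    print(s)
  }
  invisible(list(table = s$table, decision = fit$decision,
                 theta_mean = s$theta_mean))
}
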