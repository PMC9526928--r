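#' Map candidate dose levels into the unit interval
#'
#' The design works on doses scaled into \code{(0, 1]}. Original levels are
#' mapped by an affine transformation, either of the raw values
#' (\code{mode = "linear"}) or of their natural logarithms
#' (\code{mode = "log"}): \code{(x - offset) / divisor} respectively
#' \code{(log(x) - offset) / divisor}.
#'
#' @param levels Numeric vector of dose levels, strictly increasing. Must be
#'   positive when \code{mode = "log"}.
#' @param mode \code{"linear"} or \code{"log"}.
#' @param offset,divisor Transformation constants; \code{divisor} must be
#'   positive.
#' @return Numeric vector of scaled doses, all in \code{(0, 1]}.
#' @examples
#' scale_doses(1:5, "linear", offset = 0.5, divisor = 5)   # 0.1 0.3 0.5 0.7 0.9
#' @seealso [auto_scale()] for choosing the transformation automatically.
#' @export
scale_doses <- function(levels, mode = c("linear", "log"), offset, divisor) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(levels), length(levels) >= 1L,
            is.numeric(offset), is.numeric(divisor))
  if (divisor <= 0) stop("'divisor' must be positive")
  if (any(diff(levels) <= 0)) stop("'levels' must be strictly increasing")
  if (mode == "log") {
    if (any(levels <= 0)) stop("log scaling requires positive dose levels")
    x <- log(levels)
  } else {
    x <- levels
  }
  scaled <- (x - offset) / divisor
  bad <- scaled <= 0 | scaled > 1
  if (any(bad)) {
    stop(sprintf(
      "scaled value for dose level %g falls outside (0, 1] (got %.4g)",
      levels[which(bad)[1L]], scaled[which(bad)[1L]]))
  }
  scaled
}

#' Choose a dose-scaling transformation automatically
#'
#' Picks the scale on which the levels are most evenly spaced: linear when the
#' spacing is approximately additive, natural-log when approximately
#' multiplicative (judged by the coefficient of variation of successive
#' differences on each scale).  The affine map then spreads the levels over
#' \code{(0, 1]} with a half-step margin at each end:
#' \code{delta = (max - min) / (2 (K - 1))}, \code{offset = min - delta},
#' \code{divisor = max - min + 2 delta}.  For equally spaced levels
#' \code{1..5} this yields the map \code{(x - 0.5)/5}, i.e. scaled doses
#' \code{0.1, 0.3, ..., 0.9}.
#'
#' @param levels Numeric vector of at least two distinct dose levels,
#'   strictly increasing.
#' @return A list with elements \code{mode}, \code{offset}, \code{divisor}.
#' @export
auto_scale <- function(levels) {
  stopifnot(is.numeric(levels))
  if (length(unique(levels)) < 2L) stop("need at least 2 distinct dose levels")
  if (any(diff(levels) <= 0)) stop("'levels' must be strictly increasing")
  cv <- function(d) stats::sd(d) / mean(d)
  mode <- "linear"
  if (all(levels > 0) && length(levels) > 2L) {
    if (cv(diff(log(levels))) < cv(diff(levels))) mode <- "log"
  }
  x <- if (mode == "log") log(levels) else levels
  K <- length(x)
  delta <- (max(x) - min(x)) / (2 * (K - 1))
  list(mode = mode, offset = min(x) - delta,
       divisor = max(x) - min(x) + 2 * delta)
}

#' Locate the partition subinterval containing a scaled dose
#'
#' The unit interval is divided into \code{s} equal subintervals
#' \code{((j-1)/s, j/s]}; a scaled dose \code{x} belongs to the subinterval
#' with index \code{ceiling(x s)}.  Boundary doses \code{x = j/s} belong to
#' the lower subinterval under this half-open convention.
#'
#' @param x A scaled dose in \code{(0, 1]}.
#' @param s Number of subintervals (positive integer).
#' @return A list with elements \code{v0}, \code{v1} (endpoints, the interval
#'   is \code{(v0, v1]}) and \code{index}.
#' @examples
#' subinterval_of(0.2, 3)   # (0, 1/3]
#' subinterval_of(0.75, 3)  # (2/3, 1]
#' @export
subinterval_of <- function(x, s) {
  stopifnot(length(x) == 1L, length(s) == 1L, s >= 1, s == as.integer(s))
  if (!is.finite(x) || x <= 0 || x > 1) {
    stop(sprintf("scaled dose must lie in (0, 1], got %g", x))
  }
  j <- ceiling(x * s)
  list(v0 = (j - 1) / s, v1 = j / s, index = as.integer(j))
}

#' Construct a dose grid
#'
#' Bundles the candidate doses (original and scaled), the target toxicity
#' rate and the partition count used for local modelling.
#'
#' @param levels Original dose levels, strictly increasing.
#' @param alpha Target toxicity rate in \code{(0, 1)}.
#' @param s Number of subintervals of \code{(0, 1]} (default 3; small values
#'   such as 3 or 4 are recommended for up to 6 doses, 5 for 7 or more).
#' @param scaled Optional pre-scaled doses in \code{(0, 1]}; when supplied,
#'   \code{mode}/\code{offset}/\code{divisor} are ignored.
#' @param mode \code{"auto"} (default), \code{"linear"} or \code{"log"}.
#' @param offset,divisor Transformation constants; required unless
#'   \code{mode = "auto"} or \code{scaled} is given.
#' @return An object of class \code{"bsa_grid"}: a list with
#'   \code{original_levels}, \code{scaled_levels}, \code{K}, \code{s},
#'   \code{alpha} and the transformation used.
#' @examples
#' dose_grid(1:5, alpha = 0.3)
#' @export
dose_grid <- function(levels, alpha, s = 3L, scaled = NULL,
                      mode = c("auto", "linear", "log"),
                      offset = NULL, divisor = NULL) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(levels), length(levels) >= 1L,
            is.numeric(alpha), length(alpha) == 1L)
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must lie in (0, 1)")
  if (length(s) != 1L || s < 1 || s != as.integer(s)) {
    stop("'s' must be a positive integer")
  }
  if (any(diff(levels) <= 0)) stop("'levels' must be strictly increasing")
  trans <- NULL
  if (is.null(scaled)) {
    if (mode == "auto") {
      trans <- auto_scale(levels)
    } else {
      if (is.null(offset) || is.null(divisor)) {
        stop("supply 'offset' and 'divisor' (or use mode = \"auto\")")
      }
      trans <- list(mode = mode, offset = offset, divisor = divisor)
    }
    scaled <- scale_doses(levels, trans$mode, trans$offset, trans$divisor)
  } else {
    if (length(scaled) != length(levels)) {
      stop("'scaled' must match 'levels' in length")
    }
    if (any(scaled <= 0 | scaled > 1)) stop("scaled doses must lie in (0, 1]")
    if (any(diff(scaled) <= 0)) stop("scaled doses must be strictly increasing")
  }
  K <- length(levels)
  if (K <= 6L && s > 4L) {
    warning(sprintf(
      "s = %d is aggressive for K = %d doses; s = 3 is recommended for K <= 6",
      s, K))
  }
  structure(
    list(original_levels = as.numeric(levels),
         scaled_levels = as.numeric(scaled),
         K = K, s = as.integer(s), alpha = alpha, transform = trans),
    class = "bsa_grid")
}

#' @export
print.bsa_grid <- function(x, ...) {
  cat(sprintf("Dose grid: %d levels, target rate alpha = %g, s = %d subintervals\n",
              x$K, x$alpha, x$s))
  tab <- data.frame(dose = seq_len(x$K),
                    original = x$original_levels,
                    scaled = round(x$scaled_levels, 4))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Read or write a dose grid as CSV
#'
#' The file has columns \code{dose_label}, \code{original_level},
#' \code{scaled_level}; target rate and partition count are given as
#' arguments on reading.
#'
#' @param grid A \code{bsa_grid}.
#' @param path File path.
#' @param alpha,s Passed to [dose_grid()] on reading.
#' @return \code{read_dose_grid} returns a \code{bsa_grid};
#'   \code{write_dose_grid} returns \code{path} invisibly.
#' @export
write_dose_grid <- function(grid, path) {
  stopifnot(inherits(grid, "bsa_grid"))
  utils::write.csv(
    data.frame(dose_label = seq_len(grid$K),
               original_level = grid$original_levels,
               scaled_level = grid$scaled_levels),
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_dose_grid
#' @export
read_dose_grid <- function(path, alpha, s = 3L) {
  d <- utils::read.csv(path)
  need <- c("original_level", "scaled_level")
  if (!all(need %in% names(d))) {
    stop("dose grid file must have columns original_level, scaled_level")
  }
  d <- d[order(d$original_level), ]
  dose_grid(d$original_level, alpha = alpha, s = s, scaled = d$scaled_level)
}
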