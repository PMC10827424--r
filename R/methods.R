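#' Evaluate model trajectories at given times
#'
#' Closed-form spurious and corrective levels on an arbitrary time grid.  With
#' no \code{times} argument a default panel grid is used (see
#' [trajectory_panel()]).
#'
#' @param object a \code{goldrush} model.
#' @param times numeric vector of times in years; if \code{NULL}, a uniform
#'   grid over \code{[0, horizon]}.
#' @param horizon panel horizon in years; defaults to \eqn{1.2\,t_c} when
#'   self-correcting and 50 years otherwise.
#' @param ... unused.
#' @return A \code{data.frame} of class \code{"goldrush_trajectory"} with
#'   columns \code{time}, \code{x} (spurious level) and \code{y} (corrective
#'   level), carrying the parameter set and regime as attributes.
#' @examples
#' predict(goldrush(f_p = 0.05), times = 0:5)
#' @export
predict.goldrush <- function(object, times = NULL, horizon = NULL, ...) {
  if (is.null(times))
    return(trajectory_panel(object, horizon = horizon))
  new_trajectory(object, times,
                 x = spurious_level(object, times, horizon = Inf),
                 y = corrective_any(object, times))
}

new_trajectory <- function(object, times, x, y, dt = NULL, numeric = FALSE) {
  if (is.unsorted(times, strictly = TRUE))
    stop("times must be strictly increasing", call. = FALSE)
  structure(
    data.frame(time = times, x = as.numeric(x), y = as.numeric(y)),
    params = object$params, regime = object$regime, dt = dt,
    numeric = numeric,
    class = c("goldrush_trajectory", "data.frame")
  )
}

#' Finite-difference residuals of the closed forms against the model equations
#'
#' Checks that the closed-form trajectories actually solve the coupled system
#' by central-difference differentiation: reports
#' \eqn{x'(t) - (g x - d y)} and \eqn{y'(t) - e x}, scaled by the largest
#' right-hand-side magnitude on the grid so the residuals are relative.
#' Useful as a self-diagnostic; the values should be at the level of the
#' differentiation error (about \code{step^2}).
#'
#' @param object a self-correcting \code{goldrush} model.
#' @param times evaluation times; default 101 interior points of
#'   \eqn{(t_d, t_c)}.
#' @param step central-difference half-step in years.
#' @param ... unused.
#' @return A \code{data.frame} with columns \code{time}, \code{res_x},
#'   \code{res_y} (relative residuals).
#' @export
residuals.goldrush <- function(object, times = NULL, step = 1e-5, ...) {
  if (object$regime != "self_correcting")
    stop("residual diagnostics require the self-correcting regime",
         call. = FALSE)
  td <- object$params$t_d
  tc <- correction_time(object)
  if (is.null(times)) {
    eps <- (tc - td) * 1e-3
    times <- seq(td + eps, tc - eps, length.out = 101)
  }
  r <- object$rates
  xf <- function(t) spurious_level(object, t, horizon = Inf)
  yf <- function(t) corrective_any(object, t)
  dx <- (xf(times + step) - xf(times - step)) / (2 * step)
  dy <- (yf(times + step) - yf(times - step)) / (2 * step)
  rhs_x <- r$g * xf(times) - r$d * yf(times)
  rhs_y <- r$e * xf(times)
  sx <- max(abs(rhs_x))
  sy <- max(abs(rhs_y))
  data.frame(time = times,
             res_x = (dx - rhs_x) / sx,
             res_y = (dy - rhs_y) / sy)
}

#' @describeIn integrate_numeric \code{simulate} method: numerically
#'   integrates the model equations (deterministic; \code{nsim} and
#'   \code{seed} are accepted for generic compatibility and ignored).
#' @param nsim,seed ignored; the integration is deterministic.
#' @export
simulate.goldrush <- function(object, nsim = 1, seed = NULL, dt = 1e-3,
                              t_max = NULL, ...) {
  integrate_numeric(object, dt = dt, t_max = t_max)
}

#' Plot model trajectories
#'
#' Base-graphics panel of the spurious level \eqn{x(t)} (solid) and the
#' corrective level \eqn{y(t)} (dashed), with the corrective delay and, when
#' defined, the correction time marked.
#'
#' @param x a \code{goldrush} model.
#' @param horizon plot horizon in years (default as in [trajectory_panel()]).
#' @param ... passed to \code{matplot}.
#' @return The trajectory data frame, invisibly.
#' @export
plot.goldrush <- function(x, horizon = NULL, ...) {
  tr <- trajectory_panel(x, horizon = horizon)
  graphics::matplot(tr$time, cbind(tr$x, tr$y), type = "l", lty = c(1, 2),
                    col = c("firebrick", "steelblue"),
                    xlab = "time (years)", ylab = "publication level", ...)
  graphics::abline(v = x$params$t_d, lty = 3, col = "grey40")
  tc <- correction_time(x)
  if (!is.na(tc)) graphics::abline(v = tc, lty = 3, col = "grey40")
  graphics::legend("topright", c("spurious x(t)", "corrective y(t)"),
                   lty = c(1, 2), col = c("firebrick", "steelblue"),
                   bty = "n")
  invisible(tr)
}
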