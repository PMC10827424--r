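#' Fixed-step Runge-Kutta integration of the model equations
#'
#' Independent numerical solution of the coupled system
#' \eqn{x' = gx - dy}, \eqn{y' = ex}, used to cross-validate every closed
#' form.  The integration is classic fixed-step 4th-order Runge-Kutta in two
#' smooth segments: on \eqn{[0, t_d]} the corrective equation is suppressed
#' (\eqn{y \equiv 0}, \eqn{x' = gx}); from \eqn{t_d} the full coupled system
#' runs with initial state \eqn{(x(t_d), 0)}.  The step is adjusted within
#' each segment so that \eqn{t_d} and \eqn{t_{max}} fall exactly on grid
#' points.  Because the system has constant coefficients, the RK4 update is
#' linear in the state; each step is therefore applied as the precomputed
#' one-step matrix \eqn{I + \delta M + \ldots + \delta^4 M^4/24}, which is
#' algebraically identical to stepping classic RK4 and bit-reproducible.
#'
#' @param object a \code{goldrush} model.
#' @param dt nominal step size in years (> 0).
#' @param t_max integration horizon in years; defaults to \eqn{1.25\,t_c}
#'   when self-correcting and 50 years otherwise.
#' @param ... unused.
#' @return A \code{"goldrush_trajectory"} data frame (columns \code{time},
#'   \code{x}, \code{y}) on the integration grid, with attributes \code{dt},
#'   \code{numeric = TRUE}, the parameter set and the regime.
#' @examples
#' m <- goldrush(f_p = 0.05)
#' tr <- integrate_numeric(m, dt = 0.01)
#' max(abs(tr$x - spurious_level(m, tr$time)))
#' @seealso [find_tc_numeric()], [cumulative_integral()],
#'   [validate_closed_forms()]
#' @export
integrate_numeric <- function(object, dt = 1e-3, t_max = NULL, ...) {
  stopifnot(inherits(object, "goldrush"))
  if (!is.numeric(dt) || length(dt) != 1L || dt <= 0)
    stop("dt must be a single positive number", call. = FALSE)
  p <- object$params
  r <- object$rates
  if (is.null(t_max)) {
    tc <- correction_time(object)
    t_max <- if (is.na(tc)) 50 else 1.25 * tc
  }
  if (dt >= t_max) stop("dt must be smaller than t_max", call. = FALSE)
  td <- min(p$t_d, t_max)

  times <- 0
  xs <- p$x_o
  ys <- 0
  if (td > 0) {
    n1 <- max(1L, round(td / dt))
    h1 <- td / n1
    a <- r$g * h1
    step1 <- 1 + a + a^2 / 2 + a^3 / 6 + a^4 / 24  # RK4 one-step factor, x' = gx
    xs <- p$x_o * step1^(0:n1)
    ys <- numeric(n1 + 1)
    times <- seq(0, td, length.out = n1 + 1)
  }
  if (t_max > td) {
    n2 <- max(1L, ceiling((t_max - td) / dt))
    h2 <- (t_max - td) / n2
    M <- rbind(c(r$g, -r$d), c(r$e, 0))
    A <- diag(2) + h2 * M + h2^2 / 2 * M %*% M + h2^3 / 6 * M %*% M %*% M +
      h2^4 / 24 * M %*% M %*% M %*% M
    x2 <- numeric(n2)
    y2 <- numeric(n2)
    xc <- xs[length(xs)]
    yc <- 0
    a11 <- A[1, 1]; a12 <- A[1, 2]; a21 <- A[2, 1]; a22 <- A[2, 2]
    for (i in seq_len(n2)) {
      xn <- a11 * xc + a12 * yc
      yc <- a21 * xc + a22 * yc
      xc <- xn
      x2[i] <- xc
      y2[i] <- yc
    }
    times <- c(times, td + h2 * seq_len(n2))
    xs <- c(xs, x2)
    ys <- c(ys, y2)
  }
  new_trajectory(object, times, xs, ys, dt = dt, numeric = TRUE)
}

#' Numerical correction time from an integrated trajectory
#'
#' Locates the first sign change of the spurious level after the corrective
#' delay and refines the crossing by root-finding on a local spline
#' interpolant of the trajectory.  Returns \code{NA} (with the probed horizon
#' attached as attribute \code{"t_max"}) when the spurious level never crosses
#' zero before the end of the trajectory — a horizon-qualified statement, not
#' an error.
#'
#' @param trajectory a \code{"goldrush_trajectory"} from
#'   [integrate_numeric()].
#' @param tol root-refinement tolerance in years.
#' @return The numerical correction time in years, or \code{NA_real_}.
#' @examples
#' m <- goldrush(f_p = 0.05)
#' find_tc_numeric(integrate_numeric(m))
#' @export
find_tc_numeric <- function(trajectory, tol = 1e-9) {
  stopifnot(inherits(trajectory, "goldrush_trajectory"))
  td <- attr(trajectory, "params")$t_d
  tt <- trajectory$time
  xx <- trajectory$x
  post <- which(tt >= td)
  flip <- post[which(xx[post] > 0 & c(xx[post][-1] <= 0, FALSE))]
  if (length(flip) == 0L) {
    out <- NA_real_
    attr(out, "t_max") <- tt[length(tt)]
    return(out)
  }
  i <- flip[1L]
  w <- max(1L, i - 3L):min(length(tt), i + 4L)
  f <- stats::splinefun(tt[w], xx[w])
  stats::uniroot(f, lower = tt[i], upper = tt[i + 1L], tol = tol)$root
}

#' Cumulative trapezoidal integral of a trajectory series
#'
#' Trapezoid-rule running integral of the spurious (\code{"x"}) or corrective
#' (\code{"y"}) series, in publication-years — the numerical counterpart of
#' the research-waste and corrective-effort closed forms.
#'
#' @param trajectory a \code{"goldrush_trajectory"}.
#' @param which \code{"x"} or \code{"y"}.
#' @return Numeric vector of the same length as the grid: the integral from 0
#'   to each grid time.
#' @examples
#' m <- goldrush(f_p = 0.05)
#' tr <- integrate_numeric(m, dt = 0.01)
#' tail(cumulative_integral(tr, "x"), 1)
#' @export
cumulative_integral <- function(trajectory, which = c("x", "y")) {
  stopifnot(inherits(trajectory, "goldrush_trajectory"))
  which <- match.arg(which)
  as.numeric(pracma::cumtrapz(trajectory$time, trajectory[[which]]))
}

# Interpolate a cumulative series at an off-grid time.
integral_at <- function(trajectory, which, t) {
  ci <- cumulative_integral(trajectory, which)
  stats::approx(trajectory$time, ci, xout = t)$y
}

#' Random ecosystem parameter sets
#'
#' Draws parameter sets uniformly over realistic ranges (publication rates of
#' 1-5 per year, publication bias 0.6-0.99, false positive rates 0.01-0.2,
#' submitted fractions and corrective impacts 0.2-1, delays 0-2 years),
#' optionally keeping only self-correcting sets whose correction time does not
#' exceed \code{t_c_max} so that validation integrations stay affordable.
#'
#' @param n number of parameter sets.
#' @param self_correcting keep only self-correcting sets.
#' @param t_c_max when \code{self_correcting}, upper bound on the accepted
#'   correction time (years).
#' @return A list of \code{goldrush} models.
#' @examples
#' set.seed(1)
#' length(random_ecosystems(5))
#' @export
random_ecosystems <- function(n, self_correcting = TRUE, t_c_max = 12) {
  out <- vector("list", n)
  got <- 0L
  tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 1000L * n)
      stop("could not draw enough admissible parameter sets", call. = FALSE)
    m <- goldrush(f_p = stats::runif(1, 0.01, 0.2),
                  t_d = stats::runif(1, 0, 2),
                  p_r = stats::runif(1, 1, 5),
                  B = stats::runif(1, 0.6, 0.99),
                  s_r = stats::runif(1, 0.2, 1),
                  k = stats::runif(1, 0.2, 1))
    if (self_correcting) {
      tc <- correction_time(m)
      if (is.na(tc) || tc > t_c_max) next
    }
    got <- got + 1L
    out[[got]] <- m
  }
  out
}

#' Cross-validate the closed forms against the numerical oracle
#'
#' For a collection of random self-correcting parameter sets, integrates the
#' model equations with fixed-step RK4, recovers the correction time by
#' bracketed root-finding and the waste/effort integrals by trapezoidal
#' quadrature, and reports the relative discrepancies against the closed-form
#' values of [correction_time()], [research_waste()] and
#' [corrective_effort()].
#'
#' @param n number of random parameter sets.
#' @param dt integration step in years.
#' @param seed optional RNG seed for reproducible draws.
#' @param t_c_max passed to [random_ecosystems()].
#' @return A \code{data.frame} with one row per parameter set: the rate
#'   constants, delay, closed-form and numerical \code{t_c}, and relative
#'   errors \code{rel_tc}, \code{rel_rw}, \code{rel_ce}.
#' @examples
#' v <- validate_closed_forms(n = 3, dt = 0.005, seed = 1)
#' max(v$rel_tc, v$rel_rw, v$rel_ce)
#' @export
validate_closed_forms <- function(n = 25, dt = 1e-3, seed = NULL,
                                  t_c_max = 12) {
  if (!is.null(seed)) set.seed(seed)
  models <- random_ecosystems(n, self_correcting = TRUE, t_c_max = t_c_max)
  rows <- lapply(models, function(m) {
    tc <- correction_time(m)
    tr <- integrate_numeric(m, dt = dt, t_max = 1.25 * tc)
    tc_num <- find_tc_numeric(tr)
    rw <- research_waste(m, tc)
    ce <- corrective_effort(m, tc)
    rw_num <- integral_at(tr, "x", tc_num)
    ce_num <- integral_at(tr, "y", tc_num)
    data.frame(g = m$rates$g, e = m$rates$e, d = m$rates$d,
               t_d = m$params$t_d,
               t_c_closed = tc, t_c_numeric = tc_num,
               rel_tc = abs(tc_num - tc) / tc,
               rel_rw = abs(rw_num - rw) / rw,
               rel_ce = abs(ce_num - ce) / ce)
  })
  do.call(rbind, rows)
}
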