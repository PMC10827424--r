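#' Baseline scenario tables
#'
#' Evaluates the four reference scenarios of each publishing regime at the
#' baseline constants \eqn{p_r = 3} publications/year, \eqn{B = 0.95},
#' \eqn{s_r = 0.5}, \eqn{k = 0.6}, \eqn{x_o = 1}:
#' \describe{
#'   \item{biased}{the \eqn{(f_p, t_d)} pairs (0.05, 0), (0.05, 1),
#'     (0.20, 0), (0.20, 2) — low and high false positive rates with and
#'     without corrective delay.}
#'   \item{no_bias}{the pairs (0.05, 0), (0.05, 1), (0.50, 0), (0.50, 2)
#'     under the no-publication-bias mapping.}
#' }
#'
#' @param mode \code{"biased"} or \code{"no_bias"}.
#' @return A \code{data.frame} of class \code{"goldrush_table"} with columns
#'   \code{f_p}, \code{t_d}, \code{regime}, \code{t_c}, \code{r_w},
#'   \code{c_e}, \code{waste_ratio} (exact values; the print method applies
#'   display rounding: times/volumes to the nearest half unit, the ratio as a
#'   percentage to one decimal).
#' @examples
#' baseline_table("biased")
#' baseline_table("no_bias")
#' @export
baseline_table <- function(mode = c("biased", "no_bias")) {
  mode <- match.arg(mode)
  cells <- if (mode == "biased") {
    list(c(0.05, 0), c(0.05, 1), c(0.20, 0), c(0.20, 2))
  } else {
    list(c(0.05, 0), c(0.05, 1), c(0.50, 0), c(0.50, 2))
  }
  rows <- lapply(cells, function(cell) {
    m <- goldrush(f_p = cell[1], t_d = cell[2], bias_mode = mode)
    s <- summary(m)
    data.frame(f_p = cell[1], t_d = cell[2], regime = s$regime,
               t_c = s$t_c, r_w = s$r_w, c_e = s$c_e,
               waste_ratio = s$waste_ratio)
  })
  structure(do.call(rbind, rows), mode = mode,
            class = c("goldrush_table", "data.frame"))
}

#' @export
print.goldrush_table <- function(x, ...) {
  cat(sprintf("Baseline scenarios (%s mode)\n", attr(x, "mode")))
  disp <- data.frame(
    f_p = x$f_p, t_d = x$t_d,
    t_c = paste(fmt_half(x$t_c), "y"),
    r_w = fmt_volume(x$r_w), c_e = fmt_volume(x$c_e),
    waste_ratio = ifelse(is.na(x$waste_ratio), "-",
                         sprintf("%.1f%%", 100 * x$waste_ratio))
  )
  print.data.frame(disp, row.names = FALSE)
  invisible(x)
}

sweep_axes <- c("p_r", "B", "f_p", "s_r", "k", "t_d", "x_o")

#' Two-parameter sweep of correction outcomes
#'
#' Evaluates the model summary over a grid spanned by two ecosystem
#' parameters, all others held fixed — the basis of the correction-time and
#' log-research-waste contour surfaces, and of the regime-boundary maps in
#' which non-correcting cells appear masked (the "white areas" where no
#' corrective effect is possible through publication alone).
#'
#' @param axis1,axis2 names of two distinct model parameters (one of
#'   \code{"p_r"}, \code{"B"}, \code{"f_p"}, \code{"s_r"}, \code{"k"},
#'   \code{"t_d"}, \code{"x_o"}).
#' @param range1,range2 length-2 numeric ranges for the two axes (ignored
#'   when explicit \code{values1}/\code{values2} are given).
#' @param n number of grid points per axis (recycled to length 2); the
#'   default 101 gives contour-smooth surfaces in seconds.
#' @param values1,values2 optional explicit axis values.
#' @param fixed named list of the remaining parameters (defaults of
#'   [goldrush()] fill the rest).
#' @return An object of class \code{"goldrush_sweep"}: the two axes, matrices
#'   \code{t_c}, \code{r_w}, \code{c_e}, \code{waste_ratio} (rows follow
#'   \code{axis1}), a logical \code{mask} that is \code{TRUE} exactly where
#'   the regime is non-correcting, and the fixed parameters.
#' @examples
#' sg <- sweep_grid("f_p", "t_d", c(0.01, 0.25), c(0, 3), n = 11)
#' sum(sg$mask)
#' @seealso [as.data.frame.goldrush_sweep()], [plot.goldrush_sweep()]
#' @export
sweep_grid <- function(axis1, axis2, range1 = NULL, range2 = NULL, n = 101,
                       values1 = NULL, values2 = NULL, fixed = list()) {
  for (ax in c(axis1, axis2))
    if (!ax %in% sweep_axes)
      stop("unknown sweep parameter '", ax, "'; must be one of ",
           paste(sweep_axes, collapse = ", "), call. = FALSE)
  if (axis1 == axis2)
    stop("axis parameters must be distinct", call. = FALSE)
  if (any(c(axis1, axis2) %in% names(fixed)))
    stop("swept parameters cannot also appear in 'fixed'", call. = FALSE)
  n <- rep_len(n, 2L)
  if (is.null(values1)) values1 <- seq(range1[1], range1[2], length.out = n[1])
  if (is.null(values2)) values2 <- seq(range2[1], range2[2], length.out = n[2])
  dims <- c(length(values1), length(values2))
  t_c <- r_w <- c_e <- ratio <- matrix(NA_real_, dims[1], dims[2])
  mask <- matrix(FALSE, dims[1], dims[2])
  for (i in seq_along(values1)) {
    for (j in seq_along(values2)) {
      args <- fixed
      args[[axis1]] <- values1[i]
      args[[axis2]] <- values2[j]
      s <- summary(do.call(goldrush, args))
      if (s$regime == "non_correcting") {
        mask[i, j] <- TRUE
      } else {
        t_c[i, j] <- s$t_c
        r_w[i, j] <- s$r_w
        c_e[i, j] <- s$c_e
        ratio[i, j] <- s$waste_ratio
      }
    }
  }
  structure(
    list(axis1 = list(name = axis1, values = values1),
         axis2 = list(name = axis2, values = values2),
         t_c = t_c, r_w = r_w, c_e = c_e, waste_ratio = ratio,
         mask = mask, fixed = fixed),
    class = "goldrush_sweep"
  )
}

#' @export
print.goldrush_sweep <- function(x, ...) {
  cat(sprintf("Parameter sweep: %s (%d values) x %s (%d values)\n",
              x$axis1$name, length(x$axis1$values),
              x$axis2$name, length(x$axis2$values)))
  cat(sprintf("  non-correcting cells: %d of %d\n",
              sum(x$mask), length(x$mask)))
  invisible(x)
}

#' Long-format view of a sweep grid
#'
#' @param x a \code{"goldrush_sweep"}.
#' @param ... unused.
#' @return A \code{data.frame} with columns \code{axis1_name},
#'   \code{axis1_value}, \code{axis2_name}, \code{axis2_value},
#'   \code{regime}, \code{t_c}, \code{r_w}, \code{c_e}, \code{waste_ratio}
#'   and \code{log10_r_w} (research waste floored at 1e-12 before taking the
#'   log, so near-zero-waste corners stay finite).
#' @export
as.data.frame.goldrush_sweep <- function(x, ...) {
  grid <- expand.grid(i = seq_along(x$axis1$values),
                      j = seq_along(x$axis2$values))
  idx <- cbind(grid$i, grid$j)
  data.frame(
    axis1_name = x$axis1$name, axis1_value = x$axis1$values[grid$i],
    axis2_name = x$axis2$name, axis2_value = x$axis2$values[grid$j],
    regime = ifelse(x$mask[idx], "non_correcting", "self_correcting"),
    t_c = x$t_c[idx], r_w = x$r_w[idx], c_e = x$c_e[idx],
    waste_ratio = x$waste_ratio[idx],
    log10_r_w = log10(pmax(x$r_w[idx], 1e-12))
  )
}

#' Contour plot of a sweep surface
#'
#' Filled-contour rendering of one summary surface over the sweep grid;
#' non-correcting cells are left blank (white), marking the region where no
#' correction through publication alone is possible.
#'
#' @param x a \code{"goldrush_sweep"}.
#' @param what surface to draw: correction time, log10 research waste,
#'   research waste, corrective effort or waste ratio.
#' @param ... passed to \code{filled.contour}.
#' @return \code{x}, invisibly.
#' @export
plot.goldrush_sweep <- function(x, what = c("t_c", "log10_r_w", "r_w",
                                            "c_e", "waste_ratio"), ...) {
  what <- match.arg(what)
  z <- if (what == "log10_r_w") log10(pmax(x$r_w, 1e-12)) else x[[what]]
  graphics::filled.contour(x$axis1$values, x$axis2$values, z,
                           xlab = x$axis1$name, ylab = x$axis2$name,
                           main = what, ...)
  invisible(x)
}

#' Trajectory panel for one scenario
#'
#' Samples the closed-form spurious and corrective levels on a uniform grid
#' for plotting or export.  The default horizon is \eqn{1.2\,t_c} for
#' self-correcting scenarios (so the full correction episode plus a margin is
#' shown) and 50 years otherwise; non-correcting panels use the analytic
#' hyperbolic continuation for both compartments.
#'
#' @param object a \code{goldrush} model.
#' @param horizon panel horizon in years.
#' @param n number of grid points.
#' @return A \code{"goldrush_trajectory"} data frame.
#' @examples
#' tr <- trajectory_panel(goldrush(f_p = 0.05))
#' range(tr$time)
#' @export
trajectory_panel <- function(object, horizon = NULL, n = 501) {
  stopifnot(inherits(object, "goldrush"))
  if (is.null(horizon)) {
    tc <- correction_time(object)
    horizon <- if (is.na(tc)) 50 else 1.2 * tc
  }
  times <- seq(0, horizon, length.out = n)
  new_trajectory(object, times,
                 x = spurious_level(object, times, horizon = Inf),
                 y = corrective_any(object, times))
}
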