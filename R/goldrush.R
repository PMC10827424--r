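#' Construct a publishing-ecosystem model
#'
#' Sets up the 'gold rush' model of spurious and corrective publication.  An
#' initial spurious (false-positive) finding at level \code{x_o} seeds
#' follow-on spurious publications at rate \code{g}, while corrective null
#' results emerge at rate \code{e} (after a delay \code{t_d}) and suppress the
#' spurious literature with impact rate \code{d}:
#' \deqn{x'(t) = g\,x(t) - d\,y(t), \qquad y'(t) = e\,x(t),}
#' with \eqn{y(t) = 0} for \eqn{t \le t_d} and \eqn{x(0) = x_o}.
#'
#' The rate constants are derived from ecosystem parameters.  In the standard
#' (biased) mapping \eqn{g = p_r B f_p}, \eqn{e = p_r (1-B)(1-f_p) s_r} and
#' \eqn{d = k p_r}.  In the hypothetical no-publication-bias mapping
#' (\code{bias_mode = "no_bias"}) all results are submitted and valued equally,
#' so \eqn{s_r = k = 1}, \eqn{g = p_r f_p} and \eqn{e = p_r (1-f_p)} with
#' \eqn{d = p_r}; \code{B} plays no role.
#'
#' The system is \emph{self-correcting} when the discriminant
#' \eqn{\Delta = 4de - g^2} is strictly positive: the spurious level then
#' follows a damped oscillation and reaches zero at a finite correction time
#' \eqn{t_c}.  When \eqn{g^2 \ge 4de} the spurious literature grows without a
#' zero crossing and no correction through publication alone is possible.
#'
#' @param f_p false positive rate: the fraction of true nulls reported as
#'   positive findings, in \[0, 1\].
#' @param t_d corrective delay in years (\eqn{\ge 0}): the lag before
#'   corrective efforts begin.
#' @param p_r publication rate of the field (publications per year, > 0).
#' @param B publication bias: the fraction of positive findings that are
#'   published, in \[0, 1\].  Ignored in no-bias mode.
#' @param s_r submitted fraction of null results, in \[0, 1\] (the file-drawer
#'   problem).  Fixed at 1 in no-bias mode.
#' @param k corrective impact of a null publication relative to a positive one
#'   (\eqn{\ge 0}).  Fixed at 1 in no-bias mode.
#' @param x_o initial spurious publication level (> 0).
#' @param bias_mode \code{"biased"} for the standard mapping or
#'   \code{"no_bias"} for the hypothetical ecosystem without publication bias.
#'
#' @return An object of class \code{"goldrush"}: a list with components
#'   \code{params} (the validated ecosystem parameters), \code{rates} (the
#'   derived rate constants \code{g}, \code{e}, \code{d}, the discriminant
#'   \eqn{\Delta = 4de - g^2} and the oscillation rate
#'   \eqn{h = \sqrt{\Delta}}, \code{NA} when \eqn{\Delta \le 0}) and
#'   \code{regime} (\code{"self_correcting"} or \code{"non_correcting"}).
#'
#' @examples
#' m <- goldrush(f_p = 0.05, t_d = 0)
#' m
#' correction_time(m)
#' summary(m)
#' @seealso [summary.goldrush()], [correction_time()], [spurious_level()],
#'   [trajectory_panel()], [integrate_numeric()]
#' @export
goldrush <- function(f_p, t_d = 0, p_r = 3, B = 0.95, s_r = 0.5, k = 0.6,
                     x_o = 1, bias_mode = c("biased", "no_bias")) {
  bias_mode <- match.arg(bias_mode)
  if (bias_mode == "no_bias") {
    # no incentive asymmetry: every result is submitted and valued equally
    if (!missing(s_r) && !isTRUE(all.equal(s_r, 1)))
      stop("s_r is fixed at 1 in no-bias mode (got ", s_r, ")", call. = FALSE)
    if (!missing(k) && !isTRUE(all.equal(k, 1)))
      stop("k is fixed at 1 in no-bias mode (got ", k, ")", call. = FALSE)
    s_r <- 1
    k <- 1
  }
  params <- list(p_r = p_r, B = B, f_p = f_p, s_r = s_r, k = k,
                 t_d = t_d, x_o = x_o, bias_mode = bias_mode)
  validate_params(params)
  rates <- derive_rates(params)
  structure(
    list(params = params, rates = rates, regime = classify_regime(rates)),
    class = "goldrush"
  )
}

validate_params <- function(p) {
  chk_num <- function(name) {
    v <- p[[name]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop(name, " must be a single finite number", call. = FALSE)
    v
  }
  for (nm in c("f_p", "B", "s_r"))
    if (chk_num(nm) < 0 || p[[nm]] > 1)
      stop(nm, " must be in [0, 1] (got ", p[[nm]], ")", call. = FALSE)
  if (chk_num("p_r") <= 0)
    stop("p_r must be > 0 (got ", p$p_r, ")", call. = FALSE)
  if (chk_num("k") < 0)
    stop("k must be >= 0 (got ", p$k, ")", call. = FALSE)
  if (chk_num("t_d") < 0)
    stop("t_d must be >= 0 (got ", p$t_d, ")", call. = FALSE)
  if (chk_num("x_o") <= 0)
    stop("x_o must be > 0 (got ", p$x_o, ")", call. = FALSE)
  invisible(p)
}

#' Derived rate constants of the publication system
#'
#' Maps ecosystem parameters to the rate constants of the coupled system:
#' the spurious growth rate \code{g}, the corrective emergence rate \code{e},
#' the corrective impact rate \code{d}, the discriminant
#' \eqn{\Delta = 4de - g^2} and, when \eqn{\Delta > 0}, the oscillation rate
#' \eqn{h = \sqrt{4de - g^2}}.
#'
#' @param object a \code{goldrush} model.
#' @return A list with components \code{g}, \code{e}, \code{d} (per year),
#'   \code{discriminant} (per year squared) and \code{h} (per year, \code{NA}
#'   when \eqn{\Delta \le 0}).
#' @examples
#' rate_constants(goldrush(f_p = 0.05))
#' @export
rate_constants <- function(object) {
  stopifnot(inherits(object, "goldrush"))
  object$rates
}

derive_rates <- function(p) {
  if (p$bias_mode == "no_bias") {
    g <- p$p_r * p$f_p
    e <- p$p_r * (1 - p$f_p)
    d <- p$p_r
  } else {
    g <- p$p_r * p$B * p$f_p
    e <- p$p_r * (1 - p$B) * (1 - p$f_p) * p$s_r
    d <- p$k * p$p_r
  }
  disc <- 4 * d * e - g^2
  list(g = g, e = e, d = d, discriminant = disc,
       h = if (disc > 0) sqrt(disc) else NA_real_)
}

classify_regime <- function(rates) {
  if (rates$discriminant > 0) "self_correcting" else "non_correcting"
}

#' Self-correction regime of a model
#'
#' A parameter set is self-correcting when \eqn{4de > g^2} strictly; on the
#' critical boundary \eqn{4de = g^2} the spurious level never reaches zero, so
#' the boundary is classified non-correcting.
#'
#' @param object a \code{goldrush} model.
#' @return \code{"self_correcting"} or \code{"non_correcting"}.
#' @examples
#' regime(goldrush(f_p = 0.20))  # self-correcting at the baseline constants
#' regime(goldrush(f_p = 0.25))  # not correctable by publication alone
#' @export
regime <- function(object) {
  stopifnot(inherits(object, "goldrush"))
  object$regime
}

#' @export
print.goldrush <- function(x, ...) {
  p <- x$params
  r <- x$rates
  cat("Publishing-ecosystem ('gold rush') model\n")
  cat(sprintf("  mode: %s\n", p$bias_mode))
  cat(sprintf("  p_r = %g /y, B = %g, f_p = %g, s_r = %g, k = %g, t_d = %g y, x_o = %g\n",
              p$p_r, p$B, p$f_p, p$s_r, p$k, p$t_d, p$x_o))
  cat(sprintf("  rates: g = %.6g, e = %.6g, d = %.6g /y; 4de - g^2 = %.6g\n",
              r$g, r$e, r$d, r$discriminant))
  cat(sprintf("  regime: %s\n", x$regime))
  if (x$regime == "self_correcting")
    cat(sprintf("  correction time t_c = %.4g years\n", correction_time(x)))
  invisible(x)
}

#' @describeIn rate_constants \code{coef} method returning the named vector
#'   \code{c(g, e, d)}.
#' @param ... unused.
#' @export
coef.goldrush <- function(object, ...) {
  unlist(object$rates[c("g", "e", "d")])
}
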