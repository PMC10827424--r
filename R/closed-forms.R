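#' Closed-form spurious publication level x(t)
#'
#' Evaluates the closed-form solution of the spurious compartment.  Before the
#' corrective delay the spurious literature grows exponentially,
#' \eqn{x(t) = x_o e^{gt}}; afterwards, in the self-correcting regime, it
#' follows the damped oscillation
#' \deqn{x(t) = x_o e^{g t_d}\left(\cos\frac{h\tau}{2} +
#'   \frac{g}{h}\sin\frac{h\tau}{2}\right) e^{g\tau/2}, \quad \tau = t - t_d,}
#' with \eqn{h = \sqrt{4de - g^2}}.  In the non-correcting regime
#' (\eqn{4de \le g^2}) the trigonometric factors continue analytically to
#' hyperbolic ones and \eqn{x} grows without a zero crossing; values beyond
#' \code{horizon} are then capped at the horizon value and flagged via the
#' \code{"capped"} attribute, since the exponential growth quickly overflows
#' and the model is not meaningful at such magnitudes anyway.
#'
#' @param object a \code{goldrush} model.
#' @param t time(s) in years, \eqn{\ge 0}; vectorised.
#' @param horizon cap horizon in years for the non-correcting regime.
#' @return Numeric vector of publication levels.  In the non-correcting regime
#'   the result carries a logical attribute \code{"capped"} marking entries
#'   evaluated at the cap horizon instead of the requested time.
#' @examples
#' m <- goldrush(f_p = 0.05)
#' spurious_level(m, c(0, 1, 5))
#' @export
spurious_level <- function(object, t, horizon = 50) {
  stopifnot(inherits(object, "goldrush"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- object$params
  r <- object$rates
  g <- r$g
  td <- p$t_d
  capped <- logical(length(t))
  if (object$regime == "non_correcting" && any(t > horizon)) {
    capped <- t > horizon
    t <- pmin(t, horizon)
  }
  out <- numeric(length(t))
  pre <- t < td
  out[pre] <- p$x_o * exp(g * t[pre])
  tau <- t[!pre] - td
  D <- r$discriminant
  if (D > 0) {
    h <- r$h
    out[!pre] <- p$x_o * exp(g * td) *
      (cos(h * tau / 2) + (g / h) * sin(h * tau / 2)) * exp(g * tau / 2)
  } else if (D == 0) {
    out[!pre] <- p$x_o * exp(g * td) * (1 + g * tau / 2) * exp(g * tau / 2)
  } else {
    # hyperbolic continuation, in log space to survive long horizons:
    # x = x_o e^{g td} e^{g tau/2} [ (1 + g/h') e^{a} + (1 - g/h') e^{-a} ] / 2,
    # a = h' tau / 2, h' = sqrt(g^2 - 4de); note g >= h' so both bracket terms
    # combine to a positive quantity.
    hp <- sqrt(-D)
    a <- hp * tau / 2
    logx <- log(p$x_o) + g * td + g * tau / 2 + a +
      log((1 + g / hp) + (1 - g / hp) * exp(-2 * a)) - log(2)
    out[!pre] <- exp(logx)
  }
  if (any(capped)) attr(out, "capped") <- capped
  out
}

#' Closed-form corrective publication level y(t)
#'
#' The corrective compartment is zero up to the delay \eqn{t_d} and then,
#' in the self-correcting regime, follows
#' \deqn{y(t) = \frac{2 x_o}{h} e^{g t_d}\, e\, \sin\!\frac{h\tau}{2}\,
#'   e^{g\tau/2}, \quad \tau = t - t_d.}
#' It is strictly increasing on \eqn{(t_d, t_c)} because \eqn{y' = e\,x > 0}
#' there.  Calling this in the non-correcting regime is an error: the
#' oscillation rate \eqn{h} is not real.
#'
#' @inheritParams spurious_level
#' @return Numeric vector of corrective publication levels.
#' @examples
#' m <- goldrush(f_p = 0.05)
#' corrective_level(m, c(0, 1, 5))
#' @export
corrective_level <- function(object, t) {
  stopifnot(inherits(object, "goldrush"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (object$regime != "self_correcting")
    stop("corrective level is only defined in the self-correcting regime ",
         "(4de - g^2 = ", format(object$rates$discriminant), " <= 0)",
         call. = FALSE)
  corrective_any(object, t)
}

# y(t) for any regime: trig (Delta > 0), linear-in-tau limit (Delta == 0) or
# hyperbolic (Delta < 0) branch.  Internal; used by trajectory panels so that
# non-correcting scenarios can still be rendered.
corrective_any <- function(object, t) {
  p <- object$params
  r <- object$rates
  g <- r$g
  td <- p$t_d
  out <- numeric(length(t))
  post <- t > td
  tau <- t[post] - td
  D <- r$discriminant
  pref <- 2 * p$x_o * r$e * exp(g * td)
  if (D > 0) {
    out[post] <- pref / r$h * sin(r$h * tau / 2) * exp(g * tau / 2)
  } else if (D == 0) {
    out[post] <- p$x_o * r$e * exp(g * td) * tau * exp(g * tau / 2)
  } else {
    hp <- sqrt(-D)
    out[post] <- pref / hp * sinh(hp * tau / 2) * exp(g * tau / 2)
  }
  out
}

#' Correction time t_c
#'
#' The first time after the corrective delay at which the spurious level
#' reaches zero.  In the self-correcting regime this is the first positive
#' zero of the oscillatory factor of \eqn{x(t)}:
#' \deqn{t_c = t_d + \frac{2\left(\pi - \arctan(h/g)\right)}{h}}
#' (reducing to \eqn{t_d + \pi/h} when \eqn{g = 0}).  In the non-correcting
#' regime no such time exists and \code{NA} is returned — absence is a value,
#' not an error.
#'
#' @param object a \code{goldrush} model.
#' @return Correction time in years, or \code{NA_real_} when non-correcting.
#' @examples
#' correction_time(goldrush(f_p = 0.05, t_d = 0))  # ~5.05 years
#' correction_time(goldrush(f_p = 0.25))           # NA: not self-correcting
#' @export
correction_time <- function(object) {
  stopifnot(inherits(object, "goldrush"))
  if (object$regime != "self_correcting") return(NA_real_)
  g <- object$rates$g
  h <- object$rates$h
  if (g == 0) object$params$t_d + pi / h
  else object$params$t_d + 2 * (pi - atan(h / g)) / h
}

#' Research waste r_w(t)
#'
#' The cumulative spurious output \eqn{r_w(t) = \int_0^t x(s)\,ds} in
#' publication-years.  Before the delay this is the plain exponential integral
#' \eqn{x_o (e^{gt} - 1)/g} (with the \eqn{g \to 0} limit \eqn{x_o t}); from
#' \eqn{t_d} onwards the closed form
#' \deqn{r_w(t) = x_o\left(\frac{e^{g t_d} - 1}{g} +
#'   \frac{2\, e^{g(t + t_d)/2} \sin\left(h (t - t_d)/2\right)}{h}\right)}
#' applies, which requires the self-correcting regime (real \eqn{h}).
#' Evaluated at \eqn{t_c} it gives the total research waste of the episode.
#'
#' @inheritParams spurious_level
#' @return Numeric vector, publication-years.
#' @examples
#' m <- goldrush(f_p = 0.20, t_d = 0)
#' research_waste(m, correction_time(m))  # ~292 publication-years
#' @export
research_waste <- function(object, t) {
  stopifnot(inherits(object, "goldrush"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  p <- object$params
  r <- object$rates
  g <- r$g
  td <- p$t_d
  out <- numeric(length(t))
  pre <- t < td
  out[pre] <- if (g == 0) p$x_o * t[pre] else p$x_o * (exp(g * t[pre]) - 1) / g
  if (any(!pre)) {
    if (object$regime != "self_correcting")
      stop("research waste beyond t_d requires the self-correcting regime; ",
           "integrate numerically instead (see integrate_numeric)",
           call. = FALSE)
    h <- r$h
    tpost <- t[!pre]
    base <- if (g == 0) td else (exp(g * td) - 1) / g
    out[!pre] <- p$x_o *
      (base + 2 * exp(g * (tpost + td) / 2) * sin(h * (tpost - td) / 2) / h)
  }
  out
}

#' Corrective effort c_e(t)
#'
#' The cumulative corrective output \eqn{c_e(t) = \int_0^t y(s)\,ds} in
#' publication-years: zero up to \eqn{t_d}, and for \eqn{t > t_d}
#' \deqn{c_e(t) = \frac{4 e x_o}{h (g^2 + h^2)}\left(h e^{g t_d} +
#'   e^{g(t+t_d)/2}\left(g \sin\frac{h\tau}{2} - h \cos\frac{h\tau}{2}\right)
#'   \right), \quad \tau = t - t_d.}
#' Evaluated at \eqn{t_c} it gives the total corrective effort needed to
#' nullify the spurious finding.  Defined only in the self-correcting regime.
#'
#' @inheritParams spurious_level
#' @return Numeric vector, publication-years.
#' @examples
#' m <- goldrush(f_p = 0.20, t_d = 0)
#' corrective_effort(m, correction_time(m))  # ~93 publication-years
#' @export
corrective_effort <- function(object, t) {
  stopifnot(inherits(object, "goldrush"))
  if (any(t < 0)) stop("t must be >= 0", call. = FALSE)
  if (object$regime != "self_correcting")
    stop("corrective effort is only defined in the self-correcting regime",
         call. = FALSE)
  p <- object$params
  r <- object$rates
  g <- r$g
  h <- r$h
  td <- p$t_d
  out <- numeric(length(t))
  post <- t > td
  tau <- t[post] - td
  out[post] <- 4 * r$e * p$x_o / (h * (g^2 + h^2)) *
    (h * exp(g * td) +
       exp(g * (t[post] + td) / 2) *
         (g * sin(h * tau / 2) - h * cos(h * tau / 2)))
  out
}

#' Critical false positive rate without publication bias
#'
#' In the no-bias mapping (\eqn{g = p_r f_p}, \eqn{e = p_r(1 - f_p)},
#' \eqn{d = p_r}) the self-correction condition \eqn{4de - g^2 > 0} reduces to
#' \eqn{f_p^2 + 4 f_p - 4 < 0}, independent of \eqn{p_r}.  Its positive root
#' \eqn{2(\sqrt 2 - 1) \approx 0.828} is therefore the critical false positive
#' rate: an unbiased publication ecosystem remains self-correcting up to an
#' 82\% false positive rate.
#'
#' @return The critical false positive rate, \eqn{2(\sqrt{2} - 1)}.
#' @examples
#' critical_fp_no_bias()
#' @export
critical_fp_no_bias <- function() {
  2 * (sqrt(2) - 1)
}

#' Summarise a model: regime, correction time, waste and effort
#'
#' Composes the headline quantities of one parameter set: the regime, the
#' correction time \eqn{t_c}, the research waste \eqn{r_w = r_w(t_c)}, the
#' corrective effort \eqn{c_e = c_e(t_c)}, and the waste ratio
#' \eqn{r_w / (r_w + c_e)} — the fraction of all output up to correction that
#' was wasted.  In the non-correcting regime only the regime is reported; the
#' other fields are \code{NA}.
#'
#' @param object a \code{goldrush} model.
#' @param ... unused.
#' @return A list of class \code{"summary.goldrush"} with components
#'   \code{regime}, \code{t_c}, \code{r_w}, \code{c_e}, \code{waste_ratio}
#'   (a fraction in (0, 1)), \code{params} and \code{rates}.
#' @examples
#' summary(goldrush(f_p = 0.05, t_d = 0))
#' @export
summary.goldrush <- function(object, ...) {
  tc <- correction_time(object)
  if (is.na(tc)) {
    out <- list(regime = object$regime, t_c = NA_real_, r_w = NA_real_,
                c_e = NA_real_, waste_ratio = NA_real_)
  } else {
    rw <- research_waste(object, tc)
    ce <- corrective_effort(object, tc)
    out <- list(regime = object$regime, t_c = tc, r_w = rw, c_e = ce,
                waste_ratio = rw / (rw + ce))
  }
  out$params <- object$params
  out$rates <- object$rates
  class(out) <- "summary.goldrush"
  out
}

# Display rounding used for the scenario tables.  Times go to the nearest
# half year (5.046 -> "5", 0.546 -> "0.5").  Publication volumes go to the
# nearest half below 2 and the nearest integer above (1.49 -> "1.5",
# 5.69 -> "6"), matching how sub-unity and large volumes are quoted.
round_half <- function(x) round(x * 2) / 2

round_volume <- function(x) ifelse(x < 2, round_half(x), round(x))

fmt_round <- function(r) {
  ifelse(is.na(r), "-", ifelse(r == round(r), format(round(r)),
                               format(r)))
}

fmt_half <- function(x) fmt_round(round_half(x))

fmt_volume <- function(x) fmt_round(round_volume(x))

#' @export
print.summary.goldrush <- function(x, ...) {
  p <- x$params
  cat(sprintf("Model summary (%s mode; f_p = %g, t_d = %g y)\n",
              p$bias_mode, p$f_p, p$t_d))
  cat(sprintf("  regime       : %s\n", x$regime))
  if (x$regime == "self_correcting") {
    cat(sprintf("  t_c          : %.4f years   (~ %s y)\n", x$t_c,
                fmt_half(x$t_c)))
    cat(sprintf("  r_w          : %.4f publication-years (~ %s)\n", x$r_w,
                fmt_volume(x$r_w)))
    cat(sprintf("  c_e          : %.4f publication-years (~ %s)\n", x$c_e,
                fmt_volume(x$c_e)))
    cat(sprintf("  waste ratio  : %.1f%%\n", 100 * x$waste_ratio))
  } else {
    cat("  spurious publication cannot be nullified by corrective",
        "publication alone (g^2 >= 4de)\n")
  }
  invisible(x)
}
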