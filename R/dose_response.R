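# Four-parameter logistic dose-response fitting and potency comparison.
#
# Model: viability(d) = bottom + (top - bottom) / (1 + (d/ec50)^hill),
# decreasing in dose for hill > 0. Internally parameterized as
# (bottom, span = top - bottom >= 0, log(ec50), hill > 0) so that
# top >= bottom and ec50 > 0 hold by construction.

.predict_4pl <- function(d, bottom, top, ec50, hill) {
  bottom + (top - bottom) / (1 + (d / ec50)^hill)
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `v(d) = bottom + (top - bottom)/(1 + (d/ec50)^hill)`
#' by Levenberg-Marquardt with box constraints (span >= 0, hill > 0,
#' ec50 optimized on the log scale). Initialization: top = max response,
#' bottom = min response, ec50 = geometric-mean dose, hill = 1; one
#' restart from a perturbed start if the first attempt fails.
#'
#' @param doses Dose vector (µM, > 0); at least 4 distinct values.
#' @param viability Response vector (% viability), same length.
#' @param constrain Optional named list fixing `bottom` and/or `top`
#'   (e.g. `list(bottom = 0, top = 100)`); unconstrained by default.
#' @return A `dose_response_fit` with elements `bottom`, `top`, `hill`,
#'   `ec50`, `rss`, `converged`, `degenerate`, `n_points`. `ec50` is the
#'   curve midpoint (the ED50 in screen parlance).
#' @export
fit_4pl <- function(doses, viability, constrain = NULL) {
  stopifnot(length(doses) == length(viability))
  if (any(doses <= 0) || any(!is.finite(doses))) {
    stop("doses must be finite and > 0", call. = FALSE)
  }
  if (any(!is.finite(viability))) {
    stop("non-finite responses", call. = FALSE)
  }
  if (length(unique(doses)) < 4) {
    stop("need at least 4 distinct doses", call. = FALSE)
  }
  unfit <- function(degenerate) {
    structure(list(bottom = NA_real_, top = NA_real_, hill = NA_real_,
                   ec50 = NA_real_, rss = NA_real_, converged = FALSE,
                   degenerate = degenerate, n_points = length(doses)),
              class = "dose_response_fit")
  }
  if (stats::sd(viability) < 1e-9) return(unfit(degenerate = TRUE))

  fix_bottom <- constrain$bottom
  fix_top <- constrain$top
  free_b <- is.null(fix_bottom)
  free_t <- is.null(fix_top)
  b0 <- if (free_b) min(viability) else fix_bottom
  t0 <- if (free_t) max(viability) else fix_top

  # parameter vector layout: [bottom if free, span if free, lec50, hill]
  unpack <- function(p) {
    i <- 1L
    bottom <- if (free_b) { i <- i + 1L; p[i - 1L] } else fix_bottom
    span <- if (free_t) { i <- i + 1L; p[i - 1L] } else fix_top - bottom
    list(bottom = bottom, span = span, ec50 = exp(p[i]), hill = p[i + 1L])
  }
  residual_fn <- function(p) {
    q <- unpack(p)
    viability - .predict_4pl(doses, q$bottom, q$bottom + q$span,
                             q$ec50, q$hill)
  }
  # analytic Jacobian of the residuals (finite differences misbehave when
  # the log-ec50 start sits numerically at 0 on a symmetric dose grid)
  jacobian_fn <- function(p) {
    q <- unpack(p)
    t <- (doses / q$ec50)^q$hill
    w <- 1 / (1 + t)
    d_lec50 <- q$span * q$hill * t * w^2
    d_hill <- -q$span * t * (log(doses) - log(q$ec50)) * w^2
    d_bottom <- if (free_t) rep(1, length(doses)) else 1 - w
    -cbind(if (free_b) d_bottom, if (free_t) w, d_lec50, d_hill)
  }

  attempt <- function(lec50_0, hill_0) {
    start <- c(if (free_b) b0,
               if (free_t) max(t0 - b0, 1e-3),
               lec50_0, hill_0)
    lower <- c(if (free_b) -Inf, if (free_t) 0, -Inf, 1e-6)
    out <- tryCatch(
      suppressWarnings(
        minpack.lm::nls.lm(par = start, lower = lower, fn = residual_fn,
                           jac = jacobian_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200))),
      error = function(e) NULL)
    if (is.null(out) || !out$info %in% 1:4) NULL else out
  }

  fit <- attempt(mean(log(doses)), 1)
  if (is.null(fit)) fit <- attempt(mean(log(doses)) + 1, 1.5)
  if (is.null(fit)) return(unfit(degenerate = FALSE))

  q <- unpack(fit$par)
  degenerate <- q$span < 1e-6
  structure(list(bottom = q$bottom, top = q$bottom + q$span,
                 hill = q$hill, ec50 = q$ec50,
                 rss = sum(residual_fn(fit$par)^2),
                 converged = !degenerate, degenerate = degenerate,
                 n_points = length(doses)),
            class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  if (!x$converged) {
    cat("dose_response_fit: not converged",
        if (x$degenerate) "(degenerate response)", "\n")
  } else {
    cat(sprintf(
      "dose_response_fit: bottom %.3g, top %.3g, hill %.3g, ec50 %.4g uM (rss %.3g, n = %d)\n",
      x$bottom, x$top, x$hill, x$ec50, x$rss, x$n_points))
  }
  invisible(x)
}

#' Predict viability from a fitted curve
#' @param fit A converged `dose_response_fit`.
#' @param doses Doses (µM).
#' @return Predicted % viability.
#' @export
predict_4pl <- function(fit, doses) {
  stopifnot(inherits(fit, "dose_response_fit"), fit$converged)
  .predict_4pl(doses, fit$bottom, fit$top, fit$ec50, fit$hill)
}

#' Absolute IC50: the dose where the fitted curve crosses 50% viability
#'
#' Distinct from the curve midpoint `ec50` unless (bottom, top) =
#' (0, 100). Undefined (returned as `NA` with a warning) when the fitted
#' curve never crosses 50%.
#'
#' @param fit A converged `dose_response_fit`.
#' @return Dose in µM, or `NA_real_` if the curve does not reach 50%.
#' @export
ic50_absolute <- function(fit) {
  stopifnot(inherits(fit, "dose_response_fit"))
  if (!fit$converged) stop("fit did not converge", call. = FALSE)
  if (!(fit$bottom < 50 && fit$top > 50)) {
    warning("curve does not cross 50% viability; IC50 undefined",
            call. = FALSE)
    return(NA_real_)
  }
  fit$ec50 * ((fit$top - 50) / (50 - fit$bottom))^(1 / fit$hill)
}

#' Potency fold-change between two cell lines
#'
#' `fold = ed50_reference / ed50_target`; a compound is flagged
#' line-selective when the target line is at least `threshold`-fold more
#' sensitive (inclusive at exactly the threshold).
#'
#' @param fit_target,fit_reference Converged fits for the target and
#'   reference lines.
#' @param threshold Fold-change cut-off (default 10).
#' @return List with `fold` and logical `selective`.
#' @export
potency_fold_change <- function(fit_target, fit_reference, threshold = 10) {
  stopifnot(inherits(fit_target, "dose_response_fit"),
            inherits(fit_reference, "dose_response_fit"))
  if (!fit_target$converged || !fit_reference$converged) {
    stop("both fits must be converged", call. = FALSE)
  }
  fold <- fit_reference$ec50 / fit_target$ec50
  list(fold = fold, selective = fold >= threshold)
}

#' IC50 shift under a fixed modulator
#'
#' Ratio `IC50(drug alone) / IC50(drug + modulator)`; values above 1
#' indicate the modulator sensitizes the line to the drug.
#'
#' @param fit_alone,fit_with Converged fits of the drug dose-response
#'   without and with the fixed-dose modulator.
#' @return The shift ratio.
#' @export
ic50_shift <- function(fit_alone, fit_with) {
  a <- ic50_absolute(fit_alone)
  w <- ic50_absolute(fit_with)
  if (is.na(a) || is.na(w)) stop("IC50 undefined for one of the curves",
                                 call. = FALSE)
  a / w
}
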