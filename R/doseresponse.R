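## Four-parameter logistic dose-response fitting, IC50 extraction with
## flat-curve handling, and the two sensitivity classification rules (absolute
## IC50 threshold; rank-extremes grouping with undefined IC50s counted as
## maximally resistant).

fourpl <- function(x, top, bottom, hill, e) {
  bottom + (top - bottom) / (1 + 10^(hill * (x - e)))
}

#' Fit a four-parameter logistic dose-response curve
#'
#' Least-squares fit of `r = bottom + (top - bottom) / (1 + 10^(hill * (log10
#' d - log10 IC50)))` on the log10 micromolar dose scale. Vehicle wells (dose
#' 0) are anchored at `vehicle_log10` (default -5, i.e. 10 pM). Initialisation
#' uses the response extremes, the half-range crossing dose, and hill = 1;
#' optimisation is bounded L-BFGS-B with `n_restarts` jittered restarts (best
#' RSS kept, seeded). log10 IC50 is bounded to the fitted dose range extended
#' one decade each side.
#'
#' A fit is flagged flat - and its IC50 reported undefined - when the fitted
#' amplitude `|top - bottom|` is below `flat_frac` of the vehicle-level
#' response, when the approximate 95 percent CI of the hill slope spans 0, or
#' when log10 IC50 is pinned at its boundary.
#'
#' @param dose molar concentrations (0 = vehicle).
#' @param response viability readings, same length.
#' @param cell_line optional label stored in the fit.
#' @param vehicle_log10 log10(micromolar) anchor for vehicle wells.
#' @param flat_frac flatness threshold as a fraction of the vehicle response.
#' @param n_restarts jittered optimiser restarts.
#' @param seed RNG seed for the restarts.
#' @return object of class `dose_response_fit` with fields `cell_line, top,
#'   bottom, hill, log10_ic50, ic50` (molar, NA when undefined), `rss,
#'   flat_flag, converged, label` plus methods `print`, `coef`, `predict`,
#'   `plot`.
#' @export
fit_4pl <- function(dose, response, cell_line = NA_character_,
                    vehicle_log10 = -5, flat_frac = 0.2, n_restarts = 5,
                    seed = 1) {
  stopifnot(length(dose) == length(response))
  ok <- is.finite(dose) & is.finite(response)
  dose <- dose[ok]; response <- response[ok]
  if (length(unique(dose[dose > 0])) < 4L) {
    stop_invalid("fit_4pl needs >= 4 distinct positive doses")
  }
  x <- ifelse(dose == 0, vehicle_log10, log10(dose * 1e6))
  xr <- range(x[dose > 0])
  margin <- max(diff(range(response)), abs(mean(response)) / 2, 1)
  lo <- c(top = min(response) - margin, bottom = min(response) - margin,
          hill = -10, e = xr[1] - 1)
  hi <- c(top = max(response) + margin, bottom = max(response) + margin,
          hill = 10, e = xr[2] + 1)
  ## init: extremes + half-range crossing
  mx <- tapply(response, x, mean)
  xs <- as.numeric(names(mx))
  half <- (max(mx) + min(mx)) / 2
  cross <- xs[which.min(abs(mx - half))]
  init <- c(top = max(mx), bottom = min(mx), hill = 1,
            e = min(max(cross, lo["e"]), hi["e"]))
  obj <- function(par) {
    sum((response - fourpl(x, par[1], par[2], par[3], par[4]))^2)
  }
  set.seed(split_seed(seed, 41L))
  best <- NULL
  for (r in seq_len(n_restarts + 1L)) {
    p0 <- if (r == 1L) init else {
      jit <- init * (1 + runif(4, -0.3, 0.3)) +
        c(0, 0, runif(1, -0.5, 0.5), runif(1, -1, 1))
      pmin(pmax(jit, lo + 1e-9), hi - 1e-9)
    }
    f <- tryCatch(optim(p0, obj, method = "L-BFGS-B", lower = lo, upper = hi,
                        control = list(maxit = 500, factr = 1e4)),
                  error = function(e) NULL)
    if (!is.null(f) && (is.null(best) || f$value < best$value)) best <- f
  }
  if (is.null(best)) {
    warning("4PL fit did not converge")
    fit <- list(cell_line = cell_line, top = NA_real_, bottom = NA_real_,
                hill = NA_real_, log10_ic50 = NA_real_, ic50 = NA_real_,
                rss = NA_real_, flat_flag = TRUE, converged = FALSE,
                label = NA_character_, x = x, response = response,
                vehicle_log10 = vehicle_log10)
    return(structure(fit, class = "dose_response_fit"))
  }
  par <- best$par
  ## hill CI via numerical hessian of the RSS surface
  hill_ci0 <- FALSE
  h <- tryCatch(stats::optimHess(par, obj), error = function(e) NULL)
  if (!is.null(h)) {
    n <- length(response)
    sigma2 <- best$value / max(n - 4, 1)
    covm <- tryCatch(solve(h / (2 * sigma2)), error = function(e) NULL)
    if (!is.null(covm) && is.finite(covm[3, 3]) && covm[3, 3] > 0) {
      se_hill <- sqrt(covm[3, 3])
      hill_ci0 <- abs(par[3]) < 1.96 * se_hill
    }
  }
  ctrl_level <- mean(response[x == min(x)])
  flat <- abs(par[1] - par[2]) < flat_frac * abs(ctrl_level) ||
    hill_ci0 ||
    par[4] <= lo["e"] + 1e-6 || par[4] >= hi["e"] - 1e-6
  fit <- list(cell_line = cell_line,
              top = unname(par[1]), bottom = unname(par[2]),
              hill = unname(par[3]),
              log10_ic50 = if (flat) NA_real_ else unname(par[4]),
              ic50 = if (flat) NA_real_ else unname(10^par[4] * 1e-6),
              rss = best$value, flat_flag = flat, converged = TRUE,
              label = NA_character_, x = x, response = response,
              vehicle_log10 = vehicle_log10)
  structure(fit, class = "dose_response_fit")
}

#' @export
print.dose_response_fit <- function(x, ...) {
  cat("4PL dose-response fit",
      if (!is.na(x$cell_line)) paste0(" [", x$cell_line, "]"), "\n", sep = "")
  if (x$flat_flag) {
    cat("  flat curve: IC50 undefined\n")
  } else {
    cat(sprintf("  IC50 = %.3g M (log10[uM] = %.3f), hill = %.2f\n",
                x$ic50, x$log10_ic50, x$hill))
  }
  cat(sprintf("  top = %.2f, bottom = %.2f, RSS = %.3g\n",
              x$top, x$bottom, x$rss))
  if (!is.na(x$label)) cat("  label:", x$label, "\n")
  invisible(x)
}

#' @export
coef.dose_response_fit <- function(object, ...) {
  c(top = object$top, bottom = object$bottom, hill = object$hill,
    log10_ic50 = object$log10_ic50)
}

#' Predict viability at new doses
#'
#' @param object `dose_response_fit`.
#' @param newdata molar doses (0 = vehicle).
#' @param ... unused.
#' @export
predict.dose_response_fit <- function(object, newdata, ...) {
  x <- ifelse(newdata == 0, object$vehicle_log10, log10(newdata * 1e6))
  e <- if (is.na(object$log10_ic50)) {
    ## flat curves: report the fitted plateau
    return(rep(mean(object$response), length(x)))
  } else object$log10_ic50
  fourpl(x, object$top, object$bottom, object$hill, e)
}

#' @export
plot.dose_response_fit <- function(x, ...) {
  plot(x$x, x$response, xlab = "log10 dose [uM]", ylab = "response",
       main = x$cell_line, ...)
  if (!x$flat_flag) {
    xs <- seq(min(x$x), max(x$x), length.out = 200)
    graphics::lines(xs, fourpl(xs, x$top, x$bottom, x$hill, x$log10_ic50))
    graphics::abline(v = x$log10_ic50, lty = 2)
  }
  invisible(x)
}

#' Absolute-threshold sensitivity classification
#'
#' Sensitive when the fitted IC50 is strictly below `threshold`; resistant when
#' it is at/above the threshold or undefined (flat curve). Default threshold:
#' 2000 pM.
#'
#' @param fit `dose_response_fit` (or list thereof).
#' @param threshold molar IC50 cutoff.
#' @return character label(s).
#' @export
classify_threshold <- function(fit, threshold = 2000e-12) {
  one <- function(f) {
    if (is.na(f$ic50) || f$ic50 >= threshold) "resistant" else "sensitive"
  }
  if (inherits(fit, "dose_response_fit")) return(one(fit))
  vapply(fit, one, character(1))
}

#' Rank-extremes sensitivity grouping
#'
#' Ranks cell lines by IC50; lines with undefined IC50 sort above every finite
#' value. The resistant group is the `n_per_group` highest finite IC50s plus
#' all undefined lines (appended beyond `n_per_group`); the sensitive group is
#' the `n_per_group` lowest; the middle stays unclassified. Ties at a group
#' boundary are broken by cell-line name and logged.
#'
#' @param fits named list of `dose_response_fit` objects (names = cell lines)
#'   or a named numeric vector of IC50s with NA for undefined.
#' @param n_per_group lines per extreme group (default 20).
#' @return named character vector of labels
#'   (`sensitive`/`resistant`/`unclassified`).
#' @export
rank_extremes <- function(fits, n_per_group = 20) {
  ic50 <- if (is.numeric(fits)) fits else {
    vapply(fits, function(f) f$ic50, numeric(1))
  }
  if (is.null(names(ic50))) names(ic50) <- as.character(seq_along(ic50))
  n <- length(ic50)
  if (n < 2 * n_per_group) stop_invalid("too few cell lines for the grouping")
  key <- ifelse(is.na(ic50), Inf, ic50)
  o <- order(key, names(ic50))
  sorted <- names(ic50)[o]
  sk <- key[o]
  if (anyDuplicated(sk[c(n_per_group, n_per_group + 1L)]) ||
      (n > n_per_group &&
       isTRUE(sk[n - n_per_group] == sk[n - n_per_group + 1L] &&
              is.finite(sk[n - n_per_group])))) {
    message("IC50 tie at a group boundary broken by cell-line name")
  }
  lab <- setNames(rep("unclassified", n), names(ic50))
  lab[sorted[seq_len(n_per_group)]] <- "sensitive"
  n_na <- sum(is.na(ic50))
  n_res <- min(n - n_per_group, n_per_group + n_na)
  lab[sorted[seq(n - n_res + 1L, n)]] <- "resistant"
  lab
}
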