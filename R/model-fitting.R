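#' Predicted directional force ratios
#'
#' Evaluates the pure-bending force ratio ([force_ratio_approx()]) for the
#' positive and negative pull scenarios and forms the three ratios that the
#' force experiments measure: `fap_fas` (positive vs straight), `fan_fas`
#' (negative vs straight) and their quotient `fap_fan = fap_fas / fan_fas`.
#'
#' @param params A [morph_params()] object.
#' @param beta Stiffness ratio Ep/Eb (>= 1); defaults to `params$beta`.
#' @param theta1 Applied-force angle, degrees (both directions).
#' @param theta_pos,theta_neg Abscission angles `theta2` for the positive and
#'   negative pulls, degrees.
#' @return A one-row tibble with columns `fap_fas`, `fan_fas`, `fap_fan`,
#'   `valid_pos`, `valid_neg` (validity flags of the two underlying
#'   evaluations). A warning is emitted when a validity flag fails.
#' @examples
#' predict_ratios(morph_params(), beta = 25.9)
#' @export
predict_ratios <- function(params, beta = params$beta, theta1 = 90,
                           theta_pos = 15, theta_neg = 35) {
  pos <- force_ratio_approx(params,
                            pull_scenario("positive", theta1, theta_pos),
                            beta = beta)
  neg <- force_ratio_approx(params,
                            pull_scenario("negative", theta1, theta_neg),
                            beta = beta)
  if (!pos$valid || !neg$valid) {
    warn("Predicted ratios fall outside the model's validity regime.",
         class = "abscissr_validity_warning")
  }
  tibble(
    fap_fas = pos$ratio, fan_fas = neg$ratio,
    fap_fan = pos$ratio / neg$ratio,
    valid_pos = pos$valid, valid_neg = neg$valid
  )
}

fit_objective <- function(beta, params, target, theta1, theta_pos, theta_neg) {
  pred <- suppressWarnings(
    predict_ratios(params, beta = beta, theta1 = theta1,
                   theta_pos = theta_pos, theta_neg = theta_neg)
  )
  (log10(pred$fap_fas) - log10(target[["fap_fas"]]))^2 +
    (log10(pred$fan_fas) - log10(target[["fan_fas"]]))^2
}

golden_section <- function(f, lower, upper, rel_tol = 1e-4) {
  phi <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while ((b - a) > rel_tol * max(abs(a), abs(b), 1e-12)) {
    if (f1 <= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
    }
  }
  (a + b) / 2
}

#' Fit the stiffness ratio beta to measured force ratios
#'
#' The only unmeasured parameter of the bending model is the stiffness ratio
#' `beta = Ep/Eb` between pedicle and base tissue. `fit_beta()` finds the
#' value whose predicted `fap_fas` and `fan_fas` best match measured targets,
#' minimising the sum of squared differences of the log10 ratios (log space
#' balances the two ratios, which differ by an order of magnitude). The
#' optimiser is deterministic: a log-spaced grid of 400 points over `bounds`
#' followed by golden-section refinement around the grid minimum to a relative
#' tolerance of 1e-4.
#'
#' @param target Measured ratios: either a data frame with columns `fap_fas`
#'   and `fan_fas` (e.g. from [experimental_ratios()]) or a named numeric
#'   vector with those names. Defaults to the study's measured medians-of-
#'   ratios, 0.005 and 0.03.
#' @param params A [morph_params()] object.
#' @param bounds Search interval for beta, within `[1, 1000]`.
#' @param theta1,theta_pos,theta_neg Scenario angles, degrees (see
#'   [predict_ratios()]).
#' @param n_grid Number of coarse grid points.
#' @return An object of class `beta_fit` with elements `beta_star`,
#'   `objective`, `predicted` (tibble from [predict_ratios()] at `beta_star`),
#'   `target`, `boundary` (`TRUE` when the optimum sits on a search bound),
#'   `bounds`, and `grid` (the coarse objective trace, for plotting). Has
#'   [tidy()], [glance()] and [autoplot()] methods.
#' @examples
#' fit <- fit_beta(params = morph_params())
#' fit$beta_star
#' tidy(fit)
#' @export
fit_beta <- function(target = c(fap_fas = 0.005, fan_fas = 0.03),
                     params = morph_params(), bounds = c(1, 1000),
                     theta1 = 90, theta_pos = 15, theta_neg = 35,
                     n_grid = 400) {
  if (is.data.frame(target)) {
    target <- c(fap_fas = target$fap_fas[1], fan_fas = target$fan_fas[1])
  }
  if (!all(c("fap_fas", "fan_fas") %in% names(target))) {
    abort("`target` must provide fap_fas and fan_fas.")
  }
  if (any(target[c("fap_fas", "fan_fas")] <= 0)) {
    abort("Target ratios must be positive.")
  }
  if (bounds[1] < 1 || bounds[2] > 1000 || bounds[1] >= bounds[2]) {
    abort("`bounds` must be an increasing interval within [1, 1000].")
  }
  f <- function(b) fit_objective(b, params, target, theta1, theta_pos, theta_neg)
  grid_beta <- exp(seq(log(bounds[1]), log(bounds[2]), length.out = n_grid))
  grid_obj <- vapply(grid_beta, f, numeric(1))
  i <- which.min(grid_obj)
  lo <- grid_beta[max(1, i - 1)]
  hi <- grid_beta[min(n_grid, i + 1)]
  beta_star <- golden_section(f, lo, hi, rel_tol = 1e-4)
  # keep the grid point if refinement did not improve on it
  if (f(beta_star) > grid_obj[i]) beta_star <- grid_beta[i]
  boundary <- i == 1L || i == n_grid
  structure(
    list(
      beta_star = beta_star,
      objective = f(beta_star),
      predicted = suppressWarnings(
        predict_ratios(params, beta = beta_star, theta1 = theta1,
                       theta_pos = theta_pos, theta_neg = theta_neg)
      ),
      target = target,
      boundary = boundary,
      bounds = bounds,
      angles = c(theta1 = theta1, theta_pos = theta_pos, theta_neg = theta_neg),
      params = params,
      grid = tibble(beta = grid_beta, objective = grid_obj)
    ),
    class = "beta_fit"
  )
}

#' @export
print.beta_fit <- function(x, ...) {
  cat("<beta_fit>\n")
  cat(sprintf("  beta* = %.4g (objective %.4g%s)\n", x$beta_star, x$objective,
              if (x$boundary) ", at search boundary" else ""))
  cat(sprintf("  predicted: Fap/Fas = %.3g, Fan/Fas = %.3g, Fap/Fan = %.3g\n",
              x$predicted$fap_fas, x$predicted$fan_fas, x$predicted$fap_fan))
  cat(sprintf("  target:    Fap/Fas = %.3g, Fan/Fas = %.3g\n",
              x$target[["fap_fas"]], x$target[["fan_fas"]]))
  invisible(x)
}

#' @rdname fit_beta
#' @param x A `beta_fit` object.
#' @param ... Unused.
#' @method tidy beta_fit
#' @export
tidy.beta_fit <- function(x, ...) {
  tibble(
    term = c("beta_star", "fap_fas", "fan_fas", "fap_fan"),
    estimate = c(x$beta_star, x$predicted$fap_fas, x$predicted$fan_fas,
                 x$predicted$fap_fan),
    target = c(NA_real_, x$target[["fap_fas"]], x$target[["fan_fas"]],
               x$target[["fap_fas"]] / x$target[["fan_fas"]])
  )
}

#' @rdname fit_beta
#' @method glance beta_fit
#' @export
glance.beta_fit <- function(x, ...) {
  tibble(
    beta_star = x$beta_star, objective = x$objective, boundary = x$boundary,
    lower = x$bounds[1], upper = x$bounds[2],
    valid_pos = x$predicted$valid_pos, valid_neg = x$predicted$valid_neg
  )
}

#' Sensitivity sweep of the directional asymmetry over attachment geometry
#'
#' Recomputes the positive-to-negative force ratio `fap_fan` while one
#' geometric parameter varies: the pedicle radius `c`, or the base radius `r`
#' (in which case the base width is re-derived as `w = 1.6 r` at every grid
#' point, the allometric scaling observed between the two). Grid points whose
#' neutral axis leaves the pedicle are kept in the output but flagged invalid.
#'
#' @param params Baseline [morph_params()].
#' @param which `"c"` or `"r"`: the parameter to sweep.
#' @param grid Ascending positive grid of parameter values, um.
#' @param beta Stiffness ratio used for every evaluation.
#' @param theta1,theta_pos,theta_neg Scenario angles, degrees.
#' @return A tibble (class `ratio_sweep`) with columns `param`,
#'   `param_value_um`, `fap_fas`, `fan_fas`, `fap_fan`, `valid`.
#' @examples
#' sweep_parameter(morph_params(), "r", grid = seq(15, 60, by = 5), beta = 25.9)
#' @export
sweep_parameter <- function(params, which = c("c", "r"), grid,
                            beta = params$beta, theta1 = 90,
                            theta_pos = 15, theta_neg = 35) {
  which <- match.arg(which)
  if (length(grid) == 0) abort("`grid` must be nonempty.")
  if (any(grid <= 0) || is.unsorted(grid, strictly = TRUE)) {
    abort("`grid` must be positive and strictly ascending.")
  }
  rows <- purrr::map(grid, function(v) {
    p <- params
    p[[which]] <- v
    if (which == "r") p$w <- 1.6 * v
    p <- morph_params(L = p$L, w = p$w, r = p$r, c = p$c, k = p$k, ell = p$ell)
    pred <- suppressWarnings(
      predict_ratios(p, beta = beta, theta1 = theta1,
                     theta_pos = theta_pos, theta_neg = theta_neg)
    )
    tibble(param = which, param_value_um = v,
           fap_fas = pred$fap_fas, fan_fas = pred$fan_fas,
           fap_fan = pred$fap_fan,
           valid = pred$valid_pos && pred$valid_neg)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("ratio_sweep", class(out))
  out
}

#' Propagate morphology uncertainty into the predicted ratios
#'
#' Evaluates [predict_ratios()] on a collection of morphology draws (e.g. from
#' [sample_morphology()] with `spread = "se"`) and reports the half-width of
#' the central 95% interval of each predicted ratio.
#'
#' @param param_samples A data frame of morphology draws with columns `L`,
#'   `w`, `r`, `c`, `k`, `ell` (one draw per row), or a list of
#'   [morph_params()] objects. At least two draws.
#' @param beta Stiffness ratio used for every evaluation.
#' @param theta1,theta_pos,theta_neg Scenario angles, degrees.
#' @return A tibble with columns `ratio` (`fap_fas`, `fan_fas`, `fap_fan`),
#'   `half_width`, `lo`, `hi`.
#' @examples
#' draws <- sample_morphology(200, spread = "se", seed = 1)
#' propagate_errors(draws, beta = 25.9)
#' @export
propagate_errors <- function(param_samples, beta, theta1 = 90,
                             theta_pos = 15, theta_neg = 35) {
  if (is.data.frame(param_samples)) {
    param_samples <- purrr::pmap(
      param_samples[, c("L", "w", "r", "c", "k", "ell")], morph_params
    )
  }
  if (length(param_samples) < 2) abort("Need at least two parameter draws.")
  preds <- purrr::map_dfr(param_samples, function(p) {
    suppressWarnings(
      predict_ratios(p, beta = beta, theta1 = theta1,
                     theta_pos = theta_pos, theta_neg = theta_neg)
    )
  })
  purrr::map_dfr(c("fap_fas", "fan_fas", "fap_fan"), function(nm) {
    qs <- quantile(preds[[nm]], c(0.025, 0.975), names = FALSE)
    tibble(ratio = nm, half_width = diff(qs) / 2, lo = qs[1], hi = qs[2])
  })
}
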