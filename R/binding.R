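#' Mass-action 1:1 binding: equilibrium complex concentration
#'
#' Solves the quadratic depletion model for a 1:1 interaction R + L <-> RL
#' at equilibrium, valid when reactant totals are comparable to the
#' dissociation constant (so free ~ total approximations fail). The physical
#' root of \eqn{Kd \cdot [RL] = (R_t - [RL])(L_t - [RL])} is
#' \deqn{[RL] = \frac{(R_t + L_t + K_d) - \sqrt{(R_t + L_t + K_d)^2 - 4 R_t L_t}}{2}}
#' evaluated in the numerically stable form \eqn{2 R_t L_t / (b + \sqrt{b^2 - 4 R_t L_t})}
#' to avoid cancellation when \eqn{K_d \gg R_t L_t}.
#'
#' @param R_total total concentration of the receptor-like species (same units
#'   as `Kd`, typically molar).
#' @param L_total total concentration of the titrant/ligand species.
#' @param Kd equilibrium dissociation constant, > 0.
#' @return Equilibrium complex concentration `[RL]`, in the input units;
#'   always within `[0, min(R_total, L_total)]`. Vectorised over all arguments.
#' @examples
#' complex_concentration(50e-9, 100e-9, 15.5e-9)
#' @export
complex_concentration <- function(R_total, L_total, Kd) {
  if (any(R_total < 0) || any(L_total < 0))
    stop("R_total and L_total must be non-negative")
  if (any(Kd <= 0)) stop("Kd must be > 0")
  b <- R_total + L_total + Kd
  disc <- b^2 - 4 * R_total * L_total
  disc[disc < 0] <- 0  # guard against roundoff; analytically >= Kd^2 > 0
  rl <- 2 * R_total * L_total / (b + sqrt(disc))
  pmin(rl, pmin(R_total, L_total))
}

#' Fraction of a species bound at equilibrium
#'
#' @inheritParams complex_concentration
#' @param of which species' bound fraction to report: `"R"` or `"L"`.
#' @return `[RL] / total` of the chosen species, in `[0, 1]`.
#' @export
fraction_bound <- function(R_total, L_total, Kd, of = c("R", "L")) {
  of <- match.arg(of)
  total <- if (of == "R") R_total else L_total
  if (any(total <= 0)) stop("total concentration of species '", of, "' must be > 0")
  complex_concentration(R_total, L_total, Kd) / total
}

#' Predicted percent reduction in complex between two affinities
#'
#' Compares equilibrium occupancy at two dissociation constants while the
#' total concentrations are held fixed, e.g. wild-type versus mutant affinity
#' at assay concentrations. Reported as
#' \eqn{100 (1 - [RL]_b / [RL]_a)}.
#'
#' @param Kd_a reference (e.g. wild-type) dissociation constant.
#' @param Kd_b comparison (e.g. mutant) dissociation constant.
#' @param R_total,L_total fixed total concentrations, same units as the Kds.
#' @return Percent reduction (positive when `Kd_b > Kd_a`).
#' @examples
#' ## occupancy loss when affinity drops ~4-fold at 50/100 nM totals
#' percent_reduction(15.5e-9, 67.1e-9, 50e-9, 100e-9)
#' @export
percent_reduction <- function(Kd_a, Kd_b, R_total, L_total) {
  rl_a <- complex_concentration(R_total, L_total, Kd_a)
  rl_b <- complex_concentration(R_total, L_total, Kd_b)
  if (any(rl_a == 0)) stop("reference complex concentration is zero; percent reduction undefined")
  100 * (1 - rl_b / rl_a)
}

#' Design of a two-fold dilution titration
#'
#' Describes a serial-dilution binding titration (as used in microscale
#' thermophoresis): the titrant is diluted two-fold from a top concentration
#' while the labeled species is held constant, and the response interpolates
#' between a free and a bound signal level according to the labeled species'
#' bound fraction under the quadratic depletion model.
#'
#' @param n_points number of dilution points (>= 6; assays typically use 16 or 24).
#' @param top_conc top titrant concentration (M).
#' @param labeled_total constant labeled-species concentration (M); default 50 nM.
#' @param Kd true dissociation constant (M).
#' @param signal_free,signal_bound response levels (a.u.) at zero and full saturation.
#' @param noise_sd additive Gaussian noise on the response (a.u.).
#' @param dilution_factor dilution step, default 2.
#' @return An object of class `titration_design`.
#' @export
titration_design <- function(n_points, top_conc, Kd,
                             labeled_total = 50e-9,
                             signal_free = 800, signal_bound = 900,
                             noise_sd = 0, dilution_factor = 2) {
  if (n_points < 6) stop("n_points must be >= 6")
  if (top_conc <= 0) stop("top_conc must be > 0")
  if (Kd <= 0) stop("Kd must be > 0")
  if (labeled_total <= 0) stop("labeled_total must be > 0")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (dilution_factor <= 1) stop("dilution_factor must be > 1")
  structure(list(n_points = as.integer(n_points), top_conc = top_conc,
                 Kd = Kd, labeled_total = labeled_total,
                 signal_free = signal_free, signal_bound = signal_bound,
                 noise_sd = noise_sd, dilution_factor = dilution_factor),
            class = "titration_design")
}

#' Simulate a titration curve
#'
#' Generates responses for a two-fold dilution series under the 1:1 quadratic
#' depletion model plus additive Gaussian noise. Deterministic given
#' `rng_seed`.
#'
#' @param design a [titration_design()].
#' @param rng_seed integer seed.
#' @return A data frame with columns `conc` (titrant total, M, descending) and
#'   `response` (a.u.), with the design attached as attribute `"design"`.
#' @export
simulate_titration <- function(design, rng_seed = 1L) {
  stopifnot(inherits(design, "titration_design"))
  set.seed(rng_seed)
  conc <- design$top_conc / design$dilution_factor^(seq_len(design$n_points) - 1)
  fb <- fraction_bound(design$labeled_total, conc, design$Kd, of = "R")
  response <- design$signal_free + (design$signal_bound - design$signal_free) * fb +
    stats::rnorm(length(conc), 0, design$noise_sd)
  out <- data.frame(conc = conc, response = response)
  attr(out, "design") <- design
  out
}

#' Fit a dissociation constant to a titration curve
#'
#' Nonlinear least squares of
#' `response = s_free + (s_bound - s_free) * fraction_bound(labeled)` with the
#' dissociation constant parameterised in log space (respecting positivity
#' across the nanomolar-to-micromolar span of typical assays). Initialised
#' from the concentration at half-maximal response; fitted with
#' Levenberg-Marquardt.
#'
#' @param titration data frame with columns `conc` (titrant totals, M) and
#'   `response` (a.u.).
#' @param labeled_total constant labeled-species concentration (M).
#' @return An object of class `kd_fit`: list with `Kd`, `Kd_se`, `signal_free`,
#'   `signal_bound`, `log_kd`, `log_kd_se`, `residual_norm`, `valid`, and the
#'   underlying `nls` fit. `valid` is `FALSE` (with a `reason`) when the fit
#'   did not converge or the estimate escaped far outside the sampled
#'   concentration range.
#' @export
fit_kd <- function(titration, labeled_total = 50e-9) {
  stopifnot(is.data.frame(titration), all(c("conc", "response") %in% names(titration)))
  conc <- titration$conc
  resp <- titration$response
  if (length(conc) < 6) stop("need >= 6 titration points")
  if (any(conc <= 0)) stop("titrant concentrations must be > 0")
  if (stats::sd(resp) == 0) stop("responses are all equal; nothing to fit")

  ## half-maximal-response initialisation
  ord <- order(conc)
  s_lo <- mean(resp[ord][seq_len(2)])                  # low-conc plateau
  s_hi <- mean(resp[ord][length(conc) - c(1, 0)])      # high-conc plateau
  mid <- (s_lo + s_hi) / 2
  kd0 <- conc[which.min(abs(resp - mid))]

  model <- function(log_kd, s_free, s_bound, conc) {
    s_free + (s_bound - s_free) *
      fraction_bound(labeled_total, conc, exp(log_kd), of = "R")
  }
  fit <- tryCatch(
    minpack.lm::nlsLM(
      response ~ model(log_kd, s_free, s_bound, conc),
      data = data.frame(conc = conc, response = resp),
      start = list(log_kd = log(kd0), s_free = s_lo, s_bound = s_hi),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)

  if (inherits(fit, "error")) {
    return(structure(list(Kd = NA_real_, valid = FALSE,
                          reason = conditionMessage(fit)), class = "kd_fit"))
  }
  cf <- stats::coef(fit)
  se <- tryCatch(sqrt(diag(stats::vcov(fit))), error = function(e) rep(NA_real_, 3))
  kd_hat <- exp(cf[["log_kd"]])
  span <- range(conc)
  valid <- TRUE; reason <- NULL
  if (kd_hat < span[1] / 1e4 || kd_hat > span[2] * 1e4) {
    valid <- FALSE; reason <- "fitted Kd far outside the sampled concentration range"
  }
  if (cf[["s_bound"]] == cf[["s_free"]]) {
    valid <- FALSE; reason <- "degenerate fit: signal_bound == signal_free"
  }
  structure(list(
    Kd = kd_hat,
    Kd_se = kd_hat * se[1],   # delta method from log space
    log_kd = cf[["log_kd"]], log_kd_se = se[1],
    signal_free = cf[["s_free"]], signal_free_se = se[2],
    signal_bound = cf[["s_bound"]], signal_bound_se = se[3],
    residual_norm = sqrt(sum(stats::resid(fit)^2)),
    valid = valid, reason = reason, fit = fit), class = "kd_fit")
}

#' @export
print.kd_fit <- function(x, ...) {
  if (!isTRUE(x$valid)) {
    cat("Invalid Kd fit:", x$reason %||% "unknown reason", "\n")
    return(invisible(x))
  }
  cat(sprintf("Kd = %.4g (se %.2g), signals %.4g -> %.4g, residual norm %.3g\n",
              x$Kd, x$Kd_se, x$signal_free, x$signal_bound, x$residual_norm))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
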