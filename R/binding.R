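AVOGADRO <- 6.02214076e23

#' Equilibrium complex concentration under ligand depletion
#'
#' Solves the 1:1 mass-action equilibrium without assuming probe excess: the
#' complex concentration is the smaller root of the quadratic
#' `0.5 * (A + T + Kd - sqrt((A + T + Kd)^2 - 4*A*T))`, bounded by
#' `min(A, T)`. The discriminant is clamped at zero when round-off drives it
#' slightly negative.
#'
#' @param A Probe (aptamer) concentration, nM; constant per experiment.
#' @param T Protein concentration, nM (the titrated species). Vectorized.
#' @param Kd Dissociation constant, nM (> 0). Vectorized.
#' @return Complex concentration in nM, in `[0, min(A, T)]`.
#' @examples
#' complex_concentration(10, 10, 10)  # 0.5 * (30 - sqrt(500)) ~= 3.8197
#' @export
complex_concentration <- function(A, T, Kd) {
  if (any(Kd <= 0)) stop("Kd must be positive")
  if (any(A < 0) || any(T < 0)) stop("concentrations must be non-negative")
  s <- A + T + Kd
  disc <- pmax(s^2 - 4 * A * T, 0)
  # rationalized root: algebraically 0.5 * (s - sqrt(disc)), but without
  # the catastrophic cancellation that form suffers when 4AT << s^2
  2 * A * T / (s + sqrt(disc))
}

#' Quadratic binding-isotherm signal
#'
#' Signal model shared by the affinity probe CE (ratioed free-DNA peak
#' height) and fluorescence anisotropy (`r - r0`) titrations:
#' `constant / (1 + Kd / (T + complex))` with `complex` the quadratic
#' ligand-depletion root of [complex_concentration()]. At `T = 0` the signal
#' is 0 by continuity. The `"fraction_bound"` form,
#' `constant * complex / A`, is the conventional alternative offered for
#' comparison; the `"as_printed"` form is the default used for fitting.
#'
#' @param T Protein concentration, nM. Vectorized.
#' @inheritParams complex_concentration
#' @param constant Saturating amplitude, in signal units.
#' @param form `"as_printed"` (default) or `"fraction_bound"`.
#' @return Predicted signal, same length as `T`.
#' @examples
#' isotherm_signal(10, A = 10, Kd = 10, constant = 1)  # ~0.5802
#' @export
isotherm_signal <- function(T, A, Kd, constant,
                            form = c("as_printed", "fraction_bound")) {
  form <- match.arg(form)
  cx <- complex_concentration(A, T, Kd)
  if (form == "fraction_bound") {
    if (any(A <= 0)) stop("A must be positive for the fraction_bound form")
    return(constant * cx / A)
  }
  denom_arg <- T + cx
  out <- ifelse(denom_arg > 0, constant / (1 + Kd / denom_arg), 0)
  as.numeric(out)
}

#' Fit the binding isotherm to a titration
#'
#' Unweighted nonlinear least squares (Levenberg-Marquardt) of
#' [isotherm_signal()] to measured signals; replicate measurements enter as
#' individual points. `Kd` is parameterized on the log scale to enforce
#' positivity; starting values are `Kd0 = median` nonzero `T` and
#' `constant0 = max` observed signal. Standard errors come from the local
#' curvature of the least-squares objective (delta method for `Kd`).
#'
#' @param data data.frame with columns `T` (protein concentration, nM) and
#'   `signal`; an optional `replicate` column is carried but unused.
#' @param A Probe concentration, nM (known constant of the experiment).
#' @param form Isotherm form, see [isotherm_signal()].
#' @return Object of class `isotherm_fit`: list with `Kd_hat`,
#'   `constant_hat`, `se_Kd`, `se_constant`, `rss`, `converged`, `n`, plus
#'   the underlying `nls` object in `$fit` when available.
#' @examples
#' d <- simulate_binding_assay(Kd = 390, A = 10, constant = 1,
#'                             T_grid = seq(0, 240, by = 30),
#'                             noise_sd = 0, replicates = 1, seed = 1)
#' fit_isotherm(d, A = 10)
#' @export
fit_isotherm <- function(data, A,
                         form = c("as_printed", "fraction_bound")) {
  form <- match.arg(form)
  stopifnot(is.data.frame(data), all(c("T", "signal") %in% names(data)),
            A > 0)
  if (length(unique(data$T)) < 4) {
    stop("need at least 4 distinct protein concentrations")
  }
  if (all(data$signal == 0)) {
    stop("unidentifiable: all signals are zero")
  }
  Kd0 <- median(data$T[data$T > 0])
  c0 <- max(data$signal)
  df <- data.frame(T = data$T, signal = data$signal)
  fit <- tryCatch(
    minpack.lm::nlsLM(
      signal ~ isotherm_signal(T, A = A, Kd = exp(lkd),
                               constant = constant, form = form),
      data = df,
      start = list(lkd = log(Kd0), constant = c0),
      control = minpack.lm::nls.lm.control(maxiter = 500, ptol = 1e-10,
                                           ftol = 1e-12)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    out <- list(Kd_hat = NA_real_, constant_hat = NA_real_,
                se_Kd = NA_real_, se_constant = NA_real_, rss = NA_real_,
                converged = FALSE, n = nrow(df), A = A, form = form,
                message = conditionMessage(fit), fit = NULL)
    class(out) <- "isotherm_fit"
    return(out)
  }
  est <- coef(fit)
  se <- tryCatch(summary(fit)$coefficients[, "Std. Error"],
                 error = function(e) c(lkd = NA_real_, constant = NA_real_))
  Kd_hat <- unname(exp(est["lkd"]))
  out <- list(Kd_hat = Kd_hat,
              constant_hat = unname(est["constant"]),
              se_Kd = unname(Kd_hat * se["lkd"]),
              se_constant = unname(se["constant"]),
              rss = sum(residuals(fit)^2),
              converged = isTRUE(fit$convInfo$isConv),
              n = nrow(df), A = A, form = form, fit = fit)
  class(out) <- "isotherm_fit"
  out
}

#' @export
print.isotherm_fit <- function(x, ...) {
  cat("<isotherm_fit>\n")
  if (x$converged) {
    cat(sprintf("  Kd = %.4g nM (se %.3g), constant = %.4g (se %.3g)\n",
                x$Kd_hat, x$se_Kd, x$constant_hat, x$se_constant))
    cat(sprintf("  rss = %.4g over %d points (A = %g nM, %s form)\n",
                x$rss, x$n, x$A, x$form))
  } else {
    cat("  fit did not converge\n")
    if (!is.null(x$message)) cat("  ", x$message, "\n")
  }
  invisible(x)
}

#' Random-library combinatorics
#'
#' Sequence-space statistics of a randomized selection library: the number
#' of possible random regions `4^N`, the number of input molecules, and the
#' expected number of copies of any individual sequence in the input.
#'
#' @param N Random-region length in nucleotides (default 25).
#' @param amount_pmol Picomoles of input DNA (default 100).
#' @return List with `num_possible` (`4^N`), `molecules`
#'   (`amount_pmol * 1e-12 * N_A`), and `expected_abundance`
#'   (`molecules / num_possible`).
#' @examples
#' library_statistics(25, 100)  # expected abundance ~0.05
#' library_statistics(23, 100)  # expected abundance ~1
#' @export
library_statistics <- function(N = 25, amount_pmol = 100) {
  stopifnot(N >= 1, amount_pmol > 0)
  num_possible <- 4^N
  molecules <- amount_pmol * 1e-12 * AVOGADRO
  list(num_possible = num_possible, molecules = molecules,
       expected_abundance = molecules / num_possible)
}
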