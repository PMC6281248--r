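#' Shape rate of the minimal-model traveling pulse
#'
#' In the minimal model (`beta = 1`, `gamma = 0`) the steady density
#' profile is \eqn{n(y) = (N\gamma/2)\,\mathrm{sech}^2(\gamma y)} in the
#' frame moving with the pulse, with inverse-length shape rate
#' \deqn{\gamma = \frac{N(\alpha_A + \alpha_I)}{4v}.}
#' Stronger imitation or larger groups sharpen the pulse; faster walking
#' flattens it.
#'
#' @param N group size (total mass).
#' @param alpha_A,alpha_I imitation strengths (s^-1), not both zero.
#' @param v walking speed (m s^-1), positive.
#' @return Shape rate gamma (m^-1).
#' @export
gamma_shape <- function(N, alpha_A, alpha_I, v) {
  if (alpha_A + alpha_I <= 0) stop("alpha_A + alpha_I must be positive")
  if (v <= 0) stop("walking speed v must be positive")
  if (N <= 0) stop("group size N must be positive")
  N * (alpha_A + alpha_I) / (4 * v)
}

#' Steady traveling-pulse density profile
#'
#' \deqn{\eta_s(x, t) = \frac{N}{2}\gamma\,
#'   \mathrm{sech}^2\big(\gamma (x - b_s^* v t)\big)}
#' with gamma from [gamma_shape()] and moving fraction \eqn{b_s^*} from
#' [moving_fraction()]. Integrates to `N` for any parameters (the sech^2
#' integral is `2/gamma`).
#'
#' @param x abscissae (m).
#' @param t time (s).
#' @param params a [behavioural_params()] object; the minimal model reads
#'   `mu_A`, the effective spontaneous stop rate, `alpha_A`, `alpha_I`,
#'   `v`, `N`.
#' @param mode moving-fraction mode passed to [moving_fraction()];
#'   `"auto"` picks `"symmetric"` when `alpha_A == alpha_I` (within
#'   1e-12) and `"general"` otherwise.
#' @return Density eta_s at `x` (sheep m^-1).
#' @export
steady_profile <- function(x, t = 0, params, mode = "auto") {
  g <- gamma_shape(params$N, params$alpha_A, params$alpha_I, params$v)
  b <- moving_fraction(params, mode)
  (params$N / 2) * g * sech2(g * (x - b * params$v * t))
}

sech2 <- function(z) 1 / cosh(z)^2

#' Residual of the steady-pulse ordinary differential equation
#'
#' The moving-frame profile `n(y)` of the minimal model satisfies
#' \deqn{(n')^2 - n\,n'' - \frac{\alpha_A + \alpha_I}{v} n^3 = 0.}
#' This evaluates that residual for the analytic sech^2 profile using
#' exact derivatives; it vanishes to round-off, which pins down the shape
#' rate [gamma_shape()].
#'
#' @param y moving-frame abscissae (m).
#' @param params a [behavioural_params()] object.
#' @return Residual values at `y`.
#' @export
pulse_ode_residual <- function(y, params) {
  g <- gamma_shape(params$N, params$alpha_A, params$alpha_I, params$v)
  C <- params$N * g / 2
  S2 <- sech2(g * y)
  Th <- tanh(g * y)
  n <- C * S2
  np <- -2 * g * n * Th
  npp <- 2 * g^2 * n * (2 * Th^2 - S2)
  np^2 - n * npp - (params$alpha_A + params$alpha_I) / params$v * n^3
}

#' Steady moving fraction of the pulse
#'
#' The fraction \eqn{b_s^*} of the group in the walking state in the
#' steady regime; the pulse propagates at `v * b_s^*`. Three closed forms:
#' \describe{
#'   \item{`"general"`}{asymmetric imitation (`alpha_A != alpha_I`): the
#'     positive root
#'     \deqn{b_s^* = \frac{D + \sqrt{D^2 + 4\mu_A \tfrac{N}{2}(\alpha_A-\alpha_I)}}
#'       {N(\alpha_A-\alpha_I)}, \quad
#'       D = \tfrac{N}{2}(\alpha_A-\alpha_I) - \mu_A - \mu_I,}
#'     using the unscaled spontaneous stop rate `mu_I_star`. The other
#'     quadratic root falls outside [0, 1] and is rejected.}
#'   \item{`"symmetric"`}{`alpha_A == alpha_I`:
#'     \eqn{b_s^* = \mu_A / (\mu_A + \mu_I)}, independent of `N`.}
#'   \item{`"variant"`}{symmetric imitation with the group-size-regulated
#'     stop rate: \eqn{b_s^* = \mu_A / (\mu_A + \mu_I^*/N)}.}
#' }
#' For the asymmetric family of the variant model, set
#' `variant_scaling = TRUE` with `mode = "general"`: the general root is
#' then evaluated with `mu_I = mu_I_star / N`.
#'
#' @param params a [behavioural_params()] object.
#' @param mode `"auto"`, `"general"`, `"symmetric"` or `"variant"`.
#' @param variant_scaling apply the `mu_I_star / N` scaling inside the
#'   general formula.
#' @return Moving fraction in [0, 1].
#' @export
moving_fraction <- function(params, mode = "auto",
                            variant_scaling = FALSE) {
  mode <- match.arg(mode, c("auto", "general", "symmetric", "variant"))
  mu_A <- params$mu_A
  mu_I <- if (variant_scaling) params$mu_I_star / params$N else
    params$mu_I_star
  d_alpha <- params$alpha_A - params$alpha_I
  if (mode == "auto")
    mode <- if (abs(d_alpha) < 1e-12) "symmetric" else "general"
  b <- switch(mode,
    symmetric = mu_A / (mu_A + mu_I),
    variant = mu_A / (mu_A + params$mu_I_star / params$N),
    general = {
      if (abs(d_alpha) < 1e-12)
        stop("general mode requires alpha_A != alpha_I; ",
             "use mode = \"symmetric\"")
      D <- params$N / 2 * d_alpha - mu_A - mu_I
      (D + sqrt(D^2 + 4 * mu_A * params$N / 2 * d_alpha)) /
        (params$N * d_alpha)
    })
  if (is.na(b) || b < -1e-10 || b > 1 + 1e-10)
    stop("moving fraction outside [0, 1]: ", b)
  min(max(b, 0), 1)
}

#' Moving fraction versus group size under parameter variations
#'
#' Evaluates the steady moving fraction over a range of group sizes for a
#' family of perturbations around a symmetric base parameter set
#' (`alpha_A = alpha_I = alpha`), reproducing the sensitivity analysis of
#' the minimal model: the symmetric case is flat in `N`; the slightest
#' promotion of departure imitation drives `b*` to 1 at large `N`, of
#' stopping imitation to 0; under the group-size-regulated stop rate
#' (`variant = TRUE`) promoted stopping becomes non-monotone in `N`.
#'
#' @param N_range group sizes (positive integers or masses).
#' @param alpha symmetric base imitation strength (s^-1).
#' @param mu_A,mu_I base spontaneous rates (s^-1); the analytic
#'   sensitivity analysis of this family uses 0.02 and 0.08.
#' @param v walking speed (m s^-1).
#' @param variations data frame with columns `label`, `fA`, `fI` (factors
#'   multiplying `alpha` for `alpha_A` and `alpha_I`); defaults to the
#'   symmetric base plus promotions of each side by 1.001 and 1.01.
#' @param variant use the `mu_I / N` scaled stop rate.
#' @return Data frame with columns `N`, `label`, `b_star`.
#' @export
sensitivity_scan <- function(N_range, alpha = 0.5, mu_A = 0.02,
                             mu_I = 0.08, v = 1, variations = NULL,
                             variant = FALSE) {
  if (is.null(variations))
    variations <- data.frame(
      label = c("symmetric", "alpha_A x1.001", "alpha_A x1.01",
                "alpha_I x1.001", "alpha_I x1.01"),
      fA = c(1, 1.001, 1.01, 1, 1),
      fI = c(1, 1, 1, 1.001, 1.01))
  rows <- list()
  for (r in seq_len(nrow(variations))) {
    fA <- variations$fA[r]; fI <- variations$fI[r]
    b <- vapply(N_range, function(N) {
      p <- behavioural_params(mu_A = mu_A, mu_I_star = mu_I,
                              alpha_A = alpha * fA, alpha_I = alpha * fI,
                              beta_A = 1, gamma_A = 0, beta_I = 1,
                              gamma_I = 0, v = v, N = max(1L, round(N)),
                              scale_mu_I = variant)
      p$N <- N  # allow non-integer masses in the analytic formula
      symmetric <- abs(fA - fI) < 1e-15
      if (symmetric && variant) moving_fraction(p, "variant")
      else if (symmetric) moving_fraction(p, "symmetric")
      else moving_fraction(p, "general", variant_scaling = variant)
    }, numeric(1))
    rows[[r]] <- data.frame(N = N_range, label = variations$label[r],
                            b_star = b)
  }
  do.call(rbind, rows)
}
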