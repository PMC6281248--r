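#' Behavioural parameters of the double mimetic start/stop model
#'
#' Bundles every individual-level parameter of the intermittent-walk model:
#' spontaneous switching rates, imitation strengths, stimulation and
#' inhibition exponents, walking speed and group size. Defaults are the
#' values retained for the study system (small Merino sheep groups): the
#' "kept" imitation parameters rounded to one decimal, `mu_A = 0.0055` s^-1
#' (a spontaneous departure about every 3 minutes) and `mu_I_star = 0.08`
#' s^-1 with the effective spontaneous stop rate scaling as `mu_I_star / N`.
#'
#' A stopped individual switches to walking at rate
#' \deqn{K_A = \mu_A + \alpha_A (A^+)^{\beta_A} (N - A^+)^{-\gamma_A}}
#' where \eqn{A^+} counts group-mates walking ahead of it; a walking
#' individual stops at rate
#' \deqn{K_I = \mu_I + \alpha_I (I^-)^{\beta_I} (N - I^-)^{-\gamma_I}}
#' where \eqn{I^-} counts group-mates stopped behind it, and
#' \eqn{\mu_I = \mu_I^* / N} by default.
#'
#' @param mu_A spontaneous activation (departure) rate, s^-1.
#' @param mu_I_star spontaneous inactivation base rate, s^-1; the effective
#'   per-individual stop rate is `mu_I_star / N` unless `scale_mu_I = FALSE`.
#' @param alpha_A,alpha_I imitation strengths, s^-1.
#' @param beta_A,beta_I stimulation exponents (dimensionless).
#' @param gamma_A,gamma_I inhibition exponents (dimensionless).
#' @param v walking speed, m s^-1.
#' @param N group size (integer >= 1).
#' @param scale_mu_I logical; if `TRUE` (default) the effective spontaneous
#'   stop rate is `mu_I_star / N`, if `FALSE` it is `mu_I_star` itself (used
#'   by the non-variant analytic model).
#' @param focal_in_base logical; if `TRUE` (default) the inhibitory base is
#'   `N - count` exactly as the rate formulas are written, i.e. the focal
#'   individual is counted in its own inhibitory pool (the other group-mates
#'   sum to `N - 1 - count`, so the base is always >= 1). If `FALSE` the
#'   base is `N - 1 - count`, floored at 1.
#' @return An object of class `behavioural_params` (a named list).
#' @examples
#' p <- behavioural_params(N = 4)
#' activation_rate(neighbourhood_counts(A_plus = 1, I_plus = 2, N = 4), p)
#' @export
behavioural_params <- function(mu_A = 0.0055, mu_I_star = 0.08,
                               alpha_A = 0.3, beta_A = 0.6, gamma_A = 0.7,
                               alpha_I = 0.4, beta_I = 0.5, gamma_I = 0.5,
                               v = 1.0, N = 4L,
                               scale_mu_I = TRUE, focal_in_base = TRUE) {
  p <- list(mu_A = mu_A, mu_I_star = mu_I_star,
            alpha_A = alpha_A, beta_A = beta_A, gamma_A = gamma_A,
            alpha_I = alpha_I, beta_I = beta_I, gamma_I = gamma_I,
            v = v, N = as.integer(N),
            scale_mu_I = isTRUE(scale_mu_I),
            focal_in_base = isTRUE(focal_in_base))
  validate_params(p)
  class(p) <- "behavioural_params"
  p
}

validate_params <- function(p) {
  num <- c("mu_A", "mu_I_star", "alpha_A", "beta_A", "gamma_A",
           "alpha_I", "beta_I", "gamma_I")
  for (k in num) {
    if (!is.numeric(p[[k]]) || length(p[[k]]) != 1L || !is.finite(p[[k]]) ||
        p[[k]] < 0)
      stop(sprintf("parameter '%s' must be a single non-negative number", k))
  }
  if (!is.numeric(p$v) || p$v <= 0) stop("walking speed 'v' must be > 0")
  if (p$N < 1L) stop("group size 'N' must be a positive integer")
  invisible(p)
}

#' @export
print.behavioural_params <- function(x, ...) {
  cat("Double mimetic intermittent-walk parameters (N =", x$N, ")\n")
  cat(sprintf("  activation : mu_A = %.4g  alpha_A = %.4g  beta_A = %.4g  gamma_A = %.4g\n",
              x$mu_A, x$alpha_A, x$beta_A, x$gamma_A))
  cat(sprintf("  stopping   : mu_I* = %.4g (effective mu_I = %.4g)  alpha_I = %.4g  beta_I = %.4g  gamma_I = %.4g\n",
              x$mu_I_star, spontaneous_stop_rate(x), x$alpha_I, x$beta_I,
              x$gamma_I))
  cat(sprintf("  speed v = %.4g m/s; inhibitory base: %s\n", x$v,
              if (x$focal_in_base) "N - count (focal included)"
              else "N - 1 - count, floored at 1"))
  invisible(x)
}

#' State-position partition of a focal individual's group-mates
#'
#' The four pools an individual reacts to: group-mates moving ahead
#' (`A_plus`), moving behind (`A_minus`), stopped ahead (`I_plus`) and
#' stopped behind (`I_minus`). The four counts must sum to `N - 1`.
#'
#' @param A_plus,A_minus,I_plus,I_minus non-negative integer counts.
#' @param N group size the counts refer to.
#' @return An object of class `neighbourhood_counts`.
#' @export
neighbourhood_counts <- function(A_plus = 0L, A_minus = 0L, I_plus = 0L,
                                 I_minus = 0L, N) {
  cts <- c(A_plus = as.integer(A_plus), A_minus = as.integer(A_minus),
           I_plus = as.integer(I_plus), I_minus = as.integer(I_minus))
  if (any(cts < 0L)) stop("neighbourhood counts must be non-negative")
  if (sum(cts) != N - 1L)
    stop(sprintf("counts sum to %d but must sum to N - 1 = %d",
                 sum(cts), N - 1L))
  structure(as.list(c(cts, N = as.integer(N))),
            class = "neighbourhood_counts")
}

# x^e with the 0^0 == 1 convention (R's `^` already honours it); kept as a
# named helper so the convention is explicit at call sites.
pow0 <- function(x, e) x^e

inhib_base <- function(count, params) {
  if (params$focal_in_base) {
    base <- params$N - count
    if (base <= 0)
      stop("inconsistent counts: inhibitory base N - count <= 0 ",
           "(cannot occur for an eligible focal individual)")
  } else {
    base <- max(params$N - 1L - count, 1L)
  }
  base
}

#' Stopped-to-moving (activation) switching rate
#'
#' \eqn{K_A = \mu_A + \alpha_A (A^+)^{\beta_A} (N - A^+)^{-\gamma_A}}:
#' only group-mates walking ahead stimulate departure; everybody else
#' (including the focal individual itself) inhibits it through the base of
#' the negative exponent. With `A_plus = 0` and `beta_A > 0` the rate is
#' exactly `mu_A`.
#'
#' @param counts a [neighbourhood_counts()] object (or anything with an
#'   `A_plus` element).
#' @param params a [behavioural_params()] object.
#' @return Switching rate in s^-1.
#' @export
activation_rate <- function(counts, params) {
  a <- counts$A_plus
  if (!is.null(counts$N) && counts$N != params$N)
    stop("counts refer to N = ", counts$N, " but params have N = ", params$N)
  if (a == 0 && params$beta_A > 0) return(params$mu_A)
  base <- inhib_base(a, params)
  params$mu_A + params$alpha_A * pow0(a, params$beta_A) *
    pow0(base, -params$gamma_A)
}

#' Moving-to-stopped (inactivation) switching rate
#'
#' \eqn{K_I = \mu_I + \alpha_I (I^-)^{\beta_I} (N - I^-)^{-\gamma_I}} with
#' \eqn{\mu_I} = [spontaneous_stop_rate()]: only group-mates stopped behind
#' stimulate stopping.
#'
#' @inheritParams activation_rate
#' @return Switching rate in s^-1.
#' @export
inactivation_rate <- function(counts, params) {
  i <- counts$I_minus
  if (!is.null(counts$N) && counts$N != params$N)
    stop("counts refer to N = ", counts$N, " but params have N = ", params$N)
  mu_I <- spontaneous_stop_rate(params)
  if (i == 0 && params$beta_I > 0) return(mu_I)
  base <- inhib_base(i, params)
  mu_I + params$alpha_I * pow0(i, params$beta_I) * pow0(base, -params$gamma_I)
}

#' Effective spontaneous stop rate
#'
#' `mu_I_star / N` under the default group-size scaling (walking individuals
#' in larger groups spontaneously stop less often), or `mu_I_star` itself
#' when `scale_mu_I = FALSE`.
#'
#' @param params a [behavioural_params()] object.
#' @return Rate in s^-1.
#' @export
spontaneous_stop_rate <- function(params) {
  if (params$scale_mu_I) params$mu_I_star / params$N else params$mu_I_star
}

#' Read / write behavioural parameters as flat config files
#'
#' Parameters serialize to a flat YAML or JSON mapping whose keys are
#' exactly the field names of [behavioural_params()]; the format is chosen
#' from the file extension (`.yml`/`.yaml` vs `.json`).
#'
#' @param params a [behavioural_params()] object.
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return `write_params()` returns `path` invisibly; `read_params()`
#'   returns a [behavioural_params()] object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "behavioural_params"))
  x <- unclass(params)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    stop("unsupported parameter file extension: ", path)
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    x <- yaml::read_yaml(path)
  } else if (grepl("\\.json$", path, ignore.case = TRUE)) {
    x <- jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    stop("unsupported parameter file extension: ", path)
  }
  known <- names(formals(behavioural_params))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown parameter key(s): ", paste(extra, collapse = ", "))
  do.call(behavioural_params, x)
}
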