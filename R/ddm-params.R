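#' Diffusion-model parameter bundle
#'
#' Container for the parameters of the full drift-diffusion model with
#' diffusion coefficient fixed at 1 (scale convention). Under accuracy coding
#' the upper boundary is the correct response, so positive drift means
#' evidence accumulates toward the correct judgment.
#'
#' @param v drift rate (evidence units per second, signed toward the correct
#'   boundary).
#' @param a boundary separation (evidence units, > 0).
#' @param z relative starting point in (0, 1); 0.5 is unbiased.
#' @param t non-decision time in seconds (encoding + motor), >= 0.
#' @param sv inter-trial standard deviation of drift (normal mixing), >= 0.
#' @param sz inter-trial range of the starting point (uniform mixing), >= 0.
#' @param st inter-trial range of non-decision time (uniform mixing), >= 0.
#' @return an object of class `ddm_params`.
#' @examples
#' p <- ddm_params(v = 1, a = 2, z = 0.5, t = 0.3)
#' choice_probability(p)
#' @export
ddm_params <- function(v = 0, a = 1.5, z = 0.5, t = 0.3,
                       sv = 0, sz = 0, st = 0) {
  p <- structure(list(v = v, a = a, z = z, t = t, sv = sv, sz = sz, st = st),
                 class = "ddm_params")
  validate_ddm_params(p)
  p
}

validate_ddm_params <- function(p) {
  stopifnot(inherits(p, "ddm_params"))
  with(p, {
    if (any(!is.finite(v))) stop("drift rate v must be finite", call. = FALSE)
    if (!is.finite(a) || a <= 0) stop("boundary separation a must be > 0", call. = FALSE)
    if (!is.finite(z) || z <= 0 || z >= 1) stop("starting point z must lie in (0, 1)", call. = FALSE)
    if (!is.finite(t) || t < 0) stop("non-decision time t must be >= 0", call. = FALSE)
    if (sv < 0 || sz < 0 || st < 0) stop("inter-trial variabilities must be >= 0", call. = FALSE)
    if (t - st / 2 < 0) stop("t - st/2 must be >= 0 (non-decision time cannot go negative)", call. = FALSE)
    if (z - sz / 2 <= 0 || z + sz / 2 >= 1) stop("z +/- sz/2 must stay within (0, 1)", call. = FALSE)
  })
  invisible(p)
}

#' @export
print.ddm_params <- function(x, ...) {
  cat("Drift-diffusion parameters (diffusion coefficient 1, accuracy coding)\n")
  cat(sprintf("  v = %.4g  a = %.4g  z = %.4g  t = %.4g s\n", x$v, x$a, x$z, x$t))
  cat(sprintf("  sv = %.4g  sz = %.4g  st = %.4g\n", x$sv, x$sz, x$st))
  invisible(x)
}
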