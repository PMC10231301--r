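#' Wiener first-passage-time density
#'
#' Density of the observed response time at one boundary of the two-boundary
#' Wiener diffusion — the likelihood kernel for all drift-rate inference.
#' Uses the two-regime series expansion (small-time vs large-time) with the
#' standard switching rule for the number of terms, controlled by `rel_tol`.
#' Drift variability `sv` is marginalised analytically; start-point (`sz`) and
#' non-decision (`st`) ranges by fixed-order Gauss-Legendre quadrature (see
#' [integrate_variabilities()] for the adaptive version).
#'
#' Response times at or below the non-decision time have density 0 by
#' contract: no boundary passage can occur before diffusion starts.
#'
#' @param rt response time(s) in seconds (including non-decision time).
#' @param boundary `"upper"` (correct under accuracy coding) or `"lower"`,
#'   recycled along `rt`.
#' @param params a [ddm_params()] object.
#' @param rel_tol series truncation tolerance, in (0, 1e-3].
#' @param n_nodes Gauss-Legendre nodes per variability dimension.
#' @return numeric vector of densities (1/s), non-negative and finite.
#' @examples
#' p <- ddm_params(v = 1, a = 2, z = 0.5, t = 0.3)
#' wfpt_density(c(0.2, 0.8, 1.5), "upper", p)
#' @export
wfpt_density <- function(rt, boundary = c("upper", "lower"), params,
                         rel_tol = 1e-6, n_nodes = 10L) {
  validate_ddm_params(params)
  check_rel_tol(rel_tol)
  if (is.character(boundary)) {
    boundary <- match.arg(boundary, several.ok = FALSE)
    upper <- rep(as.integer(boundary == "upper"), length(rt))
  } else {
    upper <- as.integer(rep_len(as.logical(boundary), length(rt)))
  }
  .wfpt_pdf_cpp(as.numeric(rt), upper, params$v, params$a, params$z,
                params$t, params$sv, params$sz, params$st, rel_tol,
                as.integer(n_nodes))
}

check_rel_tol <- function(rel_tol) {
  if (!is.numeric(rel_tol) || rel_tol <= 0 || rel_tol > 1e-3) {
    stop("rel_tol must lie in (0, 1e-3]", call. = FALSE)
  }
  invisible(rel_tol)
}

#' Closed-form upper-boundary absorption probability
#'
#' For the diffusion without inter-trial variability the probability of
#' absorption at the upper boundary is
#' \deqn{P = \frac{1 - e^{-2vaz}}{1 - e^{-2va}}}{P = (1 - exp(-2vaz))/(1 - exp(-2va))}
#' and equals `z` when `v = 0`. Used as the independent check for both the
#' simulator and the density's integrated mass.
#'
#' @param params a [ddm_params()] object; `sv`, `sz`, `st` must be 0.
#' @return probability of hitting the upper (correct) boundary.
#' @export
choice_probability <- function(params) {
  validate_ddm_params(params)
  if (params$sv > 0 || params$sz > 0 || params$st > 0) {
    stop("closed-form absorption probability requires sv = sz = st = 0",
         call. = FALSE)
  }
  as.numeric(.choice_prob_cpp(params$v, params$a, params$z))
}

#' Density marginalised over inter-trial variabilities, with adaptive nodes
#'
#' Same quantity as [wfpt_density()] but the Gauss-Legendre order for the
#' `sz`/`st` mixing integrals is doubled until successive evaluations agree to
#' `rel_tol` (relative, on the summed density over the requested times).
#' Reduces exactly to [wfpt_density()] when all variabilities are zero.
#'
#' @inheritParams wfpt_density
#' @param max_nodes node-count cap; exceeding it without convergence is an
#'   error reporting the node count reached.
#' @return numeric vector of marginal densities.
#' @export
integrate_variabilities <- function(rt, boundary = c("upper", "lower"), params,
                                    rel_tol = 1e-6, max_nodes = 160L) {
  validate_ddm_params(params)
  check_rel_tol(rel_tol)
  if (params$sz == 0 && params$st == 0) {
    return(wfpt_density(rt, boundary, params, rel_tol = rel_tol))
  }
  n <- 10L
  prev <- wfpt_density(rt, boundary, params, rel_tol = rel_tol, n_nodes = n)
  repeat {
    n <- n * 2L
    if (n > max_nodes) {
      stop(sprintf(paste0("variability quadrature did not converge to rel_tol",
                          " = %g within %d nodes"), rel_tol, max_nodes),
           call. = FALSE)
    }
    cur <- wfpt_density(rt, boundary, params, rel_tol = rel_tol, n_nodes = n)
    denom <- max(sum(abs(cur)), .Machine$double.eps)
    if (sum(abs(cur - prev)) / denom < rel_tol) return(cur)
    prev <- cur
  }
}

#' Total log-likelihood of a set of trials
#'
#' Sums log WFPT densities over trials. The drift rate may vary per trial
#' (e.g. condition coefficient plus participant intercept); the remaining
#' parameters are shared. The sum is order-independent; any trial with a
#' non-positive density makes the data impossible under the parameters and is
#' reported by index.
#'
#' @param rt response times in seconds.
#' @param upper logical (or 0/1): did the trial end at the upper (correct)
#'   boundary?
#' @param params a [ddm_params()] object giving shared parameters (its `v` is
#'   used when `v` is `NULL`).
#' @param v optional per-trial drift vector overriding `params$v`.
#' @param a optional per-trial boundary vector overriding `params$a`.
#' @inheritParams wfpt_density
#' @return total log-likelihood (finite), or an error naming the first
#'   offending trial.
#' @export
ddm_loglik <- function(rt, upper, params, v = NULL, a = NULL,
                       rel_tol = 1e-6, n_nodes = 10L) {
  validate_ddm_params(params)
  check_rel_tol(rel_tol)
  stopifnot(length(upper) == length(rt))
  v <- v %||% params$v
  a <- a %||% params$a
  d <- .wfpt_pdf_cpp(as.numeric(rt), as.integer(as.logical(upper)),
                     as.numeric(v), as.numeric(a), params$z, params$t,
                     params$sv, params$sz, params$st, rel_tol,
                     as.integer(n_nodes))
  bad <- which(!(d > 0) | !is.finite(d))
  if (length(bad) > 0) {
    stop(sprintf(paste0("non-finite log-likelihood: trial %d (rt = %.4g s, ",
                        "boundary = %s) has zero density under the supplied ",
                        "parameters"), bad[1], rt[bad[1]],
                 if (as.logical(upper[bad[1]])) "upper" else "lower"),
         call. = FALSE)
  }
  sum(log(d))
}
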