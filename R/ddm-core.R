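#' Specify a two-boundary drift-diffusion process
#'
#' Bundles and validates the parameters of a constant-drift Wiener diffusion
#' between two absorbing boundaries: the lower boundary sits at 0, the upper
#' at `a`, and the accumulator starts at `w * a`. The noise scale `sigma` is
#' fixed at 1 by convention; all drift-side parameters are identified relative
#' to it.
#'
#' @param v Drift rate (evidence units per second). Any finite value.
#' @param a Boundary separation (> 0).
#' @param w Start point as a fraction of `a`, strictly inside (0, 1).
#' @param ndt Non-decision time in seconds (>= 0), added to the first-passage
#'   time to give the observed response time.
#' @param sigma Diffusion noise standard deviation (> 0), default 1.
#'
#' @return An object of class `ddm_spec`: a named list with the five fields.
#' @examples
#' spec <- ddm_spec(v = 1, a = 1.5, w = 0.5, ndt = 0.3)
#' ddm_choice_probability(spec)
#' @export
ddm_spec <- function(v, a, w, ndt = 0, sigma = 1) {
  if (!is.finite(v)) abort("`v` must be finite.", class = "socialddm_domain_error")
  if (!is.finite(a) || a <= 0) abort("`a` must be > 0.", class = "socialddm_domain_error")
  if (!is.finite(w) || w <= 0 || w >= 1) {
    abort("`w` must lie strictly inside (0, 1).", class = "socialddm_domain_error")
  }
  if (!is.finite(ndt) || ndt < 0) abort("`ndt` must be >= 0.", class = "socialddm_domain_error")
  if (!is.finite(sigma) || sigma <= 0) abort("`sigma` must be > 0.", class = "socialddm_domain_error")
  structure(list(v = v, a = a, w = w, ndt = ndt, sigma = sigma), class = "ddm_spec")
}

#' @export
print.ddm_spec <- function(x, ...) {
  cat(sprintf("<ddm_spec> v = %.4g, a = %.4g, w = %.4g, ndt = %.4g, sigma = %.4g\n",
              x$v, x$a, x$w, x$ndt, x$sigma))
  invisible(x)
}

#' Write / read a ddm_spec as JSON
#'
#' Round-trips the five parameters as decimal text with full double precision.
#'
#' @param spec A [ddm_spec()] object.
#' @param path File path to write to / read from.
#' @return `ddm_spec_write()` returns `path` invisibly; `ddm_spec_read()`
#'   returns the reconstructed `ddm_spec`.
#' @export
ddm_spec_write <- function(spec, path) {
  stopifnot(inherits(spec, "ddm_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname ddm_spec_write
#' @export
ddm_spec_read <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ddm_spec(v = x$v, a = x$a, w = x$w, ndt = x$ndt, sigma = x$sigma)
}

#' Probability of absorbing at the upper boundary
#'
#' Closed form for the constant-drift diffusion:
#' \deqn{P(\mathrm{upper}) = \frac{1 - e^{-2 v z / \sigma^2}}{1 - e^{-2 v a / \sigma^2}},
#' \quad z = w a,}
#' with the continuous limit `w` at `v = 0`.
#'
#' @param spec A [ddm_spec()], or a drift value if the remaining parameters are
#'   supplied through `a`, `w`, `sigma` (vectorised over `spec` in that case).
#' @param a,w,sigma Used only when `spec` is numeric.
#' @return Probability (or vector of probabilities) in \[0, 1\].
#' @export
ddm_choice_probability <- function(spec, a = NULL, w = NULL, sigma = 1) {
  if (inherits(spec, "ddm_spec")) {
    v <- spec$v; a <- spec$a; w <- spec$w; sigma <- spec$sigma
  } else {
    v <- spec
    if (is.null(a) || is.null(w)) {
      abort("supply `a` and `w` when `spec` is a numeric drift.",
            class = "socialddm_domain_error")
    }
    if (any(a <= 0) || any(w <= 0) || any(w >= 1) || any(sigma <= 0)) {
      abort("invalid parameters: need a > 0, 0 < w < 1, sigma > 0.",
            class = "socialddm_domain_error")
    }
  }
  k <- 2 * v / sigma^2
  p <- ifelse(abs(k * a) < 1e-9,
              w,  # zero-drift limit, continuous in v
              expm1(-k * w * a) / expm1(-k * a))
  pmin(pmax(p, 0), 1)
}

#' Wiener first-passage-time density
#'
#' Defective density of responding at `boundary` at time `t` (seconds,
#' including non-decision time). Computed with the standard small-time /
#' large-time series for the lower boundary, switching by the expansion that
#' needs fewer terms for truncation error below 1e-7; the upper-boundary
#' density uses the reflection `f_upper(t | v, a, w) = f_lower(t | -v, a, 1-w)`.
#'
#' @param t Response times (s). Values `<= ndt` yield density 0 (`-Inf` in log
#'   mode).
#' @param boundary `"upper"`/`"lower"` (recycled), or a logical vector where
#'   `TRUE` means upper.
#' @param spec A [ddm_spec()] whose parameters apply to every element, unless
#'   overridden by the vectorised arguments `v`, `a`, `w`, `ndt`.
#' @param v,a,w,ndt Optional per-element parameter vectors (recycled).
#' @param log Return the log density?
#' @return Numeric vector of (log) densities, same length as `t`.
#' @export
ddm_wfpt_density <- function(t, boundary, spec = NULL, v = NULL, a = NULL,
                             w = NULL, ndt = NULL, log = FALSE) {
  if (!is.null(spec)) {
    stopifnot(inherits(spec, "ddm_spec"))
    if (is.null(v)) v <- spec$v
    if (is.null(a)) a <- spec$a
    if (is.null(w)) w <- spec$w
    if (is.null(ndt)) ndt <- spec$ndt
    sigma <- spec$sigma
  } else {
    sigma <- 1
    if (is.null(ndt)) ndt <- 0
    if (is.null(v) || is.null(a) || is.null(w)) {
      abort("supply either `spec` or all of `v`, `a`, `w`.",
            class = "socialddm_domain_error")
    }
  }
  if (any(a <= 0) || any(w <= 0) || any(w >= 1) || any(ndt < 0)) {
    abort("invalid parameters: need a > 0, 0 < w < 1, ndt >= 0.",
          class = "socialddm_domain_error")
  }
  upper <- if (is.logical(boundary)) boundary else boundary == "upper"
  n <- length(t)
  ld <- cpp_wfpt_logdensity(as.double(t), rep_len(upper, n),
                            rep_len(as.double(v), n), rep_len(as.double(a), n),
                            rep_len(as.double(w), n), rep_len(as.double(ndt), n),
                            sigma, 1e-7)
  if (log) ld else exp(ld)
}

#' Simulate trials from a diffusion specification
#'
#' Euler–Maruyama integration of the diffusion path with step `dt`; the
#' response time is the first boundary-crossing time plus `ndt`. Paths that do
#' not cross either boundary before `max_time` are returned with
#' `converged = FALSE` and missing outcome, never dropped. Deterministic given
#' `set.seed()`.
#'
#' @param n Number of trials. If `v` is a vector of length `n`, each trial uses
#'   its own drift.
#' @param spec A [ddm_spec()] providing `a`, `w`, `ndt`, `sigma` (and the
#'   default drift).
#' @param v Optional per-trial drift vector overriding `spec$v`.
#' @param dt Integration step (s); 1e-3 is the data-generation default, 1e-4
#'   is used for oracle-grade simulation.
#' @param max_time Give-up horizon (s).
#' @param correct_boundary Apply the Broadie–Glasserman–Kou continuity
#'   correction (thresholds shifted inward by `0.5826 * sigma * sqrt(dt)`),
#'   removing the `O(sqrt(dt))` bias of discrete crossing detection. Default
#'   `TRUE`.
#' @return A tibble with columns `boundary` (`"upper"`/`"lower"`, `NA` if
#'   non-converged), `rt` (s) and `converged`.
#' @examples
#' set.seed(1)
#' ddm_simulate(5, ddm_spec(v = 2, a = 1, w = 0.5, ndt = 0.3))
#' @export
ddm_simulate <- function(n, spec, v = NULL, dt = 1e-3, max_time = 20,
                         correct_boundary = TRUE) {
  stopifnot(inherits(spec, "ddm_spec"))
  if (is.null(v)) v <- spec$v
  v <- rep_len(as.double(v), n)
  sim <- cpp_ddm_simulate(v, spec$a, spec$w, spec$ndt, spec$sigma, dt, max_time,
                          correct_boundary)
  tibble::tibble(
    boundary = c("lower", "upper")[sim$boundary + 1L],
    rt = sim$rt,
    converged = !is.na(sim$boundary)
  )
}

#' Per-trial log-likelihood
#'
#' Log of the first-passage density at the observed boundary and response
#' time. Observations with `rt <= ndt` (or an underflowing density) contribute
#' a large negative floor instead of `-Inf` so optimisers remain stable.
#'
#' @inheritParams ddm_wfpt_density
#' @param rt Observed response times (s), must be > 0.
#' @param floor Lower bound on each trial's log-likelihood contribution.
#' @return Vector of log-densities, floored at `floor`.
#' @export
ddm_trial_loglik <- function(rt, boundary, spec = NULL, v = NULL, a = NULL,
                             w = NULL, ndt = NULL, floor = -1e10) {
  if (any(rt <= 0)) abort("`rt` must be positive.", class = "socialddm_domain_error")
  ld <- ddm_wfpt_density(rt, boundary, spec = spec, v = v, a = a, w = w,
                         ndt = ndt, log = TRUE)
  pmax(ld, floor)
}
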