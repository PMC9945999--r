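#' Fit a normal distribution to sampled vertical energy gaps
#'
#' Within linear response, the Boltzmann distribution of a vertical energy
#' gap sampled along an equilibrated trajectory is Gaussian, and its mean and
#' standard deviation determine the quadratic free-energy surface through
#' [build_sampled_fes()].  The fit is the maximum-likelihood normal fit
#' (sample mean; sample SD with denominator n-1).  Confidence intervals are
#' exact small-sample intervals: Student-t for the mean and chi-square for
#' the standard deviation.
#'
#' @param samples Numeric vector of gap values (eV), length >= 3, nonzero
#'   variance.
#' @param confidence Confidence level in (0, 1); default 0.95.
#' @param axis Which gap the samples measure: `"ES_minus_CS"`,
#'   `"CS_minus_GS"` or `"ES_minus_GS"`.
#' @param trajectory Which state's trajectory was sampled (`"CS"` or `"GS"`).
#' @return Object of class `gap_fit`: `mu`, `sigma`, `n`, `mu_ci`,
#'   `sigma_ci` (each `c(lower, upper)`), `confidence`, `axis`, `trajectory`.
#' @examples
#' fit_gap_distribution(c(0, 1, 2))  # mu = 1, sigma = 1
#' @export
fit_gap_distribution <- function(samples, confidence = 0.95,
                                 axis = c("ES_minus_CS", "CS_minus_GS", "ES_minus_GS"),
                                 trajectory = c("CS", "GS")) {
  axis <- match.arg(axis)
  trajectory <- match.arg(trajectory)
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("'samples' must be finite numeric values", call. = FALSE)
  n <- length(samples)
  if (n < 3L) stop("need at least 3 samples to fit a gap distribution", call. = FALSE)
  .check_scalar(confidence, "confidence")
  if (confidence <= 0 || confidence >= 1)
    stop("'confidence' must lie in (0, 1)", call. = FALSE)
  mu <- mean(samples)
  sigma <- stats::sd(samples)
  if (sigma == 0) stop("zero-variance sample: gap distribution is degenerate",
                       call. = FALSE)
  alpha <- 1 - confidence
  tcrit <- stats::qt(1 - alpha / 2, df = n - 1L)
  mu_ci <- mu + c(-1, 1) * tcrit * sigma / sqrt(n)
  # (n-1) s^2 / sigma^2 ~ chi^2_{n-1}
  sigma_ci <- sigma * sqrt((n - 1L) / stats::qchisq(c(1 - alpha / 2, alpha / 2),
                                                    df = n - 1L))
  structure(list(mu = mu, sigma = sigma, n = n,
                 mu_ci = mu_ci, sigma_ci = sigma_ci,
                 confidence = confidence, axis = axis, trajectory = trajectory),
            class = "gap_fit")
}

#' @export
print.gap_fit <- function(x, ...) {
  cat(sprintf("Gap distribution fit (%s, sampled on %s trajectory)\n",
              x$axis, x$trajectory))
  cat(sprintf("  n = %d\n  mu    = %.5f eV  [%.5f, %.5f]\n  sigma = %.5f eV  [%.5f, %.5f]\n",
              x$n, x$mu, x$mu_ci[1], x$mu_ci[2],
              x$sigma, x$sigma_ci[1], x$sigma_ci[2]))
  invisible(x)
}

# --- quadratic surfaces -----------------------------------------------------

# canonical representation: V(x) = c2 (x - x0)^2 + c1 (x - x0) + c0
.quad_fes <- function(c2, c1, c0, x0, axis, provenance, temperature,
                      sample_range = NULL) {
  if (c2 <= 0) stop("surface curvature must be positive", call. = FALSE)
  structure(list(c2 = c2, c1 = c1, c0 = c0, x0 = x0, axis = axis,
                 provenance = provenance, temperature = temperature,
                 sample_range = sample_range),
            class = "quad_fes")
}

#' Build the quadratic free-energy surface implied by a Gaussian gap fit
#'
#' For a Gaussian gap distribution with mean mu and SD sigma at temperature T,
#' the free-energy surface along the gap coordinate is the parabola
#' \deqn{V(\Delta E) = \frac{kT}{2}\left(\frac{\Delta E - \mu}{\sigma}\right)^2,}
#' with its minimum at mu and V(mu) = 0.
#'
#' @param fit A [fit_gap_distribution()] result (or a list with `mu`,
#'   `sigma`).
#' @param temperature Temperature in kelvin (default 300).
#' @param sample_range Optional `c(lo, hi)` marking the directly sampled
#'   region of the axis (used by `plot` and the extrapolation flag).
#' @return Object of class `quad_fes`.  Evaluate it with [predict.quad_fes()].
#' @examples
#' f <- fit_gap_distribution(rnorm(200, 0.27, 0.18))
#' V <- build_sampled_fes(f, temperature = 300)
#' predict(V, f$mu + f$sigma)  # = kT/2
#' @export
build_sampled_fes <- function(fit, temperature = 300, sample_range = NULL) {
  kT <- .kT(temperature)
  if (!is.list(fit) || is.null(fit$mu) || is.null(fit$sigma))
    stop("'fit' must carry 'mu' and 'sigma'", call. = FALSE)
  if (fit$sigma <= 0) stop("'sigma' must be > 0", call. = FALSE)
  axis <- if (!is.null(fit$axis)) fit$axis else "ES_minus_CS"
  .quad_fes(c2 = kT / (2 * fit$sigma^2), c1 = 0, c0 = 0, x0 = fit$mu,
            axis = axis, provenance = "sampled", temperature = temperature,
            sample_range = sample_range)
}

#' Evaluate a quadratic free-energy surface
#'
#' @param object A `quad_fes`.
#' @param newdata Numeric vector of axis values (eV), or a `data.frame` with
#'   a column `x`.
#' @param ... Unused.
#' @return Numeric vector of free energies (eV).
#' @export
predict.quad_fes <- function(object, newdata, ...) {
  x <- if (is.data.frame(newdata)) newdata$x else newdata
  d <- x - object$x0
  object$c2 * d^2 + object$c1 * d + object$c0
}

#' Location and value of the minimum of a quadratic surface
#'
#' @param fes A `quad_fes`.
#' @return Named numeric `c(x = <axis location>, V = <free energy>)`, eV.
#' @export
fes_minimum <- function(fes) {
  stopifnot(inherits(fes, "quad_fes"))
  xm <- fes$x0 - fes$c1 / (2 * fes$c2)
  c(x = xm, V = fes$c0 - fes$c1^2 / (4 * fes$c2))
}

#' @export
print.quad_fes <- function(x, ...) {
  m <- fes_minimum(x)
  cat(sprintf("Quadratic FES [%s, %s] at %g K\n", x$axis, x$provenance,
              x$temperature))
  cat(sprintf("  curvature 2*c2 = %.5f eV^-1; minimum at x = %.5f eV, V = %.5f eV\n",
              2 * x$c2, m["x"], m["V"]))
  invisible(x)
}

#' Companion excited-state surface on the same gap axis
#'
#' Given the charge-separated-state surface as a function of the gap
#' \eqn{\Delta E = E_{ES} - E_{CS}}, the excited-state surface on the same
#' axis is obtained by adding the gap itself:
#' \eqn{V_{ES}(\Delta E) = V_{CS}(\Delta E) + \Delta E}.  For a sampled
#' parabola with mean mu and SD sigma this places the ES minimum at
#' \eqn{\mu - \sigma^2/kT} and yields the closed forms
#' \eqn{\lambda = \sigma^2/(2kT)} and \eqn{\Delta A = \sigma^2/(2kT) - \mu}.
#'
#' @param fes A `quad_fes` on the `ES_minus_CS` axis.
#' @return A `quad_fes` (provenance `"companion"`) on the same axis.
#' @export
companion_surface <- function(fes) {
  stopifnot(inherits(fes, "quad_fes"))
  if (fes$axis != "ES_minus_CS")
    stop("companion construction requires a surface on the ES_minus_CS axis",
         call. = FALSE)
  # V(x) + x = c2 (x-x0)^2 + (c1+1)(x-x0) + (c0 + x0)
  .quad_fes(c2 = fes$c2, c1 = fes$c1 + 1, c0 = fes$c0 + fes$x0, x0 = fes$x0,
            axis = fes$axis, provenance = "companion",
            temperature = fes$temperature, sample_range = fes$sample_range)
}

#' Fit the linear relation between two energy gaps
#'
#' Around the ground-state minimum the gap \eqn{y = E_{ES} - E_{CS}}
#' correlates linearly with \eqn{x = E_{CS} - E_{GS}}; fitting y = a x + b by
#' ordinary least squares lets the excited-state surface be defined relative
#' to the charge-separated surface on the x axis (see
#' [crossfit_es_surface()]).
#'
#' @param x_samples,y_samples Equal-length numeric vectors (eV), length >= 3.
#' @param confidence Confidence level for the parameter intervals.
#' @return Object of class `gap_relation`: `slope_a`, `intercept_b`,
#'   `residual_sd`, `r_value`, `a_ci`, `b_ci`, `n`, `confidence`.
#' @export
fit_gap_relation <- function(x_samples, y_samples, confidence = 0.95) {
  if (length(x_samples) != length(y_samples))
    stop("'x_samples' and 'y_samples' must have equal length", call. = FALSE)
  if (length(x_samples) < 3L) stop("need at least 3 points", call. = FALSE)
  if (any(!is.finite(x_samples)) || any(!is.finite(y_samples)))
    stop("gap samples must be finite", call. = FALSE)
  if (stats::sd(x_samples) == 0)
    stop("degenerate x sample (zero variance): cannot fit a slope", call. = FALSE)
  fit <- stats::lm(y ~ x, data = data.frame(x = x_samples, y = y_samples))
  ci <- stats::confint(fit, level = confidence)
  co <- stats::coef(fit)
  structure(list(slope_a = unname(co["x"]), intercept_b = unname(co["(Intercept)"]),
                 residual_sd = stats::sigma(fit),
                 r_value = stats::cor(x_samples, y_samples),
                 a_ci = unname(ci["x", ]), b_ci = unname(ci["(Intercept)", ]),
                 n = length(x_samples), confidence = confidence, lm = fit),
            class = "gap_relation")
}

#' @export
print.gap_relation <- function(x, ...) {
  cat(sprintf("Linear gap relation y = a x + b (n = %d, r = %.3f)\n", x$n, x$r_value))
  cat(sprintf("  a = %.5f  [%.5f, %.5f]\n  b = %.5f eV  [%.5f, %.5f]\n  residual SD = %.5f eV\n",
              x$slope_a, x$a_ci[1], x$a_ci[2],
              x$intercept_b, x$b_ci[1], x$b_ci[2], x$residual_sd))
  invisible(x)
}

#' Cross-fit excited-state surface from the linear gap relation
#'
#' With the charge-separated surface \eqn{V_{CS}} expressed on the
#' \eqn{x = E_{CS} - E_{GS}} axis and the fitted relation
#' \eqn{y = a x + b} for \eqn{y = E_{ES} - E_{CS}}, the excited-state surface
#' on the same axis is \eqn{V_{ES}(x) = V_{CS}(x) + a x + b}.  When a != 0
#' the surface is also re-expressed as a function of the gap
#' \eqn{\Delta E = a x + b} itself.
#'
#' @param cs_fes_on_gs_axis A sampled `quad_fes` on the `CS_minus_GS` axis.
#' @param relation A [fit_gap_relation()] result fitted on that axis.
#' @return A `quad_fes` (provenance `"crossfit"`, axis `CS_minus_GS`) with
#'   attribute fields `reexpressed` (a `quad_fes` on the `ES_minus_CS` axis,
#'   or `NULL`) and `reexpress_failed` (`TRUE` when a == 0).
#' @export
crossfit_es_surface <- function(cs_fes_on_gs_axis, relation) {
  fes <- cs_fes_on_gs_axis
  stopifnot(inherits(fes, "quad_fes"), inherits(relation, "gap_relation"))
  if (fes$axis != "CS_minus_GS")
    stop("cross-fit requires the CS surface on the CS_minus_GS axis", call. = FALSE)
  a <- relation$slope_a; b <- relation$intercept_b
  # a x + b = a (x - x0) + (a x0 + b)
  es <- .quad_fes(c2 = fes$c2, c1 = fes$c1 + a, c0 = fes$c0 + a * fes$x0 + b,
                  x0 = fes$x0, axis = fes$axis, provenance = "crossfit",
                  temperature = fes$temperature, sample_range = fes$sample_range)
  if (a == 0) {
    es$reexpressed <- NULL
    es$reexpress_failed <- TRUE
    return(es)
  }
  # substitute x = (u - b)/a with u = a x + b (= E_ES - E_CS):
  # x - x0 = (u - u0)/a, u0 = a x0 + b
  u0 <- a * fes$x0 + b
  re <- .quad_fes(c2 = es$c2 / a^2, c1 = es$c1 / a, c0 = es$c0, x0 = u0,
                  axis = "ES_minus_CS", provenance = "crossfit",
                  temperature = fes$temperature,
                  sample_range = if (!is.null(fes$sample_range))
                    sort(a * fes$sample_range + b) else NULL)
  es$reexpressed <- re
  es$reexpress_failed <- FALSE
  es
}

#' Marcus parameters and crossing point of a surface pair
#'
#' Given the excited-state (donor) and charge-separated (acceptor) surfaces
#' on a common axis, computes the driving force
#' \eqn{\Delta A = V_{CS}(x^{CS}_{min}) - V_{ES}(x^{ES}_{min})} (positive
#' when the charge-separated minimum lies above the excited-state minimum,
#' i.e. uphill charge separation), the reorganization energy
#' \eqn{\lambda = V_{CS}(x^{ES}_{min}) - V_{CS}(x^{CS}_{min})}, the crossing
#' point of the two surfaces (preferring a root between the two minima, then
#' the lower-energy root) reported as height above the ES minimum, and the
#' Marcus region (inverted iff \eqn{-\Delta A > \lambda}).
#'
#' @param es,cs `quad_fes` objects on the same axis.
#' @return Object of class `surface_pair_summary`: `delta_A`, `lambda_reorg`,
#'   `crossing_energy_above_ES_min` (`NA` if the surfaces never cross),
#'   `crossing_x`, `marcus_region`.
#' @export
summarize_surface_pair <- function(es, cs) {
  stopifnot(inherits(es, "quad_fes"), inherits(cs, "quad_fes"))
  if (es$axis != cs$axis)
    stop("surfaces must share a common axis", call. = FALSE)
  m_es <- fes_minimum(es); m_cs <- fes_minimum(cs)
  delta_A <- unname(m_cs["V"] - m_es["V"])
  lambda <- unname(predict(cs, m_es["x"]) - m_cs["V"])
  # V_ES - V_CS as A x^2 + B x + C (expanded about 0)
  A <- es$c2 - cs$c2
  B <- (-2 * es$c2 * es$x0 + es$c1) - (-2 * cs$c2 * cs$x0 + cs$c1)
  C <- (es$c2 * es$x0^2 - es$c1 * es$x0 + es$c0) -
       (cs$c2 * cs$x0^2 - cs$c1 * cs$x0 + cs$c0)
  roots <- .real_roots(A, B, C)
  crossing_x <- NA_real_; crossing <- NA_real_
  if (length(roots) == 1L && is.infinite(roots)) {   # identical surfaces
    crossing_x <- unname(m_es["x"]); crossing <- 0
  } else if (length(roots)) {
    lo <- min(m_es["x"], m_cs["x"]); hi <- max(m_es["x"], m_cs["x"])
    between <- roots[roots >= lo - 1e-12 & roots <= hi + 1e-12]
    pick <- if (length(between)) {
      if (length(between) == 1L) between
      else between[which.min(predict(es, between))]
    } else roots[which.min(predict(es, roots))]
    crossing_x <- pick
    crossing <- unname(predict(es, pick) - m_es["V"])
  }
  region <- if (-delta_A > lambda) "inverted" else "normal"
  structure(list(delta_A = delta_A, lambda_reorg = lambda,
                 crossing_energy_above_ES_min = crossing,
                 crossing_x = crossing_x, marcus_region = region,
                 axis = es$axis),
            class = "surface_pair_summary")
}

# real roots of A x^2 + B x + C; returns numeric(0) if none, Inf-length
# sentinel (Inf) if identically zero
.real_roots <- function(A, B, C, tol = 1e-14) {
  if (abs(A) < tol) {
    if (abs(B) < tol) {
      if (abs(C) < tol) return(Inf)
      return(numeric(0))
    }
    return(-C / B)
  }
  disc <- B^2 - 4 * A * C
  if (disc < 0) return(numeric(0))
  s <- sqrt(disc)
  sort(c((-B - s) / (2 * A), (-B + s) / (2 * A)))
}

#' @export
print.surface_pair_summary <- function(x, ...) {
  cat(sprintf("Surface pair on %s axis (%s Marcus region)\n", x$axis, x$marcus_region))
  cat(sprintf("  Delta A = %.5f eV\n  lambda  = %.5f eV\n", x$delta_A, x$lambda_reorg))
  if (is.na(x$crossing_energy_above_ES_min)) cat("  surfaces do not cross\n")
  else cat(sprintf("  crossing %.5f eV above the ES minimum (at x = %.5f eV)\n",
                   x$crossing_energy_above_ES_min, x$crossing_x))
  invisible(x)
}

#' Propagate parameter confidence intervals through a derived quantity
#'
#' Evaluates a derived quantity over the Cartesian product of the lower
#' bound, point estimate and upper bound of every input parameter and returns
#' the min/max envelope — the "full range of values produced by the
#' confidence intervals" convention.  A corner at which the evaluator fails
#' is recorded, not silently dropped.
#'
#' @param params Named list; each element is `list(point =, ci = c(lo, hi))`.
#' @param evaluator Function called with one named scalar argument per
#'   parameter; must return a single finite number.
#' @return List with `lower`, `upper`, `point` (evaluator at the point
#'   estimates), `n_corners`, and `failed` (a character vector describing any
#'   failing corners, empty when all succeeded).
#' @examples
#' kT <- physical_constants()$kB_eV * 300
#' propagate_uncertainty(
#'   list(sigma = list(point = 0.18, ci = c(0.17, 0.20))),
#'   function(sigma) sigma^2 / (2 * kT))
#' @export
propagate_uncertainty <- function(params, evaluator) {
  stopifnot(is.list(params), length(params) >= 1L, !is.null(names(params)),
            all(nzchar(names(params))), is.function(evaluator))
  levels <- lapply(params, function(p) {
    if (is.null(p$point) || is.null(p$ci) || length(p$ci) != 2L)
      stop("each parameter needs 'point' and a length-2 'ci'", call. = FALSE)
    if (p$ci[1] > p$point || p$point > p$ci[2])
      stop("confidence interval must bracket the point estimate", call. = FALSE)
    unique(c(p$ci[1], p$point, p$ci[2]))
  })
  grid <- expand.grid(levels, KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  names(grid) <- names(params)
  vals <- rep(NA_real_, nrow(grid))
  failed <- character(0)
  for (i in seq_len(nrow(grid))) {
    res <- tryCatch(do.call(evaluator, as.list(grid[i, , drop = FALSE])),
                    error = function(e) e)
    if (inherits(res, "error") || !is.finite(res)) {
      failed <- c(failed, sprintf("corner %d (%s): %s", i,
                                  paste(sprintf("%s=%.6g", names(grid),
                                                unlist(grid[i, ])), collapse = ", "),
                                  if (inherits(res, "error")) conditionMessage(res)
                                  else "non-finite result"))
    } else vals[i] <- res
  }
  if (all(is.na(vals))) stop("evaluator failed at every corner", call. = FALSE)
  point <- do.call(evaluator, lapply(params, `[[`, "point"))
  list(lower = min(vals, na.rm = TRUE), upper = max(vals, na.rm = TRUE),
       point = point, n_corners = nrow(grid), failed = failed)
}
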