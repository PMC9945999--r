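#' Fit free-energy surfaces to a trajectory energy table
#'
#' The central model-fitting function of the package.  Given a per-frame
#' energy table (columns `frame`, `E_GS_eV`, `E_CS_eV`, `E_ES_eV`), it
#' reconstructs the quadratic free-energy surfaces of the charge-separated
#' (CS) and photoexcited (ES) states of a chromophore pair along the vertical
#' energy-gap coordinate, extracts the Marcus parameters (reorganization
#' energy lambda and driving force Delta A), locates the surface crossing,
#' and propagates the confidence intervals on the fitted statistical
#' parameters into envelopes on lambda and Delta A by a full corner scan.
#'
#' Two constructions are available, matching the two trajectories that can be
#' sampled:
#' \describe{
#'   \item{`trajectory = "cs"`}{The gap \eqn{\Delta E = E_{ES} - E_{CS}} is
#'     fitted to a normal distribution; the CS surface is the implied
#'     parabola and the ES surface is the companion surface
#'     \eqn{V_{ES} = V_{CS} + \Delta E} on the same axis.}
#'   \item{`trajectory = "gs"`}{The gap \eqn{x = E_{CS} - E_{GS}} is fitted
#'     to a normal distribution and the linear relation between
#'     \eqn{y = E_{ES} - E_{CS}} and x is fitted by least squares; the ES
#'     surface is the cross-fit \eqn{V_{ES}(x) = V_{CS}(x) + a x + b}.  This
#'     distribution describes the thermal geometry ensemble immediately
#'     after photoexcitation, so the resulting parameters are the
#'     "initial-rate" set.}
#' }
#'
#' @param table Energy table `data.frame` (or a CSV path); see
#'   [validate_energy_table()] for the schema.
#' @param trajectory `"cs"` or `"gs"` — which state's trajectory the table
#'   samples.
#' @param temperature Kelvin; default 300.
#' @param confidence Confidence level for all intervals; default 0.95.
#' @return Object of class `fes_fit` with components `gap_fit`, `relation`
#'   (`"gs"` only), `surfaces` (list `cs`, `es`), `pair`
#'   (a [summarize_surface_pair()] result), `envelopes` (lists with `lower`,
#'   `upper` for `lambda` and `delta_A`), `sample_range` (2.5-97.5% sample
#'   quantiles of the fitted axis), `extrapolated` (TRUE when a surface
#'   minimum lies outside the sampled range), and the call parameters.
#'   Methods: `print`, `summary`, `coef`, `predict`, `plot`, `simulate`,
#'   `residuals` (the `"gs"` relation residuals).
#' @examples
#' tab <- generate_cs_trajectory(gap_model_spec(n_frames = 300, seed = 11))
#' fit <- fes_fit(tab, trajectory = "cs")
#' coef(fit)[c("lambda", "delta_A")]
#' @export
fes_fit <- function(table, trajectory = c("cs", "gs"), temperature = 300,
                    confidence = 0.95) {
  trajectory <- match.arg(trajectory)
  table <- validate_energy_table(table)
  kT <- .kT(temperature)

  if (trajectory == "cs") {
    de <- table$E_ES_eV - table$E_CS_eV
    gfit <- fit_gap_distribution(de, confidence, axis = "ES_minus_CS",
                                 trajectory = "CS")
    srange <- unname(stats::quantile(de, c(0.025, 0.975)))
    cs <- build_sampled_fes(gfit, temperature, sample_range = srange)
    es <- companion_surface(cs)
    relation <- NULL
    params <- list(mu = list(point = gfit$mu, ci = gfit$mu_ci),
                   sigma = list(point = gfit$sigma, ci = gfit$sigma_ci))
    eval_pair <- function(mu, sigma) {
      s <- build_sampled_fes(list(mu = mu, sigma = sigma, axis = "ES_minus_CS"),
                             temperature)
      summarize_surface_pair(companion_surface(s), s)
    }
  } else {
    x <- table$E_CS_eV - table$E_GS_eV
    y <- table$E_ES_eV - table$E_CS_eV
    gfit <- fit_gap_distribution(x, confidence, axis = "CS_minus_GS",
                                 trajectory = "GS")
    relation <- fit_gap_relation(x, y, confidence)
    srange <- unname(stats::quantile(x, c(0.025, 0.975)))
    cs <- build_sampled_fes(gfit, temperature, sample_range = srange)
    es <- crossfit_es_surface(cs, relation)
    params <- list(mu = list(point = gfit$mu, ci = gfit$mu_ci),
                   sigma = list(point = gfit$sigma, ci = gfit$sigma_ci),
                   a = list(point = relation$slope_a, ci = relation$a_ci),
                   b = list(point = relation$intercept_b, ci = relation$b_ci))
    eval_pair <- function(mu, sigma, a, b) {
      s <- build_sampled_fes(list(mu = mu, sigma = sigma, axis = "CS_minus_GS"),
                             temperature)
      rel <- structure(list(slope_a = a, intercept_b = b), class = "gap_relation")
      summarize_surface_pair(crossfit_es_surface(s, rel), s)
    }
  }

  pair <- summarize_surface_pair(es, cs)
  env_lambda <- propagate_uncertainty(params, function(...)
    eval_pair(...)$lambda_reorg)
  env_dA <- propagate_uncertainty(params, function(...)
    eval_pair(...)$delta_A)

  mins <- c(fes_minimum(cs)["x"], fes_minimum(es)["x"])
  extrapolated <- any(mins < srange[1] | mins > srange[2])

  structure(list(trajectory = trajectory, temperature = temperature,
                 confidence = confidence, n = nrow(table),
                 gap_fit = gfit, relation = relation,
                 surfaces = list(cs = cs, es = es), pair = pair,
                 envelopes = list(lambda = env_lambda, delta_A = env_dA),
                 sample_range = srange, extrapolated = extrapolated),
            class = "fes_fit")
}

#' @export
print.fes_fit <- function(x, ...) {
  cat(sprintf("Free-energy surface fit (%s trajectory, %d frames, %g K)\n",
              toupper(x$trajectory), x$n, x$temperature))
  cat(sprintf("  gap mu = %.4f eV, sigma = %.4f eV\n", x$gap_fit$mu, x$gap_fit$sigma))
  cat(sprintf("  lambda  = %.4f eV  [%.4f, %.4f]\n", x$pair$lambda_reorg,
              x$envelopes$lambda$lower, x$envelopes$lambda$upper))
  cat(sprintf("  Delta A = %.4f eV  [%.4f, %.4f]\n", x$pair$delta_A,
              x$envelopes$delta_A$lower, x$envelopes$delta_A$upper))
  cat(sprintf("  Marcus region: %s%s\n", x$pair$marcus_region,
              if (x$extrapolated) "  (minimum outside sampled region)" else ""))
  invisible(x)
}

#' @export
coef.fes_fit <- function(object, ...) {
  c(mu = object$gap_fit$mu, sigma = object$gap_fit$sigma,
    lambda = object$pair$lambda_reorg, delta_A = object$pair$delta_A,
    crossing = object$pair$crossing_energy_above_ES_min)
}

#' @export
summary.fes_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.fes_fit")
}

#' @export
print.summary.fes_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat(sprintf("  %d%% CI on mu:    [%.4f, %.4f] eV\n", round(100 * f$confidence),
              f$gap_fit$mu_ci[1], f$gap_fit$mu_ci[2]))
  cat(sprintf("  %d%% CI on sigma: [%.4f, %.4f] eV\n", round(100 * f$confidence),
              f$gap_fit$sigma_ci[1], f$gap_fit$sigma_ci[2]))
  if (!is.null(f$relation)) print(f$relation)
  if (!is.na(f$pair$crossing_energy_above_ES_min))
    cat(sprintf("  crossing %.4f eV above the ES minimum\n",
                f$pair$crossing_energy_above_ES_min))
  cat(sprintf("  sampled region (2.5-97.5%%): [%.4f, %.4f] eV\n",
              f$sample_range[1], f$sample_range[2]))
  invisible(x)
}

#' @export
predict.fes_fit <- function(object, newdata,
                            surface = c("cs", "es"), ...) {
  surface <- match.arg(surface)
  predict(object$surfaces[[surface]], newdata)
}

#' @export
residuals.fes_fit <- function(object, ...) {
  if (is.null(object$relation))
    stop("residuals are defined only for the 'gs' (cross-fit) construction",
         call. = FALSE)
  stats::residuals(object$relation$lm)
}

#' Simulate a new energy table from a fitted surface model
#'
#' Parametric simulation: draws a fresh table of the same size from the
#' fitted gap distribution (and, for the `"gs"` construction, the fitted
#' linear gap relation with its residual SD).
#'
#' @param object A `fes_fit`.
#' @param nsim Number of tables to simulate.
#' @param seed Integer seed.
#' @param ... Unused.
#' @return A list of `nsim` energy-table `data.frame`s.
#' @export
simulate.fes_fit <- function(object, nsim = 1, seed = 1L, ...) {
  spec_args <- list(n_frames = object$n, seed = as.integer(seed))
  lapply(seq_len(nsim), function(i) {
    spec_args$seed <- as.integer(seed) + i - 1L
    if (object$trajectory == "cs") {
      sp <- do.call(gap_model_spec, c(spec_args, list(
        mu_cs = object$gap_fit$mu, sigma_cs = object$gap_fit$sigma)))
      generate_cs_trajectory(sp)
    } else {
      sp <- do.call(gap_model_spec, c(spec_args, list(
        mu_gs_axis = object$gap_fit$mu, sigma_gs_axis = object$gap_fit$sigma,
        slope_a = object$relation$slope_a,
        intercept_b = object$relation$intercept_b,
        resid_sd = object$relation$residual_sd)))
      generate_gs_trajectory(sp)
    }
  })
}

#' Plot fitted free-energy surfaces
#'
#' Draws the CS and ES parabolas over a window around the two minima, with
#' the directly sampled region of the axis drawn as a thicker line.
#'
#' @param x A `fes_fit`.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.fes_fit <- function(x, ...) {
  cs <- x$surfaces$cs; es <- x$surfaces$es
  m_cs <- fes_minimum(cs); m_es <- fes_minimum(es)
  span <- max(abs(m_es["x"] - m_cs["x"]), 4 * x$gap_fit$sigma)
  grid <- seq(min(m_cs["x"], m_es["x"]) - 0.6 * span,
              max(m_cs["x"], m_es["x"]) + 0.6 * span, length.out = 400)
  v_cs <- predict(cs, grid); v_es <- predict(es, grid)
  graphics::plot(grid, v_cs, type = "l", col = "firebrick", lwd = 1,
                 xlab = sprintf("%s gap (eV)", cs$axis),
                 ylab = "free energy (eV)",
                 ylim = range(c(v_cs, v_es)), ...)
  graphics::lines(grid, v_es, col = "steelblue", lwd = 1)
  sr <- x$sample_range
  inside <- grid >= sr[1] & grid <= sr[2]
  graphics::lines(grid[inside], v_cs[inside], col = "firebrick", lwd = 3)
  graphics::lines(grid[inside], v_es[inside], col = "steelblue", lwd = 3)
  graphics::legend("top", legend = c("CS", "ES"), lwd = 2,
                   col = c("firebrick", "steelblue"), bty = "n", horiz = TRUE)
  invisible(x)
}
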