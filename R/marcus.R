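#' Marcus-theory electron-transfer rate constant
#'
#' Evaluates the nonadiabatic Marcus rate
#' \deqn{k = \frac{2\pi}{\hbar}\,|H_{AB}|^2\,
#'       \frac{1}{\sqrt{4\pi\lambda k_B T}}\,
#'       \exp\!\left(-\frac{(\lambda+\Delta A)^2}{4\lambda k_B T}\right)}
#' with all energies in eV, and reports the rate in ns^-1.  Delta A follows
#' the convention that positive values mean the acceptor (charge-separated)
#' minimum lies above the donor (excited-state) minimum; the process is in
#' the inverted region when \eqn{-\Delta A > \lambda}.
#'
#' @param coupling Electronic coupling |H_AB| (eV), >= 0.
#' @param lambda_reorg Reorganization energy lambda (eV), > 0.
#' @param delta_A Free-energy difference Delta A (eV).
#' @param temperature Kelvin; default 300.
#' @param bounds Optional named list giving confidence intervals to propagate
#'   into rate bounds, e.g. `list(lambda_reorg = c(0.63, 0.71), delta_A =
#'   c(0.38, 0.39))`; any subset of `coupling`, `lambda_reorg`, `delta_A`
#'   may be supplied.  The envelope is the joint corner scan.
#' @return Object of class `marcus_rate`: `k` (ns^-1), `k_bounds`
#'   (`c(lower, upper)` ns^-1 or `NULL`), `region`, and the inputs.
#' @examples
#' marcus_rate(0.115, 0.66, 0.39)        # ~0.026 ns^-1, rounds to 0.03
#' marcus_rate(0.115, 0.66, 0.39,
#'             bounds = list(lambda_reorg = c(0.63, 0.71),
#'                           delta_A = c(0.38, 0.39)))
#' @export
marcus_rate <- function(coupling, lambda_reorg, delta_A, temperature = 300,
                        bounds = NULL) {
  .check_scalar(coupling, "coupling", nonneg = TRUE)
  .check_scalar(lambda_reorg, "lambda_reorg", positive = TRUE)
  .check_scalar(delta_A, "delta_A")
  kT <- .kT(temperature)
  k <- .marcus_k_ns(coupling, lambda_reorg, delta_A, kT)
  k_bounds <- NULL
  if (!is.null(bounds)) {
    pts <- list(coupling = coupling, lambda_reorg = lambda_reorg,
                delta_A = delta_A)
    unknown <- setdiff(names(bounds), names(pts))
    if (length(unknown))
      stop(sprintf("unknown bound parameter(s): %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    params <- lapply(names(pts), function(nm) {
      ci <- if (nm %in% names(bounds)) bounds[[nm]] else rep(pts[[nm]], 2L)
      list(point = pts[[nm]], ci = ci)
    })
    names(params) <- names(pts)
    env <- propagate_uncertainty(params, function(coupling, lambda_reorg, delta_A)
      .marcus_k_ns(coupling, lambda_reorg, delta_A, kT))
    k_bounds <- c(env$lower, env$upper)
  }
  region <- if (-delta_A > lambda_reorg) "inverted" else "normal"
  structure(list(k = k, k_bounds = k_bounds, region = region,
                 coupling = coupling, lambda_reorg = lambda_reorg,
                 delta_A = delta_A, temperature = temperature),
            class = "marcus_rate")
}

# core formula, rate in ns^-1
.marcus_k_ns <- function(H, lambda, dA, kT) {
  const <- physical_constants()
  k_s <- (2 * pi / const$hbar_eVs) * H^2 / sqrt(4 * pi * lambda * kT) *
    exp(-(lambda + dA)^2 / (4 * lambda * kT))
  k_s * 1e-9
}

#' @export
print.marcus_rate <- function(x, ...) {
  cat(sprintf("Marcus rate: k = %s ns^-1 (%.6g ns^-1), %s region\n",
              format(signif(x$k, 1)), x$k, x$region))
  if (!is.null(x$k_bounds))
    cat(sprintf("  envelope: [%s, %s] ns^-1\n",
                format(signif(x$k_bounds[1], 1)), format(signif(x$k_bounds[2], 1))))
  cat(sprintf("  H = %g eV, lambda = %g eV, Delta A = %g eV, T = %g K\n",
              x$coupling, x$lambda_reorg, x$delta_A, x$temperature))
  invisible(x)
}

#' Initial (pre-relaxation) charge-separation rate
#'
#' The Marcus expression assumes the donor ensemble has relaxed to its new
#' equilibrium geometry.  Immediately after photoexcitation the geometry
#' distribution is still the ground-state thermal one; substituting the
#' reorganization energy and driving force derived from that distribution
#' gives an estimate of the initial rate.  This is the same formula as
#' [marcus_rate()] with substituted parameters and is documented as the
#' pre-relaxation estimate only.
#'
#' @inheritParams marcus_rate
#' @return A `marcus_rate` object.
#' @export
initial_rate <- function(coupling, lambda_reorg, delta_A, temperature = 300,
                         bounds = NULL) {
  marcus_rate(coupling, lambda_reorg, delta_A, temperature, bounds)
}

#' Orbital-energy decay constant of the coupling
#'
#' At long range the donor-acceptor coupling decays as exp(-n R), where the
#' decay constant follows from the asymptotic form of a Slater orbital:
#' n = sqrt(-2 epsilon) in atomic units, with epsilon the (negative) energy
#' of the shallowest occupied orbital.  By Koopmans' theorem -epsilon is the
#' ionization energy.
#'
#' @param epsilon_orbital Orbital energy in eV; must be negative.
#' @return Decay constant n in inverse angstroms.
#' @examples
#' coupling_decay_constant(-6.5)   # ~1.3 for chlorophyll
#' @export
coupling_decay_constant <- function(epsilon_orbital) {
  .check_scalar(epsilon_orbital, "epsilon_orbital")
  if (epsilon_orbital >= 0)
    stop("'epsilon_orbital' must be negative (a bound orbital)", call. = FALSE)
  const <- physical_constants()
  eps_ha <- epsilon_orbital / const$hartree_eV
  n_bohr <- sqrt(-2 * eps_ha)
  n_bohr / const$bohr_A
}

#' Coupling at a given separation under exponential decay
#'
#' \eqn{H(R) = H_{ref} \exp(-n (R - R_{ref}))}.
#'
#' @param reference_coupling Coupling at the reference distance (eV).
#' @param reference_distance Reference Mg-Mg distance (Angstrom).
#' @param n_decay Decay constant (Angstrom^-1), > 0.
#' @param R Target distance (Angstrom), > 0.
#' @return Coupling at R (eV).
#' @export
coupling_at_distance <- function(reference_coupling, reference_distance,
                                 n_decay, R) {
  .check_scalar(reference_coupling, "reference_coupling", nonneg = TRUE)
  .check_scalar(reference_distance, "reference_distance", positive = TRUE)
  .check_scalar(n_decay, "n_decay", positive = TRUE)
  if (!is.numeric(R) || any(!is.finite(R)) || any(R <= 0))
    stop("'R' must be positive", call. = FALSE)
  reference_coupling * exp(-n_decay * (R - reference_distance))
}

#' Charge-separation rate as a function of separation
#'
#' Combines a per-distance table of Marcus parameters with the exponential
#' coupling decay to give the rate profile k(R).  The coupling at each
#' distance is scaled from the reference value by [coupling_at_distance()].
#'
#' @param table `data.frame` with columns `distance` (Angstrom, sorted
#'   ascending), `lambda_reorg` (eV, > 0) and `delta_A` (eV).
#' @param reference_coupling Coupling at `reference_distance` (eV).
#' @param reference_distance Angstrom.
#' @param n_decay Decay constant (Angstrom^-1).
#' @param temperature Kelvin.
#' @return The input table with added columns `coupling` (eV) and `k_ns`
#'   (ns^-1).
#' @export
rate_distance_profile <- function(table, reference_coupling,
                                  reference_distance, n_decay,
                                  temperature = 300) {
  stopifnot(is.data.frame(table))
  required <- c("distance", "lambda_reorg", "delta_A")
  missing <- setdiff(required, names(table))
  if (length(missing))
    stop(sprintf("profile table is missing column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (nrow(table) == 0L) stop("profile table has no rows", call. = FALSE)
  for (col in required) {
    bad <- which(!is.finite(table[[col]]))
    if (length(bad))
      stop(sprintf("missing/non-finite %s at distance row %d", col, bad[1L]),
           call. = FALSE)
  }
  if (is.unsorted(table$distance, strictly = TRUE))
    stop("distances must be sorted strictly ascending", call. = FALSE)
  if (any(table$lambda_reorg <= 0))
    stop("every row must have lambda_reorg > 0", call. = FALSE)
  table$coupling <- coupling_at_distance(reference_coupling,
                                         reference_distance, n_decay,
                                         table$distance)
  kT <- .kT(temperature)
  table$k_ns <- mapply(function(H, l, d) .marcus_k_ns(H, l, d, kT),
                       table$coupling, table$lambda_reorg, table$delta_A)
  table
}

#' Branching fraction of charge separation against fluorescence
#'
#' The fraction of excited pairs that decay by charge separation when charge
#' separation (rate k_cs) competes with fluorescence (rate k_f):
#' k_cs / (k_cs + k_f).
#'
#' @param k_cs,k_f Rates in the same units, both >= 0, not both zero.
#' @return Fraction in [0, 1].
#' @examples
#' branching_fraction(0.03, 0.2)   # charge separation loses at 10 A
#' @export
branching_fraction <- function(k_cs, k_f) {
  .check_scalar(k_cs, "k_cs", nonneg = TRUE)
  .check_scalar(k_f, "k_f", nonneg = TRUE)
  if (k_cs == 0 && k_f == 0)
    stop("at least one of 'k_cs', 'k_f' must be positive", call. = FALSE)
  k_cs / (k_cs + k_f)
}

#' Pick a coupling value from a sampled distribution
#'
#' The orientation dependence of the coupling produces a broad sample of
#' values per trajectory; the analysis needs one representative number.  The
#' default, `"max"`, is the most optimistic choice (appropriate for a
#' feasibility bound); `"mean"` and `"median"` are offered as alternatives.
#'
#' @param couplings Numeric vector of coupling magnitudes (eV).
#' @param policy `"max"`, `"mean"` or `"median"`.
#' @return A single coupling value (eV).
#' @export
select_coupling <- function(couplings, policy = c("max", "mean", "median")) {
  policy <- match.arg(policy)
  if (!is.numeric(couplings) || !length(couplings) || any(!is.finite(couplings)))
    stop("'couplings' must be a nonempty finite numeric vector", call. = FALSE)
  switch(policy, max = max(couplings), mean = mean(couplings),
         median = stats::median(couplings))
}

#' Marcus-rate envelope from a fitted surface model
#'
#' Propagates the confidence intervals on the statistical parameters of a
#' [fes_fit()] (the gap-distribution mu and sigma, plus the linear-relation
#' slope and intercept for the cross-fit construction) into bounds on the
#' Marcus rate, by evaluating the full surface-pair construction and Eq.-1
#' rate at every corner of the parameter box.  Because lambda and Delta A
#' are both functions of sigma, this joint scan is tighter than combining
#' their individual envelopes as if independent.
#'
#' @param fit A `fes_fit`.
#' @param coupling Electronic coupling |H_AB| (eV).
#' @return `c(lower, upper)` rate bounds in ns^-1.
#' @export
marcus_rate_envelope <- function(fit, coupling) {
  stopifnot(inherits(fit, "fes_fit"))
  .check_scalar(coupling, "coupling", nonneg = TRUE)
  kT <- .kT(fit$temperature)
  g <- fit$gap_fit
  if (fit$trajectory == "cs") {
    params <- list(mu = list(point = g$mu, ci = g$mu_ci),
                   sigma = list(point = g$sigma, ci = g$sigma_ci))
    evalr <- function(mu, sigma) {
      lambda <- sigma^2 / (2 * kT)
      .marcus_k_ns(coupling, lambda, lambda - mu, kT)
    }
  } else {
    r <- fit$relation
    params <- list(mu = list(point = g$mu, ci = g$mu_ci),
                   sigma = list(point = g$sigma, ci = g$sigma_ci),
                   a = list(point = r$slope_a, ci = r$a_ci),
                   b = list(point = r$intercept_b, ci = r$b_ci))
    evalr <- function(mu, sigma, a, b) {
      lambda <- a^2 * sigma^2 / (2 * kT)
      if (lambda <= 0) stop("degenerate slope: lambda = 0")
      .marcus_k_ns(coupling, lambda, lambda - a * mu - b, kT)
    }
  }
  env <- propagate_uncertainty(params, evalr)
  c(env$lower, env$upper)
}
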