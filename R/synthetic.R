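#' Specification of the synthetic energy-gap model
#'
#' Describes the statistical structure of the per-frame electronic-state
#' energies sampled along two molecular-dynamics trajectories of a chlorophyll
#' pair: the charge-separated (CS) trajectory, on which the vertical gap
#' \eqn{\Delta E = E_{ES} - E_{CS}} is Gaussian, and the neutral ground-state
#' (GS) trajectory, on which the gap \eqn{x = E_{CS} - E_{GS}} is Gaussian and
#' the companion gap \eqn{y = E_{ES} - E_{CS}} follows an approximately linear
#' relation \eqn{y = a x + b} with homoscedastic Gaussian residuals.
#'
#' The defaults are back-derived from the 10 Angstrom ether-solvated pair:
#' with the companion-construction closed forms \eqn{\lambda = \sigma^2/(2kT)}
#' and \eqn{\Delta A = \sigma^2/(2kT) - \mu}, a reorganization energy of
#' 0.66 eV and driving force of 0.39 eV at 300 K give \eqn{\mu = 0.27} eV and
#' \eqn{\sigma = 0.1847} eV.  The ground-state-axis parameters are chosen so
#' the cross-fit construction reproduces the post-photoexcitation parameter
#' set (\eqn{\lambda = 0.63} eV, \eqn{\Delta A = 0.39} eV).
#'
#' @param mu_cs Mean of E_ES - E_CS on the CS trajectory (eV).
#' @param sigma_cs Standard deviation of that gap (eV), > 0.
#' @param mu_gs_axis Mean of x = E_CS - E_GS on the GS trajectory (eV).
#' @param sigma_gs_axis Standard deviation of x (eV), > 0.
#' @param slope_a,intercept_b Linear relation y = a x + b between
#'   y = E_ES - E_CS and x on the GS trajectory (a dimensionless, b in eV).
#' @param resid_sd Standard deviation of residual noise about that line (eV),
#'   >= 0.
#' @param n_frames Number of frames to generate (>= 2).
#' @param seed Integer RNG seed; a fixed seed gives byte-identical output.
#' @return Object of class `gap_model_spec`.
#' @seealso [generate_cs_trajectory()], [generate_gs_trajectory()]
#' @export
gap_model_spec <- function(mu_cs = 0.27, sigma_cs = 0.1847286,
                           mu_gs_axis = 3.32, sigma_gs_axis = 0.3609,
                           slope_a = -0.5, intercept_b = 1.9,
                           resid_sd = 0.02, n_frames = 500, seed = 1L) {
  .check_scalar(mu_cs, "mu_cs")
  .check_scalar(sigma_cs, "sigma_cs", positive = TRUE)
  .check_scalar(mu_gs_axis, "mu_gs_axis")
  .check_scalar(sigma_gs_axis, "sigma_gs_axis", positive = TRUE)
  .check_scalar(slope_a, "slope_a")
  .check_scalar(intercept_b, "intercept_b")
  .check_scalar(resid_sd, "resid_sd", nonneg = TRUE)
  if (!is.numeric(n_frames) || length(n_frames) != 1L || n_frames < 2 ||
      n_frames != round(n_frames))
    stop("'n_frames' must be an integer >= 2", call. = FALSE)
  .check_scalar(seed, "seed")
  structure(list(mu_cs = mu_cs, sigma_cs = sigma_cs,
                 mu_gs_axis = mu_gs_axis, sigma_gs_axis = sigma_gs_axis,
                 slope_a = slope_a, intercept_b = intercept_b,
                 resid_sd = resid_sd, n_frames = as.integer(n_frames),
                 seed = as.integer(seed)),
            class = "gap_model_spec")
}

#' Specification of the synthetic coupling distribution
#'
#' Electronic couplings between the excited and charge-separated states of a
#' chlorophyll pair depend strongly on relative orientation and span orders of
#' magnitude in solution.  The generator draws coupling magnitudes
#' log-normally: log10 |H| ~ Normal(log10_center, log10_spread).
#'
#' @param log10_center Location of log10 coupling (coupling in eV).
#' @param log10_spread Scale on the log10 axis (dex), >= 0.
#' @param n_samples Number of frames.
#' @param seed Integer RNG seed.
#' @return Object of class `coupling_model_spec`.
#' @export
coupling_model_spec <- function(log10_center = -2.8, log10_spread = 0.65,
                                n_samples = 500, seed = 1L) {
  .check_scalar(log10_center, "log10_center")
  .check_scalar(log10_spread, "log10_spread", nonneg = TRUE)
  if (!is.numeric(n_samples) || length(n_samples) != 1L || n_samples < 1 ||
      n_samples != round(n_samples))
    stop("'n_samples' must be a positive integer", call. = FALSE)
  .check_scalar(seed, "seed")
  structure(list(log10_center = log10_center, log10_spread = log10_spread,
                 n_samples = as.integer(n_samples), seed = as.integer(seed)),
            class = "coupling_model_spec")
}

#' Generate a synthetic charge-separated-trajectory energy table
#'
#' Emulates the per-frame state energies along an equilibrated MD trajectory
#' of the chlorophyll ion pair: the vertical gap \eqn{\Delta E = E_{ES} -
#' E_{CS}} is i.i.d. Normal(mu_cs, sigma_cs).  Absolute energies are arbitrary
#' up to a per-frame constant (only gaps enter the analysis), so E_CS is fixed
#' at 0 as the reference; E_GS is placed consistently with the ground-state
#' axis distribution so all three gap columns are well defined.
#'
#' @param spec A [gap_model_spec()].
#' @return A `data.frame` with columns `frame`, `E_GS_eV`, `E_CS_eV`,
#'   `E_ES_eV`, one row per frame.
#' @examples
#' tab <- generate_cs_trajectory(gap_model_spec(n_frames = 100, seed = 42))
#' mean(tab$E_ES_eV - tab$E_CS_eV)
#' @export
generate_cs_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gap_model_spec"))
  rng <- .local_rng(spec$seed)
  de <- rng(function() stats::rnorm(spec$n_frames, spec$mu_cs, spec$sigma_cs))
  x  <- rng(function() stats::rnorm(spec$n_frames, spec$mu_gs_axis, spec$sigma_gs_axis))
  data.frame(frame  = seq_len(spec$n_frames),
             E_GS_eV = -x,           # E_CS - E_GS = x with E_CS = 0
             E_CS_eV = 0,
             E_ES_eV = de)
}

#' Generate a synthetic ground-state-trajectory energy table
#'
#' Emulates sampling along the neutral Chl-Chl trajectory: the gap
#' \eqn{x = E_{CS} - E_{GS}} is Normal(mu_gs_axis, sigma_gs_axis) and the
#' companion gap \eqn{y = E_{ES} - E_{CS}} is \eqn{a x + b} plus Gaussian
#' residual noise of SD `resid_sd`.  E_GS is fixed at 0 as the reference.
#'
#' @inheritParams generate_cs_trajectory
#' @return A `data.frame` with columns `frame`, `E_GS_eV`, `E_CS_eV`,
#'   `E_ES_eV`.
#' @export
generate_gs_trajectory <- function(spec) {
  stopifnot(inherits(spec, "gap_model_spec"))
  rng <- .local_rng(spec$seed)
  x <- rng(function() stats::rnorm(spec$n_frames, spec$mu_gs_axis, spec$sigma_gs_axis))
  eps <- if (spec$resid_sd > 0)
    rng(function() stats::rnorm(spec$n_frames, 0, spec$resid_sd))
  else rep(0, spec$n_frames)
  y <- spec$slope_a * x + spec$intercept_b + eps
  data.frame(frame  = seq_len(spec$n_frames),
             E_GS_eV = 0,
             E_CS_eV = x,
             E_ES_eV = x + y)
}

#' Generate a synthetic coupling table
#'
#' Draws per-frame HOMO-HOMO and LUMO-LUMO coupling magnitudes independently
#' from the log-normal distribution described by `spec`, mimicking the broad
#' positively skewed spread of orientation-dependent couplings in solution.
#'
#' @param spec A [coupling_model_spec()].
#' @return A `data.frame` with columns `frame`, `H_hh_eV`, `H_ll_eV`, all
#'   couplings strictly positive.
#' @export
generate_couplings <- function(spec) {
  stopifnot(inherits(spec, "coupling_model_spec"))
  rng <- .local_rng(spec$seed)
  draws <- rng(function() stats::rnorm(2L * spec$n_samples, spec$log10_center,
                                       spec$log10_spread))
  data.frame(frame  = seq_len(spec$n_samples),
             H_hh_eV = 10^draws[seq_len(spec$n_samples)],
             H_ll_eV = 10^draws[spec$n_samples + seq_len(spec$n_samples)])
}

#' Place molecules uniformly at random with a hard-sphere exclusion
#'
#' Rejection-samples `n_molecules` points uniformly in a cubic box of side
#' `box_side` such that no two points are closer than `r_excl` (hard spheres
#' of diameter `r_excl`).  This is the Monte-Carlo counterpart of the
#' uniform-solution assumption behind the statistical-pair estimators in
#' [paired_fraction()].
#'
#' @param n_molecules Number of points (>= 0).
#' @param box_side Box edge length (nm).
#' @param r_excl Minimum allowed pair distance (nm); 0 disables exclusion.
#' @param seed Integer RNG seed.
#' @param max_attempts_per_point Rejection budget per point before giving up
#'   (the packing is then considered too dense).
#' @return A `data.frame` with columns `x`, `y`, `z` (nm), `n_molecules` rows.
#' @examples
#' p <- generate_random_placement(50, box_side = 20, r_excl = 1, seed = 3)
#' min(dist(p)) >= 1
#' @export
generate_random_placement <- function(n_molecules, box_side, r_excl = 0,
                                      seed = 1L, max_attempts_per_point = 1000L) {
  if (!is.numeric(n_molecules) || length(n_molecules) != 1L || n_molecules < 0 ||
      n_molecules != round(n_molecules))
    stop("'n_molecules' must be a nonnegative integer", call. = FALSE)
  n_molecules <- as.integer(n_molecules)
  if (n_molecules == 0L)
    return(data.frame(x = numeric(0), y = numeric(0), z = numeric(0)))
  .check_scalar(box_side, "box_side", positive = TRUE)
  .check_scalar(r_excl, "r_excl", nonneg = TRUE)
  rng <- .local_rng(seed)
  pts <- matrix(NA_real_, n_molecules, 3L)
  r2 <- r_excl^2
  for (i in seq_len(n_molecules)) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts_per_point)) {
      cand <- rng(function() stats::runif(3L, 0, box_side))
      ok <- TRUE
      if (r_excl > 0 && i > 1L) {
        prev <- pts[seq_len(i - 1L), , drop = FALSE]
        d2 <- (prev[, 1L] - cand[1L])^2 + (prev[, 2L] - cand[2L])^2 +
          (prev[, 3L] - cand[3L])^2
        ok <- all(d2 >= r2)
      }
      if (ok) { pts[i, ] <- cand; placed <- TRUE; break }
    }
    if (!placed)
      stop(sprintf(
        "could not place molecule %d within %d attempts: packing fraction too high",
        i, max_attempts_per_point), call. = FALSE)
  }
  data.frame(x = pts[, 1L], y = pts[, 2L], z = pts[, 3L])
}

# Run `expr_fun` under a seeded, isolated RNG stream so generators never
# disturb (or depend on) the caller's .Random.seed.  Returns a closure that
# advances one private stream across calls.
.local_rng <- function(seed) {
  .check_scalar(seed, "seed")
  state <- NULL
  old_exists <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  function(expr_fun) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    if (is.null(state)) set.seed(as.integer(seed))
    else assign(".Random.seed", state, envir = globalenv())
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
      else if (!old_exists) rm(".Random.seed", envir = globalenv())
    })
    expr_fun()
  }
}
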