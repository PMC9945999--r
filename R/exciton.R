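#' Define an excitation site from atomic transition charges
#'
#' A site is one chromophore's localized excitation, represented by its
#' (embedded) excitation energy and the atomic transition charges of the
#' transition density.  The transition dipole is the first moment of the
#' charges, \eqn{\mu = \sum_k q_k r_k} (e Angstrom).  A valid transition
#' density carries no monopole, so the charges must sum to (numerically)
#' zero.
#'
#' @param energy Site excitation energy E_i (eV).
#' @param positions Numeric matrix (n x 3) of charge positions (Angstrom).
#' @param charges Numeric vector of transition charges (e), `sum(charges)`
#'   within `1e-6` of zero.
#' @return Object of class `exciton_site` with `energy`, `positions`,
#'   `charges`, `dipole` (length-3, e Angstrom).
#' @export
exciton_site <- function(energy, positions, charges) {
  .check_scalar(energy, "energy")
  positions <- as.matrix(positions)
  if (ncol(positions) != 3L || !is.numeric(positions) || any(!is.finite(positions)))
    stop("'positions' must be a finite n x 3 matrix", call. = FALSE)
  if (!is.numeric(charges) || length(charges) != nrow(positions) ||
      any(!is.finite(charges)))
    stop("'charges' must be finite and match the number of positions", call. = FALSE)
  if (abs(sum(charges)) > 1e-6)
    stop(sprintf("transition charges must sum to ~0 (got %.3g e)", sum(charges)),
         call. = FALSE)
  dipole <- as.numeric(crossprod(charges, positions))
  structure(list(energy = energy, positions = positions, charges = charges,
                 dipole = dipole),
            class = "exciton_site")
}

#' Coulomb coupling between the transition charges of two sites
#'
#' \deqn{V_{ab} = f \sum_{k \in a}\sum_{l \in b}
#'       \frac{q_k q_l}{4\pi\epsilon_0 r_{kl}}}
#' with charges in elementary-charge units, distances in angstroms and the
#' Coulomb constant 14.3996 eV Angstrom.  `screening` is an optional scalar
#' multiplier f (default 1, unscreened vacuum Coulomb).
#'
#' @param site_a,site_b [exciton_site()] objects.
#' @param screening Scalar screening factor applied to the sum.
#' @return Coupling V in eV.
#' @export
transition_charge_coupling <- function(site_a, site_b, screening = 1) {
  stopifnot(inherits(site_a, "exciton_site"), inherits(site_b, "exciton_site"))
  .check_scalar(screening, "screening")
  pa <- site_a$positions; pb <- site_b$positions
  # pairwise distances between the two charge clouds
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), `+`) - 2 * tcrossprod(pa, pb)
  d <- sqrt(pmax(d2, 0))
  if (min(d) <= 0.1)
    stop("coincident (or near-coincident) charge positions across sites",
         call. = FALSE)
  const <- physical_constants()
  screening * const$coulomb_eVA *
    sum(outer(site_a$charges, site_b$charges) / d)
}

#' Assemble an exciton system
#'
#' Collects sites into a Frenkel exciton system
#' \eqn{\hat H = \sum_i E_i |i\rangle\langle i| +
#'      \sum_{i \ne j} V_{ij} |i\rangle\langle j|}.
#' Couplings default to the transition-charge Coulomb interaction between
#' every pair of sites; an explicit symmetric coupling matrix may be given
#' instead (eV, zero diagonal).
#'
#' @param sites List of [exciton_site()] objects.
#' @param couplings Optional n x n symmetric numeric matrix of couplings.
#' @param screening Screening factor passed to
#'   [transition_charge_coupling()] when couplings are computed.
#' @return Object of class `exciton_system` with `sites`, `hamiltonian`.
#' @export
exciton_system <- function(sites, couplings = NULL, screening = 1) {
  stopifnot(is.list(sites), length(sites) >= 1L,
            all(vapply(sites, inherits, TRUE, "exciton_site")))
  n <- length(sites)
  if (is.null(couplings)) {
    couplings <- matrix(0, n, n)
    if (n > 1L)
      for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
        v <- transition_charge_coupling(sites[[i]], sites[[j]], screening)
        couplings[i, j] <- v; couplings[j, i] <- v
      }
  } else {
    couplings <- as.matrix(couplings)
    if (!is.numeric(couplings) || any(dim(couplings) != n))
      stop("'couplings' must be an n x n numeric matrix", call. = FALSE)
    if (max(abs(couplings - t(couplings))) > 1e-12)
      stop("coupling matrix must be symmetric", call. = FALSE)
    diag(couplings) <- 0
  }
  H <- couplings
  diag(H) <- vapply(sites, `[[`, numeric(1), "energy")
  structure(list(sites = sites, hamiltonian = H), class = "exciton_system")
}

#' Diagonalize a Frenkel exciton Hamiltonian
#'
#' Returns the exciton eigenstates sorted by energy.  Each state carries its
#' site coefficients (normalized), a dimensionless oscillator-strength proxy
#' — the squared norm of the coefficient-weighted vector sum of site
#' transition dipoles, relative to the mean monomer dipole strength — and
#' its dominance (largest squared coefficient).  The lowest-energy state is
#' the pair excited-state energy used in the free-energy-surface analysis.
#'
#' @param system An [exciton_system()].
#' @return Object of class `exciton_states`: `energies` (eV, ascending),
#'   `coefficients` (matrix, column per state), `oscillator` (proxy per
#'   state), `dominance` (per state), `dipoles` (site dipole matrix).
#' @examples
#' # degenerate cofacial dimer: dark lower state at E - V
#' pos <- rbind(c(0, 0, 0), c(1, 0, 0))
#' s1 <- exciton_site(2.0, pos, c(0.1, -0.1))
#' s2 <- exciton_site(2.0, pos + cbind(0, 0, 8), c(0.1, -0.1))
#' st <- build_and_diagonalize(exciton_system(list(s1, s2)))
#' st$energies
#' @export
build_and_diagonalize <- function(system) {
  stopifnot(inherits(system, "exciton_system"))
  H <- system$hamiltonian
  eig <- eigen(H, symmetric = TRUE)
  ord <- order(eig$values)
  energies <- eig$values[ord]
  coef <- eig$vectors[, ord, drop = FALSE]
  dip <- t(vapply(system$sites, `[[`, numeric(3), "dipole"))  # n x 3
  mono <- mean(rowSums(dip^2))
  osc <- vapply(seq_along(energies), function(s) {
    v <- as.numeric(crossprod(coef[, s], dip))   # sum_i c_i mu_i
    sum(v^2) / if (mono > 0) mono else 1
  }, numeric(1))
  dominance <- apply(coef^2, 2L, max)
  structure(list(energies = energies, coefficients = coef,
                 oscillator = osc, dominance = dominance, dipoles = dip),
            class = "exciton_states")
}

#' @export
print.exciton_states <- function(x, ...) {
  cat(sprintf("Exciton states (%d sites)\n", length(x$energies)))
  for (s in seq_along(x$energies))
    cat(sprintf("  %d: E = %.5f eV, oscillator proxy = %.4f, dominance = %.3f\n",
                s, x$energies[s], x$oscillator[s], x$dominance[s]))
  invisible(x)
}

#' Label exciton states as dark/bright and localized/delocalized
#'
#' A state is dark when its oscillator-strength proxy falls below
#' `dark_threshold` (a fraction of the monomer strength) — the signature of
#' an H-aggregate trap state — and localized when a single site's squared
#' coefficient exceeds `dominance_threshold`, in which case the state is
#' dominated by one monomer excitation and will not act as a dark trap.
#'
#' @param states An [build_and_diagonalize()] result.
#' @param dark_threshold Oscillator-proxy cutoff; default 0.05.
#' @param dominance_threshold Squared-coefficient cutoff; default 0.8.
#' @return `data.frame` with one row per state: `energy`, `oscillator`,
#'   `dominance`, `dark` (logical), `localized` (logical).
#' @export
classify_states <- function(states, dark_threshold = 0.05,
                            dominance_threshold = 0.8) {
  stopifnot(inherits(states, "exciton_states"))
  .check_scalar(dark_threshold, "dark_threshold", nonneg = TRUE)
  .check_scalar(dominance_threshold, "dominance_threshold", nonneg = TRUE)
  data.frame(energy = states$energies,
             oscillator = states$oscillator,
             dominance = states$dominance,
             dark = states$oscillator < dark_threshold,
             localized = states$dominance > dominance_threshold)
}

#' Fraction of dark lowest states across an ensemble
#'
#' Convenience summary over a list of diagonalized systems: how often the
#' lowest-energy exciton state is dark (a potential trap state).
#'
#' @param states_list List of `exciton_states`.
#' @inheritParams classify_states
#' @return Fraction in [0, 1].
#' @export
dark_lowest_fraction <- function(states_list, dark_threshold = 0.05) {
  stopifnot(is.list(states_list), length(states_list) >= 1L)
  mean(vapply(states_list, function(s) s$oscillator[1L] < dark_threshold,
              logical(1)))
}
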