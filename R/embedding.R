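#' Ion charge correction for embedded chromophores
#'
#' Builds the partial charges for a chromophore ion forcefield from the
#' neutral forcefield charges plus the difference between quantum-derived
#' charges of the ion and the neutral molecule, per atom:
#' \eqn{q_i' = q_i + (q_i^{ion} - q_i^{neutral})}.  The total charge of the
#' result equals the neutral total plus the ion-minus-neutral total, so a
#' unit charge moved at the quantum level is conserved exactly.
#'
#' @param neutral_ff Numeric vector of neutral forcefield charges (e).
#' @param qm_ion Numeric vector of quantum charges of the ion (e), same atom
#'   ordering.
#' @param qm_neutral Numeric vector of quantum charges of the neutral
#'   molecule (e), same atom ordering.
#' @return Numeric vector of corrected charges (e).
#' @examples
#' correct_ion_charges(c(0.1, -0.2, 0.1), c(0.5, 0.1, 0.4), c(0.2, -0.1, -0.1))
#' @export
correct_ion_charges <- function(neutral_ff, qm_ion, qm_neutral) {
  if (!is.numeric(neutral_ff) || !is.numeric(qm_ion) || !is.numeric(qm_neutral))
    stop("charge sets must be numeric", call. = FALSE)
  n <- length(neutral_ff)
  if (length(qm_ion) != n || length(qm_neutral) != n)
    stop(sprintf("atom-count mismatch: %d / %d / %d",
                 n, length(qm_ion), length(qm_neutral)), call. = FALSE)
  if (any(!is.finite(neutral_ff)) || any(!is.finite(qm_ion)) ||
      any(!is.finite(qm_neutral)))
    stop("charges must be finite", call. = FALSE)
  neutral_ff + (qm_ion - qm_neutral)
}

#' Direct-sum Coulomb energy between two charge groups
#'
#' Non-periodic pairwise electrostatic energy
#' \eqn{E = k \sum_{i \in a}\sum_{j \in b} q_i q_j / r_{ij}} with charges in
#' e, positions in angstrom and k = 14.3996 eV Angstrom.
#'
#' @param charges_a,charges_b Numeric charge vectors (e).
#' @param positions_a,positions_b n x 3 position matrices (Angstrom).
#' @return Interaction energy in eV.
#' @export
point_charge_energy <- function(charges_a, positions_a, charges_b, positions_b) {
  positions_a <- as.matrix(positions_a); positions_b <- as.matrix(positions_b)
  stopifnot(is.numeric(charges_a), is.numeric(charges_b),
            nrow(positions_a) == length(charges_a),
            nrow(positions_b) == length(charges_b),
            ncol(positions_a) == 3L, ncol(positions_b) == 3L)
  d2 <- outer(rowSums(positions_a^2), rowSums(positions_b^2), `+`) -
    2 * tcrossprod(positions_a, positions_b)
  d <- sqrt(pmax(d2, 0))
  if (any(d <= 1e-8))
    stop("coincident atoms across charge groups", call. = FALSE)
  physical_constants()$coulomb_eVA * sum(outer(charges_a, charges_b) / d)
}

#' Assemble the monomer-based QM/MM total energy
#'
#' The embedded-monomer decomposition sums the polarized quantum energy of
#' each monomer with the electrostatic interaction between every pair of
#' charge groups in the system, each pair counted once:
#' \eqn{E_{total} = \sum_A E_A^{qm,pol} + \sum_{A<B} E_{AB}^{elec}}.
#'
#' @param e_qm_pol Numeric vector of per-monomer polarized QM energies (eV);
#'   may be empty when only surroundings groups are assembled.
#' @param groups List of charge groups, each a `list(charges =, positions =)`
#'   (charges in e, positions n x 3 in Angstrom).  Groups must not share
#'   atoms (checked via coincident positions across groups).
#' @return Object of class `energy_decomposition`: `e_qm_pol_total`,
#'   `e_electrostatic` (sum over group pairs), `pair_energies` (matrix),
#'   `e_total`.
#' @export
assemble_total_energy <- function(e_qm_pol, groups) {
  if (!is.numeric(e_qm_pol)) stop("'e_qm_pol' must be numeric", call. = FALSE)
  stopifnot(is.list(groups), length(groups) >= 1L)
  for (g in groups)
    if (is.null(g$charges) || is.null(g$positions))
      stop("each group needs 'charges' and 'positions'", call. = FALSE)
  n <- length(groups)
  pair <- matrix(0, n, n)
  if (n > 1L)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      e <- point_charge_energy(groups[[i]]$charges, groups[[i]]$positions,
                               groups[[j]]$charges, groups[[j]]$positions)
      pair[i, j] <- e; pair[j, i] <- e
    }
  e_elec <- sum(pair[upper.tri(pair)])
  structure(list(e_qm_pol_total = sum(e_qm_pol),
                 e_electrostatic = e_elec,
                 pair_energies = pair,
                 e_total = sum(e_qm_pol) + e_elec),
            class = "energy_decomposition")
}

#' @export
print.energy_decomposition <- function(x, ...) {
  cat(sprintf("QM/MM energy decomposition\n  sum E_qm_pol    = %.6f eV\n  electrostatics  = %.6f eV\n  total           = %.6f eV\n",
              x$e_qm_pol_total, x$e_electrostatic, x$e_total))
  invisible(x)
}
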