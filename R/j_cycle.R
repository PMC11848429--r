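# Nutrient-variant dynamics: biologically enhanced Michaelis-Menten
# interconversions, abiotic fluxes, cycling ratios and CBV indices.

#' Biologically enhanced Michaelis-Menten reaction rate
#'
#' The population of reaction performers raises the effective substrate
#' availability by `rn_bar` per individual, capped at the maximum
#' bioavailable fraction `omega`: `BE = min(omega, n_p * rn_bar)`. The
#' interconversion rate is then idealized Michaelis-Menten kinetics in the
#' effective substrate level `J * BE`:
#' `R = Rmax * J * BE / (Km + J * BE)`, so `R = Rmax/2` exactly when
#' `J * BE = Km`, `R = 0` when there are no performers or no substrate,
#' and `R < Rmax` always.
#'
#' @param J_substrate substrate J-variant level (>= 0).
#' @param n_p performer count (>= 0). Vectorized.
#' @param Rmax,Km,rn_bar,omega kinetic constants, see [cbv_params()].
#' @return Reaction rate in units of J per timestep.
#' @examples
#' p <- cbv_params()
#' reaction_rate(1, 1000, p$Rmax, p$Km, p$rn_bar, p$omega)  # Rmax/2
#' reaction_rate(1, 0, p$Rmax, p$Km, p$rn_bar, p$omega)     # 0
#' @export
reaction_rate <- function(J_substrate, n_p, Rmax, Km, rn_bar, omega) {
  stopifnot(all(J_substrate >= 0), all(n_p >= 0))
  BE <- pmin(omega, n_p * rn_bar)
  eff <- J_substrate * BE
  Rmax * eff / (Km + eff)
}

#' Time derivatives of the three J-variant levels
#'
#' Each variant receives a constant abiotic influx `Fin0`, loses material
#' at rate `Fout0` per unit level, and is transformed by the four
#' reactions according to the fixed topology (see [reaction_topology()]).
#' A fraction `eps_X` of the material processed by reactions A and B
#' leaks to the X-cycle as byproduct, so their product terms carry a
#' factor `(1 - eps_X)`:
#' \deqn{dJ1/dt = Fin0 - J1 Fout0 - R_A + R_B (1-\epsilon_X) - R_C}
#' \deqn{dJ2/dt = Fin0 - J2 Fout0 + R_A (1-\epsilon_X) - R_B + R_D}
#' \deqn{dJ3/dt = Fin0 - J3 Fout0 + R_C - R_D}
#'
#' @param J numeric length-3 vector of variant levels.
#' @param R numeric length-4 vector of reaction rates, order A, B, C, D.
#' @param Fin0,Fout0,eps_X flux constants, see [cbv_params()].
#' @return Numeric length-3 vector `c(dJ1, dJ2, dJ3)`.
#' @examples
#' j_derivatives(c(1, 1, 1), c(0, 0, 0, 0), 1, 1, 0.5)  # all zero
#' @export
j_derivatives <- function(J, R, Fin0, Fout0, eps_X) {
  stopifnot(length(J) == 3, length(R) == 4)
  c(Fin0 - J[1] * Fout0 - R[1] + R[2] * (1 - eps_X) - R[3],
    Fin0 - J[2] * Fout0 + R[1] * (1 - eps_X) - R[2] + R[4],
    Fin0 - J[3] * Fout0 + R[3] - R[4])
}

#' Cycling ratios and cycle-biota-variant abundance indices
#'
#' The cycling ratio of a variant is its level over the normalization
#' level `Ji0` -- a measure of how much biological recycling amplifies
#' the standing stock relative to abiotic supply. The abundance of each
#' cycle-biota variant (CBV) is the geometric mean of (cycling ratio x
#' performer frequency) over the reactions on its path:
#' `cbv_AB = sqrt(CR1 p_A * CR2 p_B)` for the two-step variant and
#' `cbv_CDB = (CR1 p_C * CR3 p_D * CR2 p_B)^(1/3)` for the three-step
#' variant. Normalized shares divide each index by their sum; when both
#' indices are zero the shares are reported as (0.5, 0.5) so the share
#' time series stays defined at degenerate states.
#'
#' @param J numeric length-3 vector of variant levels.
#' @param p numeric length-4 vector of p-genotype frequencies, order
#'   A, B, C, D.
#' @param Ji0 cycling-ratio normalization level.
#' @return A list with components `CR` (length 3), `cbv_AB`, `cbv_CDB`,
#'   `cbv_AB_norm`, `cbv_CDB_norm`.
#' @examples
#' cbv_metrics(c(1, 1, 1), c(1, 1, 1, 1), 1)  # symmetric: shares 0.5
#' cbv_metrics(c(1, 1, 1), c(1, 1, 0, 1), 1)  # extinct CDB path
#' @export
cbv_metrics <- function(J, p, Ji0) {
  stopifnot(length(J) == 3, length(p) == 4, Ji0 > 0,
            all(p >= 0 & p <= 1), all(J >= 0))
  CR <- J / Ji0
  cbv_AB <- sqrt(CR[1] * p[1] * CR[2] * p[2])
  cbv_CDB <- (CR[1] * p[3] * CR[3] * p[4] * CR[2] * p[2])^(1 / 3)
  tot <- cbv_AB + cbv_CDB
  if (tot > 0) {
    ab <- cbv_AB / tot
    cdb <- cbv_CDB / tot
  } else {
    ab <- cdb <- 0.5
  }
  list(CR = CR, cbv_AB = cbv_AB, cbv_CDB = cbv_CDB,
       cbv_AB_norm = ab, cbv_CDB_norm = cdb)
}
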