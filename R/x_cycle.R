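# Climate-like X dynamics: byproduct pools, reservoir titration and
# release, bistable feedback, and the suppression function alpha(X).

#' Byproduct reaction flux
#'
#' One unit of byproduct XA reacts with one unit of XB to produce one
#' unit of X, at saturating (Michaelis-Menten form) kinetics in the pool
#' product: `Xvar = Xvar0 * Rmax * XA*XB / (Km + XA*XB)`. The flux is zero
#' whenever either pool is empty or the efficiency `Xvar0` is zero, and is
#' bounded above by `Xvar0 * Rmax`.
#'
#' @param XA,XB byproduct pool levels (>= 0).
#' @param Xvar0,Rmax,Km constants, see [cbv_params()].
#' @return Reaction flux (units of X per X-cycle timestep).
#' @examples
#' xvar_flux(1, 1, 1, 1, 1)  # Rmax/2 at XA*XB = Km
#' xvar_flux(0, 5, 1, 1, 1)  # 0
#' @export
xvar_flux <- function(XA, XB, Xvar0, Rmax, Km) {
  stopifnot(all(XA >= 0), all(XB >= 0))
  Xvar0 * Rmax * (XA * XB) / (Km + XA * XB)
}

#' Time derivatives of the byproduct pools
#'
#' Each pool is fed by its reaction's byproduct leak (`eps_X` times the
#' reaction rate), removed linearly at rate `Xout0`, and drained by the
#' joint byproduct reaction flux `Xvar`:
#' `dXA/dt = eps_X * R_A - Xout0 * XA - Xvar` (and symmetrically for XB).
#'
#' @param XA,XB pool levels.
#' @param R_A,R_B rates of reactions A and B.
#' @param Xvar joint byproduct flux, see [xvar_flux()].
#' @param eps_X,Xout0 constants, see [cbv_params()].
#' @return A list with components `dXA`, `dXB`.
#' @export
byproduct_derivatives <- function(XA, XB, R_A, R_B, Xvar, eps_X, Xout0) {
  list(dXA = eps_X * R_A - Xout0 * XA - Xvar,
       dXB = eps_X * R_B - Xout0 * XB - Xvar)
}

#' Reservoir titration and release
#'
#' The initially unavailable solid-state reservoir is consumed by the
#' byproduct flux (`dXres/dt = -Xvar * Xres`) but nothing is released to
#' the environment until the entire reservoir has been titrated away.
#' While `Xres > 0` the release flux is zero and titrated material
#' accumulates in the transition pool; once `Xres = 0` the transition
#' pool plus incoming flux is released at rate `Xrel0`:
#' `Xrelease = Xrel0 * (Xres2 + Xvar)`. The transition-pool derivative is
#' `dXres2/dt = -dXres/dt - Xrelease`.
#'
#' The integrator clamps `Xres` to exactly 0 once it falls below the
#' numerical depletion threshold `Xres_tol`; the release condition then
#' switches on from the following sub-step.
#'
#' @param Xres reservoir level (>= 0).
#' @param Xres2 transition-pool level (>= 0).
#' @param Xvar byproduct flux, see [xvar_flux()].
#' @param Xrel0 release rate constant.
#' @return A list with components `dXres`, `dXres2`, `Xrelease`.
#' @examples
#' reservoir_step(5, 0, 0.3, 1)  # titrating: no release
#' reservoir_step(0, 2, 0, 1)    # depleted: Xrelease = 2
#' @export
reservoir_step <- function(Xres, Xres2, Xvar, Xrel0) {
  stopifnot(all(Xres >= 0), all(Xres2 >= 0), all(Xvar >= 0))
  dXres <- -Xvar * Xres
  Xrelease <- ifelse(Xres > 0, 0, Xrel0 * (Xres2 + Xvar))
  list(dXres = dXres, dXres2 = -dXres - Xrelease, Xrelease = Xrelease)
}

#' Bistable feedback flux
#'
#' A feedback input to X active between the thresholds `Xon` and `Xoff`,
#' the product of a rising and a falling sigmoid:
#' `Xfeedback = Xfeedback0 / (1 + exp(-a (X - Xon))) / (1 + exp(b (X - Xoff)))`.
#' Together with the linear removal this gives the X-cycle two stable
#' states (low, near `Xin0/Xout0`, and high, inside the feedback window)
#' for suitable constant forcing -- the inherent bistability that makes
#' reservoir release effectively irreversible.
#'
#' @param X level of the main pool.
#' @param Xfeedback0,Xon,Xoff,a,b constants, see [cbv_params()].
#' @return Feedback flux in `(0, Xfeedback0)`.
#' @examples
#' feedback_flux(4.5, 3, 3, 6, 10, 10)  # ~ Xfeedback0 at the midpoint
#' feedback_flux(0, 3, 3, 6, 10, 10)    # ~ 0 far below Xon
#' @export
feedback_flux <- function(X, Xfeedback0, Xon, Xoff, a, b) {
  Xfeedback0 / (1 + exp(-a * (X - Xon))) / (1 + exp(b * (X - Xoff)))
}

#' Suppression function alpha(X)
#'
#' The per-capita kill rate imposed on species C: zero below the
#' threshold `Xsuppress`, and a sigmoid rising from `alpha0/2` at the
#' threshold towards `alpha0` above it,
#' `alpha = alpha0 / (1 + exp(-k_alpha (X - Xsuppress)))` for
#' `X >= Xsuppress`. The steepness `k_alpha` smooths the switch-on to
#' avoid instabilities from a discontinuous jump. Non-decreasing in X.
#'
#' @param X level of the main pool.
#' @param alpha0,k_alpha,Xsuppress constants, see [cbv_params()].
#' @return Suppression rate in `[0, alpha0)`.
#' @examples
#' suppression_alpha(3.4, 1, 20, 3.5)  # 0 (below threshold)
#' suppression_alpha(3.5, 1, 20, 3.5)  # alpha0/2
#' @export
suppression_alpha <- function(X, alpha0, k_alpha, Xsuppress) {
  ifelse(X < Xsuppress, 0,
         alpha0 / (1 + exp(-k_alpha * (X - Xsuppress))))
}

#' Time derivative of the main X pool
#'
#' Constant influx, linear removal, plus the release and feedback fluxes:
#' `dX/dt = Xin0 - Xout0 * X + Xrelease + Xfeedback`. With no release and
#' negligible feedback the abiotic steady state is `X* = Xin0/Xout0`,
#' which sits below both `Xon` and `Xsuppress` at the default constants:
#' suppression can never activate without biological byproducts.
#'
#' @param X level of the main pool.
#' @param Xrelease release flux, see [reservoir_step()].
#' @param Xfeedback feedback flux, see [feedback_flux()].
#' @param Xin0,Xout0 constants, see [cbv_params()].
#' @return dX/dt.
#' @export
x_derivative <- function(X, Xrelease, Xfeedback, Xin0, Xout0) {
  Xin0 - Xout0 * X + Xrelease + Xfeedback
}
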