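# Multi-timescale Euler-Maruyama stepper: deterministic drift assembled
# from the biology / J-cycle / X-cycle modules, bespoke diffusion
# coefficients from the mutation-sampling variances, and a compiled hot
# loop (src/engine.cpp) behind run_simulation()/em_step().

.species <- c("A", "B", "C", "D")
.substrate_of <- c(1L, 2L, 1L, 3L)

#' Partial derivative of the reaction rate w.r.t. the performer count
#'
#' Exact analytic derivative of [reaction_rate()] with respect to `n_p`:
#' `Km * Rmax * J * rn_bar / (Km + J * n_p * rn_bar)^2` below the
#' bioavailability cap, and 0 once `n_p * rn_bar >= omega` (the flat
#' branch of the `min`). Used to propagate demographic variance into the
#' J-cycle and X-cycle diffusion terms.
#'
#' @inheritParams reaction_rate
#' @return dR/dn_p. Vectorized.
#' @examples
#' p <- cbv_params()
#' reaction_partial(1, 500, p$Rmax, p$Km, p$rn_bar, p$omega)
#' reaction_partial(1, 2000, p$Rmax, p$Km, p$rn_bar, p$omega)  # capped: 0
#' @export
reaction_partial <- function(J_substrate, n_p, Rmax, Km, rn_bar, omega) {
  stopifnot(all(J_substrate >= 0), all(n_p >= 0))
  ifelse(n_p * rn_bar >= omega, 0,
         Km * Rmax * J_substrate * rn_bar /
           (Km + J_substrate * n_p * rn_bar)^2)
}

#' Demographic and allele-frequency variance terms
#'
#' The binomial variance of the realized mutation fraction of the
#' p-genotype, `VAR_p = m0_p (1 - m0_p) / RE_p` (0 when there are no
#' events); the variance of the total offspring number approximated from
#' both genotypes' binomial reproduction,
#' `VAR_S = W_p p (1 - p) + W_q q (1 - q)`; and the variance of the
#' performer count by the product rule,
#' `VAR_np = p^2 VAR_S + M^2 VAR_p`.
#'
#' @param p frequency of the p-genotype (`q = 1 - p`).
#' @param M population size.
#' @param W_p,W_q genotype fitnesses.
#' @param RE_p p-genotype reproductive-event count.
#' @param m0_p p-to-q mutation probability.
#' @return A list with components `VAR_p`, `VAR_S`, `VAR_np`.
#' @examples
#' variance_terms(0.5, 1000, 1.01, 1, RE_p = 1, m0_p = 0.1)
#' @export
variance_terms <- function(p, M, W_p, W_q, RE_p, m0_p) {
  q <- 1 - p
  VAR_p <- ifelse(RE_p > 0, m0_p * (1 - m0_p) / RE_p, 0)
  VAR_S <- W_p * p * (1 - p) + W_q * q * (1 - q)
  list(VAR_p = VAR_p, VAR_S = VAR_S,
       VAR_np = p^2 * VAR_S + M^2 * VAR_p)
}

#' Partial derivatives of the byproduct flux
#'
#' Exact analytic derivatives of [xvar_flux()] with respect to the two
#' pool levels: `dXvar/dXA = Xvar0 * Rmax * XB * Km / (Km + XA*XB)^2` and
#' symmetrically for XB.
#'
#' @inheritParams xvar_flux
#' @return A list with components `dXA`, `dXB`.
#' @export
xvar_partials <- function(XA, XB, Xvar0, Rmax, Km) {
  d <- (Km + XA * XB)^2
  list(dXA = Xvar0 * Rmax * XB * Km / d,
       dXB = Xvar0 * Rmax * XA * Km / d)
}

#' Assemble the initial simulation state
#'
#' Default initial conditions start the system at the abiotic equilibrium
#' with both cycle variants equally represented: every species at carrying
#' capacity with `p = 0.5`, J-variants at `Fin0/Fout0`, X at
#' `Xin0/Xout0`, empty byproduct and transition pools, and a full
#' reservoir. Any field can be overridden through `run$init`.
#'
#' @param params a [cbv_params] object.
#' @param run a [run_config] object (only `init` is consulted).
#' @return A `cbv_state` list with fields `M`, `p` (length 4, named
#'   A-D), `J` (length 3), `X`, `XA`, `XB`, `Xres`, `Xres2`, `alpha`,
#'   `t`.
#' @export
init_state <- function(params, run = run_config()) {
  st <- list(
    M = stats::setNames(rep(params$K, 4), .species),
    p = stats::setNames(rep(0.5, 4), .species),
    J = rep(if (params$Fout0 > 0) params$Fin0 / params$Fout0 else 0, 3),
    X = if (params$Xout0 > 0) params$Xin0 / params$Xout0 else 0,
    XA = 0, XB = 0,
    Xres = params$Xres_init, Xres2 = 0,
    alpha = NA_real_, t = 0
  )
  if (!is.null(run$init)) {
    for (nm in names(run$init)) {
      val <- run$init[[nm]]
      if (nm %in% c("M", "p")) {
        stopifnot(length(val) == 4)
        st[[nm]] <- stats::setNames(as.numeric(val), .species)
      } else if (nm == "J") {
        stopifnot(length(val) == 3)
        st$J <- as.numeric(val)
      } else {
        stopifnot(length(val) == 1)
        st[[nm]] <- as.numeric(val)
      }
    }
  }
  st$alpha <- suppression_alpha(st$X, params$alpha0, params$k_alpha,
                                params$Xsuppress)
  class(st) <- "cbv_state"
  st
}

#' Diffusion coefficients of the Euler-Maruyama scheme
#'
#' Assembles, from a full state, every diffusion coefficient of the
#' stochastic scheme (all on the standard-deviation scale, multiplied by
#' `sigma_bar * sqrt(dt) * N(0,1)` in the stepper):
#' \itemize{
#'   \item `g_S` per species: the two genotypes' binomial mutation
#'     variance rates combined (default root-sum, see [cbv_params()]),
#'     applied to the biomass update;
#'   \item `g_R` per reaction: [reaction_partial()] times the standard
#'     deviation of the performer count (`sqrt(VAR_np)`);
#'   \item `g_J` per variant: root-sum-square of the `g_R` of the
#'     reactions entering that variant's deterministic equation;
#'   \item `g_XA`, `g_XB`: the byproduct pools inherit the corresponding
#'     reaction's `g_R`;
#'   \item `g_Xmain`: root-sum-square of the byproduct terms and their
#'     propagation through the byproduct flux partials
#'     ([xvar_partials()]).
#' }
#' All coefficients vanish when every contributing variance is zero
#' (genotypes at fixation with `m0 = 0`).
#'
#' Reproductive-event counts are taken at their deterministic values
#' (`RE = round(W * p)`, or scaled by `M` under `re_scale = "count"`);
#' no random numbers are consumed.
#'
#' @param state a `cbv_state`, see [init_state()].
#' @param params a [cbv_params] object.
#' @return A list with components `g_S` (length 4), `g_R` (length 4),
#'   `g_J` (length 3), `g_XA`, `g_XB`, `g_Xmain`.
#' @export
diffusion_terms <- function(state, params) {
  m0r <- mutation_rates(params$m0)
  scale <- if (params$re_scale == "count") state$M else rep(1, 4)
  Js <- state$J[.substrate_of]
  W_p <- params$W0 * (1 + params$s * Js)
  W_q <- rep(params$W0, 4)
  pvec <- as.numeric(state$p)
  qvec <- 1 - pvec
  RE_p <- round_half_away(W_p * pvec * scale)
  RE_q <- round_half_away(W_q * qvec * scale)
  v_p <- ifelse(RE_p > 0, m0r[["m0_p"]] * (1 - m0r[["m0_p"]]) / RE_p, 0)
  v_q <- ifelse(RE_q > 0, m0r[["m0_q"]] * (1 - m0r[["m0_q"]]) / RE_q, 0)
  g_S <- if (params$gS_combine == "root_sum") sqrt(v_p + v_q)
         else v_p * v_q
  n_p <- performer_count(pvec, as.numeric(state$M))
  VAR_np <- variance_terms(pvec, as.numeric(state$M), W_p, W_q,
                           RE_p, m0r[["m0_p"]])$VAR_np
  dRdn <- reaction_partial(Js, n_p, params$Rmax, params$Km,
                           params$rn_bar, params$omega)
  g_R <- dRdn * sqrt(VAR_np)
  g_J <- c(sqrt(g_R[1]^2 + g_R[2]^2 + g_R[3]^2),
           sqrt(g_R[1]^2 + g_R[2]^2 + g_R[4]^2),
           sqrt(g_R[3]^2 + g_R[4]^2))
  g_XA <- g_R[1]
  g_XB <- g_R[2]
  dxv <- xvar_partials(state$XA, state$XB, params$Xvar0, params$Rmax,
                       params$Km)
  g_Xmain <- sqrt(g_XA^2 + g_XB^2 +
                    dxv$dXA^2 * g_XA^2 + dxv$dXB^2 * g_XB^2)
  list(g_S = stats::setNames(g_S, .species),
       g_R = stats::setNames(g_R, .species),
       g_J = g_J, g_XA = g_XA, g_XB = g_XB, g_Xmain = g_Xmain)
}

# pack/unpack between the cbv_state list and the flat engine vector
.pack_state <- function(st) {
  c(as.numeric(st$M), as.numeric(st$p), as.numeric(st$J),
    st$X, st$XA, st$XB, st$Xres, st$Xres2)
}
.unpack_state <- function(v, alpha, t) {
  st <- list(
    M = stats::setNames(v[1:4], .species),
    p = stats::setNames(v[5:8], .species),
    J = v[9:11],
    X = v[12], XA = v[13], XB = v[14], Xres = v[15], Xres2 = v[16],
    alpha = alpha, t = t
  )
  class(st) <- "cbv_state"
  st
}

.engine_params <- function(params) {
  list(
    Fin0 = params$Fin0, Fout0 = params$Fout0, Rmax = params$Rmax,
    K = params$K, rn_bar = params$rn_bar, Km = params$Km,
    g0 = params$g0, W0 = params$W0, s = params$s, Ji0 = params$Ji0,
    m0 = params$m0, eps_X = params$eps_X, Xrel0 = params$Xrel0,
    Xfeedback0 = params$Xfeedback0, Xon = params$Xon,
    Xoff = params$Xoff, a = params$a, b = params$b,
    tau_J = params$tau_J, tau_X = params$tau_X,
    Xsuppress = params$Xsuppress, alpha0 = params$alpha0,
    k_alpha = params$k_alpha, omega = params$omega,
    Xvar0 = params$Xvar0, sigma_bar = params$sigma_bar,
    Xin0 = params$Xin0, Xout0 = params$Xout0,
    Xres_tol = params$Xres_tol,
    growth_sqdiff = as.integer(params$growth_form == "squared_difference"),
    re_count = as.integer(params$re_scale == "count"),
    gS_product = as.integer(params$gS_combine == "product")
  )
}

.series_columns <- c(
  "t", "M_A", "M_B", "M_C", "M_D", "p_A", "p_B", "p_C", "p_D",
  "J1", "J2", "J3", "X", "XA", "XB", "Xres", "Xres2", "alpha",
  "CR1", "CR2", "CR3", "cbv_AB", "cbv_CDB", "cbv_AB_norm",
  "cbv_CDB_norm", "mean_p"
)

#' Advance the full system by one biological timestep
#'
#' One Euler-Maruyama step of the coupled system. All derivatives are
#' evaluated at the incoming state and applied simultaneously: the
#' biology advances with timestep `dt_bio`; the J-cycle's deterministic
#' and diffusion contributions are scaled for an effective sub-step
#' `dt_bio / tau_J`; the X-cycle's for `dt_bio / (tau_J * tau_X)` (every
#' subsystem is integrated every biological step with scaled increments,
#' which avoids the instabilities of infrequent large steps). Each
#' stochastic increment is `sigma_bar * g * sqrt(dt) * N(0,1)`. After the
#' update, frequencies are clamped to `[0, 1]` (with `q = 1 - p`), levels
#' and populations to `>= 0`, the reservoir is clamped to 0 below
#' `Xres_tol`, and the suppression level `alpha` is recomputed from the
#' new X. Extinction of a genotype is absorbing up to mutation: at
#' `p = 0` the selection term is not applied, so an extinct
#' reaction-performing genotype can only be regenerated through mutation
#' (at `p = 1` the mean fitness equals `W_p` exactly, so the symmetric
#' case needs no special handling).
#'
#' Random numbers are consumed from the R stream in a fixed order:
#' mutation uniforms species A to D (p-genotype events then q-genotype
#' events), then standard normals for the biomass noise (A-D), the
#' J-variant noise (1-3), and the X-cycle noise (XA, XB, X). With
#' `sigma_bar = 0` no random numbers are consumed at all and the step is
#' fully deterministic (mutation fractions take their expected values).
#'
#' @param state a `cbv_state`, see [init_state()].
#' @param params a [cbv_params] object.
#' @param dt_bio biological timestep.
#' @return The successor `cbv_state`.
#' @examples
#' p <- cbv_params(sigma_bar = 0)
#' st <- init_state(p)
#' em_step(st, p)
#' @export
em_step <- function(state, params, dt_bio = 1) {
  res <- .engine_run(.pack_state(state), state$t, .engine_params(params),
                     1L, dt_bio, 0L)
  .unpack_state(res$state, res$alpha, state$t + dt_bio)
}

#' Run a full simulation
#'
#' Integrates the coupled biology / J-cycle / X-cycle system for
#' `run$n_steps` biological timesteps from the configured initial state
#' (see [init_state()]), seeding the R random number stream from
#' `run$seed`, and recording all state variables plus derived metrics
#' (cycling ratios, CBV indices and normalized shares, the suppression
#' level alpha, and the cross-species mean p-frequency) every
#' `run$record_every` steps.
#'
#' With `sigma_bar = 0` (either in `params` or overridden in `run`) the
#' run is fully deterministic and independent of the seed; with
#' `sigma_bar > 0` a fixed seed reproduces the trajectory bit-for-bit.
#'
#' @param params a [cbv_params] object; must pass [validate_params()].
#' @param run a [run_config] object.
#' @return An object of class `cbv_sim`: a list with the recorded
#'   `series` (data frame, one row per recorded step), the `final`
#'   state, and the resolved `params`, `run` and `seed`.
#' @examples
#' sim <- run_simulation(cbv_params(sigma_bar = 0),
#'                       run_config(n_steps = 100))
#' tail(sim$series[, c("t", "J1", "X", "cbv_AB_norm")], 3)
#' @export
run_simulation <- function(params = cbv_params(), run = run_config()) {
  viol <- validate_params(params)
  if (length(viol))
    stop("invalid parameters:\n  ", paste(viol, collapse = "\n  "))
  if (!is.null(run$sigma_bar)) params$sigma_bar <- run$sigma_bar
  st <- init_state(params, run)
  set.seed(run$seed)
  res <- .engine_run(.pack_state(st), st$t, .engine_params(params),
                     run$n_steps, run$dt_bio, run$record_every)
  series <- as.data.frame(res$records)
  names(series) <- .series_columns
  out <- list(series = series,
              final = .unpack_state(res$state, res$alpha,
                                    st$t + run$n_steps * run$dt_bio),
              params = params, run = run, seed = run$seed)
  class(out) <- "cbv_sim"
  out
}

#' @export
print.cbv_sim <- function(x, ...) {
  fin <- x$series[nrow(x$series), ]
  cat("<cbv_sim> ", x$run$n_steps, " biological steps, seed ", x$seed,
      if (x$params$sigma_bar == 0) " (deterministic)", "\n", sep = "")
  cat(sprintf("  tau_J = %g, tau_X = %g, s = %g, m0 = %g, Xvar0 = %g, alpha0 = %g\n",
              x$params$tau_J, x$params$tau_X, x$params$s, x$params$m0,
              x$params$Xvar0, x$params$alpha0))
  cat(sprintf("  final: mean J = %.3f, X = %.3f, alpha = %.3f, CBV share AB = %.3f\n",
              mean(c(fin$J1, fin$J2, fin$J3)), fin$X, fin$alpha,
              fin$cbv_AB_norm))
  invisible(x)
}

#' @export
summary.cbv_sim <- function(object, ...) {
  fin <- object$series[nrow(object$series), ]
  structure(list(
    n_steps = object$run$n_steps,
    seed = object$seed,
    deterministic = object$params$sigma_bar == 0,
    final = fin,
    reservoir_depleted = fin$Xres == 0,
    suppression_active = fin$alpha > 0
  ), class = "summary.cbv_sim")
}

#' @export
print.summary.cbv_sim <- function(x, ...) {
  cat("cbvsim run:", x$n_steps, "steps, seed", x$seed,
      if (x$deterministic) "(deterministic)", "\n")
  cat("  reservoir depleted:", x$reservoir_depleted,
      "| suppression active:", x$suppression_active, "\n")
  print(x$final, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.cbv_sim <- function(x, ...) x$series

#' Plot a simulation
#'
#' Four stacked panels in the style of the model's standard single-run
#' display: species biomasses and p-frequencies, J-variant levels,
#' X-cycle variables, and the normalized CBV shares with the suppression
#' level.
#'
#' @param x a `cbv_sim` object.
#' @param ... unused.
#' @return `x`, invisibly.
#' @export
plot.cbv_sim <- function(x, ...) {
  s <- x$series
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1, 1))
  on.exit(graphics::par(op))
  graphics::matplot(s$t, s[, c("M_A", "M_B", "M_C", "M_D")] / x$params$K,
                    type = "l", lty = 1, ylab = "M / K", xlab = "")
  graphics::matlines(s$t, s[, c("p_A", "p_B", "p_C", "p_D")], lty = 2)
  graphics::legend("bottomleft", legend = c("A", "B", "C", "D"),
                   col = 1:4, lty = 1, horiz = TRUE, bty = "n", cex = 0.7)
  graphics::matplot(s$t, s[, c("J1", "J2", "J3")], type = "l", lty = 1,
                    ylab = "J variants", xlab = "")
  graphics::matplot(s$t, s[, c("X", "XA", "XB", "Xres", "Xres2")],
                    type = "l", lty = 1, ylab = "X cycle", xlab = "")
  graphics::legend("topleft", legend = c("X", "XA", "XB", "Xres", "Xres2"),
                   col = 1:5, lty = 1, horiz = TRUE, bty = "n", cex = 0.7)
  graphics::matplot(s$t, s[, c("cbv_AB_norm", "cbv_CDB_norm", "alpha")],
                    type = "l", lty = 1, ylim = c(0, 1),
                    ylab = "CBV shares, alpha", xlab = "t (bio steps)")
  invisible(x)
}
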