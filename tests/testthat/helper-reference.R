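# Reference Euler-Maruyama stepper assembled from the package's exported
# module operations. Kept independent of the compiled engine so that the
# two can be compared as implementation vs oracle. Draws random numbers
# in the engine's documented order: per species A-D the mutation
# uniforms (p-events then q-events), then 10 standard normals (biomass
# A-D, J-variants 1-3, XA, XB, X).

rha <- function(x) ifelse(x >= 0, floor(x + 0.5), ceiling(x - 0.5))

reference_step <- function(st, params, dt_bio = 1) {
  stoch <- params$sigma_bar > 0
  m0r <- mutation_rates(params$m0)
  subs <- c(1L, 2L, 1L, 3L)
  np <- performer_count(st$p, st$M)
  dpv <- dMv <- numeric(4)
  for (i in 1:4) {
    fit <- fitnesses(st$p[[i]], st$M[[i]], st$J[subs[i]],
                     params$W0, params$s)
    if (stoch) {
      d <- sample_mutations(fit$W_p, fit$W_q, st$p[[i]], 1 - st$p[[i]],
                            m0r[["m0_p"]], m0r[["m0_q"]],
                            re_scale = params$re_scale, M = st$M[[i]])
      m_p <- d$m_p
      m_q <- d$m_q
    } else {
      scale <- if (params$re_scale == "count") st$M[[i]] else 1
      m_p <- if (rha(fit$W_p * st$p[[i]] * scale) > 0) m0r[["m0_p"]] else 0
      m_q <- if (rha(fit$W_q * (1 - st$p[[i]]) * scale) > 0)
        m0r[["m0_q"]] else 0
    }
    fd <- frequency_derivatives(fit$W_p, fit$W_q, fit$W_mean, m_p, m_q)
    # extinction is absorbing up to mutation: no selection term at p = 0
    dpv[i] <- if (st$p[[i]] > 0) fd$dp else -m_p + m_q
    dMv[i] <- growth_rate(st$M[[i]], params$g0, params$K,
                          alpha = st$alpha, suppressed = (i == 3),
                          form = params$growth_form)
  }
  R <- reaction_rate(st$J[subs], np, params$Rmax, params$Km,
                     params$rn_bar, params$omega)
  dJ <- j_derivatives(st$J, R, params$Fin0, params$Fout0, params$eps_X)
  Xv <- xvar_flux(st$XA, st$XB, params$Xvar0, params$Rmax, params$Km)
  bp <- byproduct_derivatives(st$XA, st$XB, R[1], R[2], Xv,
                              params$eps_X, params$Xout0)
  rs <- reservoir_step(st$Xres, st$Xres2, Xv, params$Xrel0)
  fb <- feedback_flux(st$X, params$Xfeedback0, params$Xon, params$Xoff,
                      params$a, params$b)
  dX <- x_derivative(st$X, rs$Xrelease, fb, params$Xin0, params$Xout0)

  dtJ <- dt_bio / params$tau_J
  dtX <- dt_bio / (params$tau_J * params$tau_X)
  sg <- params$sigma_bar
  nb <- nJ <- rep(0, 4)
  nJ <- rep(0, 3)
  nXA <- nXB <- nX <- 0
  if (stoch) {
    g <- diffusion_terms(st, params)
    z <- stats::rnorm(10)
    nb <- sg * g$g_S * sqrt(dt_bio) * z[1:4]
    nJ <- sg * g$g_J * sqrt(dtJ) * z[5:7]
    nXA <- sg * g$g_XA * sqrt(dtX) * z[8]
    nXB <- sg * g$g_XB * sqrt(dtX) * z[9]
    nX <- sg * g$g_Xmain * sqrt(dtX) * z[10]
  }
  out <- st
  out$p <- pmin(1, pmax(0, st$p + dpv * dt_bio))
  out$M <- pmax(0, st$M + dMv * dt_bio + nb)
  out$J <- pmax(0, st$J + dJ * dtJ + nJ)
  out$XA <- max(0, st$XA + bp$dXA * dtX + nXA)
  out$XB <- max(0, st$XB + bp$dXB * dtX + nXB)
  out$Xres <- st$Xres + rs$dXres * dtX
  if (out$Xres < params$Xres_tol) out$Xres <- 0
  out$Xres2 <- max(0, st$Xres2 + rs$dXres2 * dtX)
  out$X <- max(0, st$X + dX * dtX + nX)
  out$alpha <- suppression_alpha(out$X, params$alpha0, params$k_alpha,
                                 params$Xsuppress)
  out$t <- st$t + dt_bio
  out
}

reference_trajectory <- function(params, n_steps, seed = 1, dt_bio = 1,
                                 run = run_config()) {
  st <- init_state(params, run)
  set.seed(seed)
  for (k in seq_len(n_steps)) st <- reference_step(st, params, dt_bio)
  st
}

state_vec <- function(st) {
  c(as.numeric(st$M), as.numeric(st$p), st$J, st$X, st$XA, st$XB,
    st$Xres, st$Xres2, st$alpha)
}

# final recorded row of a simulation
final_row <- function(sim) sim$series[nrow(sim$series), ]
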