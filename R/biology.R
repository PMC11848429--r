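# Population growth, genotype fitness, selection-mutation frequency
# dynamics and reproductive-event sampling for the four species A-D.

# round half away from zero; R's round() is round-half-even
round_half_away <- function(x) {
  ifelse(x >= 0, floor(x + 0.5), ceiling(x - 0.5))
}

#' Number of reaction-performing individuals
#'
#' The count of p-genotype individuals in a species: the frequency times
#' the population size, rounded to the nearest integer (ties rounded half
#' away from zero).
#'
#' @param p frequency of the reaction-performing genotype in `[0, 1]`.
#' @param M population size (>= 0). Vectorized over both arguments.
#' @return Integer-valued numeric vector of performer counts.
#' @examples
#' performer_count(0.5, 1000)   # 500
#' performer_count(0.3333, 10)  # 3
#' @export
performer_count <- function(p, M) {
  stopifnot(all(p >= 0 & p <= 1), all(M >= 0))
  round_half_away(p * M)
}

#' Logistic population growth with optional suppression kill term
#'
#' Time derivative of population size: logistic growth towards the
#' carrying capacity `K`, minus -- for the suppressed species only -- a
#' per-capita kill term `alpha * M`. The default growth form is
#' `g0 * M * (1 - (M/K)^2)`; the alternative `g0 * M * (1 - M/K)^2` is
#' available via `form` (both vanish at `M = K`, so the equilibrium is
#' unaffected).
#'
#' @param M population size (>= 0).
#' @param g0 baseline growth rate.
#' @param K carrying capacity (> 0).
#' @param alpha per-capita suppression rate (>= 0); only applied when
#'   `suppressed` is `TRUE`.
#' @param suppressed whether this species is the suppression target
#'   (species C).
#' @param form growth-form switch, see [cbv_params()].
#' @return dM/dt.
#' @examples
#' growth_rate(500, 1, 1000)        # 375
#' growth_rate(1000, 1, 1000)       # 0 at carrying capacity
#' growth_rate(100, 1, 1000, alpha = 1, suppressed = TRUE)
#' @export
growth_rate <- function(M, g0, K, alpha = 0, suppressed = FALSE,
                        form = c("capacity_squared",
                                 "squared_difference")) {
  stopifnot(all(M >= 0), K > 0, all(alpha >= 0))
  form <- match.arg(form)
  base <- if (form == "capacity_squared") {
    g0 * M * (1 - (M / K)^2)
  } else {
    g0 * M * (1 - M / K)^2
  }
  if (suppressed) base - M * alpha else base
}

#' Genotype fitnesses and population mean fitness
#'
#' Absolute fitness of the reaction-performing genotype is the baseline
#' fitness amplified (or penalized, `s < 0`) by the level of its substrate
#' J-variant: `W_p = W0 * (1 + s * J)`. The wild type has constant fitness
#' `W_q = W0`. The mean fitness is the count-weighted average over the two
#' genotypes, with the performer count from [performer_count()] and
#' `n_q = M - n_p`. An empty population (`M = 0`) has mean fitness defined
#' as `W0` (degenerate-population guard).
#'
#' @param p frequency of the reaction-performing genotype.
#' @param M population size.
#' @param J_substrate level of the substrate J-variant (>= 0 in normal
#'   use).
#' @param W0 baseline absolute fitness.
#' @param s selection sensitivity.
#' @return A list with components `W_p`, `W_q`, `W_mean`.
#' @examples
#' fitnesses(0.5, 1000, 1, W0 = 1, s = 0.01)
#' @export
fitnesses <- function(p, M, J_substrate, W0, s) {
  W_p <- W0 * (1 + s * J_substrate)
  W_q <- rep_len(W0, length(W_p))
  n_p <- performer_count(p, M)
  n_q <- M - n_p
  W_mean <- ifelse(M > 0, (W_p * n_p + W_q * n_q) / M, W0)
  list(W_p = W_p, W_q = W_q, W_mean = W_mean)
}

#' Asymmetric mutation rates
#'
#' The reaction-performing phenotype is a gain of function that mutation
#' is more likely to disrupt than create: the p-to-q rate is the baseline
#' `m0`, the reverse q-to-p rate is `m0^2` (an order of magnitude smaller
#' at the default `m0 = 0.1`).
#'
#' @param m0 baseline mutation probability in `[0, 1]`.
#' @return Named numeric vector `c(m0_p, m0_q)`.
#' @examples
#' mutation_rates(0.1)  # c(m0_p = 0.1, m0_q = 0.01)
#' @export
mutation_rates <- function(m0) {
  stopifnot(all(m0 >= 0 & m0 <= 1))
  c(m0_p = m0, m0_q = m0^2)
}

#' Sample realized mutation fractions over reproductive events
#'
#' The number of reproductive events per genotype is the product of its
#' absolute fitness and its frequency, rounded to the nearest integer
#' (optionally additionally multiplied by the population size, switch
#' `re_scale = "count"`). For each event one uniform random number `u` is
#' drawn; the event produces the parental genotype when `u - m0_k > 0`,
#' otherwise the opposite genotype. The realized mutation fraction is the
#' mutated share of events; it is 0 when a genotype has no events
#' (division-by-zero guard).
#'
#' Consumes `RE_p + RE_q` uniforms from the R random number stream (the
#' p-genotype events first).
#'
#' @param W_p,W_q absolute fitnesses of the two genotypes.
#' @param p,q genotype frequencies (`p + q = 1`).
#' @param m0_p,m0_q per-event mutation probabilities, see
#'   [mutation_rates()].
#' @param re_scale `"frequency"` (default) or `"count"`; the latter
#'   multiplies the event counts by `M`.
#' @param M population size, only used when `re_scale = "count"`.
#' @return A list with integer event counts `RE_p`, `RE_q`, same-genotype
#'   counts `same_p`, `same_q`, and realized mutation fractions `m_p`,
#'   `m_q`.
#' @examples
#' set.seed(1)
#' sample_mutations(1.01, 1, 0.5, 0.5, 0.1, 0.01)
#' @export
sample_mutations <- function(W_p, W_q, p, q, m0_p, m0_q,
                             re_scale = c("frequency", "count"),
                             M = NULL) {
  re_scale <- match.arg(re_scale)
  stopifnot(m0_p >= 0, m0_p <= 1, m0_q >= 0, m0_q <= 1)
  scale <- if (re_scale == "count") {
    stopifnot(!is.null(M))
    M
  } else 1
  RE_p <- as.integer(round_half_away(W_p * p * scale))
  RE_q <- as.integer(round_half_away(W_q * q * scale))
  same_p <- if (RE_p > 0) sum(stats::runif(RE_p) - m0_p > 0) else 0L
  same_q <- if (RE_q > 0) sum(stats::runif(RE_q) - m0_q > 0) else 0L
  m_p <- if (RE_p > 0) (RE_p - same_p) / RE_p else 0
  m_q <- if (RE_q > 0) (RE_q - same_q) / RE_q else 0
  list(RE_p = RE_p, RE_q = RE_q, same_p = same_p, same_q = same_q,
       m_p = m_p, m_q = m_q)
}

#' Genotype frequency derivatives
#'
#' Selection enters as the normalized difference between a genotype's
#' absolute fitness and the population mean fitness; mutation enters as
#' the realized mutation fractions, which move frequency from p to q and
#' back: `dp/dt = (W_p - W_mean)/W_mean - m_p + m_q` and
#' `dq/dt = (W_q - W_mean)/W_mean + m_p - m_q`. The mutation
#' contributions cancel between the two derivatives; the constraint
#' `p + q = 1` is maintained at the state level by the integrator, which
#' clamps p to `[0, 1]` and sets `q = 1 - p` after every step.
#'
#' @param W_p,W_q,W_mean fitnesses, see [fitnesses()]. `W_mean` must be
#'   strictly positive.
#' @param m_p,m_q realized mutation fractions, see [sample_mutations()].
#' @return A list with components `dp` and `dq`.
#' @examples
#' frequency_derivatives(1.01, 1, 1.005, 0, 0)
#' @export
frequency_derivatives <- function(W_p, W_q, W_mean, m_p, m_q) {
  if (any(W_mean <= 0))
    stop("W_mean must be > 0: invalid fitness state")
  list(dp = (W_p - W_mean) / W_mean - m_p + m_q,
       dq = (W_q - W_mean) / W_mean + m_p - m_q)
}
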