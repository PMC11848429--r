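#' Default model parameters
#'
#' Construct the full parameter set of the coupled biology / J-cycle /
#' X-cycle model. Defaults are the standard parameterization of the model:
#' an abiotic influx `Fin0` of each J-variant balanced by a linear removal
#' `Fout0`, Michaelis-Menten interconversion reactions saturating at `Rmax`
#' with half-saturation level `Km`, four species at carrying capacity `K`
#' whose reaction-performing p-genotype enhances substrate availability by
#' `rn_bar` per individual (capped at the bioavailable fraction `omega`),
#' selection sensitivity `s` of the p-genotype to its substrate level,
#' asymmetric mutation at baseline probability `m0` (loss of function an
#' order of magnitude more probable than gain, so the q-to-p rate is
#' `m0^2`), and a climate-like X-cycle fed by a fraction `eps_X` of the
#' material processed by reactions A and B.
#'
#' The X-cycle carries a depletable reservoir (`Xres_init` units) that must
#' be fully titrated by the byproduct reaction flux before any release
#' occurs, a release rate constant `Xrel0`, a bistable feedback of
#' amplitude `Xfeedback0` active between thresholds `Xon` and `Xoff`
#' (sigmoid steepnesses `a`, `b`), and a suppression function that kills
#' species C at per-capita rate up to `alpha0` once X exceeds `Xsuppress`
#' (sigmoid steepness `k_alpha`). `tau_J` and `tau_X` are the timescale
#' ratios by which the J-cycle and X-cycle clocks run slower than the
#' biological clock. `sigma_bar` scales every stochastic diffusion term;
#' `sigma_bar = 0` selects a fully deterministic mode in which mutation
#' fractions take their expected values and no random numbers are drawn.
#'
#' Three documented interpretation switches are exposed:
#' \describe{
#'   \item{`growth_form`}{`"capacity_squared"` (default) uses logistic
#'     growth `g0*M*(1 - (M/K)^2)`; `"squared_difference"` uses
#'     `g0*M*(1 - M/K)^2`. Both vanish at `M = K`.}
#'   \item{`re_scale`}{`"frequency"` (default) computes reproductive-event
#'     counts as `round(W * p)`, i.e. on the frequency scale, which yields
#'     0 or 1 events at baseline fitness; `"count"` multiplies by the
#'     population size `M`.}
#'   \item{`gS_combine`}{`"root_sum"` (default) combines the two genotypes'
#'     binomial variance rates in the biomass diffusion coefficient as
#'     `sqrt(v_p + v_q)`; `"product"` uses the literal product `v_p * v_q`.}
#' }
#'
#' @param Fin0 abiotic influx of each J-variant per J-cycle timestep.
#' @param Fout0 abiotic removal rate constant (per timestep).
#' @param Rmax maximum interconversion rate (J per timestep).
#' @param K carrying capacity (individuals).
#' @param rn_bar per-individual enhancement of effective substrate
#'   availability (defaults to `1/K`).
#' @param Km half-saturation level (units of J).
#' @param g0 baseline population growth rate (per timestep).
#' @param W0 baseline absolute fitness (offspring per individual per
#'   timestep).
#' @param s fitness sensitivity of the p-genotype to its substrate level;
#'   may be negative (self-limiting reaction).
#' @param Ji0 normalization level for cycling ratios.
#' @param m0 baseline mutation probability per reproductive event.
#' @param eps_X fraction of J diverted to the X-cycle by reactions A and B.
#' @param Xrel0 reservoir release rate constant.
#' @param Xfeedback0 bistable feedback amplitude.
#' @param Xon,Xoff lower/upper thresholds of the unstable region
#'   (`Xon < Xoff`).
#' @param a,b sigmoid steepness constants of the bistable feedback.
#' @param tau_J,tau_X timescale ratios (>= 1) of the J-cycle and X-cycle
#'   relative to the biological clock.
#' @param Xsuppress level of X at which suppression of species C switches
#'   on.
#' @param alpha0 baseline suppression magnitude in `[0, 1]`.
#' @param k_alpha suppression sigmoid steepness.
#' @param omega maximum bioavailable substrate fraction in `(0, 1]`.
#' @param Xvar0 baseline byproduct-reaction efficiency in `[0, 1]`.
#' @param sigma_bar overall stochastic sensitivity (0 = deterministic
#'   mode).
#' @param Xin0 X influx constant.
#' @param Xout0 removal rate constant for X, XA and XB.
#' @param Xres_init initial size of the unreleased reservoir.
#' @param Xres_tol reservoir depletion threshold (units of X): the
#'   reservoir is treated as fully titrated -- clamped to exactly 0,
#'   which arms the release flux -- once less than this much remains.
#'   The reservoir equation is an exponential decay that never reaches 0
#'   exactly, so a threshold is structurally required; the default
#'   treats the last unit (the scale of one abiotic influx unit) as
#'   depleted, making complete titration attainable on observable
#'   horizons while leaving essentially the whole reservoir to be
#'   released.
#' @param growth_form,re_scale,gS_combine interpretation switches, see
#'   Details.
#'
#' @return An object of class `cbv_params`: a named list of all model
#'   constants.
#' @seealso [validate_params()], [read_config()], [run_simulation()]
#' @examples
#' p <- cbv_params()
#' p$K
#' cbv_params(s = 0, m0 = 0.05)$m0
#' @export
cbv_params <- function(Fin0 = 1,
                       Fout0 = Fin0,
                       Rmax = Fin0,
                       K = 1000,
                       rn_bar = 1 / K,
                       Km = 1,
                       g0 = 1,
                       W0 = 1,
                       s = 0.01,
                       Ji0 = Fin0,
                       m0 = 0.1,
                       eps_X = 0.5,
                       Xrel0 = 1,
                       Xfeedback0 = 3,
                       Xon = 3,
                       Xoff = 6,
                       a = 10,
                       b = 10,
                       tau_J = 2,
                       tau_X = 10,
                       Xsuppress = 3.5,
                       alpha0 = 1,
                       k_alpha = 20,
                       omega = 1,
                       Xvar0 = 1,
                       sigma_bar = 1,
                       Xin0 = 1,
                       Xout0 = 1,
                       Xres_init = 5,
                       Xres_tol = 1,
                       growth_form = c("capacity_squared",
                                       "squared_difference"),
                       re_scale = c("frequency", "count"),
                       gS_combine = c("root_sum", "product")) {
  p <- list(
    Fin0 = Fin0, Fout0 = Fout0, Rmax = Rmax, K = K, rn_bar = rn_bar,
    Km = Km, g0 = g0, W0 = W0, s = s, Ji0 = Ji0, m0 = m0, eps_X = eps_X,
    Xrel0 = Xrel0, Xfeedback0 = Xfeedback0, Xon = Xon, Xoff = Xoff,
    a = a, b = b, tau_J = tau_J, tau_X = tau_X, Xsuppress = Xsuppress,
    alpha0 = alpha0, k_alpha = k_alpha, omega = omega, Xvar0 = Xvar0,
    sigma_bar = sigma_bar, Xin0 = Xin0, Xout0 = Xout0,
    Xres_init = Xres_init, Xres_tol = Xres_tol,
    growth_form = match.arg(growth_form),
    re_scale = match.arg(re_scale),
    gS_combine = match.arg(gS_combine)
  )
  class(p) <- "cbv_params"
  p
}

# numeric parameter fields, in canonical order
.param_numeric_fields <- c(
  "Fin0", "Fout0", "Rmax", "K", "rn_bar", "Km", "g0", "W0", "s", "Ji0",
  "m0", "eps_X", "Xrel0", "Xfeedback0", "Xon", "Xoff", "a", "b",
  "tau_J", "tau_X", "Xsuppress", "alpha0", "k_alpha", "omega", "Xvar0",
  "sigma_bar", "Xin0", "Xout0", "Xres_init", "Xres_tol"
)
.param_switch_fields <- c("growth_form", "re_scale", "gS_combine")

#' Validate a parameter set
#'
#' Checks every invariant of the model parameter set and returns the
#' violations as a character vector (empty when the set is valid). Nothing
#' is raised: callers that want hard failure should `stop()` on a
#' non-empty result.
#'
#' @param params a [cbv_params] object (or plain named list with the same
#'   fields).
#' @return Character vector of violation messages, each naming the
#'   offending field and the bound it breaks. Length zero if valid.
#' @examples
#' validate_params(cbv_params())           # character(0)
#' validate_params(cbv_params(m0 = -0.1))  # names m0
#' @export
validate_params <- function(params) {
  v <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) v <<- c(v, msg)
  num <- params[.param_numeric_fields]
  bad <- !vapply(num, function(x) is.numeric(x) && length(x) == 1 &&
                   is.finite(x), logical(1))
  if (any(bad)) {
    v <- c(v, paste0(names(num)[bad],
                     ": must be a single finite numeric value"))
    return(v)
  }
  nonneg <- c("Fin0", "Fout0", "Rmax", "Km", "g0", "W0", "Ji0", "Xrel0",
              "Xfeedback0", "Xon", "Xoff", "a", "b", "Xsuppress",
              "k_alpha", "sigma_bar", "Xin0", "Xout0", "Xres_init",
              "Xres_tol")
  for (f in nonneg)
    chk(params[[f]] >= 0, paste0(f, ": must be non-negative"))
  for (f in c("m0", "eps_X", "omega", "alpha0", "Xvar0"))
    chk(params[[f]] >= 0 && params[[f]] <= 1,
        paste0(f, ": must be in [0, 1]"))
  chk(params$K >= 1, "K: must be >= 1")
  chk(params$rn_bar >= 0, "rn_bar: must be non-negative")
  chk(params$tau_J >= 1, "tau_J: must be >= 1")
  chk(params$tau_X >= 1, "tau_X: must be >= 1")
  chk(params$Xon < params$Xoff, "Xon: must be < Xoff")
  for (f in .param_switch_fields)
    chk(is.character(params[[f]]) && length(params[[f]]) == 1,
        paste0(f, ": must be a single string"))
  chk(params$growth_form %in% c("capacity_squared", "squared_difference"),
      "growth_form: must be 'capacity_squared' or 'squared_difference'")
  chk(params$re_scale %in% c("frequency", "count"),
      "re_scale: must be 'frequency' or 'count'")
  chk(params$gS_combine %in% c("root_sum", "product"),
      "gS_combine: must be 'root_sum' or 'product'")
  v
}

#' Reaction topology of the J-cycle
#'
#' The fixed wiring of the four interconversion reactions: species A
#' consumes J1 and produces J2, B consumes J2 and produces J1 (together
#' the two-membered cycle variant AB), C consumes J1 and produces J3, and
#' D consumes J3 and produces J2 (with B, the three-membered variant CDB).
#'
#' @return A data frame with columns `species`, `substrate`, `product`
#'   (variant indices 1-3).
#' @examples
#' reaction_topology()
#' @export
reaction_topology <- function() {
  data.frame(
    species = c("A", "B", "C", "D"),
    substrate = c(1L, 2L, 1L, 3L),
    product = c(2L, 1L, 3L, 2L),
    stringsAsFactors = FALSE
  )
}

#' Run settings
#'
#' Settings for a single simulation run: horizon, biological timestep,
#' RNG seed, recording cadence, optional `sigma_bar` override and optional
#' initial-state overrides.
#'
#' @param n_steps number of biological timesteps (>= 1).
#' @param dt_bio biological timestep (> 0).
#' @param seed integer RNG seed.
#' @param record_every record the state every this many steps (the initial
#'   state is always recorded). Use `n_steps` to keep only the first and
#'   final states.
#' @param sigma_bar optional override of the parameter set's `sigma_bar`.
#' @param init optional named list of initial-state overrides; allowed
#'   names: `M` (length 4), `p` (length 4), `J` (length 3), `X`, `XA`,
#'   `XB`, `Xres`, `Xres2`.
#' @return An object of class `cbv_run`.
#' @examples
#' run_config(n_steps = 500, seed = 42)
#' @export
run_config <- function(n_steps = 2000, dt_bio = 1, seed = 1,
                       record_every = 1, sigma_bar = NULL, init = NULL) {
  stopifnot(is.numeric(n_steps), length(n_steps) == 1, n_steps >= 1,
            is.numeric(dt_bio), length(dt_bio) == 1, dt_bio > 0,
            is.numeric(seed), length(seed) == 1,
            is.numeric(record_every), record_every >= 1)
  if (!is.null(init)) {
    allowed <- c("M", "p", "J", "X", "XA", "XB", "Xres", "Xres2")
    bad <- setdiff(names(init), allowed)
    if (length(bad))
      stop("unknown init field(s): ", paste(bad, collapse = ", "))
  }
  r <- list(n_steps = as.integer(n_steps), dt_bio = dt_bio,
            seed = as.integer(seed),
            record_every = as.integer(record_every),
            sigma_bar = sigma_bar, init = init)
  class(r) <- "cbv_run"
  r
}

#' Read a model configuration file
#'
#' Reads a flat YAML document whose keys mirror the [cbv_params()] and
#' [run_config()] field names. Unspecified keys fall back to the defaults;
#' unknown keys are an error (reported by name); the resolved parameter
#' set must pass [validate_params()].
#'
#' @param path path to a YAML configuration file.
#' @return A list with components `params` (a `cbv_params`) and `run`
#'   (a `cbv_run`).
#' @seealso [write_config()]
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines("tau_X: 20", f)
#' read_config(f)$params$tau_X
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  if (!is.list(raw)) stop("config must be a mapping of key: value pairs")
  par_fields <- c(.param_numeric_fields, .param_switch_fields)
  # sigma_bar in a config file is the model parameter; the run-level
  # override exists only at the API level
  run_fields <- c("n_steps", "dt_bio", "seed", "record_every", "init")
  unknown <- setdiff(names(raw), c(par_fields, run_fields))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  params <- do.call(cbv_params, raw[intersect(names(raw), par_fields)])
  viol <- validate_params(params)
  if (length(viol))
    stop("invalid parameter value(s):\n  ", paste(viol, collapse = "\n  "))
  run <- do.call(run_config, raw[intersect(names(raw), run_fields)])
  list(params = params, run = run)
}

#' Write a model configuration file
#'
#' Serializes a parameter set (and optionally run settings) to a flat
#' YAML document that [read_config()] reads back unchanged.
#'
#' @param params a [cbv_params] object.
#' @param path output file path.
#' @param run optional [run_config] object to include.
#' @return `path`, invisibly.
#' @export
write_config <- function(params, path, run = NULL) {
  out <- params[c(.param_numeric_fields, .param_switch_fields)]
  if (!is.null(run)) {
    r <- run[c("n_steps", "dt_bio", "seed", "record_every")]
    if (!is.null(run$init)) r$init <- run$init
    out <- c(out, r)
  }
  yaml::write_yaml(out, path, precision = 17)
  invisible(path)
}

#' Write a run metadata sidecar
#'
#' JSON document with the resolved parameter set, run settings, seed and
#' package version, written next to every experiment output so a run can
#' be reproduced bit-for-bit.
#'
#' @param path output file path.
#' @param params resolved [cbv_params].
#' @param run resolved [cbv_run] (optional).
#' @param extra optional named list of extra metadata (e.g. grids).
#' @return `path`, invisibly.
#' @export
write_run_metadata <- function(path, params, run = NULL, extra = NULL) {
  meta <- list(
    package = "cbvsim",
    version = as.character(utils::packageVersion("cbvsim")),
    params = unclass(params),
    noise_increment = "sigma_bar * g * sqrt(dt) * N(0,1)"
  )
  if (!is.null(run)) meta$run <- unclass(run)
  if (!is.null(extra)) meta <- c(meta, extra)
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' @export
print.cbv_params <- function(x, ...) {
  cat("<cbv_params>\n")
  num <- unlist(x[.param_numeric_fields])
  cat(paste0("  ", format(names(num), width = 11), " ",
             format(num, trim = TRUE)), sep = "\n")
  cat("  switches:", paste(unlist(x[.param_switch_fields]),
                           collapse = ", "), "\n")
  invisible(x)
}
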