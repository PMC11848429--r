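# Experiment harness: single-run timescale contrasts, replicate-averaged
# steady-state sweeps over selection/mutation/feedback parameters, and
# correlation analyses between suppression and CBV dominance.

#' Timescale-separation contrast runs
#'
#' Runs the full model once per value of the X-cycle timescale ratio
#' `tau_X`, with otherwise identical parameters and the same seed, so
#' that the only difference between the runs is how many biological
#' generations the X-cycle dynamics are spread over. This is the model's
#' central demonstration: with sufficient timescale overlap the byproduct
#' flux titrates the reservoir within the horizon, triggering release,
#' the bistable jump in X, suppression of species C and displacement of
#' the CDB cycle variant by AB; a modestly larger separation leaves the
#' system at its initial equilibrium.
#'
#' @param params a [cbv_params] object.
#' @param run a [run_config] object (the same seed is used for every
#'   `tau_X`).
#' @param tau_X_values numeric vector of timescale ratios to contrast.
#' @return A named list of [run_simulation()] results, one per `tau_X`
#'   (names `"tau_X=<value>"`).
#' @examples
#' \donttest{
#' res <- run_single(cbv_params(sigma_bar = 0),
#'                   run_config(n_steps = 500), tau_X_values = c(10, 20))
#' sapply(res, function(r) r$final$alpha)
#' }
#' @export
run_single <- function(params = cbv_params(), run = run_config(),
                       tau_X_values = c(10, 20)) {
  stopifnot(length(tau_X_values) >= 1, all(tau_X_values >= 1))
  out <- lapply(tau_X_values, function(tx) {
    p2 <- params
    p2$tau_X <- tx
    run_simulation(p2, run)
  })
  names(out) <- paste0("tau_X=", tau_X_values)
  out
}

.sweep_axes_allowed <- c("s", "m0", "Xvar0", "alpha0", "tau_X")

#' Define a two-axis sweep grid
#'
#' @param axes named list of exactly two ordered numeric vectors; names
#'   must be among `s`, `m0`, `Xvar0`, `alpha0`, `tau_X`.
#' @param fixed named list of additional parameter overrides applied to
#'   every cell (e.g. `list(Xvar0 = 0)` for the no-feedback condition).
#' @param replicates replicate simulations per grid cell (>= 1).
#' @param base_seed integer; per-replicate seeds are derived purely from
#'   `(base_seed, cell index, replicate index)`.
#' @return An object of class `cbv_grid`.
#' @seealso [standard_sweeps()] for the three standard sweep rows.
#' @examples
#' sweep_grid(list(s = c(0, 0.02), m0 = c(0.05, 0.2)), replicates = 3)
#' @export
sweep_grid <- function(axes, fixed = list(), replicates = 50,
                       base_seed = 1) {
  stopifnot(is.list(axes), length(axes) == 2,
            !is.null(names(axes)), all(names(axes) != ""),
            replicates >= 1)
  bad <- setdiff(names(axes), .sweep_axes_allowed)
  if (length(bad))
    stop("unsupported sweep axis: ", paste(bad, collapse = ", "))
  for (ax in axes)
    stopifnot(is.numeric(ax), all(is.finite(ax)), length(ax) >= 1)
  g <- list(axes = axes, fixed = fixed,
            replicates = as.integer(replicates),
            base_seed = as.integer(base_seed))
  class(g) <- "cbv_grid"
  g
}

#' The three standard sweep rows
#'
#' The standard sensitivity analysis: (1) selection x mutation with the
#' byproduct flux switched off (`Xvar0 = 0`, no X-cycle feedback), (2)
#' selection x mutation with full feedback (`Xvar0 = 1, alpha0 = 1`), and
#' (3) byproduct-flux magnitude x suppression magnitude at fixed
#' selection and mutation. Selection is linearly spaced on `[0, 0.05]`,
#' mutation log-spaced on `[0.01, 0.3]`, and the feedback magnitudes
#' linearly spaced on `[0, 1]`.
#'
#' @param n_axis grid points per axis.
#' @param replicates replicates per cell.
#' @param base_seed base seed for replicate-seed derivation.
#' @return Named list of three [sweep_grid()] objects:
#'   `no_feedback`, `feedback`, `feedback_magnitude`.
#' @export
standard_sweeps <- function(n_axis = 5, replicates = 50, base_seed = 1) {
  s_axis <- seq(0, 0.05, length.out = n_axis)
  m0_axis <- 10^seq(log10(0.01), log10(0.3), length.out = n_axis)
  mag_axis <- seq(0, 1, length.out = n_axis)
  list(
    no_feedback = sweep_grid(
      list(s = s_axis, m0 = m0_axis),
      fixed = list(Xvar0 = 0),
      replicates = replicates, base_seed = base_seed),
    feedback = sweep_grid(
      list(s = s_axis, m0 = m0_axis),
      fixed = list(Xvar0 = 1, alpha0 = 1),
      replicates = replicates, base_seed = base_seed),
    feedback_magnitude = sweep_grid(
      list(Xvar0 = mag_axis, alpha0 = mag_axis),
      fixed = list(s = 0.01, m0 = 0.1),
      replicates = replicates, base_seed = base_seed)
  )
}

# pure function of (base seed, cell, replicate); keeps seeds < 2^31
cell_seed <- function(base_seed, cell, rep) {
  as.integer((as.double(base_seed) + 131071 * as.double(cell) +
                524287 * as.double(rep)) %% 2147483647)
}

#' Run a replicate-averaged parameter sweep
#'
#' For every cell of the grid, runs `replicates` seeded simulations,
#' extracts the final-state metrics -- mean J-variant level
#' `(J1+J2+J3)/3`, X, the cross-species mean p-frequency, the
#' suppression level alpha, and the normalized CBV shares -- and averages
#' them over replicates. Per-replicate finals are retained for the
#' correlation analysis ([correlate_sweep()]). Per-replicate seeds are a
#' pure function of the grid's base seed and the cell/replicate indices,
#' so any single cell can be re-run in isolation and reproduces its
#' replicates exactly.
#'
#' A convergence diagnostic is reported per replicate: the relative
#' change of the mean J level over the last 10% of the run (not
#' enforced). A failed replicate is recorded (cell, replicate, seed,
#' message) and the cell mean is computed over the successes.
#'
#' @param params base [cbv_params]; axis values and `fixed` overrides are
#'   applied per cell.
#' @param grid a [sweep_grid()].
#' @param run a [run_config()]; its seed is ignored in favour of derived
#'   per-replicate seeds, and recording is reduced to a coarse cadence.
#' @return An object of class `cbv_sweep`: list with `cells` (one row
#'   per grid cell with replicate-averaged finals), `replicates` (one row
#'   per (cell, replicate)), `failures`, `grid`, `params`.
#' @examples
#' \donttest{
#' g <- sweep_grid(list(s = c(0, 0.05), m0 = c(0.1)), replicates = 2)
#' sw <- run_sweep(cbv_params(), g, run_config(n_steps = 200))
#' sw$cells
#' }
#' @export
run_sweep <- function(params = cbv_params(), grid, run = run_config()) {
  stopifnot(inherits(grid, "cbv_grid"))
  ax_names <- names(grid$axes)
  cells <- expand.grid(grid$axes[[1]], grid$axes[[2]],
                       KEEP.OUT.ATTRS = FALSE)
  names(cells) <- ax_names
  n_cells <- nrow(cells)
  # coarse recording: enough points for the convergence diagnostic
  run$record_every <- max(1L, as.integer(ceiling(run$n_steps / 10)))
  reps <- vector("list", n_cells * grid$replicates)
  fails <- list()
  k <- 0
  for (ci in seq_len(n_cells)) {
    p2 <- params
    for (ax in ax_names) p2[[ax]] <- cells[ci, ax]
    for (nm in names(grid$fixed)) p2[[nm]] <- grid$fixed[[nm]]
    for (ri in seq_len(grid$replicates)) {
      run2 <- run
      run2$seed <- cell_seed(grid$base_seed, ci, ri)
      res <- tryCatch(run_simulation(p2, run2), error = identity)
      k <- k + 1
      if (inherits(res, "error")) {
        fails[[length(fails) + 1]] <-
          data.frame(cell = ci, rep = ri, seed = run2$seed,
                     message = conditionMessage(res))
        next
      }
      s <- res$series
      fin <- s[nrow(s), ]
      mean_J <- (fin$J1 + fin$J2 + fin$J3) / 3
      i90 <- which.min(abs(s$t - 0.9 * max(s$t)))
      mJ90 <- (s$J1[i90] + s$J2[i90] + s$J3[i90]) / 3
      conv <- if (abs(mJ90) > 0) abs(mean_J - mJ90) / abs(mJ90) else
        abs(mean_J - mJ90)
      reps[[k]] <- data.frame(
        cell = ci, cells[ci, , drop = FALSE], rep = ri,
        seed = run2$seed, mean_J = mean_J, X = fin$X,
        mean_p = fin$mean_p, alpha = fin$alpha,
        cbv_AB_norm = fin$cbv_AB_norm, cbv_CDB_norm = fin$cbv_CDB_norm,
        conv_rel_change = conv, row.names = NULL)
    }
  }
  reps <- do.call(rbind, reps[!vapply(reps, is.null, logical(1))])
  agg <- function(v) tapply(v, reps$cell, mean)
  idx <- sort(unique(reps$cell))
  cell_df <- data.frame(
    cell = idx, cells[idx, , drop = FALSE],
    n = as.integer(table(factor(reps$cell, levels = idx))),
    mean_J = agg(reps$mean_J), X = agg(reps$X),
    mean_p = agg(reps$mean_p), alpha = agg(reps$alpha),
    cbv_AB_norm = agg(reps$cbv_AB_norm),
    cbv_CDB_norm = agg(reps$cbv_CDB_norm),
    conv_rel_change = agg(reps$conv_rel_change),
    row.names = NULL)
  out <- list(cells = cell_df, replicates = reps,
              failures = if (length(fails)) do.call(rbind, fails) else NULL,
              grid = grid, params = params, run = run)
  class(out) <- "cbv_sweep"
  out
}

#' @export
print.cbv_sweep <- function(x, ...) {
  cat("<cbv_sweep> ", nrow(x$cells), " cells x ", x$grid$replicates,
      " replicates (axes: ", paste(names(x$grid$axes), collapse = " x "),
      ")\n", sep = "")
  if (!is.null(x$failures))
    cat("  failed replicates:", nrow(x$failures), "\n")
  print(utils::head(x$cells, 10))
  invisible(x)
}

#' Correlation between suppression and CBV dominance
#'
#' For each grid cell, the Pearson correlation across replicates between
#' the final suppression level alpha and the final normalized share of
#' the AB cycle variant; cells with zero variance in either variable (or
#' fewer than 2 replicates) are flagged undefined. Pooled over all
#' replicates, a degree-1 least-squares regression of the share on alpha
#' and the overall correlation coefficient. A positive pooled correlation
#' is the signature of persistence selection: the climatic suppression
#' that a variant's byproducts trigger covaries with the direction of
#' variant displacement.
#'
#' @param sweep a [run_sweep()] result (or a data frame shaped like its
#'   `replicates` component, with columns `cell`, `alpha`,
#'   `cbv_AB_norm`).
#' @return An object of class `cbv_correlation`: list with `cells` (per
#'   cell: `r`, `n`, `defined`) and `pooled` (list with `slope`,
#'   `intercept`, `r`, `n`; `r` and the fit are `NA` when either pooled
#'   variable is constant).
#' @export
correlate_sweep <- function(sweep) {
  reps <- if (inherits(sweep, "cbv_sweep")) sweep$replicates else sweep
  stopifnot(all(c("cell", "alpha", "cbv_AB_norm") %in% names(reps)))
  cells <- sort(unique(reps$cell))
  per_cell <- do.call(rbind, lapply(cells, function(ci) {
    d <- reps[reps$cell == ci, ]
    ok <- nrow(d) >= 2 && stats::sd(d$alpha) > 0 &&
      stats::sd(d$cbv_AB_norm) > 0
    data.frame(cell = ci, n = nrow(d),
               r = if (ok) stats::cor(d$alpha, d$cbv_AB_norm) else NA_real_,
               defined = ok)
  }))
  pooled_ok <- nrow(reps) >= 2 &&
    isTRUE(stats::sd(reps$alpha) > 0) &&
    isTRUE(stats::sd(reps$cbv_AB_norm) > 0)
  pooled <- if (pooled_ok) {
    fit <- stats::lm(cbv_AB_norm ~ alpha, data = reps)
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r = stats::cor(reps$alpha, reps$cbv_AB_norm),
         n = nrow(reps))
  } else {
    list(slope = NA_real_, intercept = NA_real_, r = NA_real_,
         n = nrow(reps))
  }
  out <- list(cells = per_cell, pooled = pooled)
  class(out) <- "cbv_correlation"
  out
}

#' @export
print.cbv_correlation <- function(x, ...) {
  cat("<cbv_correlation>\n")
  cat("  pooled: r =", format(x$pooled$r, digits = 3),
      "slope =", format(x$pooled$slope, digits = 3),
      "n =", x$pooled$n, "\n")
  cat("  cells defined:", sum(x$cells$defined), "/", nrow(x$cells), "\n")
  invisible(x)
}
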