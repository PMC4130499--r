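# Named, parameter-complete presets reproducing the figure-level
# experiments: permeability sweeps, gradient families, protein
# surface-fraction sweeps, pump/SPAP combinations, turnover and
# stoichiometry comparisons, and external-pH fluctuations.
#
# A scenario is a list with:
#   base  : named arguments for protocell_config()
#   sweep : named list of axes; each axis is an atomic vector (one
#           config argument varied alone) or a data frame (arguments
#           varied jointly, e.g. a pH-gradient family)
#   fluctuation : default fluctuation_spec() arguments, if any
# Special sweep/base keys "<kind>.<field>" (e.g. "atpase.ions_per_cycle")
# are routed into protein_overrides.

PERM_GRID <- 10^seq(-6, -2)

scenario_registry <- function() {
  list(
    fig3a = list(
      description = "free energy vs H+ permeability, 1% ATPase, pH 7:10",
      base = list(atpase = 0.01),
      sweep = list(perm_H_cm_s = PERM_GRID)),
    fig3b = list(
      description = "gradient size at low permeability 1e-6 cm/s, 1% ATPase",
      base = list(atpase = 0.01, perm_H_cm_s = 1e-6),
      sweep = list(pH_alk = c(8, 9, 10, 11))),
    fig3c = list(
      description = "crowding: ATPase surface fraction at 1e-3 cm/s",
      base = list(perm_H_cm_s = 1e-3),
      sweep = list(atpase = c(0.01, 0.05, 0.10, 0.50))),
    fig3d = list(
      description = "Ech instead of ATPase at 1e-3 cm/s",
      base = list(perm_H_cm_s = 1e-3),
      sweep = list(ech = c(0.01, 0.05, 0.10, 0.50))),
    fig4a = list(
      description = "H+ pump without SPAP across permeabilities",
      base = list(atpase = 0.01, pump_ion = "H", t_end = 1500,
                  steady_window = 60),
      sweep = list(pump = c(0.01, 0.05), perm_H_cm_s = PERM_GRID)),
    fig4b = list(
      description = "Na+ pump without SPAP across permeabilities",
      base = list(atpase = 0.01, pump_ion = "Na", t_end = 1500,
                  steady_window = 60),
      sweep = list(pump = c(0.01, 0.05), perm_H_cm_s = PERM_GRID)),
    fig4c = list(
      description = "H+ pump with no external gradient",
      base = list(pH_acid = 7, pH_alk = 7, atpase = 0.01, pump_ion = "H",
                  t_end = 1500, steady_window = 60),
      sweep = list(pump = c(0.01, 0.05), perm_H_cm_s = PERM_GRID)),
    fig4d = list(
      description = "Na+ pump with no external gradient",
      base = list(pH_acid = 7, pH_alk = 7, atpase = 0.01, pump_ion = "Na",
                  t_end = 1500, steady_window = 60),
      sweep = list(pump = c(0.01, 0.05), perm_H_cm_s = PERM_GRID)),
    fig5a = list(
      description = "SPAP time course: initial collapse, then recovery",
      base = list(atpase = 0.01, spap = 0.05, perm_H_cm_s = 1e-3,
                  t_end = 900, steady_tol = 1e-6, steady_window = 120),
      sweep = list()),
    fig5b = list(
      description = "SPAP fraction across equal 3-unit gradients",
      base = list(atpase = 0.01, perm_H_cm_s = 1e-3, t_end = 2400,
                  steady_window = 60),
      sweep = list(spap = c(0, 0.01, 0.05, 0.10),
                   gradient = data.frame(pH_acid = c(7, 6, 5),
                                         pH_alk = c(10, 9, 8)))),
    fig5c = list(
      description = "SPAP in weak gradients (7.5:10, 8:10, 8.5:10)",
      base = list(atpase = 0.01, perm_H_cm_s = 1e-3, pH_alk = 10,
                  t_end = 2400, steady_window = 60),
      sweep = list(spap = c(0.01, 0.05, 0.10),
                   pH_acid = c(7.5, 8, 8.5))),
    fig6a = list(
      description = "H+ pump with 1% SPAP across permeabilities",
      base = list(atpase = 0.01, spap = 0.01, pump_ion = "H",
                  t_end = 1500, steady_window = 60),
      sweep = list(pump = c(0.01, 0.05), perm_H_cm_s = PERM_GRID)),
    fig6b = list(
      description = "Na+ pump with 1% SPAP across permeabilities",
      base = list(atpase = 0.01, spap = 0.01, pump_ion = "Na",
                  t_end = 1500, steady_window = 60),
      sweep = list(pump = c(0.01, 0.05), perm_H_cm_s = PERM_GRID)),
    fig6c = list(
      description = "SPAP + 5% H+ pump in weakening gradients",
      base = list(atpase = 0.01, spap = 0.01, pump = 0.05, pump_ion = "H",
                  pH_alk = 10, t_end = 1500, steady_window = 60),
      sweep = list(pH_acid = c(7, 7.5, 8), perm_H_cm_s = PERM_GRID)),
    fig6d = list(
      description = "SPAP + pump with no external gradient",
      base = list(pH_acid = 7, pH_alk = 7, atpase = 0.01, spap = 0.01,
                  pump_ion = "H", t_end = 1500, steady_window = 60),
      sweep = list(pump = c(0.01, 0.05), perm_H_cm_s = PERM_GRID)),
    figS1 = list(
      description = "enzyme efficiency 10/50/100% of modern turnover",
      base = list(atpase = 0.01, spap = 0.01, pump = 0.05, pump_ion = "H",
                  perm_H_cm_s = 1e-3, t_end = 1500, steady_window = 60),
      sweep = list(efficiency_scale = c(0.1, 0.5, 1.0))),
    figS2 = list(
      description = "ATPase stoichiometry 3.3 vs 6 H+ per ATP",
      base = list(atpase = 0.01, perm_H_cm_s = 1e-3),
      sweep = list(atpase.ions_per_cycle = c(3.3, 6))),
    figS3 = list(
      description = "fluctuating acidic pH, alkaline side fixed at 10",
      base = list(atpase = 0.01, perm_H_cm_s = 1e-3, t_end = 600),
      sweep = list(spap = c(0, 0.05)),
      fluctuation = list(side = "acid")),
    figS4 = list(
      description = "fluctuating alkaline pH, acidic side fixed at 7",
      base = list(atpase = 0.01, perm_H_cm_s = 1e-3, t_end = 600),
      sweep = list(spap = c(0, 0.05)),
      fluctuation = list(side = "alk")),
    figS5 = list(
      description = "acid adaptation: pump + SPAP across 3-unit gradients",
      base = list(atpase = 0.01, spap = 0.01, pump = 0.05, pump_ion = "H",
                  t_end = 1500, steady_window = 60),
      sweep = list(gradient = data.frame(pH_acid = c(5, 6, 7),
                                         pH_alk = c(8, 9, 10)),
                   perm_H_cm_s = PERM_GRID)),
    open_system = list(
      description = "open-system reference: interior clamped to the alkaline fluid",
      base = list(atpase = 0.01, perm_H_cm_s = 1e-2),
      sweep = list())
  )
}

#' List the available scenario presets
#'
#' @return Data frame with scenario `name` and `description`.
#' @examples
#' list_scenarios()
#' @export
list_scenarios <- function() {
  reg <- scenario_registry()
  data.frame(name = names(reg),
             description = vapply(reg, `[[`, "", "description"),
             row.names = NULL)
}

# Split "<kind>.<field>" keys off into protein_overrides.
route_protein_keys <- function(args) {
  keys <- names(args)
  special <- grepl("^(atpase|ech|spap|pump)\\.", keys)
  if (!any(special)) return(args)
  ov <- args$protein_overrides %||% list()
  for (k in keys[special]) {
    parts <- strsplit(k, ".", fixed = TRUE)[[1]]
    ov[[parts[1]]][[parts[2]]] <- args[[k]]
  }
  args <- args[!special]
  args$protein_overrides <- ov
  args
}

#' Resolve a named scenario to a fully specified configuration
#'
#' Looks the scenario up in the preset registry, applies user overrides
#' (which win over preset values), and returns the resolved bundle. A
#' key of the form `"atpase.ions_per_cycle"` addresses a single protein
#' constant.
#'
#' @param name Scenario name; see [list_scenarios()].
#' @param overrides Named list of [protocell_config()] arguments.
#' @return List of class `scenario` with `name`, `base` (full argument
#'   list), `sweep` axes and optional `fluctuation` defaults.
#' @examples
#' sc <- resolve_scenario("fig3a", list(t_end = 60))
#' names(sc$sweep)
#' @export
resolve_scenario <- function(name, overrides = list()) {
  reg <- scenario_registry()
  if (!name %in% names(reg))
    stop("unknown scenario '", name, "'; available: ",
         paste(names(reg), collapse = ", "), call. = FALSE)
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(names(overrides) == "")))
    stop("scenario overrides must be named", call. = FALSE)
  sc <- reg[[name]]
  base <- sc$base
  for (k in names(overrides)) base[[k]] <- overrides[[k]]
  base <- route_protein_keys(base)
  # every resolved scenario must build a valid config
  do.call(protocell_config, base[setdiff(names(base), "")])
  structure(list(name = name, description = sc$description, base = base,
                 sweep = sc$sweep %||% list(),
                 fluctuation = sc$fluctuation),
            class = "scenario")
}

sweep_grid <- function(axes) {
  if (!length(axes)) return(data.frame(.row = 1)[, 0, drop = FALSE])
  pieces <- lapply(axes, function(ax) {
    if (is.data.frame(ax)) seq_len(nrow(ax)) else seq_along(ax)
  })
  idx <- expand.grid(pieces, KEEP.OUT.ATTRS = FALSE)
  out <- NULL
  for (j in seq_along(axes)) {
    ax <- axes[[j]]
    cols <- if (is.data.frame(ax)) ax[idx[[j]], , drop = FALSE]
            else stats::setNames(data.frame(ax[idx[[j]]]), names(axes)[j])
    out <- if (is.null(out)) cols else cbind(out, cols)
  }
  rownames(out) <- NULL
  out
}

#' Execute a scenario's full parameter sweep
#'
#' Runs the Cartesian product of the scenario's sweep axes (a single
#' run when there are none), one simulation per cell, and tabulates the
#' steady-state summaries in deterministic order. A failing cell is
#' recorded in its row (`error` column) and the sweep continues.
#'
#' @param scenario A [resolve_scenario()] result, or a scenario name.
#' @param overrides Passed to [resolve_scenario()] when `scenario` is a
#'   name.
#' @return Data frame of class `sweep_result`: one row per cell with
#'   the axis values, `minus_dG_H`, `minus_dG_Na`, `minus_dG_reported`
#'   (kJ/mol), `dpsi` (V), `pH_in`, `t_final`, `stop_reason`, `error`.
#' @examples
#' \donttest{
#' run_sweep("fig3a", list(t_end = 30))
#' }
#' @export
run_sweep <- function(scenario, overrides = list()) {
  if (is.character(scenario))
    scenario <- resolve_scenario(scenario, overrides)
  stopifnot(inherits(scenario, "scenario"))
  grid <- sweep_grid(scenario$sweep)
  n <- max(nrow(grid), 1L)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    args <- scenario$base
    for (k in names(grid)) args[[k]] <- grid[i, k]
    args <- route_protein_keys(args)
    res <- tryCatch({
      s <- run_protocell(do.call(protocell_config, args))$summary
      data.frame(minus_dG_H = s$minus_dG_H, minus_dG_Na = s$minus_dG_Na,
                 minus_dG_reported = s$minus_dG_reported, dpsi = s$dpsi,
                 pH_in = s$pH_in, t_final = s$t_final,
                 stop_reason = s$stop_reason, error = NA_character_)
    }, error = function(e) {
      data.frame(minus_dG_H = NA_real_, minus_dG_Na = NA_real_,
                 minus_dG_reported = NA_real_, dpsi = NA_real_,
                 pH_in = NA_real_, t_final = NA_real_,
                 stop_reason = "error", error = conditionMessage(e))
    })
    rows[[i]] <- if (ncol(grid)) cbind(grid[i, , drop = FALSE], res) else res
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "scenario") <- scenario$name
  class(out) <- c("sweep_result", class(out))
  out
}

#' Specification of an external-pH fluctuation process
#'
#' Mixing of the two fluids perturbs the external pH on one side on a
#' timescale of seconds. The default process is a bounded Gaussian
#' random walk: every `step_interval` seconds the target side's pH
#' takes a N(0, amplitude^2) step, reflected into `bounds`. A
#' deterministic sinusoid is available for controlled experiments.
#'
#' @param side `"acid"` or `"alk"`: which fluid fluctuates.
#' @param process `"random_walk"` or `"sinusoid"`.
#' @param step_interval Seconds between pH updates.
#' @param amplitude Step standard deviation (random walk) or half peak
#'   amplitude (sinusoid), pH units.
#' @param bounds Numeric length-2, allowed pH range, or `NULL` for
#'   baseline +/- 1.5 pH units.
#' @param period Sinusoid period, s.
#' @param seed Integer seed; identical seeds give identical traces.
#' @return List of class `fluctuation_spec`.
#' @export
fluctuation_spec <- function(side = c("acid", "alk"),
                             process = c("random_walk", "sinusoid"),
                             step_interval = 1, amplitude = 0.25,
                             bounds = NULL, period = 60, seed = 1) {
  side <- match.arg(side); process <- match.arg(process)
  if (step_interval <= 0 || amplitude < 0 || period <= 0)
    stop("step_interval and period must be positive, amplitude >= 0",
         call. = FALSE)
  if (!is.null(bounds) && (length(bounds) != 2 || bounds[1] >= bounds[2]))
    stop("bounds must be c(pH_min, pH_max) with pH_min < pH_max",
         call. = FALSE)
  structure(list(side = side, process = process,
                 step_interval = step_interval, amplitude = amplitude,
                 bounds = bounds, period = period,
                 seed = as.integer(seed)),
            class = "fluctuation_spec")
}

# Build the piecewise-constant external-pH schedule for a run.
fluctuation_schedule <- function(spec, config) {
  baseline <- if (spec$side == "acid") config$env$pH_acid else config$env$pH_alk
  bounds <- spec$bounds %||% c(max(baseline - 1.5, 0), min(baseline + 1.5, 14))
  times <- seq(0, config$sim$t_end, by = spec$step_interval)
  if (spec$process == "random_walk") {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
    set.seed(spec$seed)
    ph <- numeric(length(times)); ph[1] <- baseline
    steps <- stats::rnorm(length(times) - 1, 0, spec$amplitude)
    for (i in seq_along(steps)) {
      p <- ph[i] + steps[i]
      # reflect into bounds
      if (p < bounds[1]) p <- 2 * bounds[1] - p
      if (p > bounds[2]) p <- 2 * bounds[2] - p
      ph[i + 1] <- min(max(p, bounds[1]), bounds[2])
    }
  } else {
    ph <- baseline + spec$amplitude * sin(2 * pi * times / spec$period)
    ph <- pmin(pmax(ph, bounds[1]), bounds[2])
  }
  if (spec$side == "acid")
    data.frame(t = times, pH_acid = ph, pH_alk = config$env$pH_alk)
  else
    data.frame(t = times, pH_acid = config$env$pH_acid, pH_alk = ph)
}

#' Run a protocell under external-pH fluctuations
#'
#' Applies a [fluctuation_spec()] process to one external fluid
#' (piecewise-constant between updates), integrates the cell, and
#' summarises the distribution of the reported -dG over the run.
#' Identical seeds give bit-identical trajectories; amplitude 0
#' reproduces the static run.
#'
#' @param config A [protocell_config()].
#' @param spec A [fluctuation_spec()].
#' @param breaks Number of histogram cells for the -dG summary.
#' @return List with `run` (a `protocell_run`), `schedule` (the pH
#'   trace), `histogram` (counts over -dG bins) and `mean_minus_dG`.
#' @examples
#' \donttest{
#' cfg <- protocell_config(atpase = 0.01, t_end = 60)
#' fl <- fluctuating_run(cfg, fluctuation_spec("acid", seed = 7))
#' fl$mean_minus_dG
#' }
#' @export
fluctuating_run <- function(config, spec, breaks = 30) {
  stopifnot(inherits(config, "protocell_config"),
            inherits(spec, "fluctuation_spec"))
  sched <- fluctuation_schedule(spec, config)
  # fluctuation runs must ride through the perturbations, not stop early
  config$sim$steady_tol <- min(config$sim$steady_tol, 1e-12)
  run <- run_protocell(config, schedule = sched)
  vals <- run$series$minus_dG_reported
  h <- graphics::hist(vals, breaks = breaks, plot = FALSE)
  list(run = run, schedule = sched,
       histogram = data.frame(mid = h$mids, count = h$counts),
       mean_minus_dG = mean(vals))
}

#' Acid-adaptation sweep: pumping across equivalent gradients
#'
#' The acid-adaptation experiment: equal 3-unit pH gradients placed at
#' 5:8, 6:9 and 7:10, each crossed with a membrane-permeability grid,
#' with 5% H+ pump, 1% SPAP and 1% ATPase. At high permeability the
#' most acidic gradient collapses -dG; at low permeability all three
#' become pump-powered.
#'
#' @param overrides Named overrides forwarded to the `figS5` preset.
#' @return A `sweep_result` data frame.
#' @export
acid_adaptation_sweep <- function(overrides = list()) {
  run_sweep("figS5", overrides)
}
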