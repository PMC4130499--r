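# Shared fixture builders. All fixtures are constructed in code; the
# short horizons keep single tests fast while still reaching the
# quasi-steady plateau (which the 7:10 cell enters well inside 10 s).

leaky_config <- function(...) {
  protocell_config(atpase = 0.01, perm_H_cm_s = 1e-3, ...)
}

# a steady-state summary for a given configuration
steady_summary <- function(...) run_protocell(protocell_config(...))$summary

steady_mdg <- function(...) steady_summary(...)$minus_dG_reported

# interior identical to both (identical) external fluids: the no-flux
# fixed point of a protein-free cell
equilibrium_config <- function() {
  protocell_config(pH_acid = 7, pH_alk = 7, init_pH = 7, t_end = 1)
}
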