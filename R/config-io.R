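# Human-readable structured-text (YAML) configuration files. Two forms are
# accepted: a `scenario:` preset name plus overrides of that preset's
# arguments, or a fully explicit configuration with one block per parameter
# group. Unknown keys are errors — with this many parameters, silent typos
# must not pass.

scenario_functions <- function() {
  list(spheroid = scenario_spheroid,
       angiogenesis = scenario_angiogenesis,
       treatment = scenario_treatment)
}

#' Read a simulation configuration file
#'
#' YAML with either a `scenario` key (`spheroid`, `angiogenesis`,
#' `treatment`) whose remaining keys override that preset's arguments, or an
#' explicit configuration with blocks `substances`, `cell_params`,
#' `geometry`, `force`, `angio`, `coupling`, `treatment` (with windows in
#' days: `dox_windows_days` / `tra_windows_days` as lists of
#' `[start, end]` pairs), `initial_cells`, `vessels` (null, `"generate"`,
#' or a vessel-tree file path) and `vasc_spec`, plus the scalar engine keys
#' of [simulation_config()]. Unknown keys are fatal.
#'
#' @param path YAML file path.
#' @return A [simulation_config()].
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$scenario)) {
    fns <- scenario_functions()
    if (!y$scenario %in% names(fns)) {
      abort(paste0("read_config: unknown scenario '", y$scenario, "'"))
    }
    fn <- fns[[y$scenario]]
    args <- y[setdiff(names(y), "scenario")]
    known <- setdiff(names(formals(fn)), "...")
    known <- c(known, setdiff(names(formals(simulation_config)), "..."))
    bad <- setdiff(names(args), known)
    if (length(bad)) {
      abort(paste0("read_config: unknown key(s): ",
                   paste(bad, collapse = ", ")))
    }
    return(do.call(fn, args))
  }

  known <- setdiff(names(formals(simulation_config)), "...")
  bad <- setdiff(names(y), known)
  if (length(bad)) {
    abort(paste0("read_config: unknown key(s): ", paste(bad, collapse = ", ")))
  }
  build <- function(key, ctor) {
    if (is.null(y[[key]])) return(NULL)
    do.call(ctor, y[[key]])
  }
  args <- y
  for (spec in list(c("cell_params", "cell_cycle_params"),
                    c("geometry", "cell_geometry"),
                    c("force", "force_params"),
                    c("angio", "angiogenesis_params"),
                    c("coupling", "coupling_params"),
                    c("vasc_spec", "vasculature_gen_spec"))) {
    if (!is.null(y[[spec[1]]])) {
      args[[spec[1]]] <- build(spec[1], get(spec[2],
                                            envir = asNamespace("vasctum")))
    }
  }
  if (!is.null(y$treatment)) {
    tr <- y$treatment
    to_h <- function(w) {
      if (is.null(w)) return(NULL)
      24 * do.call(rbind, lapply(w, as.numeric))
    }
    args$treatment <- treatment_state(
      dox_windows = to_h(tr$dox_windows_days),
      tra_windows = to_h(tr$tra_windows_days),
      chi_max = tr$chi_max %||% 1,
      tau_up = tr$tau_up %||% 12,
      tau_down = tr$tau_down %||% 48
    )
  }
  if (is.character(args$vessels) && args$vessels != "generate") {
    args$vessels <- read_vessel_tree(args$vessels)
  }
  do.call(simulation_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
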