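#' Full pipeline configuration
#'
#' Bundles every tunable parameter of the pipeline — static, dynamics,
#' spectral and evaluation configuration plus the simulator cohort sizes —
#' into one nested, YAML-serializable structure with all defaults visible.
#'
#' @param static a [static_config()].
#' @param dynamics a [dynamics_config()].
#' @param cv a [cv_config()].
#' @param simulator list with `n_td`, `n_d`, `spread`, `effect`.
#' @param seed global seed.
#' @return a list of class `run_config`.
#' @export
run_config <- function(static = static_config(),
                       dynamics = dynamics_config(),
                       cv = cv_config(),
                       simulator = list(n_td = 242, n_d = 56,
                                        spread = 0.10, effect = 1),
                       seed = 1L) {
  structure(list(static = static, dynamics = dynamics, cv = cv,
                 simulator = simulator, seed = as.integer(seed)),
            class = "run_config")
}

strip_classes <- function(x) {
  if (is.list(x)) {
    x <- lapply(x, strip_classes)
    attributes(x) <- list(names = names(x))
  }
  x
}

#' Write a configuration to YAML
#'
#' Dumps every field (including defaults) so under-specified parameters
#' are visible and versioned alongside results.
#'
#' @param cfg a [run_config()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(strip_classes(unclass(cfg)), path)
  invisible(path)
}

#' Read a configuration from YAML
#'
#' Missing fields take their defaults; unknown fields are an error. The
#' result round-trips through [write_config()].
#'
#' @param path YAML file written by [write_config()] (possibly partial).
#' @return a [run_config()].
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- c("static", "dynamics", "cv", "simulator", "seed")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config section(s): ", paste(unknown, collapse = ", "))
  build <- function(section, ctor) {
    args <- raw[[section]]
    if (is.null(args)) return(ctor())
    if (section == "dynamics" && !is.null(args$spectral))
      args$spectral <- do.call(spectral_config, args$spectral)
    do.call(ctor, args)
  }
  sim <- raw$simulator
  defaults <- list(n_td = 242, n_d = 56, spread = 0.10, effect = 1)
  sim <- utils::modifyList(defaults, if (is.null(sim)) list() else sim)
  run_config(static = build("static", static_config),
             dynamics = build("dynamics", dynamics_config),
             cv = build("cv", cv_config),
             simulator = sim,
             seed = if (is.null(raw$seed)) 1L else as.integer(raw$seed))
}
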