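#' Default run configuration
#'
#' The hierarchical configuration consumed by [run_config()] and the
#' command-line front-end. Units: conductances S/cm2, times ms, currents
#' pA, temperatures degrees Celsius.
#'
#' @return Nested list with sections `morphology`, `conductances`,
#'   `synapses`, `protocol`, `circuit`, `simulation`.
#' @export
default_config <- function() {
  list(
    morphology = list(source = "generate", seed = 1, swc = NULL),
    conductances = as.list(sc_default_conductances()),
    synapses = lapply(synapse_library(), function(s)
      c(unclass(s$tm), s$receptor)),
    protocol = list(kind = "step", amps_pA = c(0, 4, 16, -16),
                    dur = 2000, pre = 1000, post = 1000),
    circuit = list(n_pf_pc = 100, n_pf_sc = 3, n_sc_pc = 100, n_sc_sc = 32,
                   sc_sc_enabled = FALSE, seed = 1),
    simulation = list(dt = 0.025, celsius = 32, v_init = -70, seed = 1,
                      record = "soma.v"))
}

#' Read a run configuration from YAML
#'
#' Unknown keys are rejected; missing keys fall back to
#' [default_config()].
#'
#' @param path YAML file.
#' @return Validated configuration list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("no such config: ", path)
  cfg <- yaml::read_yaml(path)
  base <- default_config()
  bad <- setdiff(names(cfg), names(base))
  if (length(bad)) stop("unknown config section(s): ",
                        paste(bad, collapse = ", "))
  for (nm in names(cfg)) {
    sec <- cfg[[nm]]
    badk <- setdiff(names(sec), names(base[[nm]]))
    if (length(badk)) stop("unknown key(s) in '", nm, "': ",
                           paste(badk, collapse = ", "))
    base[[nm]][names(sec)] <- sec
  }
  base
}

#' Write a run configuration to YAML
#'
#' @param cfg configuration list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Build a model from a configuration
#'
#' @param cfg configuration list (see [default_config()]).
#' @return A `cmodel`.
#' @export
model_from_config <- function(cfg) {
  morph <- if (identical(cfg$morphology$source, "swc"))
    read_swc(cfg$morphology$swc)
  else generate_sc_morphology(seed = cfg$morphology$seed)
  g <- unlist(cfg$conductances)
  sc_model(morph = morph, conductances = g,
           celsius = cfg$simulation$celsius, dt = cfg$simulation$dt,
           v_init = cfg$simulation$v_init)
}

#' Export a trace set to CSV
#'
#' Columns: time (ms) plus one column per recorded site; spike times are
#' written to a companion `*_spikes.csv`.
#'
#' @param tr a `trace_set`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_traces <- function(tr, path) {
  df <- data.frame(t = tr$t)
  for (j in seq_len(ncol(tr$v))) df[[paste0(colnames(tr$v)[j], ".v")]] <- tr$v[, j]
  if (!is.null(tr$i_clamp)) df$i_clamp <- tr$i_clamp
  write.csv(df, path, row.names = FALSE)
  sp <- data.frame(
    cell = rep(names(tr$spikes), vapply(tr$spikes, length, 1L)),
    time = unlist(tr$spikes))
  write.csv(sp, sub("\\.csv$", "_spikes.csv", path), row.names = FALSE)
  invisible(path)
}
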