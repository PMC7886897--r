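#' Reference optimized conductance sets
#'
#' The four reference stellate-cell models shipped with the package (one
#' per generated morphology, seeds 1-4), each a 36-slot conductance vector
#' produced by [optimize_conductances()] against [sc_feature_targets()].
#' They serve as starting points for refinement and as the default models
#' for the synaptic and microcircuit experiments.
#'
#' @return Named list of four conductance vectors.
#' @export
sc_reference_models <- function() {
  path <- system.file("extdata", "sc_reference_models.json",
                      package = "stellate")
  raw <- jsonlite::read_json(path)
  lapply(raw, function(g) unlist(g))
}

#' Build the reference stellate-cell model set
#'
#' @param n number of models (up to 4).
#' @return List of `cmodel` objects, morphology seeds 1..n.
#' @export
sc_reference_model_set <- function(n = 4) {
  genomes <- sc_reference_models()
  lapply(seq_len(min(n, length(genomes))), function(i)
    sc_model(seed = i, conductances = genomes[[i]]))
}
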