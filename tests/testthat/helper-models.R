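# shared fixtures built in code

# single passive spherical compartment: leak only, C and g chosen round
passive_one_comp <- function(area_cm2 = 1e-5, g_leak = 3e-5, cm = 1,
                             e_leak = -48) {
  comp <- data.frame(name = "soma", class = "soma", L_um = 10, diam_um = 10,
                     area_cm2 = area_cm2, cm = cm, parent = -1,
                     stringsAsFactors = FALSE)
  m <- structure(list(
    compartments = comp,
    channels = data.frame(comp = 1, channel = "leak", g = g_leak),
    conductances = setNames(numeric(0), character(0)),
    synapses = list(), cells = list(cell = 1L),
    reversal = reversal_set(), ca = calcium_pool(),
    celsius = 32, dt = 0.025, v_init = e_leak, r_axial = 110, theta = 0.5),
    class = "cmodel")
  m
}

# uniform passive cable of n compartments (for analytic attenuation tests)
passive_cable <- function(n = 20, L_um = 50, diam_um = 2, g_leak = 3e-5,
                          r_axial = 110) {
  comp <- do.call(rbind, lapply(seq_len(n), function(i)
    data.frame(name = paste0("c", i), class = "soma", L_um = L_um,
               diam_um = diam_um, area_cm2 = pi * diam_um * L_um * 1e-8,
               cm = 1, parent = i - 1 - (i == 1), stringsAsFactors = FALSE)))
  comp$parent[1] <- -1
  rownames(comp) <- comp$name
  structure(list(
    compartments = comp,
    channels = data.frame(comp = seq_len(n), channel = "leak", g = g_leak),
    conductances = setNames(numeric(0), character(0)),
    synapses = list(), cells = list(cell = 1L),
    reversal = reversal_set(), ca = calcium_pool(),
    celsius = 32, dt = 0.025, v_init = -48, r_axial = r_axial, theta = 0.5),
    class = "cmodel")
}

# one cached default SC model and morphology per test session
sc_test_model <- local({
  m <- NULL
  function() {
    if (is.null(m)) m <<- sc_model(seed = 1)
    m
  }
})

ref_models_available <- function() {
  nzchar(system.file("extdata", "sc_reference_models.json",
                     package = "stellate"))
}
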