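# shared fixtures, built once per test run

FIXTURE_SMILES <- c(
  ethanol = "CCO",
  benzene = "c1ccccc1",
  methane = "C",
  ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
  caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
  paracetamol = "CC(=O)Nc1ccc(O)cc1",
  aspirin = "CC(=O)Oc1ccccc1C(=O)O",
  nicotine = "CN1CCCC1c1cccnc1",
  toluene = "Cc1ccccc1",
  glycine = "NCC(=O)O",
  thiophene = "c1ccsc1",
  piperazine = "C1CNCCN1",
  benzamide = "NC(=O)c1ccccc1",
  naphthalene = "c1ccc2ccccc2c1",
  hexane = "CCCCCC",
  phenol = "Oc1ccccc1",
  anisole = "COc1ccccc1",
  pyridine = "c1ccncc1",
  butylamine = "CCCCN",
  chlorobenzene = "Clc1ccccc1"
)

# two-family toy library: target TA (para-substituted anilines) vs
# TB (linear alkanols) - chemically disjoint, 5 actives each
toy_library <- local({
  lib <- NULL
  function() {
    if (is.null(lib)) {
      acts <- tibble::tibble(
        compound_id = c(sprintf("A%d", 1:5), sprintf("B%d", 1:5)),
        smiles = c("Nc1ccc(C)cc1", "Nc1ccc(CC)cc1", "Nc1ccc(O)cc1",
                   "Nc1ccc(Cl)cc1", "Nc1ccc(CO)cc1",
                   "CCCCO", "CCCCCO", "CCCCCCO", "CCCCCCCO", "CCCCCCCCO"),
        target_id = rep(c("TA", "TB"), each = 5),
        target_class = rep(c("GPCR", "Enzyme"), each = 5),
        activity_type = "IC50",
        value_nm = rep(c(10, 20, 50, 100, 200), 2),
        moa = "inhibitor",
        source = "fixture")
      lib <<- precompute_descriptors(make_reference_library(acts))
    }
    lib
  }
})

# the benchmark study conditions: seed-17 synthetic library, predictors
# fitted at seed 1, held-out analog queries - built lazily, shared across
# test files
bench <- local({
  env <- NULL
  function() {
    if (is.null(env)) {
      spec <- synthetic_spec(seed = 17)
      gen <- gen_reference_library(spec)
      lib <- precompute_descriptors(gen$library)
      env <<- list(
        spec = spec,
        gen = gen,
        lib = lib,
        predictors = suppressMessages(fit_predictors(lib, seed = 1)),
        queries = gen_query_drugs(spec, gen))
    }
    env
  }
})

# pessimistic rank of the true target in a method-score table
true_target_rank <- function(scores, true_target) {
  s_true <- scores$score[scores$target_id == true_target]
  if (length(s_true) == 0) return(Inf)
  sum(scores$score > max(s_true)) + 1
}
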