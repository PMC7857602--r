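# Shared synthetic cohorts, generated once per test run and cached.
# The acceptance cohorts follow the package's study conditions: 20 embryos
# per genotype, default embryo spec, threshold readout model, per-embryo
# seeds 1..20 (wild type) and 101..120 (chordin mutant).

.cohort_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .cohort_cache))
    assign(key, force(expr), envir = .cohort_cache)
  get(key, envir = .cohort_cache)
}

wt_cohort <- function() cached("wt", simulate_cohort("wild_type", 20, 0L))

chd_cohort <- function() cached("chd", simulate_cohort("chordin_mutant", 20, 100L))

wt_calls <- function() cached("wt_calls", quantify_cohort(wt_cohort()))

chd_calls <- function() cached("chd_calls", quantify_cohort(chd_cohort()))

# small embryo for fast unit tests
small_embryo <- function(seed = 7, noise = 5, n = 1500) {
  sample_embryo(embryo_spec(n_nuclei = n, noise_sd = noise, seed = seed),
                make_canonical_gradient("wild_type"))
}
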