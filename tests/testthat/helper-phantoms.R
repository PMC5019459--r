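# assembled phantoms are reused across test files (assembly is a few seconds)
.pd_test_env <- new.env(parent = emptyenv())

test_phantom <- function(name) {
  key <- paste0("ph_", name)
  if (is.null(.pd_test_env[[key]]))
    .pd_test_env[[key]] <- assemble_phantom(name)
  .pd_test_env[[key]]
}

# cached SAF helper for the acceptance suite: one Monte Carlo run per
# (phantom, source, energy) at the stated history count
test_saf <- function(phantom_name, source, energy, n = 1e6, seed = 20260900) {
  key <- paste("saf", phantom_name, source, energy, n, seed, sep = "_")
  if (is.null(.pd_test_env[[key]])) {
    ph <- test_phantom(phantom_name)
    tl <- simulate_photons(ph, source, energy, n_histories = n, seed = seed)
    .pd_test_env[[key]] <- compute_saf(tl, ph)
  }
  .pd_test_env[[key]]
}

saf_of <- function(saf_tbl, target) {
  unname(saf_tbl$saf_kg[match(target, saf_tbl$target)])
}

cv_of <- function(saf_tbl, target) {
  unname(saf_tbl$cv_percent[match(target, saf_tbl$target)])
}
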