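# Session-level cache so expensive fixtures (contexts, converged SCF
# solutions) are built once and shared across test files.

.tcache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.tcache[[key]])) .tcache[[key]] <- force(expr)
  .tcache[[key]]
}

get_ctx <- function(name, basis = "min3g", grid_level = 1L) {
  cached(paste("ctx", name, basis, grid_level, sep = "_"),
         build_context(fixture(name), basis, grid_level))
}

get_uks <- function(name, xc = "hf", basis = "min3g", grid_level = 1L) {
  cached(paste("uks", name, xc, basis, grid_level, sep = "_"),
         solve_uks(fixture(name), get_ctx(name, basis, grid_level), xc))
}

get_ro <- function(name, xc = "hf", basis = "min3g", grid_level = 1L) {
  cached(paste("ro", name, xc, basis, grid_level, sep = "_"),
         solve_ro(fixture(name), get_ctx(name, basis, grid_level), xc))
}
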