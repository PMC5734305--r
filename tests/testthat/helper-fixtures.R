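# Shared builds used across test files (computed once per test run).

canonical_dimer_spec <- function(heptads = 4, radius = 4.9, pitch = -180) {
  p <- helix_params(radius = radius, pitch = pitch, interface_angle = 26,
                    sequence = strrep("IAALKQE", heptads),
                    register = strrep("abcdefg", heptads))
  assembly_spec("basic", "coiled_coil", 2, list(p))
}

canonical_dimer_allatom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- place_sidechains(build_assembly(canonical_dimer_spec())$model)
    }
    cache
  }
})
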