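# shared fixtures: a reference hypertensive patient at the published
# baseline moments, its drug-free equilibrium, and a tiny cached population
ref_patient <- local({
  p <- NULL
  function() {
    if (is.null(p)) p <<- build_patient(SBP = 154, DBP = 101, HR = 76)
    p
  }
})

ref_equilibrium <- local({
  eq <- NULL
  function() {
    if (is.null(eq)) eq <<- find_equilibrium(ref_patient())
    eq
  }
})

ref_vp <- function() {
  eq <- ref_equilibrium()
  list(params = ref_patient(), state = eq$state, obs = eq$obs)
}

small_population <- local({
  pop <- NULL
  function(n = 4, seed = 11) {
    if (is.null(pop)) pop <<- generate_population(n, seed = seed)
    pop
  }
})
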