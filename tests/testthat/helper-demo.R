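# The full autoregulation demonstration is expensive (DE-MCz at the shipped
# settings), and several test files interrogate the same run; memoise it per
# seed for the session.
the_demo_cache <- new.env(parent = emptyenv())

get_demo <- function(seed) {
  key <- paste0("seed_", seed)
  if (!exists(key, envir = the_demo_cache, inherits = FALSE)) {
    assign(key, autoreg_demo(seed = seed), envir = the_demo_cache)
  }
  get(key, envir = the_demo_cache)
}
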