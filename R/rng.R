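# Named RNG streams so toggling one stochastic mechanism (seeding, fibers,
# apoptosis, proliferation gate, daughter placement) does not shift the draws
# of another. Each stream holds its own .Random.seed state and swaps it in
# and out around every draw; the user's global RNG state is untouched.

new_stream <- function(seed) {
  s <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  set.seed(as.integer(seed %% .Machine$integer.max))
  s$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
  s
}

with_stream <- function(stream, fn) {
  if (is.null(stream)) return(fn())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, globalenv())
  on.exit({
    stream$state <- get(".Random.seed", globalenv())
    # when no global state existed beforehand, the swapped-in state is left
    # behind (removing it on every draw is disproportionately expensive)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
  })
  fn()
}

st_runif <- function(stream, n, min = 0, max = 1) {
  with_stream(stream, function() stats::runif(n, min, max))
}

st_sample_int <- function(stream, n) {
  with_stream(stream, function() sample.int(n, 1L))
}

# Derived sub-seed for a named purpose; kept below 2^31.
sub_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 7919) %% 2147483647)
}
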