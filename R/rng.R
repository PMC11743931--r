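# Named RNG streams derived from one master seed.  Each sub-model (CPM,
# network generation, ECM noise, scheduling) draws from its own stream so
# that toggling one source of randomness does not shift the draws of the
# others.  Streams are stored as saved .Random.seed states in an
# environment, so stream_eval() mutates them in place.

make_rng_streams <- function(seed, names = c("cpm", "network", "ecm", "fa")) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  streams <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv())
  set.seed(as.integer(seed) %% .Machine$integer.max)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, length(names))
  for (k in seq_along(names)) {
    set.seed(sub_seeds[[k]])
    assign(names[[k]], get(".Random.seed", globalenv()), envir = streams)
  }
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  streams
}

# Evaluate expr under the named stream; the advanced state is saved back.
stream_eval <- function(streams, name, expr) {
  stopifnot(is.environment(streams), exists(name, envir = streams))
  old <- get0(".Random.seed", globalenv())
  assign(".Random.seed", get(name, envir = streams), envir = globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams)
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}
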