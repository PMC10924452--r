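# Reproducible child RNG streams.
#
# All randomness flows from a single master seed. Each simulated patient gets
# two child streams derived by stable indices: a "disease" stream driving the
# latent semi-Markov trajectory and a "care" stream driving diagnostic and
# treatment draws. Both model arms receive the same stream seeds, so the arms
# share disease-path randomness and differ only through the pathway draws --
# this is what makes paired-arm (A/A) comparisons exactly reproducible.

#' Create a child random-number stream
#'
#' A stream is an environment carrying a saved `.Random.seed`; drawing from it
#' leaves the global RNG state untouched.
#'
#' @param seed Integer seed for this stream.
#' @return An object of class `rng_stream`.
#' @keywords internal
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(seed)
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

#' Evaluate random draws within a stream
#'
#' @param stream An [rng_stream()].
#' @param code Expression performing the draws.
#' @return The value of `code`.
#' @keywords internal
#' @export
with_stream <- function(stream, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  code
}

# stable child-seed derivation; doubles are exact well below 2^53 and the
# result is reduced into 32-bit integer range
derive_seed <- function(master, patient_index, stream_index) {
  as.integer(
    ((master %% 100003) * 20011 + patient_index * 613 + stream_index * 101111) %%
      2147483629 + 1
  )
}
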