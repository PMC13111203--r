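#' Named random-number substreams
#'
#' The simulator draws from several independent consumers (trial-type
#' scheduler, perturbation-delay sampler, inter-trial scheduler, virtual
#' mouse). Each consumer gets its own Mersenne-Twister state derived from a
#' single master seed, so adding draws to one consumer never perturbs the
#' others and whole sessions are reproducible byte-for-byte from one integer.
#'
#' @param master_seed single integer master seed.
#' @param names character vector of stream names.
#' @return an object of class `rng_streams`.
#' @examples
#' rs <- rng_streams(42, c("a", "b"))
#' x1 <- with_stream(rs, "a", runif(3))
#' @export
rng_streams <- function(master_seed,
                        names = c("trial_type", "delay", "iti", "agent")) {
  stopifnot(length(master_seed) == 1, is.finite(master_seed))
  env <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit(restore_seed(old))
  for (i in seq_along(names)) {
    # distinct, collision-free derived seeds; arithmetic exact in doubles
    s <- (abs(as.double(master_seed)) * 48271 + i * 30269) %% 2147483629
    set.seed(as.integer(s))
    assign(names[i], get(".Random.seed", globalenv()), envir = env)
  }
  structure(list(env = env, master_seed = master_seed, names = names),
            class = "rng_streams")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, globalenv())
  }
}

#' Evaluate an expression under a named substream
#'
#' Swaps the named stream's state into the session RNG, evaluates `expr`,
#' and saves the advanced state back, leaving the caller's RNG untouched.
#'
#' @param streams an [rng_streams()] object.
#' @param name stream name.
#' @param expr expression to evaluate.
#' @export
with_stream <- function(streams, name, expr) {
  stopifnot(inherits(streams, "rng_streams"))
  if (!exists(name, streams$env, inherits = FALSE))
    stop("unknown rng stream: ", name)
  old <- get0(".Random.seed", globalenv(), inherits = FALSE)
  assign(".Random.seed", get(name, streams$env), globalenv())
  on.exit({
    assign(name, get(".Random.seed", globalenv()), envir = streams$env)
    restore_seed(old)
  })
  expr
}
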