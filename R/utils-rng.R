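# Seeded RNG helpers. All randomness in the package flows through a local
# stream so that library code never disturbs the caller's .Random.seed and
# every artifact is reproducible from its recorded seed.

#' Derive a child seed from a master seed
#'
#' Counter-based splitting rule: child `i` of master `m` is
#' `(m * 1000003 + i) mod (2^31 - 1)`. Used to give each participant,
#' trial and repetition an independent reproducible stream without
#' cross-coupling.
#'
#' @param master Master seed (integer).
#' @param index Child index (integer >= 0).
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, index) {
  m <- (as.double(master) %% 2147483647) * 1000003 + as.double(index)
  as.integer(m %% 2147483647)
}

# A callable local RNG stream. Returns function(n, what, ...) that draws n
# variates ("unif", "norm", "geom", "gamma", "binom", "perm") from a private
# Mersenne-Twister state, leaving the global .Random.seed untouched.
.local_rng <- function(seed) {
  genv <- globalenv()
  save_global <- function() {
    if (exists(".Random.seed", envir = genv, inherits = FALSE))
      get(".Random.seed", envir = genv) else NULL
  }
  restore_global <- function(s) {
    if (is.null(s)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE))
        rm(".Random.seed", envir = genv)
    } else assign(".Random.seed", s, envir = genv)
  }
  outer_state <- save_global()
  set.seed(seed)
  state <- save_global()
  restore_global(outer_state)

  function(n, what = "unif", ...) {
    outer_state <- save_global()
    assign(".Random.seed", state, envir = genv)
    out <- switch(what,
      unif  = stats::runif(n, ...),
      norm  = stats::rnorm(n, ...),
      geom  = stats::rgeom(n, ...),
      gamma = stats::rgamma(n, ...),
      binom = stats::rbinom(n, ...),
      perm  = sample.int(n),
      stop("unknown variate kind: ", what)
    )
    state <<- save_global()
    restore_global(outer_state)
    out
  }
}
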