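# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global random number generator seeded at `seed`,
#' restoring the caller's RNG state afterwards so a seeded analysis never
#' perturbs surrounding simulations. A `NULL` seed leaves the RNG untouched.
#'
#' @param seed Integer scalar or `NULL`.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

# Derive a per-stage substream seed from one master seed, so toggling or
# re-running one pipeline stage never shifts another stage's random stream.
# Kept below 2^31 - 1 (R integer range).
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offsets <- c(locations = 1L, species = 2L, sizes = 3L, autumn = 4L,
               other_autumn = 5L, dynamics = 6L, spring = 7L,
               other_spring = 8L, quadrat = 11L, joincount = 12L,
               csr = 13L, models = 14L, density = 15L)
  if (!stage %in% names(offsets)) {
    stop("unknown stage name: ", stage)
  }
  as.integer((as.double(seed) %% 1e6) * 2099 + offsets[[stage]] * 97)
}

is_count_vector <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == round(x))
}
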