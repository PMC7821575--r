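#' @keywords internal
"_PACKAGE"

# Deterministic child seeds: one user-facing seed per run, expanded into
# independent per-stage seeds so that adding a stage never perturbs the
# stream of an existing one.  Kept below 2^31 - 1 (R integers are 32-bit).
.stage_offsets <- c(
  scores       = 101L,
  questionnaire = 211L,
  connectivity = 307L,
  timeseries   = 401L,
  bootstrap    = 503L,
  nbs          = 601L,
  pipeline     = 701L
)

derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  off <- .stage_offsets[[stage]]
  if (is.null(off)) stop("unknown seed stage: ", stage)
  as.integer((as.numeric(seed) * 1021 + off * 9973) %% (2^31 - 1))
}

# with_seed: evaluate expr under a temporary RNG state
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < min ||
      x != round(x)) {
    stop("'", name, "' must be a single integer >= ", min, call. = FALSE)
  }
  as.integer(x)
}

check_nonneg <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0) {
    stop("'", name, "' must be a single non-negative number", call. = FALSE)
  }
  as.numeric(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
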