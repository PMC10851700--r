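#' Derive a stage seed from a master seed
#'
#' Every stochastic stage of the pipeline consumes its own named seed derived
#' from a single master seed by a fixed counter scheme, so that adding a stage
#' (or re-running one in isolation) never perturbs the random streams of the
#' others. The scheme is `(48271 * master + offset) mod (2^31 - 1)` with a
#' fixed integer offset per (stage, index) pair; all arithmetic is exact in
#' doubles.
#'
#' @param master integer master seed (non-negative, < 2^31).
#' @param stage character stage label, one of the names in `kc_stage_offsets`.
#' @param index non-negative integer sub-counter (e.g. observer number,
#'   replicate number). Default 0.
#' @return an integer seed suitable for [set.seed()].
#' @export
derive_seed <- function(master, stage, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, master >= 0, master < 2^31)
  stopifnot(is.character(stage), length(stage) == 1L)
  stopifnot(is.numeric(index), length(index) == 1L, index >= 0)
  off <- kc_stage_offsets[[stage]]
  if (is.null(off)) stop("unknown stage label: ", stage)
  m <- 2147483647  # 2^31 - 1
  s <- (48271 * (master %% m) + off + 1000L * index) %% m
  as.integer(s)
}

# Fixed offsets; appending a new stage never changes existing streams.
kc_stage_offsets <- list(
  stimuli      = 101L,
  design       = 202L,
  observers    = 303L,
  cv           = 404L,
  permutations = 505L,
  replicates   = 606L,
  confidence   = 707L
)
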