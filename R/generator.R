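#' Default generator parameters for synthetic reach-to-grasp stimuli
#'
#' Each stimulus is a feature-by-epoch matrix of (z-scored) kinematic
#' summaries over `n_epochs` equal bins of normalized movement time. A
#' feature value is generated as
#' \deqn{x[f, e] = a[f, agent] + s \cdot \delta[f, e] / 2 + \epsilon[f, e]}
#' where `a` is a per-agent trait (random intercept, SD `agent_sd`), `s`
#' is +1 for small-object and -1 for large-object movements, `delta[f, e]`
#' is the expected small-minus-large difference for feature `f` at epoch
#' `e`, and `eps` is i.i.d. Gaussian noise (SD `noise_sd`).
#'
#' The default size-effect profiles emulate the temporal ordering of size
#' information in real prehension kinematics: grip aperture (`GA`) is
#' informative from the first epoch and peaks at epochs 2-3; index finger
#' height (`IZ`) grows monotonically over the movement; wrist height (`WZ`)
#' carries a stable, time-constant effect; the remaining channels (wrist
#' trajectory/velocity, index and thumb coordinates) carry weaker mixed
#' profiles, and `DP` is an uninformative control channel.
#'
#' @param n_agents number of agents (default 15).
#' @param n_exemplars representative movements per agent x size (default 2).
#' @param n_epochs number of equal time epochs (default 10; the occlusion
#'   ladder at 10\%-steps exposes the first `o/10` of them).
#' @param agent_sd SD of the per-agent, per-feature trait.
#' @param noise_sd SD of the within-movement epoch noise.
#' @param size_effect_scale global multiplier applied to all size-effect
#'   profiles; 0 produces a no-signal stimulus set.
#' @param delta optional F x E matrix of size-effect profiles overriding the
#'   defaults (rownames = feature names).
#' @return a list of class `kc_params`.
#' @export
default_gen_params <- function(n_agents = 15L, n_exemplars = 2L, n_epochs = 10L,
                               agent_sd = 0.8, noise_sd = 0.95,
                               size_effect_scale = 1.0, delta = NULL) {
  if (n_agents < 1L || n_exemplars < 1L || n_epochs < 1L)
    stop("agent, exemplar and epoch counts must be positive")
  if (!all(is.finite(c(agent_sd, noise_sd, size_effect_scale))) ||
      agent_sd < 0 || noise_sd < 0)
    stop("generator parameters must be finite and SDs non-negative")
  if (is.null(delta)) {
    e <- seq_len(n_epochs)
    ga <- c(0.7, 1.1, 1.1, 0.7, 0.6, 0.6, 0.55, 0.55, 0.5, 0.5)
    iz <- c(0.25, 0.5, 0.8, 1.15, 1.5, 1.85, 1.9, 1.95, 2.0, 2.0)
    delta <- rbind(
      GA = ga[pmin(e, length(ga))],  # early, peaking at epochs 2-3
      IZ = iz[pmin(e, length(iz))],  # monotonically growing
      WZ = rep(0.15, n_epochs),      # stable across time
      WX = rep(0.10, n_epochs),
      WY = rep(0.08, n_epochs),
      WV = 0.12 * pmin(e, 6),
      IX = 0.16 * pmin(e, 6),
      IY = rep(0.08, n_epochs),
      TX = rep(0.05, n_epochs),
      TY = rep(0.05, n_epochs),
      TZ = 0.08 * pmin(e, 6),
      DP = rep(0, n_epochs)
    )
  }
  if (!all(is.finite(delta))) stop("size-effect profiles must be finite")
  if (is.null(rownames(delta))) stop("delta must have feature rownames")
  structure(list(
    n_agents = as.integer(n_agents),
    n_exemplars = as.integer(n_exemplars),
    n_epochs = as.integer(n_epochs),
    features = rownames(delta),
    agent_sd = agent_sd,
    noise_sd = noise_sd,
    size_effect_scale = size_effect_scale,
    delta = delta * size_effect_scale
  ), class = "kc_params")
}

#' Generate a synthetic stimulus set
#'
#' Produces `2 * n_exemplars * n_agents` reach-to-grasp stimuli (default 60:
#' 2 exemplars x 15 agents x 2 object sizes), each a feature-by-epoch matrix.
#' Small- and large-object movements differ in expectation by the size-effect
#' profiles in `params$delta`.
#'
#' @param params a `kc_params` object, see [default_gen_params()].
#' @param seed integer seed; identical seeds give bit-identical sets.
#' @return an object of class `kc_stimuli`: list with `features` (3-d array
#'   stimulus x feature x epoch), `meta` (data.frame of stimulus_id, agent_id,
#'   exemplar, object_size, duration_ms) and the generating `params`.
#' @export
make_stimulus_set <- function(params = default_gen_params(), seed = 1L) {
  stopifnot(inherits(params, "kc_params"))
  set.seed(seed)
  F <- length(params$features)
  E <- params$n_epochs
  sizes <- c("small", "large")
  meta <- expand.grid(exemplar = seq_len(params$n_exemplars),
                      agent_id = seq_len(params$n_agents),
                      object_size = sizes,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  meta <- meta[order(meta$agent_id, meta$object_size, meta$exemplar), ]
  rownames(meta) <- NULL
  n <- nrow(meta)
  meta$stimulus_id <- sprintf("A%02d_%s_%d", meta$agent_id,
                              substr(meta$object_size, 1, 1), meta$exemplar)
  meta$duration_ms <- round(stats::rnorm(n, mean = 1100, sd = 120))
  meta$duration_ms <- pmax(meta$duration_ms, 400)

  # per-agent, per-feature trait shared by all of the agent's movements
  trait <- array(stats::rnorm(params$n_agents * F, sd = params$agent_sd),
                 dim = c(params$n_agents, F))
  feats <- array(NA_real_, dim = c(n, F, E),
                 dimnames = list(meta$stimulus_id, params$features, NULL))
  for (i in seq_len(n)) {
    s <- if (meta$object_size[i] == "small") 1 else -1
    mu <- trait[meta$agent_id[i], ] + s * params$delta / 2  # F x E
    feats[i, , ] <- mu + stats::rnorm(F * E, sd = params$noise_sd)
  }
  meta <- meta[, c("stimulus_id", "agent_id", "exemplar", "object_size",
                   "duration_ms")]
  structure(list(features = feats, meta = meta, params = params),
            class = "kc_stimuli")
}

#' @export
print.kc_stimuli <- function(x, ...) {
  cat(sprintf("<kc_stimuli> %d stimuli (%d small, %d large), %d features x %d epochs\n",
              nrow(x$meta), sum(x$meta$object_size == "small"),
              sum(x$meta$object_size == "large"),
              dim(x$features)[2], dim(x$features)[3]))
  invisible(x)
}

#' @export
print.kc_params <- function(x, ...) {
  cat(sprintf("<kc_params> %d agents x %d exemplars x 2 sizes; %d features x %d epochs; agent_sd=%.2f noise_sd=%.2f scale=%.2f\n",
              x$n_agents, x$n_exemplars, length(x$features), x$n_epochs,
              x$agent_sd, x$noise_sd, x$size_effect_scale))
  invisible(x)
}
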