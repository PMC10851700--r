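#' Experimental design specification
#'
#' @param n_trials total trials per session (default 240).
#' @param n_blocks number of blocks (default 8); `n_trials` must be divisible
#'   by `n_blocks`.
#' @param occlusion_levels percent-of-movement occlusion ladder
#'   (default 10, 20, ..., 80); session counts are exactly balanced across
#'   levels, so `n_trials` must also be divisible by the number of levels.
#' @param counterbalance if `FALSE` (default) the instruction is
#'   `report_small` for the first half of the blocks and `report_large` for
#'   the second half; `TRUE` swaps them.
#' @param seed integer seed for the pseudorandomization.
#' @return a list of class `kc_design_spec`.
#' @export
design_spec <- function(n_trials = 240L, n_blocks = 8L,
                        occlusion_levels = seq(10L, 80L, by = 10L),
                        counterbalance = FALSE, seed = 1L) {
  n_trials <- as.integer(n_trials); n_blocks <- as.integer(n_blocks)
  if (length(occlusion_levels) == 0L) stop("occlusion level set is empty")
  if (n_trials <= 0L || n_blocks <= 0L || n_trials %% n_blocks != 0L)
    stop("n_trials must be a positive multiple of n_blocks")
  if (n_trials %% length(occlusion_levels) != 0L)
    stop("n_trials must be a multiple of the number of occlusion levels")
  if (n_trials / n_blocks < length(occlusion_levels))
    stop("block size must allow at least one trial of every occlusion level")
  structure(list(n_trials = n_trials, n_blocks = n_blocks,
                 occlusion_levels = as.integer(sort(occlusion_levels)),
                 counterbalance = isTRUE(counterbalance),
                 seed = as.integer(seed)),
            class = "kc_design_spec")
}

#' Build a pseudorandomized session design
#'
#' Creates the ordered trial stubs for one session: occlusion levels are
#' exactly balanced over the session and every block contains at least one
#' trial of every level; the small-first/large-first configuration is
#' balanced 50/50 within each occlusion level (odd counts break toward
#' `small_first` before shuffling); stimulus pairs are matched within agent
#' (an agent is drawn uniformly, then one of its small and one of its large
#' movements), so the kinematic difference between the two intervals
#' reflects the object size and movement variability, not the identity of
#' the actor. Responses are absent — see [simulate_observer()].
#'
#' @param spec a `kc_design_spec`.
#' @param stimuli a `kc_stimuli` set providing at least one small and one
#'   large stimulus.
#' @return a data.frame of trial stubs: trial_id, block, occlusion_level,
#'   first_stimulus_id, second_stimulus_id, configuration, instruction.
#' @export
make_design <- function(spec = design_spec(), stimuli) {
  stopifnot(inherits(spec, "kc_design_spec"), inherits(stimuli, "kc_stimuli"))
  small_ids <- stimuli$meta$stimulus_id[stimuli$meta$object_size == "small"]
  large_ids <- stimuli$meta$stimulus_id[stimuli$meta$object_size == "large"]
  if (length(small_ids) < 1L || length(large_ids) < 1L)
    stop("stimulus set must contain both small and large stimuli")

  set.seed(spec$seed)
  L <- length(spec$occlusion_levels)
  per_block <- spec$n_trials / spec$n_blocks
  per_level <- spec$n_trials / L

  # per-block level counts: a base count for every level plus cyclically
  # distributed extras, so session counts are exact and each block covers
  # every level at least once
  base <- per_block %/% L
  extra <- per_block - base * L
  counts <- matrix(base, nrow = spec$n_blocks, ncol = L)
  if (extra > 0L) {
    pos <- 0L
    for (b in seq_len(spec$n_blocks)) {
      idx <- (pos + seq_len(extra) - 1L) %% L + 1L
      counts[b, idx] <- counts[b, idx] + 1L
      pos <- pos + extra
    }
  }
  if (!all(colSums(counts) == per_level))
    stop("cannot balance occlusion levels across blocks for this spec")

  block <- rep(seq_len(spec$n_blocks), each = per_block)
  occl <- integer(spec$n_trials)
  for (b in seq_len(spec$n_blocks)) {
    lv <- rep(spec$occlusion_levels, times = counts[b, ])
    occl[block == b] <- sample(lv)
  }

  # configuration balanced within level; odd counts tie toward small_first
  config <- character(spec$n_trials)
  for (l in spec$occlusion_levels) {
    idx <- which(occl == l)
    k <- length(idx)
    cfg <- rep(c("small_first", "large_first"), c(ceiling(k / 2), floor(k / 2)))
    config[idx] <- sample(cfg)
  }

  # within-agent matched pairs: draw an agent, then one small and one large
  # movement of that agent
  meta <- stimuli$meta
  agents <- intersect(meta$agent_id[meta$object_size == "small"],
                      meta$agent_id[meta$object_size == "large"])
  if (length(agents) < 1L)
    stop("no agent contributes both a small and a large stimulus")
  ag <- sample(agents, spec$n_trials, replace = TRUE)
  pick <- function(a, size) {
    ids <- meta$stimulus_id[meta$agent_id == a & meta$object_size == size]
    ids[sample.int(length(ids), 1L)]
  }
  sm <- vapply(ag, pick, character(1), size = "small")
  lg <- vapply(ag, pick, character(1), size = "large")
  first <- ifelse(config == "small_first", sm, lg)
  second <- ifelse(config == "small_first", lg, sm)

  half <- spec$n_blocks / 2
  instr_first <- if (spec$counterbalance) "report_large" else "report_small"
  instr_second <- if (spec$counterbalance) "report_small" else "report_large"
  instruction <- ifelse(block <= ceiling(half), instr_first, instr_second)

  data.frame(trial_id = seq_len(spec$n_trials), block = block,
             occlusion_level = occl, first_stimulus_id = first,
             second_stimulus_id = second, configuration = config,
             instruction = instruction, stringsAsFactors = FALSE)
}
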