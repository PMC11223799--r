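# Metropolis Monte Carlo sampling: fixed-temperature runs, simulated
# annealing, unfolding, and replica exchange.  All randomness flows through
# R's RNG, so (seed, config, inputs) fully determine every output.

#' Simulation configuration
#'
#' @param n_steps attempted Monte Carlo steps.
#' @param frame_every record a frame every this many attempted steps.
#' @param temperature unitless temperature factor for fixed-T runs.
#' @param t_start,t_end annealing schedule endpoints ([anneal()]).
#' @param schedule annealing profile: `"geometric"` or `"linear"`.
#' @param n_replicas replica count for [run_remc()].
#' @param ladder replica temperature ladder (strictly increasing); default
#'   geometric between `temperature` and `2 * temperature`.
#' @param swap_every attempted steps between replica-swap attempts; default
#'   100 sweeps (100 x residue count).
#' @param n_runs independent repeats (seeds `seed + run - 1`).
#' @param seed RNG seed recorded in the trajectory header; `NULL` leaves the
#'   RNG state untouched.
#' @param move_weights relative weights of the three move kinds
#'   (bead jitter, residue rigid shift, pivot rotation).
#' @param move_sigmas move amplitudes: jitter sd (A), shift sd (A), pivot
#'   angle sd (rad).
#' @param record_initial record the starting state as a step-0 frame.
#' @return list of class `cg_sim_config`.
#' @export
sim_config <- function(n_steps = 10000L, frame_every = 100L,
                       temperature = 1.0, t_start = 4.0, t_end = 0.4,
                       schedule = c("geometric", "linear"),
                       n_replicas = 4L, ladder = NULL, swap_every = NULL,
                       n_runs = 1L, seed = NULL,
                       move_weights = c(jitter = 1, shift = 1, pivot = 1),
                       move_sigmas = c(jitter = 0.3, shift = 0.6, pivot = 0.35),
                       record_initial = TRUE) {
  schedule <- match.arg(schedule)
  stopifnot(n_steps > 0, frame_every >= 1, temperature > 0,
            t_start > 0, t_end > 0, n_replicas >= 1,
            length(move_weights) == 3, all(move_weights >= 0),
            sum(move_weights) > 0, length(move_sigmas) == 3)
  if (!is.null(ladder)) {
    stopifnot(all(ladder > 0), !is.unsorted(ladder, strictly = TRUE))
    n_replicas <- length(ladder)
  }
  structure(list(n_steps = as.integer(n_steps),
                 frame_every = as.integer(frame_every),
                 temperature = temperature, t_start = t_start, t_end = t_end,
                 schedule = schedule, n_replicas = as.integer(n_replicas),
                 ladder = ladder, swap_every = swap_every,
                 n_runs = as.integer(n_runs), seed = seed,
                 move_weights = as.numeric(move_weights),
                 move_sigmas = as.numeric(move_sigmas),
                 record_initial = isTRUE(record_initial)),
            class = "cg_sim_config")
}

#' Metropolis acceptance rule
#'
#' Accept if the energy change is downhill, otherwise with probability
#' `exp(-delta_E / T)` (compared against the supplied uniform draw).
#'
#' @param delta_E energy change of the proposal.
#' @param T temperature factor (> 0).
#' @param u uniform(0, 1) draw.
#' @return logical, vectorized over the inputs.
#' @export
metropolis_accept <- function(delta_E, T, u) {
  stopifnot(all(T > 0))
  delta_E <= 0 | u < exp(-delta_E / T)
}

#' Propose a single Monte Carlo move
#'
#' Draws one move (bead jitter, residue rigid shift, or pivot rotation about
#' a backbone bead) and applies it.  Frozen residues are never displaced;
#' pivot proposals whose segment touches a frozen residue degenerate to the
#' identity (`record$ok = FALSE`).
#'
#' @param conf a [cg_conformation()].
#' @param move_weights,move_sigmas see [sim_config()].
#' @return list with `conf` (the moved conformation) and `record` (the move
#'   parameters; pass to [apply_move()] with `inverse = TRUE` to undo).
#' @export
propose_move <- function(conf, move_weights = c(1, 1, 1),
                         move_sigmas = c(0.3, 0.6, 0.35)) {
  ctx <- build_ctx(conf)
  rec <- cpp_draw_move(ctx, as.numeric(move_weights), as.numeric(move_sigmas),
                       coords_matrix(conf))
  list(conf = apply_move(conf, rec), record = rec)
}

#' @rdname propose_move
#' @param record a move record from `propose_move()`.
#' @param inverse apply the inverse move.
#' @export
apply_move <- function(conf, record, inverse = FALSE) {
  set_coords(conf, cpp_apply_move(coords_matrix(conf), record, inverse))
}

anneal_schedule <- function(config) {
  n <- config$n_steps
  if (config$schedule == "geometric") {
    config$t_start * (config$t_end / config$t_start)^((seq_len(n) - 1) / max(1, n - 1))
  } else {
    config$t_start + (config$t_end - config$t_start) * (seq_len(n) - 1) / max(1, n - 1)
  }
}

run_engine <- function(start, model, restraints, config, tvec,
                       mode, replica = 1L, step_offset = 0L,
                       record_initial = config$record_initial) {
  ctx <- build_ctx(start, model, restraints)
  res <- cpp_run_mc(coords_matrix(start), ctx,
                    list(n_steps = length(tvec),
                         frame_every = config$frame_every,
                         tvec = tvec,
                         move_weights = config$move_weights,
                         move_sigmas = config$move_sigmas,
                         record_initial = record_initial,
                         step_offset = as.integer(step_offset)))
  res
}

engine_frames <- function(res, replica) {
  terms <- res$terms
  colnames(terms) <- TERM_COLS
  tibble::tibble(step = res$steps, replica = as.integer(replica),
                 temperature = res$temps,
                 e_total = rowSums(terms),
                 !!!as.data.frame(terms),
                 xyz = lapply(seq_len(nrow(res$frames)), function(k) {
                   matrix(res$frames[k, ], ncol = 3, byrow = TRUE)
                 }))
}

TERM_COLS <- c("e_bond", "e_ev", "e_pairing", "e_stacking", "e_slope",
               "e_well", "e_exclusion", "e_probing")

#' Run a fixed-temperature Monte Carlo simulation
#'
#' @param start starting [cg_conformation()] (see [build_strand()] for an
#'   unfolded start).
#' @param model a [energy_model()].
#' @param restraints a [restraint_set()].
#' @param config a [sim_config()]; `config$seed`, when set, seeds the RNG so
#'   that identical (config, seed, start) give identical trajectories.
#' @param mode label recorded in the trajectory header.
#' @return a `cg_trajectory` (see [trajectory()]).
#' @export
run_mc <- function(start, model = energy_model(),
                   restraints = restraint_set(), config = sim_config(),
                   mode = "fold") {
  if (!is.null(config$seed)) set.seed(config$seed)
  tvec <- rep(config$temperature, config$n_steps)
  res <- run_engine(start, model, restraints, config, tvec, mode)
  trajectory(header_from(start, config, mode, n_replicas = 1L),
             engine_frames(res, 1L),
             stats = list(accepted = res$accepted, attempted = res$attempted))
}

#' Simulated annealing
#'
#' Temperature follows the configured profile (default geometric) from
#' `t_start` down to `t_end` over `n_steps`.
#'
#' @inheritParams run_mc
#' @return a `cg_trajectory`; each frame records its temperature.
#' @export
anneal <- function(start, model = energy_model(),
                   restraints = restraint_set(), config = sim_config()) {
  stopifnot(config$t_start >= config$t_end)
  if (!is.null(config$seed)) set.seed(config$seed)
  tvec <- anneal_schedule(config)
  res <- run_engine(start, model, restraints, config, tvec, "anneal")
  trajectory(header_from(start, config, "anneal", n_replicas = 1L),
             engine_frames(res, 1L),
             stats = list(accepted = res$accepted, attempted = res$attempted))
}

#' Unfolding simulation
#'
#' Fixed-temperature run at a high temperature factor, for stability
#' analyses starting from a folded model.
#'
#' @inheritParams run_mc
#' @param temperature high temperature factor (overrides the config).
#' @return a `cg_trajectory`.
#' @export
run_unfold <- function(start, model = energy_model(),
                       restraints = restraint_set(), config = sim_config(),
                       temperature = 8.0) {
  config$temperature <- temperature
  run_mc(start, model, restraints, config, mode = "unfold")
}

#' Replica-exchange Monte Carlo
#'
#' `n_replicas` copies run at the ladder temperatures; every `swap_every`
#' attempted steps, neighbouring replicas attempt a conformation swap with
#' acceptance `min(1, exp((1/T_i - 1/T_j) (E_i - E_j)))`.  Swaps exchange
#' conformations, not temperatures, so each replica id keeps its
#' temperature throughout.
#'
#' @inheritParams run_mc
#' @return a `cg_trajectory` whose frames carry replica ids (split with
#'   [split_replicas()]); attribute `swap_stats` records per-neighbour
#'   attempt and acceptance counts.
#' @export
run_remc <- function(start, model = energy_model(),
                     restraints = restraint_set(), config = sim_config()) {
  ladder <- config$ladder
  if (is.null(ladder)) {
    stopifnot(config$n_replicas >= 2)
    ladder <- config$temperature *
      2^((seq_len(config$n_replicas) - 1) / (config$n_replicas - 1))
  }
  K <- length(ladder)
  stopifnot(K >= 2)
  if (!is.null(config$seed)) set.seed(config$seed)
  swap_every <- config$swap_every
  if (is.null(swap_every)) swap_every <- 100L * n_residues(start)
  swap_every <- max(config$frame_every,
                    (swap_every %/% config$frame_every) * config$frame_every)
  confs <- replicate(K, coords_matrix(start), simplify = FALSE)
  ctx <- build_ctx(start, model, restraints)
  energies <- numeric(K)
  frames <- vector("list", 0)
  attempts <- accepts <- integer(K - 1)
  done <- 0L
  first <- TRUE
  accepted <- attempted <- 0
  while (done < config$n_steps) {
    chunk <- min(swap_every, config$n_steps - done)
    for (r in seq_len(K)) {
      res <- cpp_run_mc(confs[[r]], ctx,
                        list(n_steps = as.integer(chunk),
                             frame_every = config$frame_every,
                             tvec = rep(ladder[r], chunk),
                             move_weights = config$move_weights,
                             move_sigmas = config$move_sigmas,
                             record_initial = first && config$record_initial,
                             step_offset = as.integer(done)))
      confs[[r]] <- res$coords
      energies[r] <- res$energy
      accepted <- accepted + res$accepted
      attempted <- attempted + res$attempted
      frames[[length(frames) + 1L]] <- engine_frames(res, r)
    }
    first <- FALSE
    done <- done + chunk
    if (done < config$n_steps) {
      for (r in seq_len(K - 1)) {
        attempts[r] <- attempts[r] + 1L
        arg <- (1 / ladder[r] - 1 / ladder[r + 1]) * (energies[r] - energies[r + 1])
        if (stats::runif(1) < min(1, exp(arg))) {
          accepts[r] <- accepts[r] + 1L
          tmp <- confs[[r]]; confs[[r]] <- confs[[r + 1]]; confs[[r + 1]] <- tmp
          energies[c(r, r + 1)] <- energies[c(r + 1, r)]
        }
      }
    }
  }
  fr <- dplyr::bind_rows(frames)
  fr <- fr[order(fr$replica, fr$step), , drop = FALSE]
  hdr <- header_from(start, config, "remc", n_replicas = K)
  hdr$ladder <- paste(formatC(ladder, format = "g", digits = 15), collapse = " ")
  trajectory(hdr, fr,
             stats = list(accepted = accepted, attempted = attempted,
                          swap_attempts = attempts, swap_accepts = accepts))
}

header_from <- function(start, config, mode, n_replicas) {
  res <- residue_table(start)
  list(format = "cgtrj-1",
       sequence = paste(cg_sequence(start), collapse = " "),
       chains = paste(unique(res$chain), collapse = " "),
       resno = paste(res$res_number, collapse = " "),
       beads = "P C4' N9|N1 C2 C6|C4",
       fields = paste(c("step", "replica", "temperature", "e_total",
                        TERM_COLS, "xyz"), collapse = " "),
       n_replicas = n_replicas,
       seed = if (is.null(config$seed)) "NA" else as.integer(config$seed),
       mode = mode,
       n_steps = config$n_steps,
       frame_every = config$frame_every)
}

#' Run independent repeats
#'
#' Executes `config$n_runs` independent simulations with seeds
#' `config$seed + run - 1`.
#'
#' @inheritParams run_mc
#' @param fun one of [run_mc()], [anneal()], [run_remc()], [run_unfold()].
#' @return list of `cg_trajectory`, one per run.
#' @export
run_repeats <- function(fun, start, model = energy_model(),
                        restraints = restraint_set(), config = sim_config()) {
  stopifnot(!is.null(config$seed))
  lapply(seq_len(config$n_runs), function(run) {
    cfg <- config
    cfg$seed <- config$seed + run - 1L
    fun(start, model, restraints, cfg)
  })
}
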