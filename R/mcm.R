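#' Move set specification for the Monte Carlo search
#'
#' Nine move kinds with per-stage selection probabilities.  By default the
#' five large-perturbation assembly stages mix SSE addition/removal,
#' large rigid translations and rotations, flips, swaps and domain moves;
#' the sixth stage applies only small-scale perturbations.
#'
#' @param mix 9 x 6 matrix of selection probabilities (rows = move kinds,
#'   columns = stages), each column summing to 1.
#' @param translate_large,translate_small translation magnitudes
#'   (Angstrom; moves draw uniformly from a ball of this radius).
#' @param rotate_large,rotate_small maximum rotation angles (degrees).
#' @param domain_translate translation magnitude for domain moves.
#' @return object of class \code{move_spec}.
#' @export
move_spec <- function(mix = NULL, translate_large = 10,
                      rotate_large = 180, translate_small = 1,
                      rotate_small = 10, domain_translate = 5) {
  kinds <- c("add_sse", "remove_sse", "translate_large", "rotate_large",
             "flip_sse", "swap_sses", "move_domain", "translate_small",
             "rotate_small")
  if (is.null(mix)) {
    big <- c(add_sse = 0.2, remove_sse = 0.1, translate_large = 0.25,
             rotate_large = 0.25, flip_sse = 0.1, swap_sses = 0.05,
             move_domain = 0.05, translate_small = 0, rotate_small = 0)
    small <- c(add_sse = 0, remove_sse = 0, translate_large = 0,
               rotate_large = 0, flip_sse = 0, swap_sses = 0,
               move_domain = 0, translate_small = 0.5, rotate_small = 0.5)
    mix <- cbind(big, big, big, big, big, small)
    rownames(mix) <- kinds
  }
  stopifnot(nrow(mix) == 9, ncol(mix) == 6,
            all(abs(colSums(mix) - 1) < 1e-9), all(mix >= 0))
  rownames(mix) <- kinds
  structure(list(mix = mix, translate_large = translate_large,
                 rotate_large = rotate_large,
                 translate_small = translate_small,
                 rotate_small = rotate_small,
                 domain_translate = domain_translate),
            class = "move_spec")
}

#' Monte Carlo Metropolis configuration
#'
#' @param models_to_sample number of independent trajectories; each yields
#'   one final model.  Desk-scale default 200; see
#'   [mcm_config_production()] for the full 20,000-model production
#'   setting.
#' @param steps_per_stage Monte Carlo steps in each of the six stages.
#' @param temperature_start,temperature_end geometric temperature decay
#'   across the six stages (score units).
#' @param seed integer; fully determines a run.
#' @param weights a [score_weights()].
#' @param moves a [move_spec()].
#' @param restraints optional [restraint_set()] extending the scoring
#'   function.
#' @param constants a [score_constants()].
#' @param potentials as returned by [default_potentials()].
#' @return object of class \code{mcm_config}.
#' @export
mcm_config <- function(models_to_sample = 200L, steps_per_stage = 300L,
                       temperature_start = 5, temperature_end = 0.1,
                       seed = 1L, weights = score_weights(),
                       moves = move_spec(), restraints = NULL,
                       constants = score_constants(),
                       potentials = default_potentials()) {
  stopifnot(models_to_sample >= 1, steps_per_stage >= 0,
            temperature_start > 0, temperature_end > 0)
  temps <- temperature_start *
    (temperature_end / temperature_start)^((0:5) / 5)
  structure(list(models_to_sample = as.integer(models_to_sample),
                 steps_per_stage = as.integer(steps_per_stage),
                 temperatures = temps, seed = as.integer(seed),
                 weights = weights, moves = moves,
                 restraints = restraints, constants = constants,
                 potentials = potentials), class = "mcm_config")
}

#' Production-scale configuration preset
#'
#' The 20,000-model sampling contract of the full pipeline; otherwise
#' identical to the defaults.
#'
#' @param ... overrides passed to [mcm_config()].
#' @export
mcm_config_production <- function(...) {
  mcm_config(models_to_sample = 20000L, ...)
}

# ---- internal light-weight model mutation ------------------------------

empty_model <- function(sequence, pool) {
  m <- structure(list(sequence = sequence, bodies = list(), pool = pool),
                 class = "protein_model")
  m$completeness <- 0
  m
}

# Recompute completeness without full revalidation (moves never create
# overlapping placements: bodies are keyed by pool index).
refresh_completeness <- function(model, pool_res_n) {
  placed <- sum(vapply(model$bodies, function(b) length(b$residues),
                       integer(1)))
  model$completeness <- placed / pool_res_n
  model
}

pool_residue_count <- function(pool) {
  length(unique(unlist(lapply(pool, function(d) d$first_res:d$last_res))))
}

set_transform <- function(body, R, t) {
  body$rotation <- R
  body$translation <- as.numeric(t)
  body$coords <- lapply(body$canonical, apply_transform, R = R, t = t)
  body
}

body_center <- function(body) colMeans(body$coords$CA)

model_center <- function(model) {
  if (length(model$bodies) == 0) return(c(0, 0, 0))
  colMeans(do.call(rbind, lapply(model$bodies, body_center)))
}

rotate_about <- function(body, R, center) {
  transform_sse(body, R, as.numeric(center - R %*% center))
}

#' Propose one Monte Carlo move
#'
#' Draws a move kind from the stage's selection probabilities and applies
#' it; kinds that are illegal in the current state (e.g. removing from an
#' empty model) are redrawn internally, so the proposal never fails.
#'
#' @param model a [protein_model()] whose bodies are drawn from
#'   \code{pool}.
#' @param pool list of [sse_definition()].
#' @param stage integer stage in [1, 6].
#' @param moves a [move_spec()].
#' @param canon optional pre-built list of canonical bodies (one per pool
#'   entry), as an efficiency aid for the engine.
#' @return list with elements \code{model} (the mutated copy) and
#'   \code{kind}.
#' @export
propose_move <- function(model, pool, stage, moves = move_spec(),
                         canon = NULL) {
  stopifnot(length(pool) >= 1)
  if (is.null(canon))
    canon <- lapply(pool, build_idealized_sse, sequence = model$sequence)
  eng <- engine_init(model$sequence, pool, canon)
  prop <- propose_state(model_to_state(model, eng), eng, stage, moves)
  list(model = state_to_model(prop$state, eng), kind = prop$kind)
}

# sample() without the length-1 surprise.
resample <- function(x, size) x[sample.int(length(x), size)]

#' Metropolis acceptance criterion
#'
#' Accepts a proposed move with probability
#' \eqn{\min(1, \exp(-\Delta / T))}: moves that do not worsen the score
#' are always accepted.
#'
#' @param delta_score score difference (proposed - current).
#' @param temperature simulated temperature, > 0 (score units).
#' @return logical.
#' @export
metropolis_accept <- function(delta_score, temperature) {
  if (!is.numeric(temperature) || temperature <= 0)
    stop("temperature must be > 0")
  if (delta_score <= 0) return(TRUE)
  runif(1) < exp(-delta_score / temperature)
}

#' One sampled model with its scores
#'
#' @param id model identifier.
#' @param model a [protein_model()].
#' @param scores a \code{score_result}.
#' @return object of class \code{model_record} carrying the model, its
#'   placed Calpha coordinates, per-term scores, total score,
#'   completeness, and (once computed) accuracy metrics vs a reference.
#' @export
model_record <- function(id, model, scores) {
  ca <- model_ca(model)
  structure(list(id = id, model = model, scores = scores,
                 total = scores$total, completeness = model$completeness,
                 ca = ca, resno = as.integer(rownames(ca)),
                 metrics = list()), class = "model_record")
}

#' @export
print.model_record <- function(x, ...) {
  cat(sprintf("<model_record> %s: total %.2f, completeness %.2f\n",
              x$id, x$total, x$completeness))
  invisible(x)
}

#' Run the staged Monte Carlo topology search
#'
#' Samples \code{config$models_to_sample} independent trajectories.  Each
#' trajectory starts from an empty model and runs the six-stage protocol:
#' five large-perturbation assembly stages with the clash weight ramping
#' up through the schedule, then one small-perturbation stage.  The final
#' state of each trajectory is emitted as one [model_record()].  A fixed
#' seed makes the run fully reproducible.
#'
#' @param sequence a [sequence_info()].
#' @param pool non-empty list of [sse_definition()].
#' @param config an [mcm_config()].
#' @return list of [model_record()].
#' @export
run_fold <- function(sequence, pool, config = mcm_config()) {
  stopifnot(inherits(sequence, "sequence_info"), length(pool) >= 1,
            inherits(config, "mcm_config"))
  pool <- pool[order(vapply(pool, `[[`, integer(1), "first_res"))]
  canon <- lapply(pool, build_idealized_sse, sequence = sequence)
  eng <- engine_init(sequence, pool, canon)
  prep <- prep_potentials(config$potentials)
  pr <- if (is.null(config$restraints)) NULL else
    prep_restraints(config$restraints, eng)
  set.seed(config$seed)
  records <- vector("list", config$models_to_sample)
  for (traj in seq_len(config$models_to_sample)) {
    st <- engine_trajectory(engine_state(eng), eng, config, 1:6, prep, pr)
    model <- state_to_model(st, eng)
    scores <- total_score(model, config$weights, 6L, config$restraints,
                          config$potentials, config$constants)
    records[[traj]] <- model_record(sprintf("m%05d", traj), model, scores)
  }
  records
}

#' Relax a reference structure in the low-resolution force field
#'
#' Starts every trajectory from the reference's SSE placements (idealized
#' bodies superposed onto the reference coordinates of each pool SSE) and
#' applies only the small-perturbation stage, probing whether
#' conformations structurally similar to the reference score favorably.
#' With \code{steps_per_stage = 0} the output is the scored input.
#'
#' @param reference a [protein_structure()] with coordinates covering
#'   every pool SSE.
#' @param pool non-empty list of [sse_definition()].
#' @param config an [mcm_config()].
#' @return list of [model_record()].
#' @export
relax_from_reference <- function(reference, pool, config = mcm_config()) {
  stopifnot(inherits(reference, "protein_structure"), length(pool) >= 1)
  sequence <- reference$sequence
  pool <- pool[order(vapply(pool, `[[`, integer(1), "first_res"))]
  canon <- lapply(pool, build_idealized_sse, sequence = sequence)
  eng <- engine_init(sequence, pool, canon)
  start <- engine_state(eng)
  for (i in seq_along(pool)) {
    rng <- pool[[i]]$first_res:pool[[i]]$last_res
    ref_ca <- reference$CA[rng, , drop = FALSE]
    if (anyNA(ref_ca))
      stop("reference lacks coordinates for SSE ", pool[[i]]$first_res,
           "-", pool[[i]]$last_res)
    fit <- .kabsch_cpp(canon[[i]]$canonical$CA, ref_ca)
    start <- state_place(start, eng, i, t(fit$rotation),
                         as.numeric(fit$translation))
  }
  prep <- prep_potentials(config$potentials)
  pr <- if (is.null(config$restraints)) NULL else
    prep_restraints(config$restraints, eng)
  set.seed(config$seed)
  records <- vector("list", config$models_to_sample)
  for (traj in seq_len(config$models_to_sample)) {
    st <- engine_trajectory(start, eng, config, 6L, prep, pr)
    model <- state_to_model(st, eng)
    scores <- total_score(model, config$weights, 6L, config$restraints,
                          config$potentials, config$constants)
    records[[traj]] <- model_record(sprintf("r%05d", traj), model, scores)
  }
  records
}
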