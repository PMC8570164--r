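## Metropolis-Hastings engine for power posterior sampling.
##
## A "model" is a plain list (class "pp_model") with:
##   log_prior(values)       -> log prior density of a named parameter list
##   log_likelihood(values)  -> UNTEMPERED log likelihood
##   moves                   -> ordered list of move kernels (see moves.R)
##   initial_state()         -> named parameter list, drawn with the current RNG
## Parameter values are named list entries: real scalars, positive reals, or
## simplex vectors (positive, summing to 1).
##
## A chain "state" (class "pp_state") carries the values plus cached log prior
## and log likelihood; the likelihood cache may be NA when the chain runs at
## beta = 0, where the likelihood never enters the acceptance ratio.

#' Construct a model for the power posterior engine
#'
#' @param name model name (used in messages and manifests).
#' @param log_prior function(values) returning the log prior density.
#' @param log_likelihood function(values) returning the untempered log
#'   likelihood.
#' @param moves ordered list of move kernels (see \code{\link{move_sliding}},
#'   \code{\link{move_scale}}, \code{\link{move_simplex}}).
#' @param initial_state function() drawing a starting parameter list with the
#'   current RNG.
#' @return an object of class \code{pp_model}.
#' @export
pp_model <- function(name, log_prior, log_likelihood, moves, initial_state) {
  stopifnot(is.function(log_prior), is.function(log_likelihood),
            is.list(moves), length(moves) >= 1L, is.function(initial_state))
  structure(list(name = name, log_prior = log_prior,
                 log_likelihood = log_likelihood, moves = moves,
                 initial_state = initial_state),
            class = "pp_model")
}

new_state <- function(model, values, compute_ll = TRUE) {
  lp <- model$log_prior(values)
  ll <- if (compute_ll) model$log_likelihood(values) else NA_real_
  structure(list(values = values, log_prior = lp, log_likelihood = ll),
            class = "pp_state")
}

state_ll <- function(model, state) {
  if (is.na(state$log_likelihood))
    state$log_likelihood <- model$log_likelihood(state$values)
  state
}

#' Tempered Metropolis-Hastings acceptance probability
#'
#' Acceptance probability of a proposed state under the power posterior at
#' power \code{beta}: \code{min(1, exp(beta*(ll_new - ll_old) +
#' (lp_new - lp_old) + log_hastings))}. At \code{beta = 0} the likelihood term
#' is dropped before any arithmetic, so prior-only sampling never touches the
#' likelihood (and never forms 0 * (-Inf)).
#'
#' @param ll_new,ll_old untempered log likelihood of proposed/current state
#'   (ignored when \code{beta == 0}; may then be NA or -Inf).
#' @param lp_new,lp_old log prior of proposed/current state.
#' @param log_hastings log of the proposal density ratio
#'   q(current | proposed) / q(proposed | current).
#' @param beta tempering power in [0, 1].
#' @return acceptance probability in [0, 1].
#' @export
tempered_acceptance <- function(ll_new, ll_old, lp_new, lp_old,
                                log_hastings, beta) {
  if (!is.numeric(beta) || length(beta) != 1L || is.na(beta) ||
      beta < 0 || beta > 1)
    stop("'beta' must be a single number in [0, 1]", call. = FALSE)
  log_ratio <- (lp_new - lp_old) + log_hastings
  if (beta > 0)
    log_ratio <- log_ratio + beta * (ll_new - ll_old)
  if (is.nan(log_ratio))
    stop("non-numeric acceptance ratio (check move / prior)", call. = FALSE)
  min(1, exp(log_ratio))
}

#' One MCMC sweep at a given power
#'
#' Applies every registered move once, in registration order; each proposal is
#' accepted with \code{\link{tempered_acceptance}} at power \code{beta}.
#' One "iteration" of the engine is exactly one such sweep.
#'
#' @param model a \code{pp_model}.
#' @param state current \code{pp_state}.
#' @param beta tempering power in [0, 1].
#' @return the updated \code{pp_state} with caches current (likelihood cache
#'   stays NA at \code{beta = 0}).
#' @export
mcmc_sweep <- function(model, state, beta) {
  for (mv in model$moves) {
    prop <- mv$propose(state$values)
    if (is.null(prop)) next          # move not applicable (e.g. fixed param)
    lp_new <- model$log_prior(prop$values)
    if (lp_new == -Inf) next         # proposal outside the prior support
    if (beta > 0) {
      state <- state_ll(model, state)
      ll_new <- model$log_likelihood(prop$values)
      if (ll_new == -Inf) next       # immediate rejection, avoids 0*(-Inf)
      a <- tempered_acceptance(ll_new, state$log_likelihood,
                               lp_new, state$log_prior,
                               prop$log_hastings, beta)
    } else {
      ll_new <- NA_real_
      a <- tempered_acceptance(NA_real_, NA_real_,
                               lp_new, state$log_prior,
                               prop$log_hastings, 0)
    }
    if (stats::runif(1) < a) {
      state$values <- prop$values
      state$log_prior <- lp_new
      state$log_likelihood <- ll_new
      acc <- attr(state, "accepted")
      acc[mv$name] <- (if (is.null(acc[mv$name]) || is.na(acc[mv$name])) 0L
                       else acc[mv$name]) + 1L
      attr(state, "accepted") <- acc
    }
  }
  state
}

move_names <- function(model) vapply(model$moves, `[[`, "", "name")

zero_counts <- function(model) {
  z <- integer(length(model$moves))
  names(z) <- move_names(model)
  z
}

#' Pre-burn-in phase
#'
#' Runs \code{preburn_iters} sweeps at the target power, starting from the
#' model's random initial state, to move the chain from its dispersed start
#' into the first sampling distribution. In a parallel analysis every worker
#' performs its own pre-burn-in at the first (highest) power of its block.
#'
#' @param model a \code{pp_model}.
#' @param config a \code{\link{stone_run_config}}.
#' @param beta_target power at which to pre-burn (1 for the first block).
#' @return the final \code{pp_state}; attribute \code{"acceptance"} carries
#'   per-move acceptance counts for logging.
#' @export
pre_burnin <- function(model, config, beta_target = 1) {
  state <- new_state(model, model$initial_state(),
                     compute_ll = beta_target > 0)
  attr(state, "accepted") <- zero_counts(model)
  for (i in seq_len(config$preburn_iters))
    state <- mcmc_sweep(model, state, beta_target)
  acc <- attr(state, "accepted") / max(1L, config$preburn_iters)
  attr(state, "accepted") <- NULL
  attr(state, "acceptance") <- acc
  state
}

#' Run configuration for power posterior simulations
#'
#' @param L iterations (sweeps) per stone; must be divisible by \code{T}.
#' @param T thinning interval: the untempered log likelihood is recorded every
#'   T-th sweep, giving L/T raw samples per stone.
#' @param burnin_frac fraction of each stone's recorded samples discarded as
#'   per-stone burn-in; \code{(1 - burnin_frac) * L / T} must be a positive
#'   integer (the retained sample count n).
#' @param preburn_iters sweeps of pre-burn-in before a worker's first stone.
#' @param seed root RNG seed for the whole analysis.
#' @return a \code{stone_run_config} list with the validated fields plus
#'   \code{n}, the retained samples per stone.
#' @export
stone_run_config <- function(L = 10000L, T = 10L, burnin_frac = 0.25,
                             preburn_iters = 10000L, seed = 1L) {
  stopifnot(L >= 1, T >= 1, preburn_iters >= 0)
  if (L %% T != 0)
    stop("'L' must be divisible by 'T'", call. = FALSE)
  if (burnin_frac < 0 || burnin_frac >= 1)
    stop("'burnin_frac' must be in [0, 1)", call. = FALSE)
  n_raw <- L / T
  n <- (1 - burnin_frac) * n_raw
  if (abs(n - round(n)) > 1e-9 || round(n) < 1)
    stop("(1 - burnin_frac) * L / T must be a positive integer", call. = FALSE)
  structure(list(L = as.integer(L), T = as.integer(T),
                 burnin_frac = burnin_frac,
                 preburn_iters = as.integer(preburn_iters),
                 seed = as.integer(seed), n = as.integer(round(n))),
            class = "stone_run_config")
}

#' Run one power posterior simulation (a "stone")
#'
#' Runs L sweeps at power \code{beta}, recording the untempered log likelihood
#' every T-th sweep, then discards the first \code{burnin_frac} fraction of
#' the recorded samples as per-stone burn-in.
#'
#' @param model a \code{pp_model}.
#' @param beta the stone's power in [0, 1].
#' @param init_state starting \code{pp_state} (the previous stone's final
#'   state, or the pre-burn-in result).
#' @param config a \code{\link{stone_run_config}}.
#' @param stone integer stone index (0-based; for messages and output files).
#' @return a \code{stone_samples} list: \code{stone}, \code{power},
#'   \code{loglik} (n retained values), \code{iterations} (sweep index of each
#'   retained sample), \code{final_state}, and per-move \code{acceptance}.
#' @export
run_stone <- function(model, beta, init_state, config, stone = NA_integer_) {
  stopifnot(inherits(init_state, "pp_state"))
  n_raw <- config$L %/% config$T
  raw <- numeric(n_raw)
  its <- integer(n_raw)
  j <- 0L
  state <- init_state
  attr(state, "accepted") <- zero_counts(model)
  for (it in seq_len(config$L)) {
    state <- mcmc_sweep(model, state, beta)
    if (it %% config$T == 0L) {
      state <- state_ll(model, state)
      j <- j + 1L
      raw[j] <- state$log_likelihood
      its[j] <- it
      if (!is.finite(raw[j]))
        stop(sprintf("non-finite log likelihood at stone %s, iteration %d",
                     as.character(stone), it), call. = FALSE)
    }
  }
  keep <- seq.int(n_raw - config$n + 1L, n_raw)
  acc <- attr(state, "accepted") / config$L
  attr(state, "accepted") <- NULL
  structure(list(stone = stone, power = beta,
                 loglik = raw[keep], iterations = its[keep],
                 final_state = state, acceptance = acc),
            class = "stone_samples")
}

#' Run a block of stones with decreasing powers
#'
#' Performs one pre-burn-in at the block's first (highest) power, then runs
#' each stone in order, threading the final chain state of each stone into
#' the next. Running posterior-to-prior makes adjacent sampling distributions
#' similar, so the carried-over state needs only a short per-stone burn-in.
#'
#' The caller is responsible for seeding the RNG before the call; given the
#' same model, block, config, and RNG state, the output is bit-identical.
#'
#' @param model a \code{pp_model}.
#' @param stones integer vector of 0-based stone indices (decreasing power).
#' @param powers numeric vector of powers, same length, strictly decreasing.
#' @param config a \code{\link{stone_run_config}}.
#' @param init_state optional starting \code{pp_state}; when supplied the
#'   pre-burn-in phase is skipped (used to resume, or to reproduce a run that
#'   starts from posterior samples).
#' @return list of \code{stone_samples}, one per stone, in block order.
#' @export
run_block <- function(model, stones, powers, config, init_state = NULL) {
  stopifnot(length(stones) == length(powers), length(powers) >= 1L)
  if (length(powers) > 1L && any(diff(powers) >= 0))
    stop("block powers must be strictly decreasing", call. = FALSE)
  state <- if (is.null(init_state)) {
    pre_burnin(model, config, beta_target = powers[1])
  } else init_state
  out <- vector("list", length(stones))
  for (i in seq_along(stones)) {
    out[[i]] <- run_stone(model, powers[i], state, config, stone = stones[i])
    state <- out[[i]]$final_state
  }
  out
}
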