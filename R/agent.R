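#' Virtual neurofeedback subject
#'
#' A deliberately simple stand-in for the human learner: a single latent
#' `coupling` parameter (the true correlation between the two target ROIs
#' during imagery, clipped to \[-1, 1\]), a `learning_rate` and a per-trial
#' exploration SD. On each trial the agent perturbs its coupling by a random
#' exploration jitter, the imagery-period activity is generated at the
#' perturbed coupling, and the received score reinforces the jitter direction
#' (reward-contingent exploration). No claim of cognitive realism is made.
#'
#' The reinforcement is the score's deviation from the agent's running
#' average score (an exponentially weighted baseline), not its raw level:
#' only doing *better than usual* in the direction of the current jitter
#' moves the coupling. This leaves the contingent learning signal intact
#' while a non-contingent (yoked sham) score series, whose level carries no
#' information about the agent's own jitter, produces a zero-mean,
#' low-variance update.
#'
#' @param coupling initial latent correlation between the target ROIs.
#' @param learning_rate step size, in units of coupling per unit (score/100)
#'   per unit standardized jitter.
#' @param exploration_sd SD of the per-trial coupling jitter.
#' @param baseline_rate exponential moving-average rate of the reward
#'   baseline.
#' @return A `cf_agent` object.
#' @seealso [run_session()], [simulate_training_trial()]
#' @export
agent_state <- function(coupling = -0.3, learning_rate = 0.1,
                        exploration_sd = 0.15, baseline_rate = 0.2) {
  stopifnot(abs(coupling) <= 1, learning_rate >= 0, exploration_sd >= 0,
            baseline_rate > 0, baseline_rate <= 1)
  structure(list(coupling = coupling, learning_rate = learning_rate,
                 exploration_sd = exploration_sd,
                 baseline_rate = baseline_rate, score_ema = NA_real_,
                 last_jitter = 0),
            class = "cf_agent")
}

#' @export
print.cf_agent <- function(x, ...) {
  cat(sprintf("<cf_agent> coupling %.3f, learning_rate %.3g, exploration_sd %.3g\n",
              x$coupling, x$learning_rate, x$exploration_sd))
  invisible(x)
}

clip1 <- function(x) pmin(1, pmax(-1, x))

# Draw the trial's exploration jitter; uses the current RNG stream.
agent_explore <- function(agent) {
  agent$last_jitter <- if (agent$exploration_sd > 0) {
    stats::rnorm(1, 0, agent$exploration_sd)
  } else 0
  agent
}

# Reward-contingent update: move coupling along the jitter direction,
# weighted by the score's advantage over the agent's running-average score.
# E[delta] > 0 only when the score actually depends on the agent's own
# activity; yoked (non-contingent) scores give a zero-mean update.
agent_learn <- function(agent, score) {
  if (is.na(score)) return(agent)
  if (is.na(agent$score_ema)) agent$score_ema <- score
  advantage <- score - agent$score_ema
  agent$score_ema <- agent$score_ema + agent$baseline_rate * advantage
  if (agent$learning_rate == 0) return(agent)
  dir <- if (agent$exploration_sd > 0) {
    agent$last_jitter / agent$exploration_sd
  } else 0
  agent$coupling <- clip1(agent$coupling +
                            agent$learning_rate * (advantage / 100) * dir)
  agent
}

#' Naive score-following coupling update
#'
#' The simplest conceivable learner update: add `learning_rate * score / 100`
#' plus a random exploration jitter to the coupling, clipping to \[-1, 1\].
#' With zero learning rate and jitter the coupling is unchanged, and repeated
#' positive scores drive it monotonically upward.
#'
#' Note: this open-loop rule is provided for completeness and for studying
#' learner dynamics; [run_session()] uses the reward-contingent rule of
#' [agent_state()] instead, because a score-following update would also
#' "learn" from yoked sham scores, which a contingency-sensitive learner (and
#' a human subject) does not.
#'
#' @param agent a `cf_agent`.
#' @param score the trial's feedback score in \[-100, 100\].
#' @param seed optional integer seed for the jitter (deterministic updates).
#' @return The updated `cf_agent`.
#' @examples
#' a <- agent_state(coupling = 0, learning_rate = 0.1, exploration_sd = 0)
#' simulate_training_trial(a, 50)$coupling
#' @export
simulate_training_trial <- function(agent, score, seed = NULL) {
  stopifnot(inherits(agent, "cf_agent"), abs(score) <= 100)
  if (!is.null(seed)) local_rng(seed)
  jitter <- if (agent$exploration_sd > 0) {
    stats::rnorm(1, 0, agent$exploration_sd)
  } else 0
  agent$coupling <- clip1(agent$coupling +
                            agent$learning_rate * score / 100 + jitter)
  agent
}

# Bivariate standard-normal samples with correlation r, as an n x 2 matrix.
rbivariate <- function(n, r) {
  z <- matrix(stats::rnorm(2 * n), n, 2)
  cbind(z[, 1], r * z[, 1] + sqrt(max(0, 1 - r^2)) * z[, 2])
}
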