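#' Mean-field victimization rates
#'
#' Expected number of exploitation attempts received per agent per round,
#' for agents without a toughness reputation (submissive agents and
#' exploiters) and for agents with one (players of the violent strategy).
#' Each exploiter draws \code{n_targets} candidate targets uniformly from
#' the population and attacks a candidate without a toughness reputation if
#' there is one, otherwise a violent candidate: choosing the violent
#' strategy is observable and deflects exploitation towards unprotected
#' targets.
#'
#' With candidate-sample size \eqn{n} and violent fraction \eqn{v}, an
#' attack lands on the unprotected class with probability \eqn{1 - v^n},
#' spread over its mass \eqn{1 - v}, and on the violent class otherwise:
#' \deqn{rate_s = e (1 - v^n) / (1 - v), \qquad rate_t = e v^{n-1}.}
#' As \eqn{v \to 1} the unprotected rate tends to \eqn{e n}: the few
#' remaining unprotected agents concentrate every attack that finds one
#' (the closed-form limit is used rather than the 0/0 ratio). At
#' \eqn{n = 1} the signal is inert and both rates equal \eqn{e}; as
#' \eqn{n \to \infty} violent agents are never victimized while any
#' unprotected agent remains.
#'
#' @param freqs a [strategy_freqs] object.
#' @param n_targets candidate-sample size (integer >= 1).
#' @return Named list with \code{rate_submissive} (per submissive or
#'   exploiting agent) and \code{rate_tough} (per violent agent), expected
#'   attacks per agent per round.
#' @examples
#' victimization_rates(strategy_freqs(e = 0.1, v = 0.3), n_targets = 1)
#' victimization_rates(strategy_freqs(e = 0.02, v = 0.5), n_targets = 50)
#' @export
victimization_rates <- function(freqs, n_targets) {
  stopifnot(inherits(freqs, "strategy_freqs"),
            n_targets >= 1, n_targets == round(n_targets))
  e <- freqs$e; v <- freqs$v
  n <- n_targets
  if (e == 0) return(list(rate_submissive = 0, rate_tough = 0))
  if (n == 1)  # inert signal: both classes are hit at the exploiter rate
    return(list(rate_submissive = e, rate_tough = e))
  if (v > 1 - 1e-12) {
    # limit v -> 1 of e*(1-v^n)/(1-v)
    rate_s <- e * n * v^(n - 1)
  } else if (v == 0) {
    rate_s <- e
  } else {
    rate_s <- e * (-expm1(n * log(v))) / (1 - v)
  }
  rate_t <- e * v^(n - 1)
  list(rate_submissive = rate_s, rate_tough = rate_t)
}

# expected attack count -> at-most-one-event probability (Poisson thinning)
attack_prob <- function(lambda) -expm1(-lambda)

# combine independent event components: each a data.frame(prob, delta,
# fights_lost); outcomes multiply, deltas and fights add, then aggregate
combine_outcomes <- function(...) {
  parts <- list(...)
  out <- parts[[1L]]
  for (p in parts[-1L]) {
    out <- data.frame(
      prob = as.vector(outer(out$prob, p$prob)),
      delta = as.vector(outer(out$delta, p$delta, `+`)),
      fights_lost = as.vector(outer(out$fights_lost, p$fights_lost, `+`)))
  }
  key <- paste(out$delta, out$fights_lost)
  agg <- rowsum(out$prob, key)
  first <- !duplicated(key)
  res <- data.frame(prob = agg[match(key[first], rownames(agg)), 1L],
                    delta = out$delta[first],
                    fights_lost = out$fights_lost[first])
  res <- res[res$prob > 0, , drop = FALSE]
  res <- res[order(res$delta, res$fights_lost), , drop = FALSE]
  rownames(res) <- NULL
  res
}

outcome_df <- function(prob, delta, fights_lost)
  data.frame(prob = prob, delta = delta, fights_lost = fights_lost)

#' Per-round outcome distribution of a strategy
#'
#' Enumerates the exact distribution of (resource change, fights lost) for
#' one round of play, for an agent using the given strategy in a population
#' with the given strategy frequencies. All encounter probabilities are
#' mean-field: they depend on the population only through \code{freqs}.
#'
#' Event semantics:
#' \itemize{
#' \item An exploiter makes one attempt per round. A submissive target
#'   surrenders the stake: the theft succeeds (\code{+beta}) unless
#'   sanctioned (probability \code{gamma}), in which case it fails and the
#'   sanction costs \code{pi_cost}. A defended target (a violent agent, or
#'   another exploiter, both of which react violently) fights: a coin toss
#'   decides the stake and the loser records a lost fight; an independent
#'   sanction then voids any gain and costs \code{pi_cost}. Exploiters
#'   carry no toughness reputation themselves, so they are victimized at
#'   the unprotected rate -- but they fight back when attacked.
#' \item A violent (non-exploiting) agent is victimized at the deflected
#'   rate and fights back; it may also start a mistaken attack with
#'   probability \code{m} (a fight only if the target is violent too) and
#'   may receive mistaken attacks from other violent agents. Mistake
#'   fights carry no resource stake; the loser records a lost fight.
#' \item A submissive agent that is victimized loses \code{beta} with
#'   certainty and never fights. Mistaken attacks on it trigger no fight
#'   and have no effect.
#' }
#' Expected per-agent attack counts are converted to at-most-one-event
#' probabilities by Poisson thinning \eqn{p = 1 - e^{-\lambda}}, which
#' keeps the support finite and is accurate in the small-\eqn{e} regime the
#' model lives in.
#'
#' @param strategy one of \code{"exploit"}, \code{"violent"},
#'   \code{"submissive"}.
#' @param freqs a [strategy_freqs] object.
#' @param params a [model_params] object.
#' @return A data.frame with columns \code{prob}, \code{delta} (resource
#'   change) and \code{fights_lost}; probabilities sum to one.
#' @examples
#' p <- model_params()
#' round_outcome_distribution("exploit", strategy_freqs(0, 0, 1), p)
#' @export
round_outcome_distribution <- function(strategy, freqs, params) {
  strategy <- match.arg(strategy, STRATEGIES)
  stopifnot(inherits(freqs, "strategy_freqs"), inherits(params, "violence_params"))
  rates <- victimization_rates(freqs, params$n_targets)
  beta <- params$beta; pi_c <- params$pi_cost; gamma <- params$gamma
  m <- params$m; e <- freqs$e; v <- freqs$v; s <- freqs$s

  # incoming victimization for an agent that fights back: coin toss over
  # its own beta, the loser records the fight
  fightback_victim <- function(p_att) outcome_df(
    prob = c(1 - p_att, p_att / 2, p_att / 2),
    delta = c(0, 0, -beta),
    fights_lost = c(0, 0, 1))

  if (strategy == "submissive") {
    p_att <- attack_prob(rates$rate_submissive)
    out <- outcome_df(prob = c(1 - p_att, p_att),
                      delta = c(0, -beta), fights_lost = c(0, 0))
    return(combine_outcomes(out))
  }

  # expected mistaken attacks received per non-exploiter agent
  lambda_mist <- if (e >= 1) 0 else m * v / (1 - e)

  if (strategy == "violent") {
    victim <- fightback_victim(attack_prob(rates$rate_tough))
    # own mistaken attack: fight iff the uniform non-exploiter target is violent
    p_own_fight <- lambda_mist
    own <- outcome_df(prob = c(1 - p_own_fight / 2, p_own_fight / 2),
                      delta = c(0, 0), fights_lost = c(0, 1))
    p_in <- attack_prob(lambda_mist)
    incoming <- outcome_df(prob = c(1 - p_in / 2, p_in / 2),
                           delta = c(0, 0), fights_lost = c(0, 1))
    return(combine_outcomes(victim, own, incoming))
  }

  # exploiter: one outgoing attempt, plus incoming attacks at the
  # unprotected rate (fighting back)
  # probability the chosen target surrenders: a submissive candidate is
  # picked (preferred pool is the non-violent class, exploiters included)
  if (v >= 1 - 1e-12) {
    q_undef <- 0
  } else {
    q_undef <- (-expm1(params$n_targets * log(max(v, .Machine$double.xmin)))) *
      s / (1 - v)
    if (v == 0) q_undef <- s / (1 - v)
  }
  vs_sub <- outcome_df(prob = c(1 - gamma, gamma),
                       delta = c(beta, -pi_c), fights_lost = c(0, 0))
  vs_defended <- outcome_df(
    prob = c((1 - gamma) / 2, gamma / 2, (1 - gamma) / 2, gamma / 2),
    delta = c(beta, -pi_c, 0, -pi_c),
    fights_lost = c(0, 0, 1, 1))
  outgoing <- rbind(
    transform(vs_sub, prob = prob * q_undef),
    transform(vs_defended, prob = prob * (1 - q_undef)))
  victim <- fightback_victim(attack_prob(rates$rate_submissive))
  combine_outcomes(outgoing, victim)
}

#' Expected per-round payoff of exploitation
#'
#' Mean resource change of one round of the exploitation strategy,
#' \eqn{\sum_o p_o \delta_o} over [round_outcome_distribution]. Under the
#' parameter constraint \eqn{(1-\gamma)\beta - \gamma\pi \le 0} this is
#' non-positive for every population composition, with equality only
#' against an all-submissive population at the boundary
#' \eqn{(1-\gamma)\beta = \gamma\pi}: stealing is on average a bad
#' decision, and desperate agents do it for its upside, not its mean.
#'
#' @inheritParams round_outcome_distribution
#' @return Expected resource change (resource units), \code{<= 0}.
#' @examples
#' expected_exploitation_payoff(model_params(), strategy_freqs(0, 0, 1))
#' @export
expected_exploitation_payoff <- function(params, freqs) {
  d <- round_outcome_distribution("exploit", freqs, params)
  sum(d$prob * d$delta)
}
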