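# Policy objects: a shared interface for the random-walk baseline and
# trained Q-table policies, so all experiment code is policy-agnostic.

#' Policy objects
#'
#' A policy is a list with fields `name`, `needs_state` (whether
#' [step_world()] must run the vision pipeline before querying it) and
#' `select(state)`, returning a 0-based action index using the current R
#' RNG stream.
#'
#' `random_walk_policy()` ignores the state and draws uniformly over the
#' action set — identical in law to an untrained Q-table's stochastic
#' policy. `q_policy()` wraps a [q_table()] with stochastic (default) or
#' greedy selection.
#'
#' @param n_actions size of the action set.
#' @return a list of class `"flock_policy"`.
#' @name flock_policy
NULL

#' @rdname flock_policy
#' @export
random_walk_policy <- function(n_actions = 24) {
  structure(list(name = "random_walk", needs_state = FALSE,
                 n_actions = n_actions,
                 select = function(state) sample.int(n_actions, 1L) - 1L),
            class = "flock_policy")
}

#' @rdname flock_policy
#' @param q a [q_table()].
#' @param mode `"stochastic"` or `"greedy"` action selection.
#' @export
q_policy <- function(q, mode = c("stochastic", "greedy")) {
  mode <- match.arg(mode)
  structure(list(name = paste0("q_", mode), needs_state = TRUE,
                 n_actions = q$n_actions, q = q, mode = mode,
                 select = function(state) select_action(q, state, mode)),
            class = "flock_policy")
}

#' @export
print.flock_policy <- function(x, ...) {
  cat(sprintf("<flock_policy> %s (%d actions, %s)\n", x$name, x$n_actions,
              if (isTRUE(x$needs_state)) "state-dependent"
              else "state-independent"))
  invisible(x)
}
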