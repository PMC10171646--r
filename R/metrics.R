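# Swarm-level order and collision metrics and the combined objective.

.wrap_angle <- function(x) {
  # wrap to (-pi, pi]
  y <- (x + pi) %% (2 * pi) - pi
  y[y == -pi] <- pi
  y
}

.circ_mean <- function(angles) atan2(mean(sin(angles)), mean(cos(angles)))

.heading_angles <- function(x) {
  if (inherits(x, "swarm")) atan2(x$heading[, 2], x$heading[, 1])
  else if (is.numeric(x)) x
  else stop("expected a swarm or a numeric vector of heading angles")
}

#' Collective-motion order metric
#'
#' The alignment disorder of the population: the mean squared angular
#' deviation of each agent's heading from the population's circular-mean
#' heading (deviations wrapped to `(-pi, pi]`), scaled by `1 / (2 pi)`.
#' Perfect alignment gives 0; independent uniform headings give
#' `pi^2 / 3 / (2 pi)`, about 0.524, in expectation. Agents with zero
#' velocity contribute their last moving heading.
#'
#' @param x a `swarm` or a numeric vector of heading angles (radians).
#' @return the disorder value `F >= 0` (lower = more aligned).
#' @export
cm_metric <- function(x) {
  ang <- .heading_angles(x)
  if (!length(ang)) stop("empty population")
  mean(.wrap_angle(ang - .circ_mean(ang))^2) / (2 * pi)
}

#' Collision-rate metric
#'
#' The number of agent pairs currently in collision (centre distance below
#' the body-size threshold, minimal image) divided by the largest possible
#' number of simultaneous collisions, `floor(|P| / 2)` disjoint pairs.
#'
#' @param x a `swarm`.
#' @param n_pairs optionally, a pre-computed colliding-pair count (skips
#'   detection).
#' @return collision rate in `[0, 1]`; 0 for fewer than two agents.
#' @export
ca_metric <- function(x, n_pairs = NULL) {
  n <- x$n
  if (n < 2) return(0)
  if (is.null(n_pairs)) n_pairs <- nrow(detect_collisions(x))
  min(1, n_pairs / (n %/% 2))
}

.clip01 <- function(x) pmin(1, pmax(0, x))

#' Combined objective and scores over a run
#'
#' The time-mean of `zeta * F_t + (1 - zeta) * C_t` over the tick window
#' `[t0, tf]`. Scores are the complements: `cm = 1 - F`, `ca = 1 - C`,
#' `cmca = 1 - (zeta F + (1 - zeta) C)`, clipped into `[0, 1]`.
#'
#' @param F_t,C_t per-tick metric vectors (equal length).
#' @param zeta weight of the alignment term.
#' @param t0,tf 1-based tick window bounds (defaults: whole series).
#' @return the mean objective (lower is better).
#' @export
cmca_objective <- function(F_t, C_t, zeta, t0 = 1L, tf = length(F_t)) {
  stopifnot(length(F_t) == length(C_t), t0 <= tf, tf <= length(F_t))
  idx <- t0:tf
  mean(zeta * F_t[idx] + (1 - zeta) * C_t[idx])
}

#' Per-tick score table
#'
#' @param F_t,C_t per-tick metric vectors.
#' @param zeta alignment weight.
#' @return a data.frame with columns `t`, `F`, `C`, `cm_score`, `ca_score`,
#'   `cmca_score`.
#' @export
score_series <- function(F_t, C_t, zeta) {
  data.frame(t = seq_along(F_t), F = F_t, C = C_t,
             cm_score = .clip01(1 - F_t), ca_score = .clip01(1 - C_t),
             cmca_score = .clip01(1 - (zeta * F_t + (1 - zeta) * C_t)))
}

#' Local (planning) objective of a patch rollout
#'
#' The same combined objective restricted to the focal agent's local patch
#' over a planning rollout: the mean over the `eta + 1` evaluated snapshots
#' (initial state included) of `zeta * F_t + (1 - zeta) * C_t` computed on
#' the patch population. A lone focal agent scores 0 on both terms.
#'
#' @param F_t,C_t per-snapshot patch metrics (length `eta + 1`).
#' @param zeta alignment weight.
#' @return the rollout objective (lower is better); its complement, clipped
#'   to `[0, 1]`, is the planning score fed to the Q-update.
#' @export
local_objective <- function(F_t, C_t, zeta) {
  stopifnot(length(F_t) == length(C_t), length(F_t) >= 1)
  mean(zeta * F_t + (1 - zeta) * C_t)
}

#' Write a score series to CSV
#' @param scores data.frame from [score_series()].
#' @param path output file.
#' @export
write_scores <- function(scores, path) {
  utils::write.csv(scores, path, row.names = FALSE)
  invisible(path)
}
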