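# Synchronised discrete-time world: action application, toroidal movement,
# collision detection and the active/passive collision protocol.

#' The discrete action set
#'
#' Action `i` (0-based) is the unit heading at `i * (360 / n_actions)`
#' degrees counter-clockwise from the +x axis.
#'
#' @param n_actions number of actions (e.g. 24 for a 15-degree grid).
#' @return an `n_actions` x 2 matrix of unit direction vectors; row `i + 1`
#'   is action `i`.
#' @export
action_set <- function(n_actions) {
  ang <- (seq_len(n_actions) - 1) * 2 * pi / n_actions
  cbind(cos(ang), sin(ang))
}

#' Initialise a swarm
#'
#' Positions uniform over the arena; each velocity component drawn as
#' `U[0, v_init_max]` with an independent random sign, so initial headings
#' are spread over all quadrants; accelerations zero.
#'
#' @param config a [flock_config()].
#' @return a list of class `"swarm"` with position/velocity/acceleration
#'   and heading matrices (`n` x 2) plus per-agent body and sensing sizes.
#' @export
make_swarm <- function(config) {
  n <- as.integer(config$n_agents)
  l <- cbind(stats::runif(n, 0, config$width),
             stats::runif(n, 0, config$height))
  v <- cbind(stats::runif(n, 0, config$v_init_max) * sample(c(-1, 1), n, TRUE),
             stats::runif(n, 0, config$v_init_max) * sample(c(-1, 1), n, TRUE))
  sp <- sqrt(rowSums(v^2))
  heading <- v / ifelse(sp > 0, sp, 1)
  if (any(sp == 0))
    heading[sp == 0, ] <- matrix(c(1, 0), sum(sp == 0), 2, byrow = TRUE)
  structure(list(n = n, l = l, v = v, a = matrix(0, n, 2), heading = heading,
                 h = rep(config$body_h, n), w = rep(config$body_w, n),
                 r = rep(config$radius, n),
                 width = config$width, height = config$height),
            class = "swarm")
}

#' @export
print.swarm <- function(x, ...) {
  cat(sprintf("<swarm> %d agents in %g x %g m (toroidal)\n",
              x$n, x$width, x$height))
  cat(sprintf("  mean speed %.3f m/step, order metric F = %.3f\n",
              mean(sqrt(rowSums(x$v^2))), cm_metric(x)))
  invisible(x)
}

# Extract one agent as an agent_state view.
as_agent <- function(swarm, i) {
  agent_state(id = i, l = swarm$l[i, ], v = swarm$v[i, ],
              h = swarm$h[i], w = swarm$w[i], r = swarm$r[i],
              heading = swarm$heading[i, ])
}

#' Apply an action to one agent
#'
#' The movement update: the acceleration is set to the chosen unit
#' direction, the velocity gains `delta` times that direction, and the
#' position advances by the new velocity (wrapped). With
#' `renorm = TRUE` (the default) the new velocity is rescaled to the
#' pre-update speed, so the action steers the heading only; an agent at
#' rest simply accelerates to speed `delta`.
#'
#' @param agent an `agent_state`.
#' @param action 0-based action index, or a unit direction 2-vector.
#' @param delta action influence weight.
#' @param n_actions size of the action set (used when `action` is an index).
#' @param width,height arena dimensions for wrapping (default unbounded).
#' @param renorm rescale speed to its pre-update magnitude.
#' @return the updated `agent_state`.
#' @export
apply_action <- function(agent, action, delta, n_actions = 24,
                         width = Inf, height = Inf, renorm = TRUE) {
  dir <- if (length(action) == 2) action
         else action_set(n_actions)[as.integer(action) + 1, ]
  v0 <- sqrt(sum(agent$v^2))
  v <- agent$v + delta * dir
  if (renorm && v0 > 0) {
    nv <- sqrt(sum(v^2))
    if (nv > 0) v <- v * (v0 / nv)
  }
  agent$a <- dir
  agent$v <- v
  l <- agent$l + v
  agent$l <- if (is.finite(width)) wrap_position(l, width, height) else l
  sp <- sqrt(sum(v^2))
  if (sp > 0) agent$heading <- v / sp
  agent
}

# Vectorised movement update for a whole swarm.
.apply_actions <- function(swarm, action_idx, dirs, delta, renorm = TRUE) {
  a <- dirs[action_idx + 1L, , drop = FALSE]
  v0 <- sqrt(rowSums(swarm$v^2))
  v <- swarm$v + delta * a
  if (renorm) {
    nv <- sqrt(rowSums(v^2))
    scale <- ifelse(v0 > 0 & nv > 0, v0 / nv, 1)
    v <- v * scale
  }
  swarm$a <- a
  swarm$v <- v
  swarm$l <- wrap_position(swarm$l + v, swarm$width, swarm$height)
  sp <- sqrt(rowSums(v^2))
  upd <- sp > 0
  swarm$heading[upd, ] <- v[upd, , drop = FALSE] / sp[upd]
  swarm
}

# All-pairs minimal-image centre distances (n x n matrix).
.pair_distances <- function(swarm) {
  dx <- outer(swarm$l[, 1], swarm$l[, 1], "-")
  dy <- outer(swarm$l[, 2], swarm$l[, 2], "-")
  dx <- dx - swarm$width * round(dx / swarm$width)
  dy <- dy - swarm$height * round(dy / swarm$height)
  sqrt(dx^2 + dy^2)
}

#' Detect colliding pairs
#'
#' Two agents collide when the minimal-image distance between their
#' centres is at most `max(h1 + h2, w1 + w2) / 2` (0.07 m with the default
#' body). Detection runs on current (post-move) positions.
#'
#' @param swarm a `swarm`.
#' @return a matrix with columns `i`, `j` (`i < j`), ordered by `(i, j)`;
#'   zero rows if no pair collides.
#' @export
detect_collisions <- function(swarm) {
  n <- swarm$n
  if (n < 2) return(matrix(integer(0), 0, 2, dimnames = list(NULL, c("i", "j"))))
  d <- .pair_distances(swarm)
  thr <- pmax(outer(swarm$h, swarm$h, "+"), outer(swarm$w, swarm$w, "+")) / 2
  hit <- d <= thr
  hit[lower.tri(hit, diag = TRUE)] <- FALSE
  idx <- which(hit, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  colnames(idx) <- c("i", "j")
  idx
}

#' Active/passive roles of a colliding pair
#'
#' An agent is the active (ramming) party iff the other's centre lies in
#' its front half-plane (positive dot product of its heading with the
#' minimal-image displacement to the partner). A head-tail collision thus
#' stops the follower and pushes the leader; a frontal collision makes
#' both active. Mutual rear contact (neither faces the other) is a
#' degenerate case treated as both active.
#'
#' @param a1,a2 `agent_state`s of a colliding pair.
#' @param width,height arena dimensions.
#' @return character vector of two roles, `"active"` or `"passive"`.
#' @export
classify_roles <- function(a1, a2, width = Inf, height = Inf) {
  d12 <- torus_delta(a1$l, a2$l, width, height)
  act1 <- sum(a1$heading * d12) > 0
  act2 <- sum(a2$heading * -d12) > 0
  if (!act1 && !act2) { # mutual rear contact: degenerate, both stopped
    act1 <- act2 <- TRUE
  }
  ifelse(c(act1, act2), "active", "passive")
}

#' Resolve collisions for the current tick
#'
#' Applies the collision protocol to every detected pair, in ascending
#' `(i, j)` order: active agents are stopped (`v = 0`) for this tick;
#' each passive agent gains its partner's velocity at collision time
#' (the pre-resolution snapshot). Updates compose when one agent sits in
#' several pairs.
#'
#' @param swarm a `swarm` (post-move).
#' @param events pair matrix from [detect_collisions()].
#' @return a list with the updated `swarm` and a data.frame `log` of
#'   `(i, j, role_i, role_j)`.
#' @export
resolve_collisions <- function(swarm, events) {
  if (!nrow(events))
    return(list(swarm = swarm,
                log = data.frame(i = integer(0), j = integer(0),
                                 role_i = character(0),
                                 role_j = character(0))))
  v0 <- swarm$v # velocities at collision time
  roles <- matrix("", nrow(events), 2)
  for (e in seq_len(nrow(events))) {
    i <- events[e, 1]; j <- events[e, 2]
    d <- torus_delta(swarm$l[i, ], swarm$l[j, ], swarm$width, swarm$height)
    act_i <- sum(swarm$heading[i, ] * d) > 0
    act_j <- sum(swarm$heading[j, ] * -d) > 0
    if (!act_i && !act_j) act_i <- act_j <- TRUE
    if (act_i) swarm$v[i, ] <- c(0, 0) else swarm$v[i, ] <- swarm$v[i, ] + v0[j, ]
    if (act_j) swarm$v[j, ] <- c(0, 0) else swarm$v[j, ] <- swarm$v[j, ] + v0[i, ]
    roles[e, ] <- ifelse(c(act_i, act_j), "active", "passive")
  }
  sp <- sqrt(rowSums(swarm$v^2))
  upd <- sp > 0
  swarm$heading[upd, ] <- swarm$v[upd, , drop = FALSE] / sp[upd]
  list(swarm = swarm,
       log = data.frame(i = events[, 1], j = events[, 2],
                        role_i = roles[, 1], role_j = roles[, 2]))
}

#' Initial simulation state
#'
#' @param swarm a `swarm`.
#' @return a list of class `"sim_state"` carrying the swarm, the tick
#'   counter, per-agent previous observations (for derivative channels)
#'   and per-tick metric accumulators.
#' @export
sim_state <- function(swarm) {
  structure(list(swarm = swarm, tick = 0L,
                 prev_obs = vector("list", swarm$n),
                 F_t = numeric(0), C_t = numeric(0),
                 collisions = list()),
            class = "sim_state")
}

#' Advance the world by one tick
#'
#' Phase 1: every agent senses the tick-start snapshot and chooses an
#' action, in a random permutation (perception is synchronous, so the
#' permutation only orders the random draws). Policies that ignore the
#' state (`needs_state = FALSE`) skip the sensing work. Phase 2: all
#' agents move simultaneously. Phase 3: collisions are detected on the
#' post-move positions and resolved; the per-tick order and collision
#' metrics are recorded.
#'
#' @param state a `sim_state`.
#' @param policy a [flock_policy] object.
#' @param config a [flock_config()].
#' @return the advanced `sim_state`.
#' @export
step_world <- function(state, policy, config) {
  swarm <- state$swarm
  n <- swarm$n
  dirs <- action_set(config$n_actions)
  ord <- sample.int(n)
  actions <- integer(n)
  if (isTRUE(policy$needs_state)) {
    pd <- .pair_distances(swarm)
    new_prev <- vector("list", n)
    for (i in ord) {
      nb_idx <- which(pd[i, ] < swarm$r[i])
      nb_idx <- nb_idx[nb_idx != i]
      neighbors <- lapply(nb_idx, function(j) as_agent(swarm, j))
      focal <- as_agent(swarm, i)
      visible <- occlusion_filter(focal, neighbors, swarm$width, swarm$height)
      # overlapping bodies (mid-collision) trigger the full-occupancy
      # warning routinely; not actionable inside the stepping loop
      obs <- suppressWarnings(
        observe(focal, visible, previous = state$prev_obs[[i]],
                width = swarm$width, height = swarm$height,
                signed_theta = isTRUE(config$signed_theta)))
      enc <- encode_state(obs, config$k_max, config$bin_width)
      actions[i] <- policy$select(enc)
      new_prev[[i]] <- obs
    }
    state$prev_obs <- new_prev
  } else {
    for (i in ord) actions[i] <- policy$select(NULL)
  }
  swarm <- .apply_actions(swarm, actions, dirs, config$delta,
                          renorm = isTRUE(config$speed_renorm))
  events <- detect_collisions(swarm)
  res <- resolve_collisions(swarm, events)
  swarm <- res$swarm
  state$swarm <- swarm
  state$tick <- state$tick + 1L
  state$F_t <- c(state$F_t, cm_metric(swarm))
  state$C_t <- c(state$C_t, ca_metric(swarm, n_pairs = nrow(events)))
  if (nrow(res$log)) {
    res$log$t <- state$tick
    state$collisions[[length(state$collisions) + 1L]] <- res$log
  }
  state
}

#' Run a full-world simulation
#'
#' @param config a [flock_config()].
#' @param policy a [flock_policy] object.
#' @param steps number of ticks (default `config$steps`).
#' @param seed optional seed set before initialisation, making the run
#'   bit-reproducible.
#' @param record_trajectory keep one row per (tick, agent)?
#' @return a list with the per-tick `scores` data.frame (see
#'   [score_series()]), the final `swarm`, the collision `log`, and the
#'   `trajectory` data.frame when requested.
#' @export
simulate_swarm <- function(config, policy, steps = config$steps,
                           seed = NULL, record_trajectory = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  swarm <- make_swarm(config)
  state <- sim_state(swarm)
  traj <- if (record_trajectory) vector("list", steps) else NULL
  for (s in seq_len(steps)) {
    state <- step_world(state, policy, config)
    if (record_trajectory) {
      sw <- state$swarm
      collided <- rep(FALSE, sw$n)
      if (length(state$collisions)) {
        last <- state$collisions[[length(state$collisions)]]
        if (nrow(last) && last$t[1] == state$tick)
          collided[c(last$i, last$j)] <- TRUE
      }
      traj[[s]] <- data.frame(t = state$tick, id = seq_len(sw$n),
                              lx = sw$l[, 1], ly = sw$l[, 2],
                              vx = sw$v[, 1], vy = sw$v[, 2],
                              collided = collided)
    }
  }
  log <- if (length(state$collisions)) do.call(rbind, state$collisions)
         else data.frame(i = integer(0), j = integer(0),
                         role_i = character(0), role_j = character(0),
                         t = integer(0))
  list(scores = score_series(state$F_t, state$C_t, config$zeta),
       swarm = state$swarm, collision_log = log,
       trajectory = if (record_trajectory) do.call(rbind, traj) else NULL)
}

#' Write a trajectory to CSV
#' @param trajectory data.frame from [simulate_swarm()].
#' @param path output file.
#' @export
write_trajectory <- function(trajectory, path) {
  utils::write.csv(trajectory, path, row.names = FALSE)
  invisible(path)
}

#' Write a collision log as JSON lines
#'
#' One JSON object per collision event (`t`, `i`, `j`, `role_i`,
#' `role_j`).
#'
#' @param log collision log data.frame from [simulate_swarm()].
#' @param path output file.
#' @export
write_collision_log <- function(log, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in seq_len(nrow(log)))
    writeLines(jsonlite::toJSON(as.list(log[r, ]), auto_unbox = TRUE), con)
  invisible(path)
}
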