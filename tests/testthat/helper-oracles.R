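# Independent oracles and small generators used across the suite.

# Dense boundary-sampling oracle for the subtended angle: sample points on
# the rectangle outline and take the maximum pairwise angular span of their
# bearings (width of the minimal covering arc).
oracle_subtended <- function(focal_l, neighbor, n_pts = 2500) {
  u <- neighbor$v
  sp <- sqrt(sum(u^2))
  u <- if (sp > 0) u / sp else neighbor$heading
  up <- c(-u[2], u[1])
  tpar <- seq(-0.5, 0.5, length.out = n_pts %/% 2)
  edge <- function(a0, da, b0, db) {
    cbind(neighbor$l[1] + a0 * u[1] + da * tpar * u[1] +
            b0 * up[1] + db * tpar * up[1],
          neighbor$l[2] + a0 * u[2] + da * tpar * u[2] +
            b0 * up[2] + db * tpar * up[2])
  }
  h <- neighbor$h; w <- neighbor$w
  pts <- rbind(edge(h / 2, 0, 0, w), edge(-h / 2, 0, 0, w),
               edge(0, h, w / 2, 0), edge(0, h, -w / 2, 0))
  b <- sort(atan2(pts[, 2] - focal_l[2], pts[, 1] - focal_l[1]))
  gaps <- diff(c(b, b[1] + 2 * pi))
  2 * pi - max(gaps)
}

# Ray-casting oracle for occlusion: a neighbour is visible iff at least one
# of `rays` rays from the focal centre hits it before any other neighbour.
oracle_visible <- function(focal, neighbors, rays = 3600) {
  ang <- seq(0, 2 * pi, length.out = rays + 1)[-(rays + 1)]
  ray_hit <- function(theta, p) {
    # distance along the ray to the rectangle of p, Inf if missed
    d <- c(cos(theta), sin(theta))
    u <- visflock:::.heading_of(p)
    up <- c(-u[2], u[1])
    rel <- p$l - focal$l
    # solve in body frame: along = rel.u + t d.u etc.
    a0 <- sum(rel * u); b0 <- sum(rel * up)
    da <- sum(d * u); db <- sum(d * up)
    ts <- c()
    if (abs(da) > 1e-12) for (s in c(-1, 1)) {
      t <- (s * p$h / 2 - a0) / da
      if (t > 0 && abs(b0 + db * t) <= p$w / 2) ts <- c(ts, t)
    }
    if (abs(db) > 1e-12) for (s in c(-1, 1)) {
      t <- (s * p$w / 2 - b0) / db
      if (t > 0 && abs(a0 + da * t) <= p$h / 2) ts <- c(ts, t)
    }
    if (length(ts)) min(ts) else Inf
  }
  m <- length(neighbors)
  seen <- rep(FALSE, m)
  for (theta in ang) {
    d <- vapply(neighbors, function(p) ray_hit(theta, p), numeric(1))
    hit <- which.min(d)
    if (is.finite(d[hit])) seen[hit] <- TRUE
  }
  seen
}

# Plain-R reference rollout for the GA fitness: focal follows the gene,
# neighbours ballistic, unbounded patch, collisions counted not resolved.
oracle_gene_objective <- function(scenario, gene, cfg) {
  agents <- c(list(scenario$focal), scenario$neighbors)
  m <- length(agents)
  patch_cost <- function(agents) {
    ang <- vapply(agents, function(p) {
      u <- visflock:::.heading_of(p); atan2(u[2], u[1])
    }, numeric(1))
    F <- cm_metric(ang)
    C <- 0
    if (m >= 2) {
      pairs <- 0
      for (i in seq_len(m - 1)) for (j in (i + 1):m) {
        thr <- max(agents[[i]]$h + agents[[j]]$h,
                   agents[[i]]$w + agents[[j]]$w) / 2
        if (sqrt(sum((agents[[i]]$l - agents[[j]]$l)^2)) <= thr)
          pairs <- pairs + 1
      }
      C <- min(1, pairs / (m %/% 2))
    }
    cfg$zeta * F + (1 - cfg$zeta) * C
  }
  acc <- patch_cost(agents)
  for (t in seq_along(gene)) {
    agents[[1]] <- apply_action(agents[[1]], gene[t], cfg$delta,
                                n_actions = cfg$n_actions,
                                renorm = isTRUE(cfg$speed_renorm))
    for (i in seq_len(m)[-1]) agents[[i]]$l <- agents[[i]]$l + agents[[i]]$v
    acc <- acc + patch_cost(agents)
  }
  acc / (length(gene) + 1)
}

# Exhaustive search over all action sequences of length eta.
brute_force_best <- function(scenario, cfg) {
  eta <- cfg$eta; n <- cfg$n_actions
  grid <- as.matrix(expand.grid(rep(list(0:(n - 1)), eta)))
  obj <- gene_objectives(scenario, grid, cfg)
  list(objective = min(obj), gene = grid[which.min(obj), ])
}

random_agent <- function(id, box = 2, cfg = flock_config()) {
  agent_state(id, stats::runif(2, -box, box),
              stats::runif(2, -0.15, 0.15),
              h = cfg$body_h, w = cfg$body_w, r = cfg$radius)
}

# A two-agent head-on scenario: neighbour approaching the focal agent
# front-to-front at the given gap.
head_on_scenario <- function(cfg, gap = 0.1, speed = 0.05) {
  structure(list(
    focal = agent_state(0L, c(0, 0), c(speed, 0), h = cfg$body_h,
                        w = cfg$body_w, r = cfg$radius),
    neighbors = list(agent_state(1L, c(gap, 0), c(-speed, 0),
                                 h = cfg$body_h, w = cfg$body_w,
                                 r = cfg$radius))), class = "scenario")
}

# Hand-built swarm with given positions/velocities and default bodies.
make_test_swarm <- function(l, v, width = 5, height = 5,
                            h = 0.07, w = 0.01, r = 0.21) {
  n <- nrow(l)
  sp <- sqrt(rowSums(v^2))
  heading <- v / ifelse(sp > 0, sp, 1)
  if (any(sp == 0))
    heading[sp == 0, ] <- matrix(c(1, 0), sum(sp == 0), 2, byrow = TRUE)
  structure(list(n = n, l = l, v = v, a = matrix(0, n, 2),
                 heading = heading, h = rep(h, n), w = rep(w, n),
                 r = rep(r, n), width = width, height = height),
            class = "swarm")
}
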