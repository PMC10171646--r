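# Vision geometry: corner projection, subtended angle, angular position,
# occlusion, observation derivatives and state discretisation.

SENTINEL_BIN <- 1000000L

#' Construct a single agent state
#'
#' @param id integer identifier.
#' @param l position (2-vector), metres.
#' @param v velocity (2-vector), metres per tick.
#' @param a acceleration (2-vector).
#' @param h,w body length (along heading) and width, metres.
#' @param r sensing radius, metres.
#' @param heading optional unit 2-vector; defaults to the direction of `v`,
#'   or the +x axis when the agent has never moved.
#' @return a list of class `"agent_state"`.
#' @export
agent_state <- function(id, l, v, a = c(0, 0), h = 0.07, w = 0.01,
                        r = 0.21, heading = NULL) {
  stopifnot(length(l) == 2, length(v) == 2, h > 0, w > 0, r > 0)
  if (is.null(heading)) {
    sp <- sqrt(sum(v^2))
    heading <- if (sp > 0) v / sp else c(1, 0)
  }
  structure(list(id = as.integer(id), l = as.numeric(l), v = as.numeric(v),
                 a = as.numeric(a), h = h, w = w, r = r,
                 heading = as.numeric(heading)),
            class = "agent_state")
}

.heading_of <- function(agent) {
  sp <- sqrt(sum(agent$v^2))
  if (sp > 0) agent$v / sp else agent$heading
}

#' Minimal-image displacement on the torus
#'
#' Displacement from `from` to `to` with both components wrapped into
#' `[-width/2, width/2]` x `[-height/2, height/2]`, i.e. the shortest
#' vector between the two points under periodic boundaries. `to` may be a
#' matrix of points (one per row).
#'
#' @param from 2-vector.
#' @param to 2-vector or n x 2 matrix.
#' @param width,height arena dimensions; use `Inf` for an unbounded patch.
#' @return displacement with the same shape as `to`.
#' @export
torus_delta <- function(from, to, width = Inf, height = Inf) {
  if (is.matrix(to)) {
    d <- cbind(to[, 1] - from[1], to[, 2] - from[2])
    if (is.finite(width))  d[, 1] <- d[, 1] - width  * round(d[, 1] / width)
    if (is.finite(height)) d[, 2] <- d[, 2] - height * round(d[, 2] / height)
    d
  } else {
    d <- to - from
    if (is.finite(width))  d[1] <- d[1] - width  * round(d[1] / width)
    if (is.finite(height)) d[2] <- d[2] - height * round(d[2] / height)
    d
  }
}

#' Wrap a position into the periodic arena
#'
#' @param l 2-vector or n x 2 matrix of positions.
#' @param width,height arena dimensions.
#' @return position(s) with both components in `[0, width) x [0, height)`.
#' @export
wrap_position <- function(l, width, height) {
  if (is.matrix(l)) cbind(l[, 1] %% width, l[, 2] %% height)
  else c(l[1] %% width, l[2] %% height)
}

#' Body-rectangle corners of an agent
#'
#' The four lab-frame corners of the `h` x `w` rectangle centred on the
#' agent and aligned with its heading:
#' `l + s1 * (h/2) * u + s2 * (w/2) * u_perp`, `s1, s2 in {-1, +1}`,
#' where `u` is the unit heading and `u_perp` its left-hand perpendicular.
#' A zero-velocity agent keeps its last stored heading.
#'
#' @param agent an `agent_state`.
#' @return a 4 x 2 matrix of corner positions (rows: `(-,+), (+,-), (-,-),
#'   (+,+)` sign pairs).
#' @export
corner_positions <- function(agent) {
  u <- .heading_of(agent)
  up <- c(-u[2], u[1])
  s1 <- c(-1, 1, -1, 1) * agent$h / 2
  s2 <- c(1, -1, -1, 1) * agent$w / 2
  cbind(agent$l[1] + s1 * u[1] + s2 * up[1],
        agent$l[2] + s1 * u[2] + s2 * up[2])
}

# Focal-frame corner vectors under the minimal-image convention: the
# neighbour centre is wrapped to its nearest image, corners ride along.
.focal_frame_corners <- function(focal, neighbor, width = Inf, height = Inf) {
  d <- torus_delta(focal$l, neighbor$l, width, height)
  corners <- corner_positions(neighbor)
  cbind(corners[, 1] - neighbor$l[1] + d[1],
        corners[, 2] - neighbor$l[2] + d[2])
}

.point_in_rect <- function(point_rel, agent) {
  u <- .heading_of(agent)
  up <- c(-u[2], u[1])
  along <- sum(point_rel * u)
  across <- sum(point_rel * up)
  abs(along) <= agent$h / 2 && abs(across) <= agent$w / 2
}

#' Angle subtended by a neighbour on the focal agent's retina
#'
#' The maximum over all corner pairs of the angle between the focal-frame
#' corner vectors. This covers the three geometric cases: a diagonal pair
#' is extreme in general position, and the near-edge pair is extreme when
#' the line of sight is perpendicular or parallel to the neighbour's
#' heading.
#'
#' @param focal,neighbor `agent_state`s; their centres must not coincide.
#' @param width,height arena dimensions for the minimal-image convention
#'   (default unbounded).
#' @return the subtended angle in `[0, pi]` radians. If the focal centre
#'   lies inside the neighbour's body rectangle the view is fully occupied:
#'   returns `pi` with a warning.
#' @export
subtended_angle <- function(focal, neighbor, width = Inf, height = Inf) {
  d <- torus_delta(focal$l, neighbor$l, width, height)
  if (all(d == 0)) stop("degenerate geometry: coincident agent centres")
  chi <- .focal_frame_corners(focal, neighbor, width, height)
  if (.point_in_rect(-d, neighbor)) {
    warning("focal centre inside neighbour body; subtended angle set to pi")
    return(pi)
  }
  nrm <- sqrt(rowSums(chi^2))
  best <- 0
  for (i in 1:3) for (j in (i + 1):4) {
    cs <- sum(chi[i, ] * chi[j, ]) / (nrm[i] * nrm[j])
    ang <- acos(min(1, max(-1, cs)))
    if (ang > best) best <- ang
  }
  best
}

#' Angular position of a neighbour
#'
#' The angle between the focal agent's heading and the bearing of the
#' neighbour's centre, `acos` of their normalised dot product, hence
#' unsigned in `[0, pi]` (an agent cannot tell left from right). With
#' `signed = TRUE` the angle keeps the sign of the cross product instead.
#'
#' @param focal,neighbor `agent_state`s with distinct centres.
#' @param width,height arena dimensions (minimal image).
#' @param signed return a signed angle in `(-pi, pi]` instead.
#' @return angle in radians.
#' @export
angular_position <- function(focal, neighbor, width = Inf, height = Inf,
                             signed = FALSE) {
  d <- torus_delta(focal$l, neighbor$l, width, height)
  nd <- sqrt(sum(d^2))
  if (nd == 0) stop("degenerate geometry: coincident agent centres")
  u <- .heading_of(focal)
  th <- acos(min(1, max(-1, sum(u * d) / nd)))
  if (signed && (u[1] * d[2] - u[2] * d[1]) < 0) th <- -th
  th
}

#' Neighbours within sensing range
#'
#' The local environment of the focal agent: every other agent whose
#' minimal-image centre distance is strictly below the focal sensing
#' radius.
#'
#' @param focal an `agent_state`.
#' @param population list of `agent_state`s, excluding the focal agent.
#' @param width,height arena dimensions.
#' @return the sub-list of in-range agents.
#' @export
local_environment <- function(focal, population, width = Inf, height = Inf) {
  if (!length(population)) return(list())
  keep <- vapply(population, function(p) {
    d <- torus_delta(focal$l, p$l, width, height)
    sqrt(sum(d^2)) < focal$r
  }, logical(1))
  population[keep]
}

# Minimal covering arc of a set of bearings: c(start, width), start in
# (-pi, pi]. The arc is the complement of the largest angular gap.
.bearing_arc <- function(chi) {
  b <- sort(atan2(chi[, 2], chi[, 1]))
  gaps <- diff(c(b, b[1] + 2 * pi))
  gi <- which.max(gaps)
  start <- if (gi == length(b)) b[1] else b[gi + 1]
  c(start = start, width = 2 * pi - gaps[gi])
}

#' Drop fully hidden neighbours
#'
#' A neighbour is removed iff its angular interval on the focal retina is
#' entirely covered by the union of the angular intervals of strictly
#' nearer neighbours. Partially hidden neighbours are kept with their full
#' geometric subtended angle.
#'
#' @param focal an `agent_state`.
#' @param neighbors list of in-range `agent_state`s.
#' @param width,height arena dimensions (minimal image).
#' @return the visible sub-list, in the input order.
#' @export
occlusion_filter <- function(focal, neighbors, width = Inf, height = Inf) {
  m <- length(neighbors)
  if (m < 2) return(neighbors)
  dist <- vapply(neighbors, function(p) {
    d <- torus_delta(focal$l, p$l, width, height)
    sqrt(sum(d^2))
  }, numeric(1))
  arcs <- lapply(neighbors, function(p)
    .bearing_arc(.focal_frame_corners(focal, p, width, height)))
  hidden <- vapply(seq_len(m), function(i) {
    nearer <- which(dist < dist[i])
    if (!length(nearer)) return(FALSE)
    tgt <- arcs[[i]]
    # Rebase every covering arc to the target's start angle and test that
    # the union of intervals covers [0, target width].
    ivs <- do.call(rbind, lapply(arcs[nearer], function(a) {
      cs <- (a[1] - tgt[1]) %% (2 * pi)
      rbind(c(cs, cs + a[2]), c(cs - 2 * pi, cs - 2 * pi + a[2]))
    }))
    ivs <- ivs[ivs[, 2] > 0 & ivs[, 1] < tgt[2], , drop = FALSE]
    if (!nrow(ivs)) return(FALSE)
    ivs <- ivs[order(ivs[, 1]), , drop = FALSE]
    covered_to <- 0
    for (r in seq_len(nrow(ivs))) {
      if (ivs[r, 1] > covered_to + 1e-12) return(FALSE)
      covered_to <- max(covered_to, ivs[r, 2])
      if (covered_to >= tgt[2] - 1e-12) return(TRUE)
    }
    covered_to >= tgt[2] - 1e-12
  }, logical(1))
  neighbors[!hidden]
}

#' Visual observation of the visible neighbours
#'
#' Computes the vision tuple `(psi, psi_dot, theta, theta_dot)` for each
#' visible neighbour: subtended angle and angular position from the
#' geometry, and their one-step backward finite differences against the
#' previous observation matched by neighbour id. A neighbour seen for the
#' first time gets zero derivatives.
#'
#' @param focal an `agent_state`.
#' @param visible occlusion-filtered list of `agent_state`s.
#' @param previous optional previous observation list as returned by this
#'   function (matched on `$id`).
#' @param width,height arena dimensions.
#' @param signed_theta see [angular_position()].
#' @return a list of vision tuples, each a list with `id`, `psi`,
#'   `psi_dot`, `theta`, `theta_dot`, `dist`.
#' @export
observe <- function(focal, visible, previous = NULL,
                    width = Inf, height = Inf, signed_theta = FALSE) {
  prev_ids <- if (length(previous))
    vapply(previous, `[[`, integer(1), "id") else integer(0)
  lapply(visible, function(p) {
    psi <- subtended_angle(focal, p, width, height)
    th <- angular_position(focal, p, width, height, signed = signed_theta)
    d <- torus_delta(focal$l, p$l, width, height)
    pm <- match(p$id, prev_ids)
    if (!is.na(pm)) {
      pv <- previous[[pm]]
      psid <- psi - pv$psi
      thd <- th - pv$theta
    } else psid <- thd <- 0
    list(id = p$id, psi = psi, psi_dot = psid, theta = th,
         theta_dot = thd, dist = sqrt(sum(d^2)))
  })
}

#' Discretise an observation into a Q-table state
#'
#' Observations are sorted by ascending angular position (ties by distance,
#' then id), truncated to the `k` nearest slots, and each scalar floored to
#' its bin index at resolution `bin_width`. Derivative channels are clipped
#' to `[-pi, pi]` per step before binning. Absent slots are filled with a
#' sentinel bin that no real value can produce, so the all-sentinel vector
#' is the "alone" state. The encoding is a pure function of its inputs.
#'
#' @param observations list of vision tuples from [observe()].
#' @param k number of neighbour slots.
#' @param bin_width bin resolution in radians (and radians/step).
#' @return an integer vector of length `4 * k` of class `"encoded_state"`
#'   with a `key` attribute (a hashable string).
#' @export
encode_state <- function(observations, k, bin_width) {
  stopifnot(bin_width > 0, k >= 1)
  m <- length(observations)
  if (m > 1) {
    th <- vapply(observations, `[[`, numeric(1), "theta")
    ds <- vapply(observations, `[[`, numeric(1), "dist")
    id <- vapply(observations, `[[`, integer(1), "id")
    observations <- observations[order(th, ds, id)]
  }
  if (m > k) observations <- observations[seq_len(k)]
  out <- rep(SENTINEL_BIN, 4 * k)
  clip <- function(x) min(pi, max(-pi, x))
  for (i in seq_len(min(m, k))) {
    o <- observations[[i]]
    out[(4 * (i - 1) + 1):(4 * i)] <-
      as.integer(floor(c(o$psi, clip(o$psi_dot), o$theta,
                         clip(o$theta_dot)) / bin_width))
  }
  structure(as.integer(out), key = paste(out, collapse = ","),
            class = "encoded_state")
}

#' Hash key of an encoded state
#' @param state an `encoded_state`.
#' @return the state's key string.
#' @export
state_key <- function(state) attr(state, "key")
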