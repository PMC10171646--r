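cfg <- flock_config()

test_that("positions wrap into the arena", {
  expect_equal(wrap_position(c(5.2, -0.3), 5, 5), c(0.2, 4.7))
  expect_equal(wrap_position(c(2, 2), 5, 5), c(2, 2))
  expect_equal(wrap_position(c(10, 10), 5, 5), c(0, 0))
  m <- wrap_position(rbind(c(5.2, -0.3), c(2, 2)), 5, 5)
  expect_equal(m[1, ], c(0.2, 4.7))
})

test_that("the movement update steers the heading at fixed speed", {
  a <- agent_state(1, c(0, 0), c(0.1, 0))
  # action parallel to v: heading unchanged, advance by v
  out <- apply_action(a, c(1, 0), delta = 0.05)
  expect_equal(out$v, c(0.1, 0))
  expect_equal(out$l, c(0.1, 0))
  # perpendicular action: rotate by atan(delta/speed), keep speed
  out2 <- apply_action(a, c(0, 1), delta = 0.05)
  expect_equal(sqrt(sum(out2$v^2)), 0.1, tolerance = 1e-12)
  expect_equal(atan2(out2$v[2], out2$v[1]), atan2(0.05, 0.1),
               tolerance = 1e-12)
  expect_equal(out2$v, 0.1 * c(0.1, 0.05) / sqrt(0.1^2 + 0.05^2),
               tolerance = 1e-12)
  # raw update mode adds the full delta * direction
  out3 <- apply_action(a, c(0, 1), delta = 0.05, renorm = FALSE)
  expect_equal(out3$v, c(0.1, 0.05))
  # wrapping after the move
  b <- agent_state(2, c(4.99, 2.5), c(0.05, 0))
  expect_equal(apply_action(b, c(1, 0), 0.05, width = 5, height = 5)$l,
               c(0.04, 2.5))
  # from rest the agent accelerates to speed delta
  z <- agent_state(3, c(0, 0), c(0, 0), heading = c(1, 0))
  outz <- apply_action(z, c(0, 1), 0.05)
  expect_equal(outz$v, c(0, 0.05))
})

test_that("collision detection applies the body-size threshold on the torus", {
  mk <- function(l1, l2) {
    s <- make_test_swarm(rbind(l1, l2), rbind(c(0.1, 0), c(0.1, 0)))
    detect_collisions(s)
  }
  expect_equal(nrow(mk(c(1, 1), c(1.05, 1))), 1) # 0.05 <= 0.07
  expect_equal(nrow(mk(c(1, 1), c(1.071, 1))), 0)
  expect_equal(nrow(mk(c(0.02, 1), c(4.96, 1))), 1) # wrap distance 0.06
})

test_that("collision roles follow the front-half-plane rule", {
  leader <- agent_state(1, c(0.05, 0), c(0.1, 0))
  follower <- agent_state(2, c(0, 0), c(0.2, 0))
  expect_equal(classify_roles(follower, leader), c("active", "passive"))
  # frontal: both active
  a <- agent_state(1, c(0, 0), c(0.1, 0))
  b <- agent_state(2, c(0.05, 0), c(-0.1, 0))
  expect_equal(classify_roles(a, b), c("active", "active"))
  # perpendicular T-bone: only the agent facing the other is active
  tb <- agent_state(3, c(-0.02, -0.03), c(0, 0.1))
  expect_equal(classify_roles(tb, a), c("active", "passive"))
  # mutual rear contact degenerates to both active
  r1 <- agent_state(1, c(0, 0), c(-0.1, 0))
  r2 <- agent_state(2, c(0.05, 0), c(0.1, 0))
  expect_equal(classify_roles(r1, r2), c("active", "active"))
})

test_that("collision resolution stops active agents and transfers velocity", {
  s <- make_test_swarm(rbind(c(1, 1), c(1.05, 1)),
                       rbind(c(0.2, 0), c(0.1, 0)))
  ev <- detect_collisions(s)
  out <- resolve_collisions(s, ev)
  expect_equal(out$swarm$v[1, ], c(0, 0))         # rammer stopped
  expect_equal(out$swarm$v[2, ], c(0.3, 0))       # leader gains its velocity
  expect_equal(out$log$role_i, "active")
  expect_equal(out$log$role_j, "passive")
  # frontal: both stopped
  s2 <- make_test_swarm(rbind(c(1, 1), c(1.05, 1)),
                        rbind(c(0.1, 0), c(-0.1, 0)))
  out2 <- resolve_collisions(s2, detect_collisions(s2))
  expect_true(all(out2$swarm$v == 0))
  # simultaneous chain resolved deterministically in ascending pair order
  s3 <- make_test_swarm(rbind(c(1, 1), c(1.05, 1), c(1.1, 1)),
                        rbind(c(0.2, 0), c(0.1, 0), c(0.05, 0)))
  ev3 <- detect_collisions(s3)
  expect_equal(nrow(ev3), 2)
  out3a <- resolve_collisions(s3, ev3)
  out3b <- resolve_collisions(s3, ev3)
  expect_identical(out3a$swarm$v, out3b$swarm$v)
  expect_equal(out3a$swarm$v[1, ], c(0, 0))
  # middle agent was active against 3 after being passive against 1
  expect_equal(out3a$swarm$v[2, ], c(0, 0))
  expect_equal(out3a$swarm$v[3, ], c(0.05 + 0.1, 0))
})

test_that("far-apart agents under a straight policy move ballistically", {
  cfg2 <- flock_config(n_agents = 2)
  straight <- structure(list(name = "straight", needs_state = FALSE,
                             n_actions = cfg2$n_actions,
                             select = function(state) 0L),
                        class = "flock_policy")
  set.seed(1)
  sw <- make_swarm(cfg2)
  sw$l <- rbind(c(1, 1), c(4, 4))
  sw$v <- rbind(c(0.1, 0), c(0.1, 0))
  sw$heading <- rbind(c(1, 0), c(1, 0))
  st <- sim_state(sw)
  for (i in 1:10) st <- step_world(st, straight, cfg2)
  expect_equal(st$swarm$l[1, ], c(2, 1), tolerance = 1e-9)
  # agent 2 ends on the seam x = 5 == 0 (wrapped); compare on the torus
  expect_lt(sqrt(sum(torus_delta(st$swarm$l[2, ], c(0, 4), 5, 5)^2)), 1e-9)
  expect_equal(st$C_t, rep(0, 10))
})

test_that("runs are bit-reproducible under a fixed seed", {
  pol <- random_walk_policy(cfg$n_actions)
  short <- flock_config(steps = 60)
  s1 <- simulate_swarm(short, pol, seed = 99)
  s2 <- simulate_swarm(short, pol, seed = 99)
  expect_identical(s1$swarm$l, s2$swarm$l)
  expect_identical(s1$scores, s2$scores)
  s3 <- simulate_swarm(short, pol, seed = 100)
  expect_false(identical(s1$swarm$l, s3$swarm$l))
})

test_that("neighbour counts match the density expectation", {
  # pi r^2 (|P|-1) / (W H) = pi * 0.21^2 * 29 / 25 ~ 0.16 expected
  # neighbours per agent; small but nonzero
  pol <- random_walk_policy(cfg$n_actions)
  set.seed(2)
  counts <- c()
  sw <- make_swarm(cfg)
  st <- sim_state(sw)
  for (i in 1:40) {
    st <- step_world(st, pol, cfg)
    pd <- visflock:::.pair_distances(st$swarm)
    diag(pd) <- Inf
    counts <- c(counts, rowSums(pd < cfg$radius))
  }
  expect_gt(mean(counts), 0.08)
  expect_lt(mean(counts), 0.5)
})
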