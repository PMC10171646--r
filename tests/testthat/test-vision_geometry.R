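cfg <- flock_config()

test_that("body corners form the heading-aligned rectangle", {
  a <- agent_state(1, c(0, 0), c(1, 0), h = 0.07, w = 0.01)
  got <- corner_positions(a)
  expect_setequal(apply(got, 1, paste, collapse = "/"),
                  apply(expand.grid(c(-0.035, 0.035), c(-0.005, 0.005)),
                        1, paste, collapse = "/"))
  b <- agent_state(2, c(1, 1), c(0, 2), h = 0.2, w = 0.1)
  gb <- corner_positions(b)
  expect_setequal(round(gb[, 1], 10), round(c(0.95, 1.05, 0.95, 1.05), 10))
  expect_true(all(abs(sort(gb[, 2]) - c(0.9, 0.9, 1.1, 1.1)) < 1e-12))
  # centroid equals the centre for any heading
  set.seed(4)
  for (i in 1:20) {
    p <- random_agent(i)
    expect_equal(colMeans(corner_positions(p)), p$l, tolerance = 1e-12)
  }
  # zero-velocity agent falls back to its stored heading
  z <- agent_state(3, c(0, 0), c(0, 0), heading = c(0, 1), h = 0.2, w = 0.1)
  expect_equal(sort(corner_positions(z)[, 2]), c(-0.1, -0.1, 0.1, 0.1))
})

test_that("subtended angle matches geometry and the sampling oracle", {
  f <- agent_state(0, c(0, 0), c(1, 0))
  sq <- agent_state(1, c(1, 0), c(1, 0), h = 0.1, w = 0.1)
  expect_equal(subtended_angle(f, sq), 2 * atan(0.05 / 0.95),
               tolerance = 1e-6)
  # shrinking body -> angle to 0; doubling distance ~ halves a small angle
  tiny <- agent_state(1, c(1, 0), c(1, 0), h = 1e-6, w = 1e-6)
  expect_lt(subtended_angle(f, tiny), 1e-5)
  far1 <- agent_state(1, c(5, 0), c(0, 1), h = 0.07, w = 0.01)
  far2 <- agent_state(1, c(10, 0), c(0, 1), h = 0.07, w = 0.01)
  expect_equal(subtended_angle(f, far1) / subtended_angle(f, far2), 2,
               tolerance = 0.01)
  # 200 random configurations against the dense boundary-sampling oracle
  set.seed(42)
  for (i in 1:200) {
    nb <- agent_state(1, stats::runif(2, -1, 1), stats::runif(2, -1, 1),
                      h = stats::runif(1, 0.02, 0.3),
                      w = stats::runif(1, 0.02, 0.3))
    if (sqrt(sum(nb$l^2)) < max(nb$h, nb$w)) next # skip near-overlap
    got <- subtended_angle(f, nb)
    expect_equal(got, oracle_subtended(c(0, 0), nb, n_pts = 10000),
                 tolerance = 1e-3)
    expect_gte(got, 0); expect_lte(got, pi)
  }
  # focal centre inside the neighbour body -> full occupancy, with warning
  inside <- agent_state(1, c(0.01, 0), c(1, 0), h = 0.1, w = 0.1)
  expect_warning(psi <- subtended_angle(f, inside), "inside")
  expect_equal(psi, pi)
})

test_that("angular position is the unsigned bearing off the heading", {
  f <- agent_state(0, c(0, 0), c(0.1, 0))
  mk <- function(l) agent_state(1, l, c(0, 0.1))
  expect_equal(angular_position(f, mk(c(2, 0))), 0)
  expect_equal(angular_position(f, mk(c(0, 1))), pi / 2)
  expect_equal(angular_position(f, mk(c(-3, 0))), pi)
  expect_equal(angular_position(f, mk(c(0, -1))), pi / 2) # unsigned
  expect_equal(angular_position(f, mk(c(0, -1)), signed = TRUE), -pi / 2)
  expect_error(angular_position(f, mk(c(0, 0))), "degenerate")
})

test_that("vision quantities are invariant to translation and rotation", {
  set.seed(9)
  for (i in 1:25) {
    f <- random_agent(0)
    nb <- random_agent(1)
    if (sqrt(sum((nb$l - f$l)^2)) < 0.3) next
    psi0 <- subtended_angle(f, nb); th0 <- angular_position(f, nb)
    shift <- stats::runif(2, -10, 10)
    phi <- stats::runif(1, 0, 2 * pi)
    R <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2)
    tf <- function(p, about) {
      p$l <- as.numeric(R %*% (p$l - about)) + about + shift
      p$v <- as.numeric(R %*% p$v)
      p$heading <- as.numeric(R %*% p$heading)
      p
    }
    expect_equal(subtended_angle(tf(f, f$l), tf(nb, f$l)), psi0,
                 tolerance = 1e-10)
    expect_equal(angular_position(tf(f, f$l), tf(nb, f$l)), th0,
                 tolerance = 1e-10)
  }
})

test_that("local environment uses strict wrapped distances", {
  f <- agent_state(0, c(0.1, 0.1), c(0.1, 0), r = 0.21)
  near_wrap <- agent_state(1, c(4.95, 0.1), c(0.1, 0))
  expect_length(local_environment(f, list(near_wrap), 5, 5), 1)
  at_r <- agent_state(2, c(0.1 + 0.21, 0.1), c(0.1, 0))
  expect_length(local_environment(f, list(at_r), 5, 5), 0) # strict <
  expect_length(local_environment(f, list(), 5, 5), 0)
})

test_that("occlusion removes only fully hidden neighbours", {
  f <- agent_state(0, c(0, 0), c(1, 0))
  near_wide <- agent_state(1, c(0.5, 0), c(0, 1), h = 0.2, w = 0.05)
  far_narrow <- agent_state(2, c(1, 0), c(0, 1), h = 0.05, w = 0.02)
  kept <- occlusion_filter(f, list(near_wide, far_narrow))
  expect_equal(vapply(kept, `[[`, integer(1), "id"), 1L)
  # disjoint bearings: both kept
  side <- agent_state(3, c(0, 0.8), c(1, 0))
  kept2 <- occlusion_filter(f, list(near_wide, side))
  expect_length(kept2, 2)
  # input-order invariance
  kept3 <- occlusion_filter(f, list(far_narrow, near_wide))
  expect_setequal(vapply(kept3, `[[`, integer(1), "id"),
                  vapply(kept, `[[`, integer(1), "id"))
})

test_that("occlusion agrees with a ray-casting oracle", {
  set.seed(17)
  for (rep in 1:12) {
    f <- agent_state(0, c(0, 0), c(1, 0))
    m <- sample(2:5, 1)
    nbs <- lapply(seq_len(m), function(i) {
      ang <- stats::runif(1, 0, 2 * pi)
      d <- stats::runif(1, 0.3, 1.5)
      agent_state(i, d * c(cos(ang), sin(ang)), stats::runif(2, -0.1, 0.1),
                  h = stats::runif(1, 0.1, 0.5), w = stats::runif(1, 0.05, 0.3))
    })
    kept_ids <- vapply(occlusion_filter(f, nbs), `[[`, integer(1), "id")
    seen <- which(oracle_visible(f, nbs))
    # the implementation may keep a neighbour the discrete rays miss, but
    # must never drop one the oracle can see
    expect_true(all(seen %in% kept_ids))
    dropped <- setdiff(seq_len(m), kept_ids)
    expect_true(all(!(dropped %in% seen)))
  }
})

test_that("observation derivatives are backward differences by id", {
  f <- agent_state(0, c(0, 0), c(0.1, 0))
  nb <- agent_state(7, c(0.15, 0.02), c(-0.05, 0))
  o1 <- observe(f, list(nb))
  expect_equal(o1[[1]]$psi_dot, 0) # first sighting
  expect_equal(o1[[1]]$theta_dot, 0)
  nb2 <- nb; nb2$l <- nb$l + nb$v
  o2 <- observe(f, list(nb2), previous = o1)
  expect_equal(o2[[1]]$psi_dot, o2[[1]]$psi - o1[[1]]$psi)
  expect_equal(o2[[1]]$theta_dot, o2[[1]]$theta - o1[[1]]$theta)
  expect_gt(o2[[1]]$psi_dot, 0) # looming as it approaches head-on
  # static scene: zero derivatives
  o3 <- observe(f, list(nb), previous = o1)
  expect_equal(o3[[1]]$psi_dot, 0)
  expect_equal(o3[[1]]$theta_dot, 0)
})

test_that("state encoding floors, fills sentinels, and is pure", {
  obs <- list(list(id = 1L, psi = 0.1049, psi_dot = 0, theta = 0.02,
                   theta_dot = -0.005, dist = 0.1))
  enc <- encode_state(obs, k = 8, bin_width = 0.01)
  expect_length(enc, 32)
  expect_equal(enc[1], 10L)          # floor(0.1049 / 0.01)
  expect_equal(enc[4], -1L)          # floor(-0.005 / 0.01)
  expect_true(all(enc[5:32] == visflock:::SENTINEL_BIN))
  expect_identical(state_key(enc),
                   state_key(encode_state(obs, 8, 0.01)))
  alone <- encode_state(list(), 8, 0.01)
  expect_true(all(alone == visflock:::SENTINEL_BIN))
  # sentinel can never collide with a real bin
  expect_gt(visflock:::SENTINEL_BIN, floor(pi / 0.01))
  # sorting by angular position, ties by distance
  o2 <- list(list(id = 2L, psi = 0.2, psi_dot = 0, theta = 0.5,
                  theta_dot = 0, dist = 0.1),
             list(id = 1L, psi = 0.3, psi_dot = 0, theta = 0.1,
                  theta_dot = 0, dist = 0.2))
  e2 <- encode_state(o2, 2, 0.01)
  expect_equal(e2[1], 30L) # the theta = 0.1 neighbour fills slot 1
  # truncation keeps the first k in sort order
  e3 <- encode_state(o2, 1, 0.01)
  expect_length(e3, 4)
  expect_equal(e3[1], 30L)
})

test_that("compiled scenario encoder matches the R reference pipeline", {
  set.seed(23)
  for (i in 1:200) {
    sc <- generate_scenario(cfg)
    expect_identical(state_key(encode_scenario(sc, cfg, engine = "cpp")),
                     state_key(encode_scenario(sc, cfg, engine = "R")))
  }
})
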