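# The three-phase evolution-learning loop: GA-driven training of the
# Q-table on random local scenarios, KNN/TVD validation that redirects
# scenario sampling, and full-population testing.

#' Generate a random training scenario
#'
#' A local patch: a focal agent at the origin and `0..k` neighbours placed
#' uniformly in the disc of its sensing radius, every velocity component
#' drawn as `U[0, v_init_max]` with an independent random sign. When a
#' sampling bias is supplied, candidate scenarios are rejection-sampled so
#' that their state descriptors follow the biased distribution.
#'
#' @param config a [flock_config()].
#' @param bias optional `sampling_distribution` from [validate_phase()].
#' @param max_tries rejection-sampling cap per accepted scenario.
#' @return a list of class `"scenario"` with `focal` and `neighbors`
#'   (`agent_state`s, ids 0 and `1..m`).
#' @export
generate_scenario <- function(config, bias = NULL, max_tries = 50L) {
  draw <- function() {
    m <- sample.int(config$k_max + 1L, 1L) - 1L
    rand_v <- function() stats::runif(2, 0, config$v_init_max) *
      sample(c(-1, 1), 2, replace = TRUE)
    focal <- agent_state(0L, c(0, 0), rand_v(), h = config$body_h,
                         w = config$body_w, r = config$radius)
    neighbors <- lapply(seq_len(m), function(i) {
      repeat {
        rad <- config$radius * sqrt(stats::runif(1))
        ang <- stats::runif(1, 0, 2 * pi)
        l <- rad * c(cos(ang), sin(ang))
        if (sum(l^2) > 1e-12) break
      }
      agent_state(i, l, rand_v(), h = config$body_h, w = config$body_w,
                  r = config$radius)
    })
    structure(list(focal = focal, neighbors = neighbors),
              class = "scenario")
  }
  if (is.null(bias)) return(draw())
  wmax <- attr(bias, "max_weight")
  for (try in seq_len(max_tries)) {
    sc <- draw()
    w <- .bias_weight(bias, scenario_descriptor(sc, config))
    if (stats::runif(1) * wmax <= w) return(sc)
  }
  sc
}

#' Encode the Q-state of a scenario
#'
#' Computes the focal agent's observation of the occlusion-filtered patch
#' and discretises it. The derivative channels come from backward finite
#' differences against the scene rewound by one tick (`l - v`), so a
#' one-shot scenario still carries the velocity information that the
#' retinal derivatives encode.
#'
#' @param scenario a [generate_scenario()] result.
#' @param config a [flock_config()].
#' @param engine `"cpp"` (compiled fast path, the training default) or
#'   `"R"` (reference path through [observe()] and [encode_state()]); the
#'   two are cross-checked in the test suite and produce identical keys.
#' @return an `encoded_state`.
#' @export
encode_scenario <- function(scenario, config, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    enc <- .cpp_patch(scenario, config)
    return(structure(enc$bins, key = enc$key, class = "encoded_state"))
  }
  obs <- .scenario_observation(scenario, config)
  encode_state(obs, config$k_max, config$bin_width)
}

.cpp_patch <- function(scenario, config) {
  arr <- .scenario_arrays(scenario)
  cpp_encode_patch(arr$focal_l, arr$focal_v, arr$focal_heading,
                   arr$nb_l, arr$nb_v, arr$nb_heading,
                   arr$body_h, arr$body_w,
                   as.integer(config$k_max), config$bin_width)
}

.scenario_observation <- function(scenario, config) {
  focal <- scenario$focal
  visible <- occlusion_filter(focal, scenario$neighbors)
  # bodies may overlap at t = 0; the full-occupancy warning of
  # subtended_angle is routine here, not actionable
  suppressWarnings({
    if (length(visible)) {
      back <- function(p) { p$l <- p$l - p$v; p }
      prev <- observe(back(focal), lapply(visible, back),
                      signed_theta = isTRUE(config$signed_theta))
    } else prev <- NULL
    observe(focal, visible, previous = prev,
            signed_theta = isTRUE(config$signed_theta))
  })
}

#' State descriptor used by validation and biased sampling
#'
#' A coarse projection of the encoded state: the neighbour count and the
#' binned subtended angle and angular position of the nearest visible
#' neighbour (zeros when the focal agent is alone). The full discretised
#' state space is astronomically large; validation estimates performance,
#' and redirects sampling, over this occupied low-dimensional projection.
#'
#' @param scenario a scenario.
#' @param config a [flock_config()].
#' @param engine `"cpp"` or `"R"`, as in [encode_scenario()].
#' @return integer vector `(n, psi_bin, theta_bin)`.
#' @export
scenario_descriptor <- function(scenario, config, engine = c("cpp", "R")) {
  engine <- match.arg(engine)
  if (engine == "cpp") {
    enc <- .cpp_patch(scenario, config)
    return(c(n = enc$n_visible, psi_bin = enc$psi_bin,
             theta_bin = enc$theta_bin))
  }
  obs <- .scenario_observation(scenario, config)
  if (!length(obs)) return(c(n = 0L, psi_bin = 0L, theta_bin = 0L))
  ds <- vapply(obs, `[[`, numeric(1), "dist")
  o <- obs[[which.min(ds)]]
  c(n = length(obs),
    psi_bin = as.integer(floor(o$psi / config$bin_width)),
    theta_bin = as.integer(floor(o$theta / config$bin_width)))
}

.bias_weight <- function(bias, desc) {
  key <- paste(desc, collapse = ",")
  w <- attr(bias, "lookup")[[key]]
  if (!is.null(w)) return(w)
  # cell not in the probe support: smooth to the neighbour-count marginal;
  # a count absent from the support has weight 0 (a point-mass bias must
  # concentrate sampling)
  wn <- attr(bias, "by_count")[[as.character(desc[1])]]
  if (!is.null(wn)) return(wn)
  0
}

#' Training phase
#'
#' Repeats `n` times: draw a scenario (optionally biased), encode its
#' state, plan the focal action with the GA, and add the planning score to
#' the Q-table at (state, first action).
#'
#' @param q a [q_table()] (mutated in place).
#' @param config a [flock_config()].
#' @param bias optional `sampling_distribution`.
#' @param n number of training samples (default `config$z_train`).
#' @return invisibly, a list with the table, the mean planning score and
#'   the number of samples.
#' @export
train_phase <- function(q, config, bias = NULL, n = config$z_train) {
  n <- as.integer(n)
  score_acc <- 0
  for (i in seq_len(n)) {
    sc <- generate_scenario(config, bias)
    enc <- encode_scenario(sc, config)
    pl <- plan_action(sc, config, engine = "cpp")
    q_update(q, enc, pl$action, pl$score)
    score_acc <- score_acc + pl$score
  }
  invisible(list(q = q, mean_score = if (n) score_acc / n else NA_real_,
                 n = n))
}

# One eta-step patch rollout in which every agent follows the Q-policy
# (or, when focal_gene is given, the focal agent executes that action
# sequence while the neighbours follow the policy). Collisions are
# counted, not resolved; the patch is unbounded.
.policy_rollout_objective <- function(scenario, q, config,
                                      focal_gene = NULL) {
  agents <- c(list(scenario$focal), scenario$neighbors)
  m <- length(agents)
  back <- function(p) { p$l <- p$l - p$v; p }
  prev <- suppressWarnings(lapply(seq_len(m), function(i) {
    vis <- local_environment(back(agents[[i]]),
                             lapply(agents[-i], back))
    observe(back(agents[[i]]), vis,
            signed_theta = isTRUE(config$signed_theta))
  }))
  dirs <- action_set(config$n_actions)
  patch_F <- function() {
    cm_metric(vapply(agents, function(p) atan2(.heading_of(p)[2],
                                               .heading_of(p)[1]),
                     numeric(1)))
  }
  patch_C <- function() {
    if (m < 2) return(0)
    pairs <- 0L
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      thr <- max(agents[[i]]$h + agents[[j]]$h,
                 agents[[i]]$w + agents[[j]]$w) / 2
      if (sqrt(sum((agents[[i]]$l - agents[[j]]$l)^2)) <= thr)
        pairs <- pairs + 1L
    }
    min(1, pairs / (m %/% 2))
  }
  F_t <- patch_F(); C_t <- patch_C()
  for (t in seq_len(config$eta)) {
    acts <- integer(m)
    for (i in seq_len(m)) {
      vis <- local_environment(agents[[i]], agents[-i])
      vis <- occlusion_filter(agents[[i]], vis)
      obs <- suppressWarnings(
        observe(agents[[i]], vis, previous = prev[[i]],
                signed_theta = isTRUE(config$signed_theta)))
      enc <- encode_state(obs, config$k_max, config$bin_width)
      acts[i] <- if (i == 1L && !is.null(focal_gene)) focal_gene[t]
                 else select_action(q, enc)
      prev[[i]] <- obs
    }
    agents <- lapply(seq_len(m), function(i)
      apply_action(agents[[i]], acts[i], config$delta,
                   n_actions = config$n_actions,
                   renorm = isTRUE(config$speed_renorm)))
    F_t <- c(F_t, patch_F()); C_t <- c(C_t, patch_C())
  }
  local_objective(F_t, C_t, config$zeta)
}

#' Total variation distance
#'
#' @param p,q probability vectors of equal length (renormalised
#'   defensively).
#' @return `0.5 * sum(|p - q|)`, in `[0, 1]`.
#' @export
tvd <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p / sum(p) - q / sum(q)))
}

# Inverse-distance-weighted KNN regression on normalised descriptors.
.knn_estimate <- function(train_x, train_y, probe_x, y) {
  scale <- apply(rbind(train_x, probe_x), 2, function(col) {
    r <- diff(range(col))
    if (r > 0) r else 1
  })
  tr <- sweep(train_x, 2, scale, "/")
  pr <- sweep(probe_x, 2, scale, "/")
  y <- min(y, nrow(tr))
  est <- numeric(nrow(pr))
  block <- 2000L
  for (b0 in seq(1L, nrow(pr), by = block)) {
    b1 <- min(b0 + block - 1L, nrow(pr))
    d2 <- outer(rowSums(pr[b0:b1, , drop = FALSE]^2), rowSums(tr^2), "+") -
      2 * pr[b0:b1, , drop = FALSE] %*% t(tr)
    d2[d2 < 0] <- 0
    for (rix in seq_len(b1 - b0 + 1L)) {
      dd <- sqrt(d2[rix, ])
      nn <- order(dd)[seq_len(y)]
      dnn <- dd[nn]
      if (dnn[1] == 0) {
        est[b0 + rix - 1L] <- mean(train_y[nn[dnn == 0]])
      } else {
        w <- 1 / dnn
        est[b0 + rix - 1L] <- sum(w * train_y[nn]) / sum(w)
      }
    }
  }
  est
}

#' Validation phase
#'
#' Rolls out `n` random scenarios for `eta` steps with every agent
#' following the Q-policy and scores each by the complement of the local
#' objective. A uniform set of probe descriptors then gets KNN-estimated
#' performance (inverse-distance weights, `knn_y` neighbours, Euclidean
#' metric on range-normalised descriptor coordinates). Deficiency weights
#' `1 - estimated performance`, L1-normalised over the probes, form the
#' sampling distribution for the next training round; training stops when
#' its total variation distance from uniform is at most `kappa`.
#'
#' @param q a [q_table()].
#' @param config a [flock_config()].
#' @param n number of validation scenarios (default `config$z_validate`).
#' @param probes number of uniform probe descriptors.
#' @return a list: `mean_performance`, `distribution` (a
#'   `sampling_distribution` data.frame over descriptors), `tvd`, `stop`,
#'   and the per-scenario `samples` data.frame.
#' @export
validate_phase <- function(q, config, n = config$z_validate,
                           probes = config$probes) {
  n <- as.integer(n)
  perf <- numeric(n)
  desc <- matrix(0L, n, 3,
                 dimnames = list(NULL, c("n", "psi_bin", "theta_bin")))
  for (i in seq_len(n)) {
    sc <- generate_scenario(config)
    desc[i, ] <- scenario_descriptor(sc, config)
    perf[i] <- .clip01(1 - .policy_rollout_objective(sc, q, config))
  }
  max_bin <- as.integer(floor(pi / config$bin_width))
  pn <- sample.int(config$k_max + 1L, probes, replace = TRUE) - 1L
  ppsi <- ifelse(pn > 0, sample.int(max_bin + 1L, probes, replace = TRUE) - 1L,
                 0L)
  pth <- ifelse(pn > 0, sample.int(max_bin + 1L, probes, replace = TRUE) - 1L,
                0L)
  probe_x <- cbind(n = pn, psi_bin = ppsi, theta_bin = pth)
  est <- .knn_estimate(desc, perf, probe_x, config$knn_y)
  defic <- pmax(0, 1 - est)
  p <- if (sum(defic) > 0) defic / sum(defic) else rep(1 / probes, probes)
  tv <- tvd(p, rep(1 / probes, probes))
  dist <- data.frame(probe_x, weight = p)
  agg <- stats::aggregate(weight ~ n + psi_bin + theta_bin, dist, sum)
  lookup <- new.env(parent = emptyenv())
  for (r in seq_len(nrow(agg)))
    lookup[[paste(agg$n[r], agg$psi_bin[r], agg$theta_bin[r], sep = ",")]] <-
      agg$weight[r]
  by_count <- new.env(parent = emptyenv())
  for (nn in unique(agg$n))
    by_count[[as.character(nn)]] <- mean(agg$weight[agg$n == nn])
  out_dist <- structure(agg, class = c("sampling_distribution", "data.frame"),
                        lookup = lookup, by_count = by_count,
                        mean_weight = mean(agg$weight),
                        max_weight = max(agg$weight))
  list(mean_performance = mean(perf), distribution = out_dist, tvd = tv,
       stop = tv <= config$kappa,
       samples = data.frame(desc, performance = perf))
}

#' Testing phase
#'
#' Full-population simulations under a policy: `reps` independent runs of
#' `config$steps` ticks, each from a seed derived from `seed`, scored by
#' the combined alignment/collision objective.
#'
#' @param policy a [flock_policy] object, or a [q_table()] (wrapped as a
#'   stochastic policy).
#' @param config a [flock_config()].
#' @param reps number of replicate simulations.
#' @param seed master seed for the replicate substreams.
#' @return a list: `mean_cmca`, a `per_run` summary data.frame and the
#'   list of per-run score tables.
#' @export
test_phase <- function(policy, config, reps = 30, seed = 1L) {
  if (inherits(policy, "q_table")) policy <- q_policy(policy)
  runs <- vector("list", reps)
  per_run <- data.frame(run = seq_len(reps), cm_mean = NA_real_,
                        ca_mean = NA_real_, cmca_mean = NA_real_,
                        cm_final = NA_real_, ca_final = NA_real_)
  for (rep in seq_len(reps)) {
    sim <- simulate_swarm(config, policy,
                          seed = derive_seed(seed, "test-run", rep))
    sc <- sim$scores
    runs[[rep]] <- sc
    per_run$cm_mean[rep] <- mean(sc$cm_score)
    per_run$ca_mean[rep] <- mean(sc$ca_score)
    per_run$cmca_mean[rep] <- mean(sc$cmca_score)
    per_run$cm_final[rep] <- sc$cm_score[nrow(sc)]
    per_run$ca_final[rep] <- sc$ca_score[nrow(sc)]
  }
  list(mean_cmca = mean(per_run$cmca_mean), per_run = per_run, scores = runs)
}

#' Logarithmic learning-curve fit
#'
#' Least-squares fit of `performance = a * ln(samples) + b`.
#'
#' @param samples cumulative sample counts (> 0).
#' @param performance matching performance values.
#' @return a list with `a` (slope), `b` (intercept) and `r_squared`.
#' @export
fit_log_curve <- function(samples, performance) {
  stopifnot(length(samples) == length(performance), all(samples > 0))
  fit <- stats::lm(performance ~ log(samples))
  co <- stats::coef(fit)
  ss_res <- sum(stats::resid(fit)^2)
  ss_tot <- sum((performance - mean(performance))^2)
  list(a = unname(co[2]), b = unname(co[1]),
       r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else 1)
}

#' Train, validate and test the policy
#'
#' Alternates training (`z_train` scenarios per round) and validation
#' until the TVD stop criterion is met or `max_rounds` rounds have run,
#' then optionally tests the learned policy on full-population
#' simulations. The learning curve collects the validation mean
#' performance against cumulative training samples, with its logarithmic
#' least-squares fit.
#'
#' @param config a [flock_config()].
#' @param seed master seed.
#' @param test_reps replicate count of the final testing phase; 0 skips
#'   testing.
#' @param verbose print one line per round?
#' @return a list: the trained `q` table, `learning_curve` data.frame
#'   (`samples`, `performance`, `tvd`), `fit` from [fit_log_curve()],
#'   `rounds` used, and `test` (when run).
#' @export
fit_policy <- function(config, seed = 1L, test_reps = 0L, verbose = FALSE) {
  q <- q_table(config)
  bias <- NULL
  curve <- data.frame(samples = numeric(0), performance = numeric(0),
                      tvd = numeric(0))
  set.seed(derive_seed(seed, "policy-train"))
  total <- 0
  for (round in seq_len(config$max_rounds)) {
    train_phase(q, config, bias = bias, n = config$z_train)
    total <- total + config$z_train
    val <- validate_phase(q, config, n = config$z_validate)
    curve <- rbind(curve, data.frame(samples = total,
                                     performance = val$mean_performance,
                                     tvd = val$tvd))
    if (verbose)
      message(sprintf("round %d: %g samples, perf %.3f, tvd %.3f%s",
                      round, total, val$mean_performance, val$tvd,
                      if (val$stop) " (stop)" else ""))
    bias <- val$distribution
    if (val$stop) break
  }
  fit <- if (nrow(curve) >= 2)
    fit_log_curve(curve$samples, curve$performance) else NULL
  out <- list(q = q, learning_curve = curve, fit = fit, rounds = round)
  if (test_reps > 0)
    out$test <- test_phase(q_policy(q), config, reps = test_reps,
                           seed = derive_seed(seed, "policy-test"))
  out
}
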