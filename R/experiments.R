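# Experiment suite: baseline comparisons, parameter sensitivity sweeps and
# tree-ensemble surrogate analysis of a learned policy.

#' Compare policies on full-population simulations
#'
#' Runs each named policy for `reps` replicate simulations and summarises
#' the alignment, collision and combined scores as mean +/- sd, both over
#' all ticks and per tick (for score-vs-time curves). All policies share
#' the same derived replicate seeds, so comparisons are paired.
#'
#' @param policies a named list of [flock_policy] objects (e.g.
#'   `list(random = random_walk_policy())`).
#' @param config a [flock_config()].
#' @param reps replicates per policy.
#' @param seed master seed.
#' @return a list: `summary` data.frame (one row per policy x metric with
#'   `mean` and `sd` over runs of the per-run time means) and `curves`
#'   (per-tick mean and sd of each score, per policy).
#' @export
run_baseline_comparison <- function(policies, config, reps = 30, seed = 1L) {
  stopifnot(length(policies) >= 1, !is.null(names(policies)))
  summary <- NULL
  curves <- NULL
  for (nm in names(policies)) {
    res <- test_phase(policies[[nm]], config, reps = reps, seed = seed)
    pr <- res$per_run
    summary <- rbind(summary, data.frame(
      policy = nm,
      metric = c("cm", "ca", "cmca"),
      mean = c(mean(pr$cm_mean), mean(pr$ca_mean), mean(pr$cmca_mean)),
      sd = c(stats::sd(pr$cm_mean), stats::sd(pr$ca_mean),
             stats::sd(pr$cmca_mean))))
    arr <- simplify2array(lapply(res$scores, function(s)
      as.matrix(s[, c("cm_score", "ca_score", "cmca_score")])))
    mu <- apply(arr, c(1, 2), mean)
    sdv <- apply(arr, c(1, 2), stats::sd)
    curves <- rbind(curves, data.frame(
      policy = nm, t = rep(seq_len(nrow(mu)), 3),
      metric = rep(c("cm", "ca", "cmca"), each = nrow(mu)),
      mean = c(mu[, 1], mu[, 2], mu[, 3]),
      sd = c(sdv[, 1], sdv[, 2], sdv[, 3])))
  }
  list(summary = summary, curves = curves)
}

#' Parameter sensitivity sweep
#'
#' Evaluates one trained (or baseline) policy across a grid of a single
#' swept parameter, without retraining: `population_size` varies
#' `n_agents`, `aspect_ratio` holds the body length at `body_h` and sets
#' the width to `body_h / value`, and `sensing_radius` varies `radius`.
#' The population density `|P| / (W * H)` is reported alongside.
#'
#' @param param one of `"population_size"`, `"aspect_ratio"`,
#'   `"sensing_radius"`.
#' @param values grid values.
#' @param policy a [flock_policy] object.
#' @param config the base [flock_config()].
#' @param reps replicates per grid value.
#' @param seed master seed.
#' @return a data.frame: `value`, `density`, `cmca_mean`, `cmca_sd`.
#' @export
run_sensitivity <- function(param = c("population_size", "aspect_ratio",
                                      "sensing_radius"),
                            values, policy, config, reps = 30, seed = 1L) {
  param <- match.arg(param)
  stopifnot(length(values) >= 1, reps >= 1)
  out <- data.frame(value = values, density = NA_real_,
                    cmca_mean = NA_real_, cmca_sd = NA_real_)
  for (i in seq_along(values)) {
    cfg <- config
    if (param == "population_size") cfg$n_agents <- values[i]
    else if (param == "aspect_ratio") cfg$body_w <- cfg$body_h / values[i]
    else cfg$radius <- values[i]
    validate_config(cfg)
    res <- test_phase(policy, cfg, reps = reps,
                      seed = derive_seed(seed, param, i))
    out$density[i] <- cfg$n_agents / (cfg$width * cfg$height)
    out$cmca_mean[i] <- mean(res$per_run$cmca_mean)
    out$cmca_sd[i] <- stats::sd(res$per_run$cmca_mean)
  }
  out
}

#' Plot score-versus-time curves
#'
#' Draws the per-tick mean of one score metric for each policy, with a
#' shaded one-standard-deviation band, from the `curves` table of
#' [run_baseline_comparison()].
#'
#' @param curves data.frame with `policy`, `t`, `metric`, `mean`, `sd`.
#' @param metric which score to draw (`"cm"`, `"ca"` or `"cmca"`).
#' @param main plot title.
#' @return invisibly, the subset of `curves` drawn.
#' @export
plot_score_curves <- function(curves, metric = c("cmca", "cm", "ca"),
                              main = NULL) {
  metric <- match.arg(metric)
  d <- curves[curves$metric == metric, , drop = FALSE]
  stopifnot(nrow(d) > 0)
  pols <- unique(d$policy)
  cols <- grDevices::hcl.colors(max(3, length(pols)), "Dark 3")
  graphics::plot(NULL, xlim = range(d$t), ylim = c(0, 1),
                 xlab = "simulation step", ylab = paste(metric, "score"),
                 main = if (is.null(main)) paste(toupper(metric),
                                                 "score over time") else main)
  for (i in seq_along(pols)) {
    di <- d[d$policy == pols[i], ]
    lo <- pmax(0, di$mean - di$sd); hi <- pmin(1, di$mean + di$sd)
    graphics::polygon(c(di$t, rev(di$t)), c(lo, rev(hi)), border = NA,
                      col = grDevices::adjustcolor(cols[i], alpha.f = 0.2))
    graphics::lines(di$t, di$mean, col = cols[i], lwd = 2)
  }
  graphics::legend("bottomright", legend = pols, col = cols[seq_along(pols)],
                   lwd = 2, bty = "n")
  invisible(d)
}

#' Build a surrogate dataset from a policy
#'
#' Draws `n_cases` random scenarios exactly as the training/testing
#' scenario generator does, encodes each state, and records the policy's
#' greedy action, giving a (state features, action label) classification
#' dataset for surrogate models.
#'
#' @param policy a [flock_policy] with `needs_state = TRUE`, or any policy
#'   (state-independent policies give a label distribution independent of
#'   the features).
#' @param config a [flock_config()].
#' @param n_cases number of rows.
#' @return a data.frame with `4 * k` integer feature columns (`slotJ_psi`,
#'   `slotJ_psi_dot`, `slotJ_theta`, `slotJ_theta_dot`) and an `action`
#'   factor label.
#' @export
build_surrogate_dataset <- function(policy, config, n_cases) {
  k <- config$k_max
  feats <- matrix(0L, n_cases, 4 * k)
  labs <- integer(n_cases)
  for (i in seq_len(n_cases)) {
    sc <- generate_scenario(config)
    enc <- encode_scenario(sc, config)
    feats[i, ] <- as.integer(enc)
    labs[i] <- policy$select(enc)
  }
  colnames(feats) <- paste0("slot", rep(seq_len(k), each = 4), "_",
                            c("psi", "psi_dot", "theta", "theta_dot"))
  df <- as.data.frame(feats)
  df$action <- factor(labs, levels = 0:(config$n_actions - 1))
  df
}

#' Surrogate accuracy against tree-size constraints
#'
#' Fits an ensemble of size-constrained decision trees to reproduce the
#' policy's action choices and reports the holdout fraction of matching
#' predictions per constraint value. Depth constraints use `ranger`
#' (`max.depth`); leaf-count constraints use `randomForest` (`maxnodes`).
#'
#' @param dataset from [build_surrogate_dataset()].
#' @param constraint `"max_depth"` or `"max_leaves"`.
#' @param values constraint values to sweep.
#' @param trees ensemble size.
#' @param holdout fraction of rows held out for accuracy estimation.
#' @param seed seed for the split and the forests.
#' @return a data.frame `value`, `accuracy`.
#' @export
surrogate_accuracy_curve <- function(dataset,
                                     constraint = c("max_depth",
                                                    "max_leaves"),
                                     values, trees = 1000, holdout = 0.2,
                                     seed = 1L) {
  constraint <- match.arg(constraint)
  set.seed(derive_seed(seed, "surrogate-split"))
  n <- nrow(dataset)
  test_idx <- sample.int(n, max(1L, round(holdout * n)))
  train <- dataset[-test_idx, , drop = FALSE]
  test <- dataset[test_idx, , drop = FALSE]
  train$action <- droplevels(train$action)
  acc <- numeric(length(values))
  if (nlevels(train$action) < 2) {
    # degenerate single-label policy: any tree reproduces it exactly
    only <- levels(train$action)[1]
    acc[] <- mean(as.character(test$action) == only)
    return(data.frame(value = values, accuracy = acc))
  }
  for (i in seq_along(values)) {
    if (constraint == "max_depth") {
      if (!requireNamespace("ranger", quietly = TRUE))
        stop("package `ranger` is required for depth-constrained surrogates")
      fit <- ranger::ranger(action ~ ., data = train, num.trees = trees,
                            max.depth = values[i],
                            seed = derive_seed(seed, "surrogate-fit", i))
      pred <- stats::predict(fit, data = test)$predictions
    } else {
      if (!requireNamespace("randomForest", quietly = TRUE))
        stop("package `randomForest` is required for leaf-constrained surrogates")
      set.seed(derive_seed(seed, "surrogate-fit", i))
      fit <- randomForest::randomForest(action ~ ., data = train,
                                        ntree = trees, maxnodes = values[i])
      pred <- stats::predict(fit, newdata = test)
    }
    acc[i] <- mean(as.character(pred) == as.character(test$action))
  }
  data.frame(value = values, accuracy = acc)
}
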