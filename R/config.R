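#' Simulation and learning configuration
#'
#' Builds the full parameter set of the model with its default values: a
#' 5 x 5 m toroidal arena holding 30 rectangular agents (body 0.07 x 0.01 m,
#' the rounded locust aspect ratio 7:1), metric sensing radius 0.21 m,
#' steering weight `delta` = 0.05, and the learning-side parameters of the
#' evolution-learning loop (state discretisation 0.01, 15-degree action
#' grid, GA population 20 over 10 generations with 5% elitism, planning
#' horizon `eta` = 5, KNN validation with `knn_y` = 3 and stop threshold
#' `kappa` = 0.05).
#'
#' @param width,height arena dimensions in metres; the boundary is always
#'   periodic (toroidal).
#' @param n_agents population size `|P|`.
#' @param v_init_max initial speed scale: each velocity component is drawn
#'   as `U[0, v_init_max]` with an independent random sign.
#' @param body_h,body_w agent body length (along the heading) and width, m.
#' @param delta action influence weight of Eq-style steering update,
#'   in (0, 1].
#' @param radius metric sensing radius, m.
#' @param zeta weight of the alignment objective against the
#'   collision objective, in `[0, 1]`.
#' @param steps ticks per full-world simulation (`T`).
#' @param k_max maximum number of neighbours encoded in a state (`k`).
#' @param bin_width state-space discretisation, radians (and radians/step
#'   for the derivative channels).
#' @param action_deg action-space discretisation in degrees; the action set
#'   holds `360 / action_deg` unit headings.
#' @param z_train,z_validate,z_test sample counts of the training,
#'   validation and testing phases. `z_train` counts scenarios per
#'   train-validate round.
#' @param kappa total-variation-distance stop threshold of validation.
#' @param mut_mean,mut_sd mean and sd of the Gaussian-distributed per-gene
#'   mutation probability (clipped to `[0, 1]`).
#' @param generations,ga_pop GA generations `g` and population size `tau`.
#' @param eta planning horizon: gene length, in ticks.
#' @param knn_y number of neighbours of the validation KNN regressor.
#' @param elite_frac elitism ("royalty") fraction `iota`.
#' @param learning_rate Q-table learning rate `lambda`. Not fixed by the
#'   model description; 0.1 is the usual tabular magnitude.
#' @param max_rounds cap on train/validate rounds so the loop terminates
#'   even when the TVD criterion is never met.
#' @param probes number of uniform probe points of the validation KNN pass.
#' @param signed_theta if `TRUE`, the angular position keeps its sign
#'   (left/right); the default `FALSE` matches the arccos definition, which
#'   is unsigned.
#' @param speed_renorm if `TRUE` (default) the velocity update only steers
#'   the heading: after adding `delta * a` the speed is rescaled to its
#'   pre-update magnitude. `FALSE` applies the raw additive update.
#'
#' @return A list of class `"flock_config"`; `n_actions` is derived as
#'   `360 / action_deg`.
#' @examples
#' cfg <- flock_config()
#' cfg$n_actions # 24
#' @export
flock_config <- function(width = 5, height = 5, n_agents = 30,
                         v_init_max = 0.15, body_h = 0.07, body_w = 0.01,
                         delta = 0.05, radius = 0.21, zeta = 0.5,
                         steps = 500, k_max = 8, bin_width = 0.01,
                         action_deg = 15,
                         z_train = 1e7, z_validate = 1e5, z_test = 450000,
                         kappa = 0.05, mut_mean = 0.1, mut_sd = 0.05,
                         generations = 10, ga_pop = 20, eta = 5,
                         knn_y = 3, elite_frac = 0.05,
                         learning_rate = 0.1, max_rounds = 10,
                         probes = 10000, signed_theta = FALSE,
                         speed_renorm = TRUE) {
  cfg <- list(width = width, height = height, n_agents = n_agents,
              v_init_max = v_init_max, body_h = body_h, body_w = body_w,
              delta = delta, radius = radius, zeta = zeta, steps = steps,
              k_max = k_max, bin_width = bin_width, action_deg = action_deg,
              z_train = z_train, z_validate = z_validate, z_test = z_test,
              kappa = kappa, mut_mean = mut_mean, mut_sd = mut_sd,
              generations = generations, ga_pop = ga_pop, eta = eta,
              knn_y = knn_y, elite_frac = elite_frac,
              learning_rate = learning_rate, max_rounds = max_rounds,
              probes = probes, signed_theta = signed_theta,
              speed_renorm = speed_renorm)
  cfg$n_actions <- as.integer(round(360 / action_deg))
  class(cfg) <- "flock_config"
  validate_config(cfg)
  cfg
}

#' Validate a configuration
#'
#' Checks every invariant of the parameter set and fails with a message
#' naming the offending field.
#'
#' @param cfg a `flock_config` list.
#' @return `cfg`, invisibly, if valid.
#' @export
validate_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!isTRUE(ok)) stop("invalid configuration: `", field, "` ", what,
                          call. = FALSE)
  }
  pos <- function(f) chk(is.numeric(cfg[[f]]) && length(cfg[[f]]) == 1 &&
                           cfg[[f]] > 0, f, "must be a positive number")
  for (f in c("width", "height", "n_agents", "v_init_max", "body_h",
              "body_w", "radius", "steps", "k_max", "bin_width",
              "action_deg", "z_train", "z_validate", "z_test", "generations",
              "ga_pop", "eta", "knn_y", "max_rounds", "probes")) pos(f)
  chk(cfg$delta > 0 && cfg$delta <= 1, "delta", "must be in (0, 1]")
  chk(cfg$zeta >= 0 && cfg$zeta <= 1, "zeta", "must be in [0, 1]")
  chk(cfg$kappa >= 0 && cfg$kappa <= 1, "kappa", "must be in [0, 1]")
  chk(cfg$elite_frac >= 0 && cfg$elite_frac <= 1, "elite_frac",
      "must be in [0, 1]")
  chk(cfg$learning_rate >= 0 && cfg$learning_rate <= 1, "learning_rate",
      "must be in [0, 1]")
  chk(cfg$mut_mean >= 0, "mut_mean", "must be nonnegative")
  chk(cfg$mut_sd >= 0, "mut_sd", "must be nonnegative")
  chk(cfg$ga_pop >= 2, "ga_pop", "must be at least 2")
  chk(cfg$eta >= 1, "eta", "must be at least 1")
  chk(360 %% cfg$action_deg == 0, "action_deg", "must divide 360")
  invisible(cfg)
}

#' Load a configuration from a YAML file
#'
#' Unknown keys are rejected; keys absent from the file keep their
#' defaults, so an empty file yields the default configuration.
#'
#' @param path YAML file path.
#' @return a validated `flock_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  known <- names(formals(flock_config))
  bad <- setdiff(names(raw), known)
  if (length(bad))
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "),
         "; known keys: ", paste(known, collapse = ", "))
  do.call(flock_config, raw)
}

#' @export
print.flock_config <- function(x, ...) {
  cat("<flock_config>\n")
  cat(sprintf("  arena %g x %g m (toroidal), %d agents, body %g x %g m\n",
              x$width, x$height, x$n_agents, x$body_h, x$body_w))
  cat(sprintf("  r = %g m, delta = %g, zeta = %g, T = %d steps\n",
              x$radius, x$delta, x$zeta, as.integer(x$steps)))
  cat(sprintf("  k = %d, bins %g rad, %d actions (%g deg)\n",
              as.integer(x$k_max), x$bin_width, x$n_actions, x$action_deg))
  cat(sprintf("  GA: tau = %d, g = %d, eta = %d, elites %g; lambda = %g\n",
              as.integer(x$ga_pop), as.integer(x$generations),
              as.integer(x$eta), x$elite_frac, x$learning_rate))
  invisible(x)
}

# Deterministic per-purpose seed derived from one master seed, so unrelated
# random substreams (scenarios, GA, world init, ...) never share draws.
#' Derive a named sub-seed from a master seed
#'
#' @param master integer master seed.
#' @param name character label of the substream.
#' @param index optional replicate index folded into the seed.
#' @return an integer in `[0, 2^31 - 2]` suitable for `set.seed()`.
#' @export
derive_seed <- function(master, name, index = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(master) * 48271 + h * 8191 + index * 257) %%
               2147483629)
}
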