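# Genetic-algorithm action planner: genes are eta-step action sequences
# scored by the local patch objective (lower is better).

#' GA parameter bundle
#'
#' @param tau population size.
#' @param generations number of generations.
#' @param elite_frac elitism fraction; the elite count is
#'   `max(1, floor(elite_frac * tau))`.
#' @param mut_mean,mut_sd mean/sd of the clipped-Gaussian per-gene mutation
#'   probability.
#' @param eta gene length (planning horizon, ticks).
#' @param n_actions action-set size.
#' @param cut_weights optional probability weights over crossover cut
#'   points `2..eta` (default uniform).
#' @return a list of class `"ga_config"`.
#' @export
ga_config <- function(tau = 20, generations = 10, elite_frac = 0.05,
                      mut_mean = 0.1, mut_sd = 0.05, eta = 5,
                      n_actions = 24, cut_weights = NULL) {
  stopifnot(tau >= 2, generations >= 1, elite_frac >= 0, elite_frac <= 1,
            mut_mean >= 0, mut_sd >= 0, eta >= 1)
  if (is.null(cut_weights)) cut_weights <- rep(1, max(1, eta - 1))
  structure(list(tau = as.integer(tau), generations = as.integer(generations),
                 elite_frac = elite_frac, mut_mean = mut_mean,
                 mut_sd = mut_sd, eta = as.integer(eta),
                 n_actions = as.integer(n_actions),
                 cut_weights = cut_weights),
            class = "ga_config")
}

#' @rdname ga_config
#' @param config a [flock_config()] to lift the GA parameters from.
#' @export
ga_config_from <- function(config) {
  ga_config(tau = config$ga_pop, generations = config$generations,
            elite_frac = config$elite_frac, mut_mean = config$mut_mean,
            mut_sd = config$mut_sd, eta = config$eta,
            n_actions = config$n_actions)
}

#' Initial gene population
#'
#' @param cfg a [ga_config()].
#' @return a `tau` x `eta` integer matrix of uniform 0-based action indices.
#' @export
init_population <- function(cfg) {
  matrix(sample.int(cfg$n_actions, cfg$tau * cfg$eta, replace = TRUE) - 1L,
         nrow = cfg$tau, ncol = cfg$eta)
}

#' Single-point crossover
#'
#' Swaps the tails of two genes at a cut index `i` sampled from `2..eta`
#' under the weight vector `w`: the first child is
#' `g1[1..i-1] + g2[i..eta]` and symmetrically for the second.
#'
#' @param g1,g2 integer action vectors of equal length.
#' @param w weights over the cut points `2..eta`.
#' @return a list of the two children.
#' @export
crossover <- function(g1, g2, w = NULL) {
  eta <- length(g1)
  stopifnot(length(g2) == eta)
  if (eta < 2) return(list(g1, g2))
  if (is.null(w)) w <- rep(1, eta - 1)
  cuts <- 2:eta
  cut <- cuts[sample.int(length(cuts), 1L, prob = w)]
  tail_idx <- cut:eta
  c1 <- g1; c2 <- g2
  c1[tail_idx] <- g2[tail_idx]
  c2[tail_idx] <- g1[tail_idx]
  list(c1, c2)
}

#' Point mutation
#'
#' With probability `p` drawn as `clip(Normal(mut_mean, mut_sd), 0, 1)` per
#' gene, one uniformly chosen position is replaced by a different,
#' uniformly chosen action; otherwise the gene is returned unchanged.
#'
#' @param g integer action vector.
#' @param cfg a [ga_config()].
#' @param p optional forced mutation probability (overrides the Gaussian
#'   draw).
#' @return the (possibly) mutated gene.
#' @export
mutate_gene <- function(g, cfg, p = NULL) {
  if (is.null(p)) p <- min(1, max(0, stats::rnorm(1, cfg$mut_mean, cfg$mut_sd)))
  if (stats::runif(1) >= p || cfg$n_actions < 2) return(g)
  pos <- sample.int(length(g), 1L)
  repl <- sample.int(cfg$n_actions - 1L, 1L) - 1L
  if (repl >= g[pos]) repl <- repl + 1L
  g[pos] <- repl
  g
}

#' Next GA generation
#'
#' Elites (`max(1, floor(elite_frac * tau))` genes with the lowest
#' objective) are copied unchanged. The remaining slots are filled by
#' fitness-proportionate selection on the complement score
#' `max(0, 1 - objective)` (L1-normalised; uniform when all scores
#' vanish), followed by pairwise single-point crossover and point
#' mutation of the selected genes.
#'
#' @param pop `tau` x `eta` integer matrix of genes.
#' @param objectives per-gene rollout objectives (lower is better).
#' @param cfg a [ga_config()].
#' @return the next `tau` x `eta` population; rows `1..n_elite` are the
#'   elites in rank order.
#' @export
next_generation <- function(pop, objectives, cfg) {
  tau <- nrow(pop)
  stopifnot(length(objectives) == tau)
  n_elite <- max(1L, floor(cfg$elite_frac * tau))
  rank <- order(objectives)
  out <- pop[rank[seq_len(n_elite)], , drop = FALSE]
  n_rest <- tau - n_elite
  if (n_rest > 0) {
    w <- pmax(0, 1 - objectives)
    if (sum(w) <= 0) w <- rep(1, tau)
    chosen <- pop[sample.int(tau, n_rest, replace = TRUE, prob = w), ,
                  drop = FALSE]
    s <- 1L
    while (s + 1L <= n_rest) {
      kids <- crossover(chosen[s, ], chosen[s + 1L, ], cfg$cut_weights)
      chosen[s, ] <- kids[[1]]
      chosen[s + 1L, ] <- kids[[2]]
      s <- s + 2L
    }
    for (s in seq_len(n_rest)) chosen[s, ] <- mutate_gene(chosen[s, ], cfg)
    out <- rbind(out, chosen)
  }
  out
}

# Pack a scenario into the matrix form the compiled rollout expects.
.scenario_arrays <- function(scenario) {
  f <- scenario$focal
  m <- length(scenario$neighbors)
  nb_l <- matrix(0, m, 2); nb_v <- matrix(0, m, 2); nb_h <- matrix(0, m, 2)
  bh <- numeric(m + 1); bw <- numeric(m + 1)
  bh[1] <- f$h; bw[1] <- f$w
  for (i in seq_len(m)) {
    p <- scenario$neighbors[[i]]
    nb_l[i, ] <- p$l; nb_v[i, ] <- p$v; nb_h[i, ] <- .heading_of(p)
    bh[i + 1] <- p$h; bw[i + 1] <- p$w
  }
  list(focal_l = f$l, focal_v = f$v, focal_heading = .heading_of(f),
       nb_l = nb_l, nb_v = nb_v, nb_heading = nb_h,
       body_h = bh, body_w = bw)
}

#' Rollout objectives of a set of genes
#'
#' Scores each gene by simulating the focal agent executing its action
#' sequence over `eta` steps while the neighbours move ballistically, and
#' averaging the patch objective over the `eta + 1` snapshots (initial
#' state included). The patch is unbounded: no wrapping inside a rollout,
#' and collisions are counted, not resolved.
#'
#' @param scenario a scenario from [generate_scenario()].
#' @param genes integer matrix of genes (one per row, 0-based actions).
#' @param config a [flock_config()].
#' @return numeric vector of objectives (lower is better).
#' @export
gene_objectives <- function(scenario, genes, config) {
  arr <- .scenario_arrays(scenario)
  cpp_gene_objectives(arr$focal_l, arr$focal_v, arr$focal_heading,
                      arr$nb_l, arr$nb_v, arr$nb_heading,
                      arr$body_h, arr$body_w,
                      genes, action_set(config$n_actions),
                      config$delta, config$zeta,
                      isTRUE(config$speed_renorm))
}

#' Plan the focal agent's next action
#'
#' Runs the GA over `generations` generations and returns the first action
#' of the best gene together with its planning score (the complement of
#' the best rollout objective, clipped to `[0, 1]`).
#'
#' The `"cpp"` engine runs the whole GA in compiled code (the training
#' default); the `"R"` engine drives [init_population()],
#' [next_generation()] and [gene_objectives()] from R. Both implement the
#' same operators; their random draws differ.
#'
#' @param scenario a scenario from [generate_scenario()].
#' @param config a [flock_config()].
#' @param engine `"cpp"` or `"R"`.
#' @param trace record best/mean objective per generation?
#' @param init_pop optional initial population (R engine only), e.g. an
#'   exhaustive enumeration on tiny instances.
#' @param neighbor_q optional [q_table()]: when given, rollout neighbours
#'   follow this policy stochastically instead of moving ballistically —
#'   the costlier closed-loop planning variant (forces the R engine).
#' @return a list with `action` (0-based first action), `score`,
#'   `objective`, `best_gene`, and optionally `trace_best`/`trace_mean`.
#' @export
plan_action <- function(scenario, config, engine = c("cpp", "R"),
                        trace = FALSE, init_pop = NULL, neighbor_q = NULL) {
  engine <- match.arg(engine)
  if (!is.null(neighbor_q)) engine <- "R"
  if (engine == "cpp") {
    arr <- .scenario_arrays(scenario)
    return(cpp_plan(arr$focal_l, arr$focal_v, arr$focal_heading,
                    arr$nb_l, arr$nb_v, arr$nb_heading,
                    arr$body_h, arr$body_w,
                    action_set(config$n_actions), config$delta, config$zeta,
                    isTRUE(config$speed_renorm),
                    as.integer(config$ga_pop), as.integer(config$generations),
                    as.integer(config$eta), config$elite_frac,
                    config$mut_mean, config$mut_sd, trace))
  }
  cfg <- ga_config_from(config)
  pop <- if (is.null(init_pop)) init_population(cfg) else init_pop
  cfg$tau <- nrow(pop)
  best_obj <- Inf
  best_gene <- pop[1, ]
  tr_best <- tr_mean <- numeric(0)
  score_pop <- function(pop) {
    if (is.null(neighbor_q)) return(gene_objectives(scenario, pop, config))
    vapply(seq_len(nrow(pop)), function(i)
      .policy_rollout_objective(scenario, neighbor_q, config,
                                focal_gene = pop[i, ]), numeric(1))
  }
  for (gen in seq_len(cfg$generations)) {
    obj <- score_pop(pop)
    b <- which.min(obj)
    if (obj[b] < best_obj) { best_obj <- obj[b]; best_gene <- pop[b, ] }
    if (trace) { tr_best <- c(tr_best, best_obj); tr_mean <- c(tr_mean, mean(obj)) }
    if (gen == cfg$generations) break
    pop <- next_generation(pop, obj, cfg)
  }
  out <- list(action = best_gene[1], score = .clip01(1 - best_obj),
              objective = best_obj, best_gene = best_gene)
  if (trace) { out$trace_best <- tr_best; out$trace_mean <- tr_mean }
  out
}
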