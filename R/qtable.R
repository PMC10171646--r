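# Tabular stochastic policy: sparse state -> action-value table with a
# uniform default row.

#' Create an empty Q-table
#'
#' The table is sparse: only visited states are stored; any unseen state
#' behaves as the uniform row with each entry `1 / n_actions`, which is
#' observationally identical to initialising every possible state
#' uniformly while staying memory-bounded.
#'
#' @param config a [flock_config()]; the table records the configuration
#'   fingerprint (bin width, action grid, `k`, learning rate) so a policy
#'   can refuse to load into a mismatched setup.
#' @return a list of class `"q_table"` holding an environment of rows and
#'   one of visit counts.
#' @export
q_table <- function(config) {
  structure(list(rows = new.env(parent = emptyenv()),
                 visits = new.env(parent = emptyenv()),
                 n_actions = config$n_actions,
                 bin_width = config$bin_width,
                 action_deg = config$action_deg,
                 k_max = config$k_max,
                 learning_rate = config$learning_rate),
            class = "q_table")
}

.q_key <- function(state) {
  if (is.character(state)) state
  else if (inherits(state, "encoded_state")) attr(state, "key")
  else stop("state must be an encoded_state or its key string")
}

#' Action-value row of a state
#'
#' @param q a `q_table`.
#' @param state an `encoded_state` or its key.
#' @return the stored nonnegative row, or the uniform row for an unseen
#'   state.
#' @export
q_row <- function(q, state) {
  key <- .q_key(state)
  row <- q$rows[[key]]
  if (is.null(row)) rep(1 / q$n_actions, q$n_actions) else row
}

#' Number of stored (visited) states
#' @param q a `q_table`.
#' @return integer count of rows materialised by updates.
#' @export
q_size <- function(q) length(ls(q$rows))

#' @export
print.q_table <- function(x, ...) {
  cat(sprintf("<q_table> %d visited states, %d actions, lambda = %g\n",
              q_size(x), x$n_actions, x$learning_rate))
  invisible(x)
}

#' Select an action from the policy table
#'
#' Stochastic mode samples action `i` with probability proportional to its
#' row value; greedy mode returns the argmax with lowest-index tie-break.
#' A row summing to zero falls back to the uniform distribution.
#'
#' @param q a `q_table`.
#' @param state an `encoded_state` or key.
#' @param mode `"stochastic"` or `"greedy"`.
#' @return a 0-based action index.
#' @export
select_action <- function(q, state, mode = c("stochastic", "greedy")) {
  mode <- match.arg(mode)
  row <- q_row(q, state)
  s <- sum(row)
  if (mode == "greedy") return(which.max(row) - 1L)
  if (s <= 0) return(sample.int(q$n_actions, 1L) - 1L)
  sample.int(q$n_actions, 1L, prob = row) - 1L
}

#' Additive Q-update
#'
#' Adds `learning_rate * score` to the (state, action) entry, where the
#' score is the complement of the planning objective (in `[0, 1]`, larger
#' is better), and increments the state's visit count.
#'
#' @param q a `q_table` (mutated in place; also returned invisibly).
#' @param state an `encoded_state` or key.
#' @param action 0-based action index.
#' @param score planning score in `[0, 1]`.
#' @export
q_update <- function(q, state, action, score) {
  stopifnot(is.finite(score), score >= 0, score <= 1,
            action >= 0, action < q$n_actions)
  key <- .q_key(state)
  row <- q$rows[[key]]
  if (is.null(row)) row <- rep(1 / q$n_actions, q$n_actions)
  row[action + 1L] <- row[action + 1L] + q$learning_rate * score
  q$rows[[key]] <- row
  cnt <- q$visits[[key]]
  q$visits[[key]] <- if (is.null(cnt)) 1L else cnt + 1L
  invisible(q)
}

#' Serialise a Q-table to a JSON archive
#'
#' The archive stores a configuration header (bin width, action grid, `k`,
#' learning rate) plus the sparse rows and visit counts; loading into a
#' mismatched configuration is refused.
#'
#' @param q a `q_table`.
#' @param path output file.
#' @export
save_q_table <- function(q, path) {
  keys <- ls(q$rows)
  obj <- list(format = "visflock-qtable", version = 1L,
              n_actions = q$n_actions, bin_width = q$bin_width,
              action_deg = q$action_deg, k_max = q$k_max,
              learning_rate = q$learning_rate,
              states = keys,
              rows = lapply(keys, function(k) q$rows[[k]]),
              visits = vapply(keys, function(k) q$visits[[k]], integer(1),
                              USE.NAMES = FALSE))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_q_table
#' @param config the configuration the loaded table must match.
#' @return `load_q_table` returns the reconstructed `q_table`.
#' @export
load_q_table <- function(path, config) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$format, "visflock-qtable"))
    stop("not a visflock Q-table archive: ", path)
  for (f in c("n_actions", "bin_width", "action_deg", "k_max")) {
    want <- if (f == "n_actions") config$n_actions else config[[f]]
    if (!isTRUE(all.equal(as.numeric(obj[[f]]), as.numeric(want))))
      stop("configuration mismatch on `", f, "`: archive has ", obj[[f]],
           ", configuration has ", want)
  }
  cfg <- config
  cfg$learning_rate <- obj$learning_rate
  q <- q_table(cfg)
  keys <- obj$states
  if (length(keys)) {
    rows <- obj$rows
    if (is.matrix(rows)) rows <- lapply(seq_len(nrow(rows)), function(i) rows[i, ])
    for (i in seq_along(keys)) {
      q$rows[[keys[i]]] <- as.numeric(rows[[i]])
      q$visits[[keys[i]]] <- as.integer(obj$visits[i])
    }
  }
  q
}
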