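# Agent-based dynamics: recruitment attempts, noise conversions and
# replication over a system of N half-nucleosomes.

#' Simulation parameters
#'
#' Defaults follow the standard screening protocol: 30 half-nucleosomes,
#' 50 recruitment attempts per nucleosome per generation, 250 generations
#' per initialisation and 4 paired (E1-init, E2-init) runs, i.e. 2000
#' recorded generations per circuit. `alpha` is the per-iteration
#' probability of a noise conversion somewhere in the system; the default
#' 0.004 corresponds to 0.2 random conversions per nucleosome per
#' generation, keeping recruitment two orders of magnitude faster than
#' noise as heritable bistability requires.
#'
#' @param N number of half-nucleosomes (>= 2).
#' @param attempts recruitment attempts per nucleosome per generation; one
#'   generation is `attempts * N` iterations.
#' @param alpha per-iteration noise probability in `[0, 1]`.
#' @param gens generations per initialisation.
#' @param repeats number of paired (E1-init, E2-init) runs.
#' @param replication if `FALSE`, the replication step is skipped and a
#'   "generation equivalent" is `attempts * N` iterations.
#' @param replace_prob per-nucleosome probability of replacement by the R
#'   type at replication (0.5 in the standard model).
#' @param seed optional RNG seed applied by [run_circuit()] before the run.
#' @return A `sim_params` list.
#' @export
sim_params <- function(N = 30, attempts = 50, alpha = 0.004, gens = 250,
                       repeats = 4, replication = TRUE, replace_prob = 0.5,
                       seed = NULL) {
  stopifnot(N >= 2, attempts >= 1, gens >= 1, repeats >= 1)
  if (alpha < 0 || alpha > 1) stop("alpha must be in [0, 1]")
  if (replace_prob < 0 || replace_prob > 1) stop("replace_prob must be in [0, 1]")
  structure(
    list(N = as.integer(N), attempts = as.integer(attempts), alpha = alpha,
         gens = as.integer(gens), repeats = as.integer(repeats),
         replication = isTRUE(replication), replace_prob = replace_prob,
         seed = seed),
    class = "sim_params"
  )
}

.check_state <- function(state) {
  if (!is.numeric(state) || length(state) < 2 || !all(state %in% 0:3)) {
    stop("state must be a vector of >= 2 nucleosome type indices in 0..3")
  }
  as.integer(state)
}

#' One recruitment attempt (reference implementation)
#'
#' Draws an ordered pair of distinct nucleosomes (substrate first, then
#' recruiter among the remaining N-1); if the recruiter's type catalyses at
#' least one reaction applicable to the substrate's type, one applicable
#' reaction (fair coin between two) converts the substrate. This pure-R
#' stepper defines the RNG draw sequence that the compiled kernel mirrors
#' exactly.
#'
#' @param state integer vector of nucleosome types (0..3).
#' @param code code string or `circuit_code`.
#' @return The updated state vector.
#' @export
step_recruitment <- function(state, code) {
  state <- .check_state(state)
  slots <- parse_code(code)
  N <- length(state)
  n1 <- min(floor(stats::runif(1) * N) + 1, N)
  j <- min(floor(stats::runif(1) * (N - 1)) + 1, N - 1)
  n2 <- j + (j >= n1)
  app <- applicable_reactions(slots, recruiter = state[n2], substrate = state[n1])
  if (nrow(app) == 1L) {
    state[n1] <- app$target
  } else if (nrow(app) == 2L) {
    state[n1] <- if (stats::runif(1) < 0.5) app$target[1] else app$target[2]
  }
  state
}

#' One noise step (reference implementation)
#'
#' With probability `alpha`, a uniformly chosen nucleosome switches to one
#' of its two Hamming-neighbour types (fair coin, position-1 flip first).
#'
#' @inheritParams step_recruitment
#' @param alpha per-iteration noise probability.
#' @return The updated state vector.
#' @export
step_noise <- function(state, alpha) {
  state <- .check_state(state)
  if (stats::runif(1) < alpha) {
    N <- length(state)
    k <- min(floor(stats::runif(1) * N) + 1, N)
    nb <- neighbor_types(state[k])
    state[k] <- if (stats::runif(1) < 0.5) nb[1] else nb[2]
  }
  state
}

#' One replication step (reference implementation)
#'
#' Each nucleosome is independently replaced by the R type with probability
#' `replace_prob`.
#'
#' @inheritParams step_recruitment
#' @param R nucleosome type inserted on newly replicated DNA.
#' @param replace_prob per-nucleosome replacement probability.
#' @return The updated state vector.
#' @export
replicate_state <- function(state, R, replace_prob = 0.5) {
  state <- .check_state(state)
  stopifnot(R %in% 0:3)
  hit <- stats::runif(length(state)) < replace_prob
  state[hit] <- as.integer(R)
  state
}

.trajectory_df <- function(mat, E1, E2) {
  data.frame(
    run = mat[, 1],
    init = ifelse(mat[, 2] == E1, "E1", "E2"),
    gen = mat[, 3],
    n_E1 = mat[, 4],
    n_E2 = mat[, 5],
    stringsAsFactors = FALSE
  )
}

#' Simulate a circuit under the standard protocol
#'
#' Executes `repeats` paired runs, each pair starting once from all-E1 and
#' once from all-E2, for `gens` generations each. A generation is
#' `attempts * N` interleaved recruitment+noise iterations followed by one
#' replication (skipped when `params$replication` is `FALSE`); the numbers
#' of E1 and E2 nucleosomes are recorded just before each replication
#' point. Fully reproducible from `params$seed`.
#'
#' @param code code string or `circuit_code`.
#' @param arr an [arrangement()].
#' @param params a [sim_params()] object.
#' @return A trajectory `data.frame` with columns `run`, `init` ("E1" or
#'   "E2"), `gen`, `n_E1`, `n_E2` and attributes `N`, `code`,
#'   `arrangement`, `params`.
#' @examples
#' arr <- standard_arrangement("e-opposite-r-out")
#' traj <- run_circuit("x003xx3x", arr, sim_params(gens = 20, repeats = 1, seed = 1))
#' head(traj)
#' @export
run_circuit <- function(code, arr, params = sim_params()) {
  if (!inherits(arr, "arrangement")) stop("arr must be an arrangement object")
  if (!inherits(params, "sim_params")) stop("params must come from sim_params()")
  slots <- parse_code(code)
  if (!is.null(params$seed)) set.seed(params$seed)
  mat <- .sim_run_cpp(unclass(slots), arr$E1, arr$E2, arr$R,
                      params$N, params$attempts, params$alpha,
                      params$gens, params$repeats,
                      params$replication, params$replace_prob)
  traj <- .trajectory_df(mat, arr$E1, arr$E2)
  attr(traj, "N") <- params$N
  attr(traj, "code") <- as.character(slots)
  attr(traj, "arrangement") <- arr
  attr(traj, "params") <- params
  traj
}

#' Simulate a circuit with the pure-R reference stepper
#'
#' Slow, loop-level composition of [step_recruitment()], [step_noise()] and
#' [replicate_state()]. Consumes the RNG stream in exactly the same order
#' as the compiled kernel, so with the same seed the two produce identical
#' trajectories; used as an independent cross-check at small problem sizes.
#'
#' @inheritParams run_circuit
#' @return A trajectory `data.frame` as from [run_circuit()].
#' @export
run_circuit_r <- function(code, arr, params = sim_params()) {
  if (!inherits(arr, "arrangement")) stop("arr must be an arrangement object")
  slots <- parse_code(code)
  if (!is.null(params$seed)) set.seed(params$seed)
  T_iter <- params$attempts * params$N
  n_runs <- 2L * params$repeats
  rows <- vector("list", n_runs * params$gens)
  row <- 0L
  for (run in seq_len(n_runs)) {
    init <- if (run %% 2L == 1L) arr$E1 else arr$E2
    state <- rep(init, params$N)
    for (g in seq_len(params$gens)) {
      for (it in seq_len(T_iter)) {
        state <- step_recruitment(state, slots)
        state <- step_noise(state, params$alpha)
      }
      row <- row + 1L
      rows[[row]] <- c(run, init, g, sum(state == arr$E1), sum(state == arr$E2))
      if (params$replication) {
        state <- replicate_state(state, arr$R, params$replace_prob)
      }
    }
  }
  traj <- .trajectory_df(do.call(rbind, rows), arr$E1, arr$E2)
  attr(traj, "N") <- params$N
  attr(traj, "code") <- as.character(slots)
  attr(traj, "arrangement") <- arr
  attr(traj, "params") <- params
  traj
}

#' Write a trajectory to a tab-separated file
#'
#' Columns `generation`, `n_E1`, `n_E2`, `run_id`, `init_state`; a `#`
#' header line embeds the circuit code, arrangement and parameters for
#' provenance.
#'
#' @param traj a trajectory from [run_circuit()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(traj, path) {
  arr <- attr(traj, "arrangement")
  p <- attr(traj, "params")
  hdr <- sprintf(
    "# histcirc trajectory code=%s E1=%s E2=%s R=%s N=%s attempts=%s alpha=%s gens=%s repeats=%s replication=%s seed=%s",
    attr(traj, "code") %||% "?",
    if (is.null(arr)) "?" else arr$E1, if (is.null(arr)) "?" else arr$E2,
    if (is.null(arr)) "?" else arr$R,
    attr(traj, "N") %||% "?",
    if (is.null(p)) "?" else p$attempts, if (is.null(p)) "?" else p$alpha,
    if (is.null(p)) "?" else p$gens, if (is.null(p)) "?" else p$repeats,
    if (is.null(p)) "?" else p$replication,
    if (is.null(p) || is.null(p$seed)) "NA" else p$seed
  )
  out <- data.frame(generation = traj$gen, n_E1 = traj$n_E1, n_E2 = traj$n_E2,
                    run_id = traj$run, init_state = traj$init)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a trajectory written by [write_trajectory()]
#'
#' @param path file path.
#' @param N system size to attach (needed for scoring); defaults to
#'   `max(n_E1 + n_E2)` if not given.
#' @return A trajectory `data.frame`.
#' @export
read_trajectory <- function(path, N = NULL) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  traj <- data.frame(run = tab$run_id, init = tab$init_state,
                     gen = tab$generation, n_E1 = tab$n_E1, n_E2 = tab$n_E2,
                     stringsAsFactors = FALSE)
  attr(traj, "N") <- if (is.null(N)) max(traj$n_E1 + traj$n_E2) else as.integer(N)
  traj
}

`%||%` <- function(a, b) if (is.null(a)) b else a
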