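# Bistability measures: balance B, spontaneous switch frequency f, and the
# mean intermediate dwell time tau, plus the working-circuit verdict.

#' Working-circuit criteria
#'
#' A circuit "works" when its trajectory is balanced (`B >= B_min`), stable
#' (`f <= f_max`, i.e. switching less than once per `1/f_max` generations)
#' and decisive (`tau <= tau_max` generations spent in intermediate states
#' while switching).
#'
#' @param B_min minimum balance score (default 0.75).
#' @param f_max maximum spontaneous switches per recorded generation
#'   (default 0.1).
#' @param tau_max maximum mean dwell, in generations, in unclassified
#'   states during a switch (default 5).
#' @return A `working_criteria` list.
#' @export
working_criteria <- function(B_min = 0.75, f_max = 0.1, tau_max = 5) {
  stopifnot(B_min > 0, f_max > 0, tau_max > 0)
  structure(list(B_min = B_min, f_max = f_max, tau_max = tau_max),
            class = "working_criteria")
}

#' Classify a recorded generation
#'
#' The system is in state E1 when the E1 count exceeds the E2 count by at
#' least half the nucleosomes (`n_E1 - n_E2 >= N/2`), in E2 for the reverse,
#' and undecided otherwise. Vectorised over records.
#'
#' @param n_E1,n_E2 counts of E1 and E2 nucleosomes.
#' @param N system size.
#' @return Character vector over `"E1"`, `"E2"`, `"undecided"`.
#' @examples
#' classify_generation(c(23, 20, 0), c(7, 10, 15), 30)
#' @export
classify_generation <- function(n_E1, n_E2, N) {
  if (any(n_E1 < 0) || any(n_E2 < 0)) stop("nucleosome counts must be non-negative")
  if (any(n_E1 + n_E2 > N)) stop("n_E1 + n_E2 cannot exceed N")
  d <- n_E1 - n_E2
  ifelse(d >= N / 2, "E1", ifelse(-d >= N / 2, "E2", "undecided"))
}

#' Balance score
#'
#' `B = 4 * P1 * P2`, where `P1` and `P2` are the fractions of recorded
#' generations classified as E1 and E2. B is 1 for a perfectly balanced
#' trajectory (each state half the time) and crosses the 0.75 working
#' threshold exactly when either fraction leaves `[0.25, 0.75]` for a fully
#' classified trajectory; a system in each state 43.3% of the time (the
#' rest undecided) also scores 0.75.
#'
#' @param P1,P2 state fractions, `P1 + P2 <= 1`.
#' @return The balance score in `[0, 1]`.
#' @examples
#' balance_score(0.5, 0.5)     # 1
#' balance_score(0.25, 0.75)   # 0.75
#' @export
balance_score <- function(P1, P2) {
  if (any(P1 < 0) || any(P2 < 0) || any(P1 + P2 > 1 + 1e-12)) {
    stop("P1 and P2 must be non-negative with P1 + P2 <= 1")
  }
  4 * P1 * P2
}

# switch statistics on one run's classification sequence:
# undecided gaps are collapsed; a switch is a change between consecutive
# classified states; each switch contributes its gap length to the dwell
# sample.
.run_switches <- function(cls) {
  idx <- which(cls != "undecided")
  if (length(idx) < 2L) {
    return(list(n = 0L, gaps = numeric(0)))
  }
  v <- cls[idx]
  chg <- which(v[-1L] != v[-length(v)])
  list(n = length(chg), gaps = idx[chg + 1L] - idx[chg] - 1L)
}

#' Score a trajectory for heritable bistability
#'
#' Computes the state fractions `P1`, `P2`, the balance `B = 4 P1 P2`, the
#' spontaneous switch frequency `f` (switches per recorded generation) and
#' the mean intermediate dwell `tau` (mean number of undecided generations
#' separating opposite classified states). Switches are counted within
#' runs only: re-initialisation boundaries are forced flips and never count.
#' A trajectory with no spontaneous switch has `f = 0` and `tau = 0`.
#'
#' @param traj trajectory `data.frame` with columns `n_E1`, `n_E2` and
#'   (optionally) `run`; typically from [run_circuit()].
#' @param N system size; defaults to the trajectory's `N` attribute.
#' @param criteria a [working_criteria()] object.
#' @return A `bistability_scores` list: `P1`, `P2`, `B`, `f`, `tau`,
#'   `n_switches`, `n_records`, `working`.
#' @export
score_trajectory <- function(traj, N = attr(traj, "N"),
                             criteria = working_criteria()) {
  if (is.null(N)) stop("N must be supplied (or attached to the trajectory)")
  if (!all(c("n_E1", "n_E2") %in% names(traj))) {
    stop("trajectory needs columns n_E1 and n_E2")
  }
  if (nrow(traj) < 2L) stop("trajectory must contain at least 2 records")
  cls <- classify_generation(traj$n_E1, traj$n_E2, N)
  n_rec <- length(cls)
  P1 <- mean(cls == "E1")
  P2 <- mean(cls == "E2")
  run <- if ("run" %in% names(traj)) traj$run else rep(1L, n_rec)
  sw <- lapply(split(cls, run), .run_switches)
  n_switch <- sum(vapply(sw, `[[`, integer(1), "n"))
  gaps <- unlist(lapply(sw, `[[`, "gaps"), use.names = FALSE)
  f <- n_switch / n_rec
  tau <- if (n_switch > 0) mean(gaps) else 0
  B <- balance_score(P1, P2)
  structure(
    list(P1 = P1, P2 = P2, B = B, f = f, tau = tau,
         n_switches = n_switch, n_records = n_rec,
         working = B >= criteria$B_min && f <= criteria$f_max &&
           tau <= criteria$tau_max),
    class = "bistability_scores"
  )
}

#' @export
print.bistability_scores <- function(x, ...) {
  cat(sprintf(
    "<bistability_scores> B=%.3f (P1=%.3f, P2=%.3f)  f=%.4g  tau=%.3g  %s\n",
    x$B, x$P1, x$P2, x$f, x$tau,
    if (x$working) "WORKING" else "not working"))
  invisible(x)
}
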