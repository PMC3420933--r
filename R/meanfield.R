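# Deterministic mean-field rate equations for a circuit (no replication):
# fixed points on the occupancy simplex and their stability.

#' Build the mean-field model of a circuit
#'
#' Occupancies `P_t` of the four types evolve by mass-action recruitment
#' fluxes and symmetric noise. Each recruited reaction `s -> t` by type `q`
#' contributes a flux `P_q * P_s` (recruitment rate normalised to 1); noise
#' moves occupancy at rate `alpha_mf` per nucleosome, split equally to the
#' two Hamming neighbours. Replication is not modelled; the total occupancy
#' is conserved.
#'
#' @param code code string or `circuit_code`.
#' @param alpha_mf noise-to-recruitment rate ratio (>= 0).
#' @return A `meanfield_model` list with `deriv(P)` (length-4 derivative),
#'   `flux_decomposition(P)` (per-type inflow and outflow-rate terms),
#'   `code`, `alpha_mf`.
#' @export
build_meanfield <- function(code, alpha_mf) {
  stopifnot(alpha_mf >= 0)
  slots <- unclass(parse_code(code))
  rt <- reaction_table()
  rec <- rt[!is.na(slots), , drop = FALSE]
  rec$q <- slots[!is.na(slots)]
  nb <- rbind(sapply(0:3, function(t) neighbor_types(t)))
  deriv <- function(P) {
    dP <- numeric(4)
    if (nrow(rec) > 0L) {
      flux <- P[rec$q + 1L] * P[rec$source + 1L]
      for (k in seq_len(nrow(rec))) {
        dP[rec$source[k] + 1L] <- dP[rec$source[k] + 1L] - flux[k]
        dP[rec$target[k] + 1L] <- dP[rec$target[k] + 1L] + flux[k]
      }
    }
    if (alpha_mf > 0) {
      for (t in 0:3) {
        dP[t + 1L] <- dP[t + 1L] - alpha_mf * P[t + 1L] +
          (alpha_mf / 2) * (P[nb[1, t + 1L] + 1L] + P[nb[2, t + 1L] + 1L])
      }
    }
    dP
  }
  flux_decomposition <- function(P) {
    inflow <- numeric(4)   # rate of occupancy entering each type
    outrate <- numeric(4)  # total first-order loss coefficient of each type
    if (nrow(rec) > 0L) {
      flux <- P[rec$q + 1L] * P[rec$source + 1L]
      for (k in seq_len(nrow(rec))) {
        inflow[rec$target[k] + 1L] <- inflow[rec$target[k] + 1L] + flux[k]
        outrate[rec$source[k] + 1L] <- outrate[rec$source[k] + 1L] +
          P[rec$q[k] + 1L]
      }
    }
    if (alpha_mf > 0) {
      outrate <- outrate + alpha_mf
      for (t in 0:3) {
        inflow[t + 1L] <- inflow[t + 1L] +
          (alpha_mf / 2) * (P[nb[1, t + 1L] + 1L] + P[nb[2, t + 1L] + 1L])
      }
    }
    list(inflow = inflow, outrate = outrate)
  }
  structure(list(deriv = deriv, flux_decomposition = flux_decomposition,
                 code = as.character(parse_code(code)), alpha_mf = alpha_mf),
            class = "meanfield_model")
}

# radical-inverse (van der Corput) sequence in the given base
.vdc <- function(n, base) {
  vapply(seq_len(n), function(i) {
    x <- 0; f <- 1 / base
    while (i > 0) {
      x <- x + f * (i %% base)
      i <- i %/% base
      f <- f / base
    }
    x
  }, numeric(1))
}

# deterministic low-discrepancy (Halton) starts on the occupancy simplex
.simplex_starts <- function(n) {
  h <- cbind(.vdc(n, 2), .vdc(n, 3), .vdc(n, 5), .vdc(n, 7))
  y <- -log(pmax(1 - h, 1e-12))
  sweep(y, 1, rowSums(y), "/")
}

#' Locate the fixed points of a mean-field model
#'
#' Multi-start root finding on the simplex (reduced coordinates
#' `(P0, P1, P2)`, `P3 = 1 - sum`), starting from a low-discrepancy point
#' set plus near-vertex and centre starts. Solutions are filtered to the
#' simplex, deduplicated, and classified by the eigenvalues of the reduced
#' Jacobian (stable when all real parts are negative).
#'
#' @param model from [build_meanfield()].
#' @param n_starts number of multi-starts (default 100).
#' @param dedup_tol Euclidean tolerance for merging duplicate solutions.
#' @return A data.frame with columns `P0`..`P3`, `stable`,
#'   `max_re_eigen`; attribute `n_failed` counts non-converged starts.
#' @export
find_fixed_points <- function(model, n_starts = 100, dedup_tol = 1e-8) {
  g <- function(x) model$deriv(c(x, 1 - sum(x)))[1:3]
  starts <- .simplex_starts(n_starts)[, 1:3, drop = FALSE]
  eps <- 1e-3
  corners <- rbind(
    c(1 - 3 * eps, eps, eps), c(eps, 1 - 3 * eps, eps),
    c(eps, eps, 1 - 3 * eps), c(eps, eps, eps),
    c(0.25, 0.25, 0.25)
  )
  starts <- rbind(starts, corners)
  sols <- list()
  n_failed <- 0L
  for (i in seq_len(nrow(starts))) {
    x <- .newton_root(g, starts[i, ])
    if (is.null(x)) {
      n_failed <- n_failed + 1L
      next
    }
    P <- c(x, 1 - sum(x))
    if (any(P < -1e-7) || any(P > 1 + 1e-7)) next
    sols[[length(sols) + 1L]] <- pmin(pmax(P, 0), 1)
  }
  if (length(sols) == 0L) {
    out <- data.frame(P0 = numeric(0), P1 = numeric(0), P2 = numeric(0),
                      P3 = numeric(0), stable = logical(0),
                      max_re_eigen = numeric(0))
    attr(out, "n_failed") <- n_failed
    return(out)
  }
  pts <- do.call(rbind, sols)
  keep <- rep(TRUE, nrow(pts))
  for (i in seq_len(nrow(pts))) {
    if (!keep[i]) next
    for (j in seq_len(i - 1L)) {
      if (keep[j] && sqrt(sum((pts[i, ] - pts[j, ])^2)) < max(dedup_tol, 1e-6)) {
        keep[i] <- FALSE
        break
      }
    }
  }
  pts <- pts[keep, , drop = FALSE]
  max_re <- apply(pts, 1, function(P) {
    J <- pracma::jacobian(g, P[1:3])
    max(Re(eigen(J, only.values = TRUE)$values))
  })
  out <- data.frame(P0 = pts[, 1], P1 = pts[, 2], P2 = pts[, 3],
                    P3 = pts[, 4], stable = max_re < -1e-8,
                    max_re_eigen = max_re)
  out <- out[order(-out$stable, -pmax(out$P0, out$P3)), ]
  rownames(out) <- NULL
  attr(out, "n_failed") <- n_failed
  out
}

# damped Newton with numerical Jacobian; NULL on non-convergence
.newton_root <- function(g, x0, tol = 1e-12, max_iter = 200) {
  x <- x0
  for (it in seq_len(max_iter)) {
    fx <- g(x)
    if (max(abs(fx)) < tol) return(x)
    J <- pracma::jacobian(g, x)
    step <- tryCatch(solve(J, fx), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) return(NULL)
    lambda <- 1
    repeat {
      xn <- x - lambda * step
      if (sum(g(xn)^2) < sum(fx^2) || lambda < 1e-6) break
      lambda <- lambda / 2
    }
    if (max(abs(x - xn)) < 1e-15) return(if (max(abs(fx)) < 1e-8) x else NULL)
    x <- xn
  }
  if (max(abs(g(x))) < 1e-8) x else NULL
}

#' Integrate the mean-field dynamics
#'
#' @param model from [build_meanfield()].
#' @param P0 initial occupancy vector (length 4, summing to 1).
#' @param times output time points.
#' @return A deSolve matrix with columns `time`, `P0`..`P3`.
#' @export
integrate_meanfield <- function(model, P0, times = seq(0, 100, by = 1)) {
  stopifnot(length(P0) == 4, abs(sum(P0) - 1) < 1e-8)
  rhs <- function(t, y, parms) list(model$deriv(y))
  out <- deSolve::ode(y = c(P0 = P0[1], P1 = P0[2], P2 = P0[3], P3 = P0[4]),
                      times = times, func = rhs, parms = NULL)
  out
}

#' Is a circuit bistable in mean field?
#'
#' `TRUE` when the mean-field model has at least two stable fixed points
#' that are dominated by different E types (separated by at least
#' `separation` in the E occupancy difference `P_E1 - P_E2`).
#'
#' @param code code string or `circuit_code`.
#' @param alpha_mf noise-to-recruitment ratio.
#' @param arr an [arrangement()] naming E1 and E2 (default E1 = 0, E2 = 3).
#' @param separation minimal difference in `P_E1 - P_E2` between two
#'   stable fixed points (default 0.5).
#' @return Logical.
#' @export
meanfield_bistable <- function(code, alpha_mf,
                               arr = standard_arrangement("e-opposite-r-out"),
                               separation = 0.5) {
  fp <- find_fixed_points(build_meanfield(code, alpha_mf))
  st <- fp[fp$stable, , drop = FALSE]
  if (nrow(st) < 2L) return(FALSE)
  d <- as.matrix(st[, paste0("P", 0:3)])[, arr$E1 + 1L] -
    as.matrix(st[, paste0("P", 0:3)])[, arr$E2 + 1L]
  max(d) - min(d) >= separation
}

#' Stable-fixed-point count across a noise sweep
#'
#' @param code code string or `circuit_code`.
#' @param alphas vector of `alpha_mf` values.
#' @return A data.frame `alpha_mf`, `n_stable`, `bistable`.
#' @export
meanfield_sweep <- function(code, alphas) {
  rows <- lapply(alphas, function(a) {
    fp <- find_fixed_points(build_meanfield(code, a))
    data.frame(alpha_mf = a, n_stable = sum(fp$stable),
               bistable = meanfield_bistable(code, a))
  })
  do.call(rbind, rows)
}
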