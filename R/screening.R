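# Exhaustive simulation-based screening of circuit-code spaces.

#' Enumerate circuit codes
#'
#' Yields every code in the (possibly restricted) circuit space. The
#' template fixes slots to a character in `{0,1,2,3,x}` and leaves `*`
#' slots free (5 choices each); the full space `"********"` holds
#' `5^8 = 390625` codes.
#'
#' @param template 8-character string over `{0,1,2,3,x,*}`.
#' @return Character vector of code strings, each exactly once.
#' @examples
#' length(enumerate_codes("x***xx*x"))  # 625, the classical-containing subspace
#' @export
enumerate_codes <- function(template = "********") {
  stopifnot(is.character(template), length(template) == 1L)
  if (nchar(template) != 8L) stop("template must have exactly 8 characters")
  chars <- tolower(strsplit(template, "")[[1]])
  ok <- chars %in% c("0", "1", "2", "3", "x", "*")
  if (!all(ok)) {
    stop("illegal template character '", chars[which(!ok)[1]],
         "' at position ", which(!ok)[1])
  }
  choices <- lapply(chars, function(ch) {
    if (ch == "*") c("0", "1", "2", "3", "x") else ch
  })
  grid <- do.call(expand.grid, c(rev(choices),
                                 list(stringsAsFactors = FALSE,
                                      KEEP.OUT.ATTRS = FALSE)))
  do.call(paste0, rev(grid))
}

# canonical index of a code in the enumeration (0 .. 5^8 - 1)
.code_index <- function(code) {
  slots <- unclass(parse_code(code))
  digits <- ifelse(is.na(slots), 4, slots)
  sum(digits * 5^(seq_len(8) - 1))
}

#' Derive a per-circuit seed from a master seed
#'
#' Deterministic hash of (master seed, code), independent of the order in
#' which codes are screened, so screens are reproducible and
#' embarrassingly parallel.
#'
#' @param master_seed integer master seed.
#' @param code code string or `circuit_code`.
#' @return An integer seed in `[1, 2^31 - 2]`.
#' @export
code_seed <- function(master_seed, code) {
  idx <- .code_index(code)
  m <- 2147483647 # 2^31 - 1, prime
  h <- ((as.numeric(master_seed) %% m) * 48271) %% m
  h <- (h + (idx %% m) * 69621) %% m
  as.integer(h %% (m - 1)) + 1L
}

#' Screen circuit codes for heritable bistability
#'
#' Runs the full simulation protocol for each code, scores the trajectory,
#' and attaches the structural motif summary. Each code gets its own RNG
#' seed derived from `(seed, code)` via [code_seed()], so results are
#' independent of screening order and can be partitioned across workers.
#'
#' With `early_abort = TRUE`, the remaining repeats of a code are skipped
#' as soon as the balance score can no longer reach `criteria$B_min` even
#' if every remaining record were classified optimally; this cannot change
#' a verdict (a circuit failing the balance bound fails `working`
#' regardless of `f` and `tau`), only the reported scores of non-working
#' circuits, which are then computed from the completed records.
#'
#' @param codes character vector of code strings (e.g. from
#'   [enumerate_codes()]).
#' @param arr an [arrangement()].
#' @param params a [sim_params()] object (its `seed` field is ignored;
#'   seeding is per code).
#' @param criteria a [working_criteria()] object.
#' @param seed master seed.
#' @param motifs attach motif columns (default `TRUE`).
#' @param destab_scope destabilisation recruiter scope, see
#'   [count_standard_two_step()].
#' @param early_abort skip hopeless repeats (default `FALSE`).
#' @param checkpoint optional CSV path; completed rows are appended as the
#'   screen runs and already-present codes are skipped on restart, so an
#'   interrupted screen resumes without duplicating rows.
#' @param progress print a progress line every 1000 codes.
#' @return A `data.frame` with one row per code: `code`, `arrangement`,
#'   `B`, `P1`, `P2`, `f`, `tau`, `working`, `seed`, motif columns.
#' @export
screen_codes <- function(codes, arr, params = sim_params(),
                         criteria = working_criteria(), seed = 1,
                         motifs = TRUE, destab_scope = "non-driver",
                         early_abort = FALSE, checkpoint = NULL,
                         progress = FALSE) {
  stopifnot(is.character(codes))
  if (anyDuplicated(codes)) stop("codes must be deduplicated")
  done <- NULL
  if (!is.null(checkpoint) && file.exists(checkpoint)) {
    done <- utils::read.csv(checkpoint, stringsAsFactors = FALSE,
                            colClasses = c(code = "character"))
    codes <- setdiff(codes, done$code)
  }
  n <- length(codes)
  out <- data.frame(
    code = codes, arrangement = rep(arr$category, n),
    B = numeric(n), P1 = numeric(n), P2 = numeric(n),
    f = numeric(n), tau = numeric(n),
    working = logical(n), aborted = logical(n), seed = integer(n),
    stringsAsFactors = FALSE
  )
  if (motifs) {
    for (cl in c("n_recruited", "min_enzymes", "toward_E1", "toward_E2",
                 "away_E1", "away_E2", "n_std_two_step", "n_std_destabilized",
                 "n_pull_push", "n_pp_destabilized")) {
      out[[cl]] <- integer(n)
    }
    out$exotic <- logical(n)
  }
  for (i in seq_len(n)) {
    row <- .screen_one(codes[i], arr, params, criteria, seed, motifs,
                       destab_scope, early_abort)
    out[i, names(row)] <- row
    if (!is.null(checkpoint)) {
      utils::write.table(out[i, , drop = FALSE], checkpoint, sep = ",",
                         row.names = FALSE,
                         col.names = !file.exists(checkpoint),
                         append = file.exists(checkpoint), quote = FALSE)
    }
    if (progress && i %% 1000 == 0) {
      message("screened ", i, " / ", n, " codes")
    }
  }
  if (!is.null(done)) {
    out <- rbind(done[, names(out), drop = FALSE], out)
    rownames(out) <- NULL
  }
  if (nrow(out) == 0L) stop("no codes to screen")
  out
}

.screen_one <- function(code, arr, params, criteria, seed, motifs,
                        destab_scope, early_abort) {
  p <- params
  p$seed <- code_seed(seed, code)
  aborted <- FALSE
  if (early_abort && params$repeats > 1L) {
    # run one repeat pair first; bound the best achievable balance
    p1 <- p; p1$repeats <- 1L
    set.seed(p$seed)
    p1$seed <- NULL
    traj <- run_circuit(code, arr, p1)
    total <- 2 * params$repeats * params$gens
    cls <- classify_generation(traj$n_E1, traj$n_E2, params$N)
    c1 <- sum(cls == "E1"); c2 <- sum(cls == "E2")
    m <- total - length(cls)
    # remaining m records split to maximise 4 (c1+a)(c2+m-a) / total^2
    a <- max(0, min(m, round((c2 + m - c1) / 2)))
    B_max <- 4 * (c1 + a) * (c2 + m - a) / total^2
    if (B_max < criteria$B_min) {
      aborted <- TRUE
    } else {
      p2 <- p; p2$repeats <- params$repeats - 1L; p2$seed <- NULL
      rest <- run_circuit(code, arr, p2)
      rest$run <- rest$run + 2L
      traj <- rbind(traj, rest)
      attr(traj, "N") <- params$N
    }
  } else {
    traj <- run_circuit(code, arr, p)
  }
  attr(traj, "N") <- params$N
  sc <- score_trajectory(traj, params$N, criteria)
  out <- list(
    code = as.character(parse_code(code)),
    B = sc$B, P1 = sc$P1, P2 = sc$P2, f = sc$f, tau = sc$tau,
    working = if (aborted) FALSE else sc$working,
    aborted = aborted,
    seed = p$seed
  )
  if (motifs) {
    mr <- motif_report(code, arr, destab_scope)
    out$n_recruited <- mr$n_recruited
    out$min_enzymes <- mr$min_enzymes
    out$toward_E1 <- unname(mr$toward["E1"])
    out$toward_E2 <- unname(mr$toward["E2"])
    out$away_E1 <- unname(mr$away["E1"])
    out$away_E2 <- unname(mr$away["E2"])
    out$n_std_two_step <- mr$n_std_two_step
    out$n_std_destabilized <- mr$n_std_destabilized
    out$n_pull_push <- mr$n_pull_push
    out$n_pp_destabilized <- mr$n_pp_destabilized
    out$exotic <- out$working && mr$n_std_two_step == 0L
  }
  out
}

#' Summarise a screen
#'
#' Emits the standard summary surfaces over the working circuits: working
#' count, the 8 x 5 reaction-usage table (slot value per reaction),
#' histograms of toward/away reaction counts, recruited-reaction and
#' minimal-enzyme counts, pathway-class tables for standard two-step and
#' pull-push motifs (split by direction and by over-R vs non-R), the
#' motif-combination histogram, counts of exotic (no standard two-step)
#' and neither-motif circuits, and the twin-discordance diagnostic (the
#' fraction of working circuits whose complement twin was screened with
#' the opposite verdict -- Monte-Carlo boundary noise that shrinks with
#' more repeats).
#'
#' @param result a [screen_codes()] result (with motif columns).
#' @param arr the [arrangement()] screened.
#' @return A `screen_summary` list of tables; empty result gives an empty
#'   summary with a warning.
#' @export
summarize_screen <- function(result, arr) {
  if (nrow(result) == 0L) {
    warning("empty screen result")
    return(structure(list(n_screened = 0L, n_working = 0L),
                     class = "screen_summary"))
  }
  if (!"n_std_two_step" %in% names(result)) {
    stop("result lacks motif columns; run screen_codes() with motifs = TRUE")
  }
  wk <- result[result$working, , drop = FALSE]
  usage <- matrix(0L, nrow = 8, ncol = 5,
                  dimnames = list(reaction = paste0("r", 1:8),
                                  recruiter = c("0", "1", "2", "3", "x")))
  if (nrow(wk) > 0L) {
    mat <- do.call(rbind, strsplit(wk$code, ""))
    for (r in 1:8) {
      t <- table(factor(mat[, r], levels = c("0", "1", "2", "3", "x")))
      usage[r, ] <- as.integer(t)
    }
  }
  # pathway classes: for each working code, number of pathways over R and
  # over the non-R intermediate (any direction), 0/1/2 each
  class_counts <- function(codes, fun) {
    overR <- nonR <- integer(length(codes))
    d_overR <- d_nonR <- integer(length(codes))
    for (i in seq_along(codes)) {
      p <- fun(codes[i], arr)
      overR[i] <- sum(p$over_R)
      nonR[i] <- sum(!p$over_R)
      d_overR[i] <- sum(p$over_R & p$destabilized)
      d_nonR[i] <- sum(!p$over_R & p$destabilized)
    }
    list(
      all = rbind("over-R" = tabulate(overR + 1L, 3L),
                  "non-R" = tabulate(nonR + 1L, 3L)),
      destabilized = rbind("over-R" = tabulate(d_overR + 1L, 3L),
                           "non-R" = tabulate(d_nonR + 1L, 3L))
    )
  }
  std_classes <- pp_classes <- NULL
  combo <- NULL
  if (nrow(wk) > 0L) {
    std_classes <- class_counts(wk$code, count_standard_two_step)
    colnames(std_classes$all) <- colnames(std_classes$destabilized) <- 0:2
    pp_classes <- class_counts(wk$code, count_pull_push)
    colnames(pp_classes$all) <- colnames(pp_classes$destabilized) <- 0:2
    combo <- table(std_destabilized = wk$n_std_destabilized,
                   pp_destabilized = wk$n_pp_destabilized)
  }
  # twin discordance among screened within-arrangement twin pairs (the
  # E-role swap fixes the intermediates and hence an R-out R type)
  twins <- vapply(result$code, function(cd) as.character(e_swap_twin(cd)),
                  character(1))
  have <- match(twins, result$code)
  paired <- !is.na(have)
  discord <- if (any(paired)) {
    mean(result$working[paired] != result$working[have[paired]])
  } else NA_real_
  structure(
    list(
      n_screened = nrow(result),
      n_working = nrow(wk),
      reaction_usage = usage,
      toward_hist = table(factor(wk$toward_E1 + wk$toward_E2, levels = 0:8)),
      away_hist = table(factor(wk$away_E1 + wk$away_E2, levels = 0:8)),
      n_recruited_hist = table(factor(wk$n_recruited, levels = 0:8)),
      min_enzymes_hist = table(factor(wk$min_enzymes, levels = 0:8)),
      std_two_step_classes = std_classes,
      pull_push_classes = pp_classes,
      motif_combinations = combo,
      n_with_std_two_step = sum(wk$n_std_two_step > 0),
      n_std_destabilized = sum(wk$n_std_destabilized > 0),
      n_with_pull_push = sum(wk$n_pull_push > 0),
      n_pp_destabilized = sum(wk$n_pp_destabilized > 0),
      n_exotic = sum(wk$exotic),
      n_neither_motif = sum(wk$n_std_destabilized == 0 &
                              wk$n_pp_destabilized == 0),
      twin_discordance = discord
    ),
    class = "screen_summary"
  )
}

#' @export
print.screen_summary <- function(x, ...) {
  cat("<screen_summary> ", x$n_working, " working of ", x$n_screened,
      " screened circuits\n", sep = "")
  if (!is.null(x$n_exotic)) {
    cat("  exotic (no standard two-step): ", x$n_exotic,
        "; neither destabilized motif: ", x$n_neither_motif, "\n", sep = "")
    cat("  twin discordance: ",
        if (is.na(x$twin_discordance)) "NA"
        else sprintf("%.3f", x$twin_discordance), "\n", sep = "")
  }
  invisible(x)
}

#' Working-verdict sensitivity to the score thresholds
#'
#' Re-thresholds a completed screen's stored scores under alternative
#' criteria without re-simulating, reporting the working count for every
#' combination. The dwell threshold is the least constrained by the model
#' definition, so its `{2, 5, 10}` sensitivity is the default report.
#'
#' @param result a [screen_codes()] result.
#' @param B_min,f_max,tau_max vectors of candidate thresholds; the full
#'   grid is evaluated.
#' @return A data.frame `B_min`, `f_max`, `tau_max`, `n_working`.
#' @export
working_sensitivity <- function(result, B_min = 0.75, f_max = 0.1,
                                tau_max = c(2, 5, 10)) {
  grid <- expand.grid(B_min = B_min, f_max = f_max, tau_max = tau_max,
                      KEEP.OUT.ATTRS = FALSE)
  grid$n_working <- vapply(seq_len(nrow(grid)), function(i) {
    sum(result$B >= grid$B_min[i] & result$f <= grid$f_max[i] &
          result$tau <= grid$tau_max[i] & !result$aborted)
  }, numeric(1))
  grid
}

#' Calibrate the noise level against a target working count
#'
#' Screens the same code set at each candidate `alpha` and reports the
#' working count per alpha together with the alpha whose count best
#' matches `target`. Used to recover a screening noise level compatible
#' with a reference working count before comparing downstream motif
#' statistics.
#'
#' @param alphas numeric vector of candidate noise levels.
#' @param codes codes to screen at each alpha.
#' @param arr,params,criteria,seed as in [screen_codes()].
#' @param target target working count.
#' @return A list with `sweep` (data.frame `alpha`, `n_working`) and
#'   `best_alpha`.
#' @export
calibrate_alpha <- function(alphas, codes, arr, params = sim_params(),
                            criteria = working_criteria(), seed = 1,
                            target = 202) {
  counts <- vapply(alphas, function(a) {
    p <- params
    p$alpha <- a
    res <- screen_codes(codes, arr, p, criteria, seed = seed, motifs = FALSE)
    sum(res$working)
  }, numeric(1))
  sweep <- data.frame(alpha = alphas, n_working = counts)
  list(sweep = sweep, best_alpha = alphas[which.min(abs(counts - target))])
}
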