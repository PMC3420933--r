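# Simulation-free structural analysis of a circuit: cooperativity motifs
# (standard two-step and pull-push, with or without a destabilised
# intermediate), reaction-usage classes and the minimal enzyme count.

# slot value (recruiting type, NA for noise) of the reaction s -> t;
# errors if s -> t is not one of the eight reactions
.slot_of <- function(slots, s, t) {
  rt <- reaction_table()
  id <- rt$id[rt$source == s & rt$target == t]
  if (length(id) != 1L) stop("no reaction ", s, " -> ", t)
  unclass(slots)[id]
}

# candidate (driver, intermediate) pairs: intermediates one step from both
# the driver E and its opponent O. For an E-opposite arrangement these are
# the two non-E types; for E-adjacent there are none (the generalised
# definition finds no one-step intermediate between adjacent E types).
.pathway_candidates <- function(arr) {
  out <- list()
  for (E in c(arr$E1, arr$E2)) {
    O <- setdiff(c(arr$E1, arr$E2), E)
    for (I in setdiff(0:3, c(arr$E1, arr$E2))) {
      if (type_distance(O, I) == 1L && type_distance(I, E) == 1L) {
        out[[length(out) + 1L]] <- c(E = E, O = O, I = I)
      }
    }
  }
  out
}

# shared scan over candidate pathways; `second_by` gives the required
# recruiter of the I -> E step ("driver" = E, "intermediate" = I)
.scan_pathways <- function(code, arr, second_by,
                           destab_scope = c("non-driver", "attacked-E")) {
  destab_scope <- match.arg(destab_scope)
  slots <- parse_code(code)
  cand <- .pathway_candidates(arr)
  rows <- lapply(cand, function(p) {
    E <- p[["E"]]; O <- p[["O"]]; I <- p[["I"]]
    first <- .slot_of(slots, O, I)
    second <- .slot_of(slots, I, E)
    need <- if (second_by == "driver") E else I
    present <- !is.na(first) && first == E && !is.na(second) && second == need
    if (!present) return(NULL)
    back <- .slot_of(slots, I, O)
    destab <- if (destab_scope == "non-driver") {
      !is.na(back) && back != E
    } else {
      !is.na(back) && back == O
    }
    data.frame(driver = E, opponent = O, intermediate = I,
               over_R = I == arr$R, destabilized = destab)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) {
    return(data.frame(driver = integer(0), opponent = integer(0),
                      intermediate = integer(0), over_R = logical(0),
                      destabilized = logical(0)))
  }
  do.call(rbind, rows)
}

#' Standard two-step positive-feedback pathways of a circuit
#'
#' A standard two-step pathway toward an E type over intermediate I is
#' present when E recruits both the attack on its opponent (`O -> I`) and
#' its own creation from the intermediate (`I -> E`). Successive action of
#' two E nucleosomes makes the feedback quadratic in the E count
#' (two-step cooperativity). Each pathway is annotated with whether it runs
#' over the replication-inserted type R and whether its intermediate is
#' destabilised (see [detect_destabilization()]).
#'
#' @param code code string or `circuit_code`.
#' @param arr an [arrangement()].
#' @param destab_scope `"non-driver"` (default): the back-reaction
#'   `I -> O` counts as destabilising when recruited by any type other than
#'   the driver; `"attacked-E"`: only when recruited by the attacked E type
#'   (sensitivity diagnostic).
#' @return A data.frame with one row per pathway: `driver`, `opponent`,
#'   `intermediate`, `over_R`, `destabilized` (0 to 4 rows).
#' @examples
#' count_standard_two_step("00033033", standard_arrangement("e-opposite-r-out"))
#' @export
count_standard_two_step <- function(code, arr, destab_scope = "non-driver") {
  .scan_pathways(code, arr, second_by = "driver", destab_scope = destab_scope)
}

#' Pull-push positive-feedback pathways of a circuit
#'
#' In a pull-push pathway toward an E type, E recruits the attack
#' converting its opponent into an intermediate (`O -> I` by E) and the
#' intermediate recruits the conversion of its own type into E (`I -> E`
#' by I). E thereby creates both the recruiter and the target of its own
#' creation reaction, again giving two-step cooperativity.
#'
#' @inheritParams count_standard_two_step
#' @return A data.frame as in [count_standard_two_step()].
#' @export
count_pull_push <- function(code, arr, destab_scope = "non-driver") {
  .scan_pathways(code, arr, second_by = "intermediate",
                 destab_scope = destab_scope)
}

#' Is a standard two-step pathway's intermediate destabilised?
#'
#' The intermediate of a cooperativity pathway is destabilised when the
#' back-reaction `I -> O` (intermediate to the attacked E type) is
#' recruited. This "loss" term is what makes the intermediate occupancy,
#' and hence the feedback, ultrasensitive -- but only when the loss is not
#' catalysed by enzymes recruited by the driving E type itself, so the
#' driver-recruited case is excluded.
#'
#' @inheritParams count_standard_two_step
#' @param driver,intermediate the pathway to check; must be a standard
#'   two-step pathway of `code` (error otherwise).
#' @return `TRUE` or `FALSE`.
#' @examples
#' arr <- standard_arrangement("e-opposite-r-out")
#' detect_destabilization("x003xx3x", arr, driver = 0, intermediate = 2)
#' @export
detect_destabilization <- function(code, arr, driver, intermediate,
                                   destab_scope = "non-driver") {
  paths <- count_standard_two_step(code, arr, destab_scope = destab_scope)
  hit <- paths$driver == driver & paths$intermediate == intermediate
  if (!any(hit)) {
    stop("(driver ", driver, ", intermediate ", intermediate,
         ") is not a standard two-step pathway of this circuit")
  }
  paths$destabilized[hit]
}

#' Minimal number of recruited enzymes
#'
#' Two recruited reactions can be served by a single enzyme when they share
#' the recruiting type, the modified histone position and the add/remove
#' direction -- the enzyme then modifies that position regardless of the
#' other position's state. The minimal enzyme count is the number of
#' distinct (recruiter, position, direction) triples.
#'
#' @param code code string or `circuit_code`.
#' @return Integer between `ceiling(n_recruited/2)` and `n_recruited`.
#' @examples
#' minimal_enzymes("00033033")  # 8 recruited reactions, 4 enzymes
#' @export
minimal_enzymes <- function(code) {
  slots <- parse_code(code)
  rt <- reaction_table()
  keep <- !is.na(slots)
  if (!any(keep)) return(0L)
  length(unique(paste(unclass(slots)[keep], rt$position[keep],
                      rt$direction[keep])))
}

#' Reaction-usage profile of a circuit
#'
#' Counts, for each E type, the recruited reactions moving toward it
#' (target strictly closer to it than the source) that it recruits itself,
#' and the recruited reactions moving away from it that it recruits; also
#' flags self-destruction (a type recruiting a reaction whose source is its
#' own type), separately for E types and intermediates.
#'
#' @param code code string or `circuit_code`.
#' @param arr an [arrangement()].
#' @return A list: `toward` (named counts for E1, E2), `away`,
#'   `e_self_destruction`, `intermediate_self_destruction`.
#' @export
usage_profile <- function(code, arr) {
  slots <- unclass(parse_code(code))
  rt <- reaction_table()
  toward <- away <- c(E1 = 0L, E2 = 0L)
  for (nm in c("E1", "E2")) {
    E <- arr[[nm]]
    to_E <- type_distance_vec(rt$target, E) < type_distance_vec(rt$source, E)
    toward[nm] <- sum(!is.na(slots) & slots == E & to_E)
    away[nm] <- sum(!is.na(slots) & slots == E & !to_E)
  }
  self_destr <- !is.na(slots) & slots == rt$source
  list(
    toward = toward,
    away = away,
    e_self_destruction = any(self_destr & rt$source %in% c(arr$E1, arr$E2)),
    intermediate_self_destruction = any(self_destr &
                                          rt$source %in% arr$intermediates)
  )
}

# vectorised type distance (internal)
type_distance_vec <- function(a, b) {
  x <- bitwXor(as.integer(a), as.integer(b))
  (x %% 2L) + (x %/% 2L)
}

#' Recruited feedback paths of arbitrary length
#'
#' Depth-first enumeration of reaction paths from type `from` to type `to`
#' in which every step is recruited by `driver`, visiting no type twice.
#' Generalises the two-step pathway notion (e.g. 3-step feedback in
#' E-adjacent circuits).
#'
#' @param code code string or `circuit_code`.
#' @param driver recruiting type whose enzymes must carry every step.
#' @param from,to start and end types.
#' @param max_len maximum number of reaction steps.
#' @return A list of integer type paths (each starting at `from` and ending
#'   at `to`), possibly empty.
#' @export
feedback_paths <- function(code, driver, from, to, max_len = 3) {
  slots <- unclass(parse_code(code))
  rt <- reaction_table()
  edges <- rt[!is.na(slots) & slots == driver, , drop = FALSE]
  paths <- list()
  walk <- function(path) {
    here <- path[length(path)]
    if (here == to && length(path) > 1L) {
      paths[[length(paths) + 1L]] <<- path
      return()
    }
    if (length(path) > max_len) return()
    for (nxt in edges$target[edges$source == here]) {
      if (!(nxt %in% path)) walk(c(path, nxt))
    }
  }
  walk(from)
  paths
}

#' Full motif report for a circuit
#'
#' Assembles the structural summary used by the screen: recruited-reaction
#' count, toward/away usage, standard two-step and pull-push pathway
#' tables with destabilisation flags, and the minimal enzyme count.
#'
#' @inheritParams count_standard_two_step
#' @return A `motif_report` list.
#' @export
motif_report <- function(code, arr, destab_scope = "non-driver") {
  slots <- parse_code(code)
  std <- count_standard_two_step(slots, arr, destab_scope)
  pp <- count_pull_push(slots, arr, destab_scope)
  prof <- usage_profile(slots, arr)
  structure(
    list(
      code = as.character(slots),
      arrangement = arr,
      n_recruited = n_recruited(slots),
      toward = prof$toward,
      away = prof$away,
      e_self_destruction = prof$e_self_destruction,
      intermediate_self_destruction = prof$intermediate_self_destruction,
      std_two_step = std,
      pull_push = pp,
      n_std_two_step = nrow(std),
      n_std_destabilized = sum(std$destabilized),
      n_pull_push = nrow(pp),
      n_pp_destabilized = sum(pp$destabilized),
      min_enzymes = minimal_enzymes(slots)
    ),
    class = "motif_report"
  )
}

#' @export
print.motif_report <- function(x, ...) {
  cat("<motif_report> ", x$code, "\n",
      "  recruited reactions: ", x$n_recruited,
      "  minimal enzymes: ", x$min_enzymes, "\n",
      "  standard two-step: ", x$n_std_two_step,
      " (", x$n_std_destabilized, " destabilized)\n",
      "  pull-push: ", x$n_pull_push,
      " (", x$n_pp_destabilized, " destabilized)\n", sep = "")
  invisible(x)
}
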