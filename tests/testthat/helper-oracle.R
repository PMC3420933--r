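# Independent brute-force oracles for the motif detectors, written from the
# definitions alone. The slot table is typed out literally (source, target
# per slot) rather than taken from reaction_table(), so the two routes share
# only the documented code-string convention.

ORACLE_SRC <- c(1, 2, 3, 0, 0, 3, 2, 1)
ORACLE_TGT <- c(0, 0, 2, 2, 1, 1, 3, 3)

# slot character of the reaction s -> t in a split code string
oracle_slot_char <- function(chars, s, t) {
  i <- which(ORACLE_SRC == s & ORACLE_TGT == t)
  stopifnot(length(i) == 1)
  chars[i]
}

# every (driver, intermediate) standard two-step pathway by direct definition
oracle_std_two_step <- function(code_str, E1 = 0, E2 = 3, Rtype = 2,
                                scope = "non-driver") {
  chars <- strsplit(code_str, "")[[1]]
  out <- NULL
  for (E in c(E1, E2)) {
    O <- if (E == E1) E2 else E1
    for (I in setdiff(0:3, c(E1, E2))) {
      # only intermediates one step from both ends qualify
      d <- function(a, b) sum(c(a %% 2 != b %% 2, a %/% 2 != b %/% 2))
      if (d(O, I) != 1 || d(I, E) != 1) next
      if (oracle_slot_char(chars, O, I) == as.character(E) &&
          oracle_slot_char(chars, I, E) == as.character(E)) {
        back <- oracle_slot_char(chars, I, O)
        destab <- if (scope == "non-driver") {
          back != "x" && back != as.character(E)
        } else {
          back == as.character(O)
        }
        out <- rbind(out, data.frame(driver = E, intermediate = I,
                                     over_R = I == Rtype,
                                     destabilized = destab))
      }
    }
  }
  if (is.null(out)) {
    data.frame(driver = integer(0), intermediate = integer(0),
               over_R = logical(0), destabilized = logical(0))
  } else out
}

# every (driver, intermediate) pull-push pathway by direct definition
oracle_pull_push <- function(code_str, E1 = 0, E2 = 3, Rtype = 2,
                             scope = "non-driver") {
  chars <- strsplit(code_str, "")[[1]]
  out <- NULL
  for (E in c(E1, E2)) {
    O <- if (E == E1) E2 else E1
    for (I in setdiff(0:3, c(E1, E2))) {
      d <- function(a, b) sum(c(a %% 2 != b %% 2, a %/% 2 != b %/% 2))
      if (d(O, I) != 1 || d(I, E) != 1) next
      if (oracle_slot_char(chars, O, I) == as.character(E) &&
          oracle_slot_char(chars, I, E) == as.character(I)) {
        back <- oracle_slot_char(chars, I, O)
        destab <- if (scope == "non-driver") {
          back != "x" && back != as.character(E)
        } else {
          back == as.character(O)
        }
        out <- rbind(out, data.frame(driver = E, intermediate = I,
                                     over_R = I == Rtype,
                                     destabilized = destab))
      }
    }
  }
  if (is.null(out)) {
    data.frame(driver = integer(0), intermediate = integer(0),
               over_R = logical(0), destabilized = logical(0))
  } else out
}

# minimal enzymes: group recruited slots by (recruiter, changed position,
# add/remove), derived from the bits of source and target
oracle_min_enzymes <- function(code_str) {
  chars <- strsplit(code_str, "")[[1]]
  keys <- character(0)
  for (i in 1:8) {
    if (chars[i] == "x") next
    s <- ORACLE_SRC[i]; t <- ORACLE_TGT[i]
    pos <- if (s %% 2 != t %% 2) 1 else 2
    bit_s <- if (pos == 1) s %% 2 else s %/% 2
    dir <- if (bit_s == 0) "add" else "remove"
    keys <- c(keys, paste(chars[i], pos, dir))
  }
  length(unique(keys))
}

random_code <- function() {
  paste(sample(c("0", "1", "2", "3", "x"), 8, replace = TRUE), collapse = "")
}

# small hand-made trajectory builder
make_traj <- function(n_E1, n_E2, run = 1L) {
  data.frame(run = rep(run, length.out = length(n_E1)),
             init = "E1", gen = seq_along(n_E1),
             n_E1 = n_E1, n_E2 = n_E2, stringsAsFactors = FALSE)
}
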