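# Nucleosome types, the fixed interconversion-reaction table, circuit codes,
# E1/E2/R arrangements and the two relabelling symmetries.

# Type index convention: index = pos1 + 2*pos2, i.e. 0 = 00, 1 = 10, 2 = 01,
# 3 = 11 (pos1 is the first printed digit).

#' Nucleosome type table
#'
#' The four half-nucleosome modification states of the two-position histone
#' code. Each type carries one bit per histone position; the integer index is
#' `pos1 + 2*pos2`, so 0 = "00", 1 = "10", 2 = "01", 3 = "11".
#'
#' @return A data.frame with columns `index`, `pos1`, `pos2`, `label`.
#' @examples
#' nuc_types()
#' @export
nuc_types <- function() {
  idx <- 0:3
  data.frame(
    index = idx,
    pos1 = idx %% 2L,
    pos2 = idx %/% 2L,
    label = sprintf("%d%d", idx %% 2L, idx %/% 2L),
    stringsAsFactors = FALSE
  )
}

#' Hamming-neighbour types of a nucleosome type
#'
#' Each type has exactly two neighbours, reached by flipping the modification
#' bit at position 1 or position 2. The first element is always the
#' position-1 flip.
#'
#' @param type integer type index in 0..3.
#' @return Integer vector of length 2.
#' @examples
#' neighbor_types(0) # 1 (10) and 2 (01)
#' @export
neighbor_types <- function(type) {
  stopifnot(length(type) == 1L, type %in% 0:3)
  c(bitwXor(as.integer(type), 1L), bitwXor(as.integer(type), 2L))
}

#' Hamming distance between two nucleosome types
#'
#' @param a,b integer type indices in 0..3.
#' @return 0, 1 or 2 (number of differing modification positions).
#' @export
type_distance <- function(a, b) {
  stopifnot(a %in% 0:3, b %in% 0:3)
  x <- bitwXor(as.integer(a), as.integer(b))
  (x %% 2L) + (x %/% 2L)
}

#' The fixed table of the eight interconversion reactions
#'
#' Every directed edge of the 2-bit modification hypercube appears exactly
#' once. Reactions 1, 2, 3, 6 move toward type 0 (demodification when E1 = 0)
#' and reactions 4, 5, 7, 8 move toward type 3. The slot order is the order
#' in which circuit-code characters are read.
#'
#' @return A data.frame with columns `id`, `source`, `target`, `position`
#'   (which histone position changes) and `direction` (`"add"` or
#'   `"remove"`).
#' @examples
#' reaction_table()
#' @export
reaction_table <- function() {
  data.frame(
    id = 1:8,
    source = c(1L, 2L, 3L, 0L, 0L, 3L, 2L, 1L),
    target = c(0L, 0L, 2L, 2L, 1L, 1L, 3L, 3L),
    position = c(1L, 2L, 1L, 2L, 1L, 2L, 1L, 2L),
    direction = c("remove", "remove", "remove", "add",
                  "add", "remove", "add", "add"),
    stringsAsFactors = FALSE
  )
}

# slot permutations induced by the two type relabellings; entry i is the
# reaction that reaction i maps onto.
.COMPLEMENT_PERM <- c(7L, 8L, 5L, 6L, 3L, 4L, 1L, 2L)
.POSSWAP_PERM <- c(2L, 1L, 6L, 5L, 4L, 3L, 8L, 7L)
.POSSWAP_VALUE <- c(0L, 2L, 1L, 3L) # value map under 1 <-> 2, indexed by t+1

#' Parse a circuit code
#'
#' A circuit code is an 8-character string over `{0,1,2,3,x}`; character i
#' names the nucleosome type recruiting the enzyme for reaction i of
#' [reaction_table()], or `x` for a noise-only (non-recruited) reaction.
#' `x` is accepted case-insensitively.
#'
#' @param text an 8-character code string, or a `circuit_code` object
#'   (returned unchanged).
#' @return A `circuit_code` object: an integer vector of length 8 with `NA`
#'   marking noise-only slots.
#' @examples
#' parse_code("00033033")  # the consensus circuit
#' parse_code("x003xx3x")  # the classical circuit
#' @export
parse_code <- function(text) {
  if (inherits(text, "circuit_code")) return(text)
  stopifnot(is.character(text), length(text) == 1L)
  if (nchar(text) != 8L) {
    stop("circuit code must have exactly 8 characters, got ", nchar(text))
  }
  chars <- tolower(strsplit(text, "")[[1]])
  ok <- chars %in% c("0", "1", "2", "3", "x")
  if (!all(ok)) {
    stop("illegal circuit-code character '", chars[which(!ok)[1]],
         "' at position ", which(!ok)[1])
  }
  slots <- suppressWarnings(as.integer(chars))
  structure(slots, class = "circuit_code")
}

#' @export
as.character.circuit_code <- function(x, ...) {
  chars <- ifelse(is.na(x), "x", as.character(unclass(x)))
  paste(chars, collapse = "")
}

#' @export
format.circuit_code <- function(x, ...) as.character(x)

#' @export
print.circuit_code <- function(x, ...) {
  cat("<circuit_code> ", as.character(x), "  (",
      sum(!is.na(x)), " recruited reactions)\n", sep = "")
  invisible(x)
}

#' Number of recruited (non-noise) reactions in a code
#'
#' @param code code string or `circuit_code`.
#' @return Integer count of non-`x` slots.
#' @export
n_recruited <- function(code) {
  sum(!is.na(parse_code(code)))
}

#' Reactions a recruiter type can apply to a substrate type
#'
#' Returns every reaction whose slot is assigned to `recruiter` and whose
#' source type is `substrate`; a recruiter can catalyse 0, 1 or 2 reactions
#' on a given substrate.
#'
#' @param code code string or `circuit_code`.
#' @param recruiter,substrate type indices in 0..3.
#' @return Subset of [reaction_table()] rows (possibly empty).
#' @examples
#' applicable_reactions("00033033", recruiter = 0, substrate = 3)
#' @export
applicable_reactions <- function(code, recruiter, substrate) {
  stopifnot(recruiter %in% 0:3, substrate %in% 0:3)
  slots <- parse_code(code)
  rt <- reaction_table()
  hit <- !is.na(slots) & slots == recruiter & rt$source == substrate
  rt[hit, , drop = FALSE]
}

#' Symmetry twin under type complementation
#'
#' Applies the relabelling `t -> 3 - t` (swap the roles of the two opposite
#' E types and of the two intermediates). Slot values are complemented and
#' slots are permuted by the induced reaction map (1<->7, 2<->8, 3<->5,
#' 4<->6). An involution; the consensus circuit is a fixed point.
#'
#' @param code code string or `circuit_code`.
#' @return A `circuit_code`.
#' @examples
#' as.character(complement_twin("x003xx3x")) # "0xxx30x3", the reverse classical
#' @export
complement_twin <- function(code) {
  slots <- parse_code(code)
  out <- rep(NA_integer_, 8L)
  out[.COMPLEMENT_PERM] <- 3L - unclass(slots)
  structure(out, class = "circuit_code")
}

#' Symmetry twin under histone-position exchange
#'
#' Applies the relabelling that exchanges the two histone positions
#' (types 1 <-> 2; 0 and 3 fixed). Slot values 1 and 2 are swapped and slots
#' are permuted by the induced reaction map (1<->2, 3<->6, 4<->5, 7<->8).
#' An involution; exchanges the two intermediates of an E-opposite
#' arrangement (equivalently, the two possible R-out choices of R).
#'
#' @param code code string or `circuit_code`.
#' @return A `circuit_code`.
#' @export
position_swap_twin <- function(code) {
  slots <- parse_code(code)
  v <- unclass(slots)
  mapped <- ifelse(is.na(v), NA_integer_, .POSSWAP_VALUE[v + 1L])
  out <- rep(NA_integer_, 8L)
  out[.POSSWAP_PERM] <- mapped
  structure(out, class = "circuit_code")
}

#' Within-arrangement symmetry twin (E-role swap)
#'
#' The composition of [complement_twin()] and [position_swap_twin()]: the
#' relabelling `0 <-> 3` that swaps the two E types of the standard
#' E-opposite arrangement while fixing both intermediates, and hence the
#' R type of an R-out arrangement. This is the symmetry under which a
#' fixed-arrangement screen's working set is closed (up to Monte-Carlo
#' noise): the "symmetrical twin" of a working circuit.
#'
#' @param code code string or `circuit_code`.
#' @return A `circuit_code`.
#' @examples
#' as.character(e_swap_twin("x003xx3x"))  # the classical circuit is its own twin
#' @export
e_swap_twin <- function(code) {
  position_swap_twin(complement_twin(code))
}

#' Symmetry orbit of a circuit code
#'
#' The orbit of `code` under the group generated by [complement_twin()] and
#' [position_swap_twin()] (order at most 4).
#'
#' @param code code string or `circuit_code`.
#' @return Character vector of 1, 2 or 4 distinct code strings.
#' @export
code_orbit <- function(code) {
  c0 <- as.character(parse_code(code))
  cc <- as.character(complement_twin(c0))
  cp <- as.character(position_swap_twin(c0))
  ccp <- as.character(position_swap_twin(cc))
  unique(c(c0, cc, cp, ccp))
}

#' Define an E1/E2/R arrangement
#'
#' An arrangement assigns the two epigenetically read types E1 and E2 and
#' the type R inserted on newly replicated DNA. It is `E-opposite` when E1
#' and E2 differ at both histone positions, else `E-adjacent`; `R-in` when R
#' is one of the E types, else `R-out`.
#'
#' @param E1,E2,R nucleosome type indices in 0..3 (`E1 != E2`).
#' @return An `arrangement` object (list with `E1`, `E2`, `R`, `category`,
#'   `intermediates` = the non-E types).
#' @examples
#' arrangement(0, 3, 2)  # the standard E-opposite/R-out screen arrangement
#' @export
arrangement <- function(E1, E2, R) {
  stopifnot(E1 %in% 0:3, E2 %in% 0:3, R %in% 0:3)
  E1 <- as.integer(E1); E2 <- as.integer(E2); R <- as.integer(R)
  if (E1 == E2) stop("E1 and E2 must be distinct nucleosome types")
  e_rel <- if (type_distance(E1, E2) == 2L) "E-opposite" else "E-adjacent"
  r_rel <- if (R %in% c(E1, E2)) "R-in" else "R-out"
  structure(
    list(
      E1 = E1, E2 = E2, R = R,
      category = paste(e_rel, r_rel, sep = "/"),
      intermediates = setdiff(0:3, c(E1, E2))
    ),
    class = "arrangement"
  )
}

#' @export
print.arrangement <- function(x, ...) {
  cat("<arrangement> E1=", x$E1, " E2=", x$E2, " R=", x$R,
      "  [", x$category, "]\n", sep = "")
  invisible(x)
}

#' Standard named arrangements
#'
#' The four canonical E1/E2/R assignments used in the exhaustive screens,
#' with E1 = 0. The E-opposite/R-out default places R on the intermediate
#' the classical circuit's two-step pathway runs over (type 01, index 2);
#' the position-swapped choice R = 1 gives an equivalent screen by
#' [position_swap_twin()] symmetry.
#'
#' @param name one of `"e-opposite-r-out"`, `"e-opposite-r-in"`,
#'   `"e-adjacent-r-out"`, `"e-adjacent-r-in"`.
#' @return An [arrangement()].
#' @export
standard_arrangement <- function(name = c("e-opposite-r-out", "e-opposite-r-in",
                                          "e-adjacent-r-out", "e-adjacent-r-in")) {
  name <- match.arg(name)
  switch(name,
    "e-opposite-r-out" = arrangement(0, 3, 2),
    "e-opposite-r-in"  = arrangement(0, 3, 0),
    "e-adjacent-r-out" = arrangement(0, 1, 2),
    "e-adjacent-r-in"  = arrangement(0, 1, 0)
  )
}
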