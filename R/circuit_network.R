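# Single-mutation (Hamming-1) evolutionary network of working circuits.

#' Hamming distance between two circuit codes
#'
#' Number of slots at which the codes differ; `x` is an ordinary symbol.
#'
#' @param code_a,code_b code strings or `circuit_code` objects.
#' @return Integer in 0..8.
#' @examples
#' hamming_distance("00033033", "x003xx3x")  # 4
#' @export
hamming_distance <- function(code_a, code_b) {
  a <- unclass(parse_code(code_a))
  b <- unclass(parse_code(code_b))
  both_x <- is.na(a) & is.na(b)
  same <- both_x | (!is.na(a) & !is.na(b) & a == b)
  sum(!same)
}

# the 32 single-slot variants of a code
.code_neighbors <- function(code) {
  chars <- strsplit(as.character(parse_code(code)), "")[[1]]
  out <- character(0)
  for (i in 1:8) {
    for (v in setdiff(c("0", "1", "2", "3", "x"), chars[i])) {
      nb <- chars
      nb[i] <- v
      out <- c(out, paste(nb, collapse = ""))
    }
  }
  out
}

#' Build the single-mutation network of circuits
#'
#' Nodes are circuit codes; undirected edges join codes at Hamming
#' distance 1 (one reaction catalysed differently). Node attributes from
#' `attributes` (a data.frame with a `code` column, e.g. a
#' [screen_codes()] result restricted to working circuits) are attached to
#' the vertices.
#'
#' @param codes character vector of deduplicated code strings.
#' @param attributes optional data.frame with a `code` column of vertex
#'   attributes.
#' @return An [igraph::graph] with vertex names = code strings.
#' @examples
#' g <- build_circuit_graph(c("00033033", "x0033033"))
#' igraph::ecount(g)  # 1
#' @export
build_circuit_graph <- function(codes, attributes = NULL) {
  stopifnot(is.character(codes))
  codes <- vapply(codes, function(cd) as.character(parse_code(cd)), character(1))
  names(codes) <- NULL
  if (anyDuplicated(codes)) stop("duplicate circuit codes in node list")
  present <- new.env(hash = TRUE, parent = emptyenv())
  for (cd in codes) assign(cd, TRUE, envir = present)
  from <- character(0); to <- character(0)
  for (cd in codes) {
    for (nb in .code_neighbors(cd)) {
      if (nb > cd && exists(nb, envir = present, inherits = FALSE)) {
        from <- c(from, cd)
        to <- c(to, nb)
      }
    }
  }
  verts <- data.frame(name = codes, stringsAsFactors = FALSE)
  if (!is.null(attributes)) {
    if (!"code" %in% names(attributes)) stop("attributes needs a 'code' column")
    m <- match(codes, attributes$code)
    extra <- attributes[m, setdiff(names(attributes), "code"), drop = FALSE]
    verts <- cbind(verts, extra)
  }
  igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = verts
  )
}

#' Connected components of a circuit graph
#'
#' @param graph from [build_circuit_graph()].
#' @return A list: `n_components`, `sizes` (decreasing), `largest_size`,
#'   `membership` (named by code).
#' @export
graph_components <- function(graph) {
  comp <- igraph::components(graph)
  list(
    n_components = comp$no,
    sizes = sort(comp$csize, decreasing = TRUE),
    largest_size = max(comp$csize),
    membership = comp$membership
  )
}

#' Shortest neutral path between two circuits
#'
#' Shortest path within the working-circuit network, i.e. a sequence of
#' single enzymatic replacements that never leaves the working set.
#'
#' @param graph from [build_circuit_graph()].
#' @param code_a,code_b code strings; must be nodes of `graph`.
#' @return Character vector of codes from `code_a` to `code_b` (length 1
#'   when identical), or an empty character vector with attribute
#'   `disconnected = TRUE` when no path exists.
#' @export
neutral_path <- function(graph, code_a, code_b) {
  code_a <- as.character(parse_code(code_a))
  code_b <- as.character(parse_code(code_b))
  nodes <- igraph::V(graph)$name
  for (cd in c(code_a, code_b)) {
    if (!cd %in% nodes) stop("code ", cd, " is not a node of the graph")
  }
  if (code_a == code_b) return(code_a)
  sp <- suppressWarnings(
    igraph::shortest_paths(graph, from = code_a, to = code_b, output = "vpath")
  )
  path <- sp$vpath[[1]]
  if (length(path) == 0L) {
    return(structure(character(0), disconnected = TRUE))
  }
  igraph::as_ids(path)
}

#' Export a circuit graph
#'
#' @param graph from [build_circuit_graph()].
#' @param path output file.
#' @param format `"graphml"` or `"edgelist"` (tab-separated code pairs).
#' @return `path`, invisibly.
#' @export
export_graph <- function(graph, path, format = c("graphml", "edgelist")) {
  format <- match.arg(format)
  if (format == "graphml") {
    igraph::write_graph(graph, path, format = "graphml")
  } else {
    el <- igraph::as_edgelist(graph)
    utils::write.table(el, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = c("from", "to"))
  }
  invisible(path)
}
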