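# Deterministic small fixtures for tests and examples.

#' Generate a small deterministic fixture
#'
#' Writes one of three text fixtures: a classical-circuit trajectory TSV
#' (`"trajectory"`), a restricted 625-code screen CSV over the
#' classical-containing subspace at reduced depth (`"screen-sample"`), or a
#' 5-node toy Hamming-1 graph edge list (`"graph-toy"`). Byte-identical for
#' a given seed.
#'
#' @param kind one of `"trajectory"`, `"screen-sample"`, `"graph-toy"`.
#' @param seed integer seed.
#' @param dir output directory (created if needed).
#' @return Path of the written file, invisibly.
#' @export
make_fixture <- function(kind, seed = 1, dir = tempdir()) {
  kinds <- c("trajectory", "screen-sample", "graph-toy")
  if (!kind %in% kinds) {
    stop("unknown fixture kind '", kind, "'; valid kinds: ",
         paste(kinds, collapse = ", "))
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  arr <- standard_arrangement("e-opposite-r-out")
  path <- switch(kind,
    "trajectory" = {
      p <- file.path(dir, "classical_trajectory.tsv")
      traj <- run_circuit("x003xx3x", arr,
                          sim_params(gens = 100, repeats = 1, seed = seed))
      write_trajectory(traj, p)
      p
    },
    "screen-sample" = {
      p <- file.path(dir, "screen_sample.csv")
      res <- screen_codes(enumerate_codes("x***xx*x"), arr,
                          sim_params(gens = 25, repeats = 1),
                          seed = seed)
      utils::write.csv(res, p, row.names = FALSE)
      p
    },
    "graph-toy" = {
      p <- file.path(dir, "graph_toy.tsv")
      nodes <- c("00033033", "x0033033", "x003x033", "x003xx33", "x003xx3x")
      g <- build_circuit_graph(nodes)
      export_graph(g, p, format = "edgelist")
      p
    }
  )
  invisible(path)
}
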