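# small graph builders used across the suite

gid <- function(i) sprintf("GO:%07d", i)

toy_graph <- function(child, parent, relation, ns = "CC") {
  ids <- sort(unique(c(child, parent)))
  ontology_graph(
    data.frame(id = ids, name = ids, namespace = ns, stringsAsFactors = FALSE),
    data.frame(child = child, parent = parent, relation = relation,
               stringsAsFactors = FALSE)
  )
}

# a1 -> a2 -> ... -> an (child to parent)
chain_graph <- function(n, relation = "is_a", ns = "CC") {
  toy_graph(gid(seq_len(n - 1)), gid(seq_len(n - 1) + 1L),
            rep(relation, n - 1), ns)
}

# edgeless ontology of n terms (flat term space: basic VSM conditions)
flat_graph <- function(n, ns = "CC") {
  ids <- gid(seq_len(n))
  ontology_graph(
    data.frame(id = ids, name = ids, namespace = ns, stringsAsFactors = FALSE),
    NULL
  )
}

# random small DAG through the package generator
small_dag <- function(seed, n_terms = NULL, p_part_of = 0.3) {
  if (is.null(n_terms)) {
    n_terms <- 3L + (seed %% 10L)   # 3..12 terms
  }
  generate_ontology(fixture_spec(n_terms = n_terms, max_parents = 2L,
                                 p_part_of = p_part_of, seed = seed))
}

non_root_terms <- function(graph, ns = "CC") {
  setdiff(graph$terms$id[graph$terms$namespace == ns],
          tryCatch(namespace_root(graph, ns), error = function(e) NA))
}

# parameter settings exercised by the oracle-equivalence checks: the three
# uniform corners plus seeded random corner combinations of {0, default, 1}
oracle_param_sets <- function(n_random = 8L, seed = 1L) {
  defaults <- list(w_is_a = 1, w_part_of = 0.7, w_parent = 0.5,
                   w_child = 0.2, w_incre = 1 / 6, w_r_g = 0.5)
  mk <- function(vals) suppressWarnings(do.call(hvsm_params, vals))
  sets <- list(
    mk(defaults),
    mk(lapply(defaults, function(x) 0)),
    mk(lapply(defaults, function(x) 1))
  )
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  for (i in seq_len(n_random)) {
    vals <- lapply(defaults, function(d) sample(c(0, d, 1), 1L))
    sets[[length(sets) + 1L]] <- mk(vals)
  }
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  sets
}
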