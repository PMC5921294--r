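#' Construct an ontology graph
#'
#' Builds the typed directed acyclic graph (DAG) of GO terms used by every
#' similarity measure in the package. Terms belong to one of the three GO
#' namespaces (BP, CC, MF) and are connected by \code{is_a} and
#' \code{part_of} edges running from child (more specific) to parent (more
#' general). Any other relationship type is outside the model and must be
#' removed before construction (\code{\link{parse_obo}} does this).
#'
#' @param terms data.frame with columns \code{id}, \code{name},
#'   \code{namespace} (one of \code{"BP"}, \code{"CC"}, \code{"MF"}).
#' @param edges data.frame with columns \code{child}, \code{parent},
#'   \code{relation} (one of \code{"is_a"}, \code{"part_of"}). May have zero
#'   rows.
#' @param alt_ids named character vector mapping secondary accessions to
#'   canonical term ids (may be empty).
#' @return An object of class \code{ontology_graph}: a list with elements
#'   \code{terms}, \code{edges}, \code{alt_ids}, \code{roots} (named by
#'   namespace, only where a unique parentless term exists), \code{ns}
#'   (term id to namespace lookup) and precomputed adjacency lists.
#' @details Validation enforces that every edge joins two known terms of the
#'   same namespace, that relations are restricted to is_a/part_of, and that
#'   the subgraph of each relation is acyclic (a violation reports one term
#'   on the cycle).
#' @seealso \code{\link{parse_obo}}, \code{\link{relation_neighbors}},
#'   \code{\link{namespace_root}}
#' @export
ontology_graph <- function(terms, edges, alt_ids = character()) {
  stopifnot(is.data.frame(terms), all(c("id", "name", "namespace") %in% names(terms)))
  terms <- data.frame(
    id = as.character(terms$id),
    name = as.character(terms$name),
    namespace = as.character(terms$namespace),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(terms$id)) {
    stop("duplicate term ids: ", paste(unique(terms$id[duplicated(terms$id)]), collapse = ", "))
  }
  bad_ns <- setdiff(unique(terms$namespace), c("BP", "CC", "MF"))
  if (length(bad_ns)) stop("unknown namespace(s): ", paste(bad_ns, collapse = ", "))

  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(child = character(), parent = character(),
                        relation = character(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(
      child = as.character(edges$child),
      parent = as.character(edges$parent),
      relation = as.character(edges$relation),
      stringsAsFactors = FALSE
    )
  }
  bad_rel <- setdiff(unique(edges$relation), c("is_a", "part_of"))
  if (length(bad_rel)) stop("unknown relation(s): ", paste(bad_rel, collapse = ", "))
  ns <- stats::setNames(terms$namespace, terms$id)
  missing_nodes <- setdiff(unique(c(edges$child, edges$parent)), terms$id)
  if (length(missing_nodes)) {
    stop("edges reference unknown term(s): ", paste(utils::head(missing_nodes, 5), collapse = ", "))
  }
  cross <- ns[edges$child] != ns[edges$parent]
  if (any(cross)) {
    stop("edges join terms from different namespaces: ",
         paste(utils::head(paste(edges$child[cross], edges$parent[cross]), 3), collapse = "; "))
  }
  edges <- unique(edges)

  for (rel in c("is_a", "part_of")) {
    sub <- edges[edges$relation == rel, , drop = FALSE]
    cyc <- .find_cycle_member(sub$child, sub$parent)
    if (!is.na(cyc)) {
      stop("cyclic ", rel, " structure involving term ", cyc)
    }
  }

  up <- list(
    is_a = .adjacency(edges, "is_a", from = "child", to = "parent"),
    part_of = .adjacency(edges, "part_of", from = "child", to = "parent")
  )
  down <- list(
    is_a = .adjacency(edges, "is_a", from = "parent", to = "child"),
    part_of = .adjacency(edges, "part_of", from = "parent", to = "child")
  )

  alt_ids <- alt_ids[!names(alt_ids) %in% terms$id]
  if (length(alt_ids)) alt_ids <- stats::setNames(as.character(alt_ids), names(alt_ids))

  has_parent <- unique(edges$child)
  roots <- character()
  for (nsp in unique(terms$namespace)) {
    cand <- setdiff(terms$id[terms$namespace == nsp], has_parent)
    if (length(cand) == 1L) roots[nsp] <- cand
  }

  structure(
    list(terms = terms, edges = edges, alt_ids = alt_ids, roots = roots,
         ns = ns, up = up, down = down),
    class = "ontology_graph"
  )
}

# Kahn peeling on child->parent arcs; returns NA when acyclic, else one
# member of a cycle.
.find_cycle_member <- function(child, parent) {
  if (!length(child)) return(NA_character_)
  nodes <- unique(c(child, parent))
  outdeg <- table(factor(child, levels = nodes))
  outdeg <- stats::setNames(as.integer(outdeg), nodes)
  preds <- split(child, factor(parent, levels = nodes))
  queue <- nodes[outdeg == 0L]
  seen <- 0L
  while (length(queue)) {
    n <- queue[[1L]]
    queue <- queue[-1L]
    seen <- seen + 1L
    for (p in preds[[n]]) {
      outdeg[[p]] <- outdeg[[p]] - 1L
      if (outdeg[[p]] == 0L) queue <- c(queue, p)
    }
  }
  if (seen == length(nodes)) NA_character_ else sort(nodes[outdeg > 0L])[1L]
}

.adjacency <- function(edges, rel, from, to) {
  sub <- edges[edges$relation == rel, , drop = FALSE]
  if (!nrow(sub)) return(list())
  lapply(split(sub[[to]], sub[[from]]), unique)
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("ontology_graph:", nrow(x$terms), "terms,",
      sum(x$edges$relation == "is_a"), "is_a edges,",
      sum(x$edges$relation == "part_of"), "part_of edges\n")
  tab <- table(x$terms$namespace)
  cat("  namespaces:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' Resolve a possibly secondary term id to its canonical id
#'
#' @param graph an \code{ontology_graph}.
#' @param id term accession, possibly an \code{alt_id}.
#' @return the canonical id, or \code{NA_character_} when unknown.
#' @export
resolve_term <- function(graph, id) {
  out <- ifelse(id %in% graph$terms$id, id,
                ifelse(id %in% names(graph$alt_ids), unname(graph$alt_ids[id]), NA_character_))
  as.character(out)
}

.ns_long <- c(BP = "biological_process", CC = "cellular_component",
              MF = "molecular_function")
.ns_short <- stats::setNames(names(.ns_long), .ns_long)

#' Parse an OBO 1.2/1.4 ontology file
#'
#' Reads the flat-file format distributed by the GO Consortium into an
#' \code{\link{ontology_graph}}. Only the hierarchical relations the model
#' uses are retained: \code{is_a:} tags and \code{relationship: part_of}
#' tags become edges; every other relationship type (regulates, occurs_in,
#' ...) is discarded. Obsolete terms are dropped together with all edges
#' touching them, and the rare cross-namespace part_of edges are dropped so
#' that each namespace remains a self-contained DAG. \code{alt_id} entries
#' are recorded so annotations using secondary accessions still resolve.
#'
#' @param path path to an OBO file.
#' @return an \code{\link{ontology_graph}}.
#' @export
parse_obo <- function(path) {
  if (!file.exists(path)) stop("cannot read OBO file: ", path)
  lines <- readLines(path, warn = FALSE)
  # stanza boundaries
  starts <- grep("^\\[", lines)
  if (!length(starts)) stop("no stanzas found in OBO file: ", path)
  ends <- c(starts[-1L] - 1L, length(lines))
  is_term <- lines[starts] == "[Term]"

  ids <- character(); names_ <- character(); nss <- character()
  alt_from <- character(); alt_to <- character()
  e_child <- character(); e_parent <- character(); e_rel <- character()

  for (k in which(is_term)) {
    block <- lines[(starts[k] + 1L):ends[k]]
    block <- sub("\\s*!.*$", "", block)        # trailing comments
    block <- block[nzchar(trimws(block))]
    tag_val <- regmatches(block, regexpr("^[A-Za-z_]+:", block))
    vals <- trimws(sub("^[A-Za-z_]+:\\s*", "", block))
    tags <- sub(":$", "", tag_val)

    if (any(tags == "is_obsolete" & vals == "true")) next
    id <- vals[tags == "id"][1L]
    if (is.na(id)) next
    nm <- vals[tags == "name"]
    nsl <- vals[tags == "namespace"]
    nsv <- if (length(nsl)) {
      if (nsl[1L] %in% names(.ns_short)) .ns_short[[nsl[1L]]] else nsl[1L]
    } else NA_character_
    ids <- c(ids, id)
    names_ <- c(names_, if (length(nm)) nm[1L] else "")
    nss <- c(nss, nsv)
    for (a in vals[tags == "alt_id"]) {
      alt_from <- c(alt_from, a)
      alt_to <- c(alt_to, id)
    }
    for (p in vals[tags == "is_a"]) {
      e_child <- c(e_child, id); e_parent <- c(e_parent, p); e_rel <- c(e_rel, "is_a")
    }
    rel_lines <- vals[tags == "relationship"]
    for (rl in rel_lines) {
      parts <- strsplit(trimws(rl), "\\s+")[[1L]]
      if (length(parts) >= 2L && parts[1L] == "part_of") {
        e_child <- c(e_child, id); e_parent <- c(e_parent, parts[2L]); e_rel <- c(e_rel, "part_of")
      }
    }
  }

  if (!length(ids)) stop("no usable [Term] stanzas in ", path)
  if (anyNA(nss)) stop("term(s) missing namespace: ",
                       paste(utils::head(ids[is.na(nss)], 5), collapse = ", "))

  terms <- data.frame(id = ids, name = names_, namespace = nss,
                      stringsAsFactors = FALSE)
  # drop edges touching terms absent after obsolete removal, and edges that
  # would cross namespaces
  ns <- stats::setNames(terms$namespace, terms$id)
  keep <- e_child %in% terms$id & e_parent %in% terms$id
  keep[keep] <- ns[e_child[keep]] == ns[e_parent[keep]]
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message("parse_obo: dropped ", n_dropped,
            " edge(s) referencing obsolete, unknown or cross-namespace terms")
  }
  edges <- data.frame(child = e_child[keep], parent = e_parent[keep],
                      relation = e_rel[keep], stringsAsFactors = FALSE)

  dup <- duplicated(alt_from)
  if (any(dup)) {
    warning("alt_id collision(s), keeping first mapping: ",
            paste(unique(alt_from[dup]), collapse = ", "))
  }
  alt_ids <- stats::setNames(alt_to[!dup], alt_from[!dup])

  ontology_graph(terms, edges, alt_ids)
}

#' Write an ontology graph as an OBO file
#'
#' Serialises the parsed term and edge sets back to OBO 1.2 text, the
#' converse of \code{\link{parse_obo}}. Used by the fixture generator so
#' synthetic ontologies are consumable by any OBO-aware tool.
#'
#' @param graph an \code{\link{ontology_graph}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_obo <- function(graph, path) {
  stopifnot(inherits(graph, "ontology_graph"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  ord <- order(graph$terms$id)
  alt_by_term <- if (length(graph$alt_ids)) {
    split(names(graph$alt_ids), graph$alt_ids)
  } else {
    list()
  }
  for (i in ord) {
    id <- graph$terms$id[i]
    out <- c("[Term]",
             paste0("id: ", id),
             paste0("name: ", graph$terms$name[i]),
             paste0("namespace: ", .ns_long[[graph$terms$namespace[i]]]))
    for (a in sort(alt_by_term[[id]])) out <- c(out, paste0("alt_id: ", a))
    e <- graph$edges[graph$edges$child == id, , drop = FALSE]
    e <- e[order(e$relation, e$parent), , drop = FALSE]
    for (j in seq_len(nrow(e))) {
      out <- c(out, if (e$relation[j] == "is_a") paste0("is_a: ", e$parent[j])
               else paste0("relationship: part_of ", e$parent[j]))
    }
    writeLines(c(out, ""), con)
  }
  invisible(path)
}

#' One- and two-step typed neighbourhoods of a term
#'
#' Returns the set of terms reached from \code{term} by exactly \code{steps}
#' edges of a single relation type, either upward (towards parents) or
#' downward (towards children). Two-step queries require both edges to carry
#' the same relation; mixed-relation paths are the concern of the vector
#' expansion's part_of stage, not of this query.
#'
#' @param graph an \code{\link{ontology_graph}}.
#' @param term a term id present in the graph.
#' @param relation \code{"is_a"} or \code{"part_of"}.
#' @param direction \code{"up"} (parents) or \code{"down"} (children).
#' @param steps 1 or 2.
#' @return character vector of term ids (set semantics, sorted, never
#'   containing \code{term} itself).
#' @export
relation_neighbors <- function(graph, term, relation = c("is_a", "part_of"),
                               direction = c("up", "down"), steps = 1L) {
  stopifnot(inherits(graph, "ontology_graph"))
  relation <- match.arg(relation)
  direction <- match.arg(direction)
  steps <- as.integer(steps)
  if (!steps %in% c(1L, 2L)) stop("steps must be 1 or 2")
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  adj <- if (direction == "up") graph$up[[relation]] else graph$down[[relation]]
  one <- adj[[term]]
  if (is.null(one)) one <- character()
  if (steps == 1L) return(sort(one))
  two <- unique(unlist(lapply(one, function(p) adj[[p]]), use.names = FALSE))
  if (is.null(two)) two <- character()
  sort(setdiff(two, term))
}

#' Root term of a namespace
#'
#' The unique term of the namespace with no outgoing is_a or part_of edge.
#' Annotation parsing excludes this term from every gene's set, since being
#' annotated only to the root carries no functional information.
#'
#' @param graph an \code{\link{ontology_graph}}.
#' @param namespace \code{"BP"}, \code{"CC"} or \code{"MF"}.
#' @return a term id.
#' @export
namespace_root <- function(graph, namespace = c("BP", "CC", "MF")) {
  stopifnot(inherits(graph, "ontology_graph"))
  namespace <- match.arg(namespace)
  ids <- graph$terms$id[graph$terms$namespace == namespace]
  if (!length(ids)) stop("namespace ", namespace, " is empty")
  has_parent <- unique(graph$edges$child)
  cand <- setdiff(ids, has_parent)
  if (length(cand) != 1L) {
    stop("namespace ", namespace, " has ", length(cand),
         " parentless terms; expected exactly one root")
  }
  cand
}

# Memoised ancestor closure over the chosen relation types. Returns a
# function(term, include_self) -> character vector of ancestor ids.
.ancestor_fun <- function(graph, relations = c("is_a", "part_of")) {
  cache <- new.env(parent = emptyenv())
  adj <- graph$up[relations]
  anc <- function(t) {
    hit <- cache[[t]]
    if (!is.null(hit)) return(hit)
    parents <- unique(unlist(lapply(adj, function(a) a[[t]]), use.names = FALSE))
    if (is.null(parents)) parents <- character()
    res <- unique(c(parents, unlist(lapply(parents, anc), use.names = FALSE)))
    cache[[t]] <- res
    res
  }
  function(term, include_self = FALSE) {
    res <- anc(term)
    if (include_self) unique(c(term, res)) else res
  }
}

#' Ancestors of a term
#'
#' Transitive closure over parents, optionally restricted by relation type.
#'
#' @param graph an \code{\link{ontology_graph}}.
#' @param term a term id present in the graph.
#' @param relations relation types to traverse (default both).
#' @param include_self whether to include \code{term} itself.
#' @return character vector of term ids.
#' @export
term_ancestors <- function(graph, term, relations = c("is_a", "part_of"),
                           include_self = FALSE) {
  if (!term %in% graph$terms$id) stop("unknown term: ", term)
  .ancestor_fun(graph, relations)(term, include_self)
}
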