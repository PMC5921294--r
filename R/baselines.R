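#' Information content of ontology terms from an annotation corpus
#'
#' For each term, counts the genes annotated to it or to any of its
#' descendants (propagation over both is_a and part_of), turns the counts
#' into occurrence probabilities relative to the namespace root, and takes
#' the negative natural log. The loaded annotation set is the corpus; terms
#' no gene reaches are omitted.
#'
#' @param ann an \code{\link{annotation_set}} (nonempty).
#' @param graph an \code{\link{ontology_graph}}.
#' @return an object of class \code{ic_table}: list with \code{namespace},
#'   \code{p} (term -> probability in (0,1], \code{p(root) = 1}) and
#'   \code{ic} (term -> nats, \code{ic(root) = 0}).
#' @export
compute_ic <- function(ann, graph) {
  stopifnot(inherits(ann, "annotation_set"), inherits(graph, "ontology_graph"))
  if (!length(ann$gene_terms)) stop("empty annotation corpus")
  anc <- .ancestor_fun(graph)
  counts <- new.env(parent = emptyenv())
  for (tset in ann$gene_terms) {
    reached <- unique(unlist(lapply(tset, anc, include_self = TRUE),
                             use.names = FALSE))
    for (t in reached) {
      counts[[t]] <- (counts[[t]] %||% 0L) + 1L
    }
  }
  ids <- ls(counts)
  n <- vapply(ids, function(t) counts[[t]], integer(1))
  root <- namespace_root(graph, ann$namespace)
  n_root <- counts[[root]] %||% 0L
  if (n_root == 0L) stop("no annotation reaches the namespace root")
  p <- n / n_root
  structure(
    list(namespace = ann$namespace, p = p, ic = -log(p)),
    class = "ic_table"
  )
}

#' @export
print.ic_table <- function(x, ...) {
  cat("ic_table:", length(x$ic), x$namespace, "terms, max IC",
      sprintf("%.3f", max(x$ic)), "nats\n")
  invisible(x)
}

#' Basic vector space model similarity
#'
#' Cosine of the two binary annotation vectors:
#' \code{|intersection| / sqrt(|A| |B|)}. The flat baseline the hierarchical
#' model improves on — related but disjoint term sets score 0 here.
#'
#' @param terms1,terms2 nonempty character vectors of term ids.
#' @return a score in [0, 1].
#' @export
vsm_similarity <- function(terms1, terms2) {
  terms1 <- unique(terms1); terms2 <- unique(terms2)
  if (!length(terms1) || !length(terms2)) stop("empty term set")
  length(intersect(terms1, terms2)) / sqrt(length(terms1) * length(terms2))
}

#' Set-based Jaccard and Dice similarity
#'
#' Tversky ratio-model instances with set cardinality as the additive
#' function: Jaccard is \code{|A&B|/|A|B|} union, Dice is
#' \code{2|A&B|/(|A|+|B|)}.
#'
#' @param terms1,terms2 nonempty character vectors of term ids.
#' @param method \code{"jaccard"} or \code{"dice"}.
#' @return a score in [0, 1].
#' @export
set_similarity <- function(terms1, terms2, method = c("jaccard", "dice")) {
  method <- match.arg(method)
  terms1 <- unique(terms1); terms2 <- unique(terms2)
  if (!length(terms1) || !length(terms2)) stop("empty term set")
  ni <- length(intersect(terms1, terms2))
  if (method == "jaccard") ni / length(union(terms1, terms2))
  else 2 * ni / (length(terms1) + length(terms2))
}

#' Information-content term-pair similarity
#'
#' Classic IC-based measures built on the most informative common ancestor
#' (MICA): the common ancestor (over both relations, a term counting as its
#' own ancestor) of maximal IC.
#' \itemize{
#'   \item \code{resnik}: \code{IC(MICA)}
#'   \item \code{lin}: \code{2 IC(MICA) / (IC(t1) + IC(t2))}, 0 when the
#'     denominator is 0
#'   \item \code{jiang}: distance \code{IC(t1) + IC(t2) - 2 IC(MICA)},
#'     reported as the bounded similarity \code{1 / (1 + distance)}
#'   \item \code{schlicker}: \code{lin(t1, t2) * (1 - p(MICA))}, the
#'     relevance-weighted Lin score
#' }
#'
#' @param t1,t2 term ids with IC entries.
#' @param ic an \code{\link{compute_ic}} table.
#' @param graph an \code{\link{ontology_graph}}.
#' @param method one of \code{"resnik"}, \code{"lin"}, \code{"jiang"},
#'   \code{"schlicker"}.
#' @return a nonnegative score (resnik in nats; the others in [0, 1]).
#' @export
term_similarity <- function(t1, t2, ic, graph,
                            method = c("resnik", "lin", "jiang", "schlicker")) {
  method <- match.arg(method)
  stopifnot(inherits(ic, "ic_table"), inherits(graph, "ontology_graph"))
  for (t in c(t1, t2)) {
    if (is.na(ic$ic[t])) stop("no IC entry for term ", t)
  }
  mica <- .mica(t1, t2, ic, graph)
  ic_m <- if (is.na(mica)) 0 else unname(ic$ic[mica])
  p_m <- if (is.na(mica)) 1 else unname(ic$p[mica])
  switch(method,
    resnik = ic_m,
    lin = .lin_score(t1, t2, ic_m, ic),
    jiang = {
      dist <- (unname(ic$ic[t1]) + unname(ic$ic[t2])) - 2 * ic_m
      1 / (1 + dist)
    },
    schlicker = .lin_score(t1, t2, ic_m, ic) * (1 - p_m)
  )
}

.lin_score <- function(t1, t2, ic_m, ic) {
  denom <- unname(ic$ic[t1]) + unname(ic$ic[t2])
  if (denom == 0) 0 else 2 * ic_m / denom
}

# most informative common ancestor; NA when the terms share no ancestor
# with an IC entry
.mica <- function(t1, t2, ic, graph) {
  anc <- .ancestor_fun(graph)
  common <- intersect(anc(t1, include_self = TRUE), anc(t2, include_self = TRUE))
  common <- common[!is.na(ic$ic[common])]
  if (!length(common)) return(NA_character_)
  best <- common[ic$ic[common] == max(ic$ic[common])]
  sort(best)[1L]
}

#' Combine a term-pair similarity over two annotation sets
#'
#' Lifts a term-level measure to the gene level. \code{MAX} and \code{AVG}
#' are the maximum and the mean of the full cross matrix; \code{BMA}
#' (best-match average) averages each row's best match, averages each
#' column's best match, and takes the mean of the two.
#'
#' @param terms1,terms2 nonempty character vectors of term ids.
#' @param termfn function of two term ids returning a scalar similarity.
#' @param strategy \code{"max"}, \code{"avg"} or \code{"bma"}.
#' @return a scalar score.
#' @export
combine_pairwise <- function(terms1, terms2, termfn,
                             strategy = c("max", "avg", "bma")) {
  strategy <- match.arg(strategy)
  terms1 <- unique(terms1); terms2 <- unique(terms2)
  if (!length(terms1) || !length(terms2)) stop("empty term set")
  m <- matrix(0, length(terms1), length(terms2))
  for (i in seq_along(terms1)) {
    for (j in seq_along(terms2)) {
      m[i, j] <- termfn(terms1[i], terms2[j])
    }
  }
  switch(strategy,
    max = max(m),
    avg = mean(m),
    bma = (mean(apply(m, 1, max)) + mean(apply(m, 2, max))) / 2
  )
}

#' SimGIC: IC-weighted Jaccard over ancestor-extended annotation sets
#'
#' Each gene's term set is extended with all ancestors (both relations);
#' the score is the summed IC of the intersection over the summed IC of the
#' union. Terms without IC entries contribute zero weight, so sets sharing
#' only the root (IC 0) score 0.
#'
#' @param terms1,terms2 nonempty character vectors of term ids.
#' @param ic an \code{\link{compute_ic}} table.
#' @param graph an \code{\link{ontology_graph}}.
#' @return a score in [0, 1]; 0 when the union carries no IC at all.
#' @export
simgic_similarity <- function(terms1, terms2, ic, graph) {
  stopifnot(inherits(ic, "ic_table"), inherits(graph, "ontology_graph"))
  if (!length(terms1) || !length(terms2)) stop("empty term set")
  anc <- .ancestor_fun(graph)
  ext <- function(ts) unique(unlist(lapply(ts, anc, include_self = TRUE),
                                    use.names = FALSE))
  s1 <- ext(terms1); s2 <- ext(terms2)
  icv <- function(ts) {
    v <- ic$ic[ts]
    sum(v[!is.na(v)])
  }
  denom <- icv(union(s1, s2))
  if (denom == 0) return(0)
  icv(intersect(s1, s2)) / denom
}

#' IntelliGO configuration
#'
#' Evidence-code weights for the IntelliGO vector measure. The default
#' weight of every code is 1; supply a named vector to down-weight, e.g.,
#' electronic annotations.
#'
#' @param evidence_weights named numeric vector of per-evidence-code
#'   weights, all positive.
#' @param default_weight weight of codes not listed (default 1).
#' @return an object of class \code{intelligo_config}.
#' @export
intelligo_config <- function(evidence_weights = numeric(), default_weight = 1) {
  if (length(evidence_weights) && (is.null(names(evidence_weights)) ||
                                   any(evidence_weights <= 0))) {
    stop("evidence_weights must be a named vector of positive weights")
  }
  if (default_weight <= 0) stop("default_weight must be positive")
  structure(list(evidence_weights = evidence_weights,
                 default_weight = default_weight),
            class = "intelligo_config")
}

# minimum edge distance from the namespace root to every reachable term,
# BFS over both relation types
.depth_table <- function(graph, namespace) {
  root <- namespace_root(graph, namespace)
  depth <- stats::setNames(0L, root)
  frontier <- root
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(lapply(frontier, function(t)
      c(graph$down$is_a[[t]], graph$down$part_of[[t]])), use.names = FALSE))
    nxt <- setdiff(nxt, names(depth))
    if (length(nxt)) depth[nxt] <- d
    frontier <- nxt
  }
  depth
}

# minimum upward edge distance from term to each of its ancestors
# (including itself at 0), BFS over both relation types
.up_dist <- function(graph, term) {
  dist <- stats::setNames(0L, term)
  frontier <- term
  d <- 0L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(lapply(frontier, function(t)
      c(graph$up$is_a[[t]], graph$up$part_of[[t]])), use.names = FALSE))
    nxt <- setdiff(nxt, names(dist))
    if (length(nxt)) dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

# IntelliGO basis-vector dot product e_i * e_j for two terms: the deepest
# common ancestor is the LCA (ties broken by minimal path length through it,
# then by term id); the dot product relates its depth to the shortest path
# between the terms passing through it. Identical terms give exactly 1; an
# LCA at the root (depth 0) gives 0.
.intelligo_e <- function(t1, t2, graph, depth) {
  if (t1 == t2) return(1)
  d1 <- .up_dist(graph, t1)
  d2 <- .up_dist(graph, t2)
  common <- intersect(names(d1), names(d2))
  common <- common[!is.na(depth[common])]
  if (!length(common)) return(0)
  dmax <- max(depth[common])
  if (dmax == 0L) return(0)
  cand <- common[depth[common] == dmax]
  spl <- d1[cand] + d2[cand]
  lca <- sort(cand[spl == min(spl)])[1L]
  minspl <- unname(d1[lca] + d2[lca])
  2 * dmax / (minspl + 2 * dmax)
}

#' IntelliGO vector-based gene similarity
#'
#' Represents each gene as a weighted sum of term basis vectors with
#' coefficients \code{w(g,t) * IFA(t)}, where \code{w(g,t)} is the
#' evidence-code weight of the annotation and \code{IFA(t) = ln(N / n_t)}
#' is the inverse annotation frequency over the corpus (N genes, n_t of
#' them directly annotated to t). Basis vectors are non-orthogonal: their
#' dot product relates the depth of the two terms' lowest common ancestor
#' to the shortest path between them, so hierarchically related terms
#' contribute. The gene similarity is the cosine under this inner product.
#'
#' @param gene1,gene2 gene ids present in \code{ann}.
#' @param ann an \code{\link{annotation_set}}.
#' @param graph an \code{\link{ontology_graph}}.
#' @param cfg an \code{\link{intelligo_config}}.
#' @return a score in [0, 1].
#' @export
intelligo_similarity <- function(gene1, gene2, ann, graph,
                                 cfg = intelligo_config()) {
  stopifnot(inherits(ann, "annotation_set"), inherits(graph, "ontology_graph"),
            inherits(cfg, "intelligo_config"))
  ts1 <- annotation_lookup(ann, gene1)
  ts2 <- annotation_lookup(ann, gene2)
  if (is.null(ts1) || is.null(ts2)) stop("gene(s) not annotated")
  n_genes <- length(ann$gene_terms)
  n_with <- function(t) sum(vapply(ann$gene_terms, function(x) t %in% x, logical(1)))
  ifa <- function(t) log(n_genes / n_with(t))
  evw <- function(g, t) {
    code <- if (!is.null(ann$evidence)) unname(ann$evidence[[g]][t]) else NA
    if (is.null(code) || is.na(code)) return(cfg$default_weight)
    wv <- cfg$evidence_weights[code]
    if (is.na(wv)) cfg$default_weight else unname(wv)
  }
  alpha <- vapply(ts1, function(t) evw(gene1, t) * ifa(t), numeric(1))
  beta <- vapply(ts2, function(t) evw(gene2, t) * ifa(t), numeric(1))
  depth <- .depth_table(graph, ann$namespace)
  inner <- function(ta, ca, tb, cb) {
    s <- 0
    for (i in seq_along(ta)) {
      for (j in seq_along(tb)) {
        s <- s + ca[i] * cb[j] * .intelligo_e(ta[i], tb[j], graph, depth)
      }
    }
    s
  }
  n1 <- inner(ts1, alpha, ts1, alpha)
  n2 <- inner(ts2, beta, ts2, beta)
  if (n1 <= 0 || n2 <= 0) return(0)
  as.numeric(inner(ts1, alpha, ts2, beta) / (sqrt(n1) * sqrt(n2)))
}
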