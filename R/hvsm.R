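#' Contribution factors of the hierarchical vector space model
#'
#' The six unitless weights controlling how much ancestors and descendants
#' of directly annotated terms contribute to a gene's vector. Defaults are
#' the published trade-off values; the \code{"cessm"} profile lowers
#' \code{w_child} to 0.05, the preset used when scoring CESSM-style protein
#' pair collections.
#'
#' @param w_is_a contribution factor of the is_a relation (default 1).
#' @param w_part_of contribution factor of the part_of relation (default
#'   0.7); part_of is semantically weaker than is_a.
#' @param w_parent factor for direct parents (default 0.5).
#' @param w_child factor for common children (default 0.2); descendants are
#'   less relevant than ancestors.
#' @param w_incre increment factor applied when a component is already
#'   nonzero (default 1/6).
#' @param w_r_g ratio scaling two-step (grandparent/grandchild)
#'   contributions relative to one-step ones (default 0.5).
#' @param profile \code{"default"} or \code{"cessm"}; a profile sets the
#'   baseline values, explicit arguments still override.
#' @return an object of class \code{hvsm_params}.
#' @details All six values must lie in [0,1]. The intended ordering
#'   \code{w_is_a > w_part_of}, \code{w_parent > w_child} and
#'   \code{w_r_g < 1} is checked with a warning, not an error, so parameter
#'   sweeps over the full cube remain possible.
#' @export
hvsm_params <- function(w_is_a = NULL, w_part_of = NULL, w_parent = NULL,
                        w_child = NULL, w_incre = NULL, w_r_g = NULL,
                        profile = c("default", "cessm")) {
  profile <- match.arg(profile)
  p <- list(w_is_a = 1, w_part_of = 0.7, w_parent = 0.5,
            w_child = if (profile == "cessm") 0.05 else 0.2,
            w_incre = 1 / 6, w_r_g = 0.5)
  override <- list(w_is_a = w_is_a, w_part_of = w_part_of, w_parent = w_parent,
                   w_child = w_child, w_incre = w_incre, w_r_g = w_r_g)
  for (nm in names(override)) {
    if (!is.null(override[[nm]])) p[[nm]] <- as.numeric(override[[nm]])
  }
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals < 0) || any(vals > 1)) {
    stop("all contribution factors must lie in [0, 1]")
  }
  if (p$w_is_a <= p$w_part_of) warning("expected w_is_a > w_part_of")
  if (p$w_parent <= p$w_child) warning("expected w_parent > w_child")
  if (p$w_r_g >= 1) warning("expected w_r_g < 1")
  structure(p, class = "hvsm_params")
}

#' Read contribution factors from a key=value config file
#'
#' Lines of the form \code{w_parent = 0.5}; \code{#} comments and blank
#' lines ignored; keys not among the six factors are an error.
#'
#' @param path config file path.
#' @param profile base profile the file's values override.
#' @return an \code{\link{hvsm_params}} object.
#' @export
read_hvsm_params <- function(path, profile = "default") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- lines[grepl("=", lines, fixed = TRUE)]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- as.numeric(trimws(sub("^[^=]*=", "", lines)))
  known <- c("w_is_a", "w_part_of", "w_parent", "w_child", "w_incre", "w_r_g")
  bad <- setdiff(keys, known)
  if (length(bad)) stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  args <- stats::setNames(as.list(vals), keys)
  args$profile <- profile
  do.call(hvsm_params, args)
}

#' @export
print.hvsm_params <- function(x, ...) {
  cat("hvsm_params:", paste(sprintf("%s=%.4g", names(unclass(x)), unlist(x)),
                            collapse = ", "), "\n")
  invisible(x)
}

# Two-step upward/downward neighbourhoods for the part_of stage: all
# two-edge paths containing at least one part_of edge (pure is_a two-step
# paths belong to the is_a stage).
.two_step_mixed_part_of <- function(graph, term, direction) {
  adj <- if (direction == "up") graph$up else graph$down
  g1_isa <- adj$is_a[[term]]
  g1_part <- adj$part_of[[term]]
  out <- c(
    unlist(lapply(g1_isa, function(p) adj$part_of[[p]]), use.names = FALSE),
    unlist(lapply(g1_part, function(p) c(adj$is_a[[p]], adj$part_of[[p]])),
           use.names = FALSE)
  )
  setdiff(unique(out), term)
}

.two_step_same <- function(graph, term, relation, direction) {
  adj <- if (direction == "up") graph$up[[relation]] else graph$down[[relation]]
  one <- adj[[term]]
  setdiff(unique(unlist(lapply(one, function(p) adj[[p]]), use.names = FALSE)), term)
}

#' Build the expanded HVSM vector of one gene
#'
#' Starting from the binary vector of directly annotated terms (each at
#' weight 1), the expansion runs two relation stages — first is_a, then
#' part_of — and within each stage four steps in order: (i) direct parents,
#' (ii) grandparents, (iii) children common to at least two annotated terms,
#' (iv) grandchildren common to at least two annotated terms. A component
#' first reached gets the product of the step's contribution factors; a
#' component already nonzero is incremented by the increment factor scaled
#' the same way, capped at 1. Grandparent/grandchild contributions are
#' additionally scaled by \code{w_r_g}. In the part_of stage, two-step paths
#' qualify when at least one of their two edges is part_of.
#'
#' @param terms character vector of directly annotated term ids (nonempty,
#'   all present in \code{graph}, none the namespace root).
#' @param graph an \code{\link{ontology_graph}}.
#' @param params an \code{\link{hvsm_params}} object.
#' @param gene optional gene id to record on the result.
#' @return an object of class \code{gene_vector}: list with \code{gene},
#'   \code{namespace}, \code{weights} (sorted named numeric, all in (0,1],
#'   zero components absent) and \code{direct_count}.
#' @details Updates are deterministic: annotated terms, and neighbours
#'   within a term, are visited in sorted id order, and every update sees
#'   values produced earlier in the same step. Directly annotated terms stay
#'   at 1 (the cap makes all updates on them no-ops).
#' @export
build_vector <- function(terms, graph, params = hvsm_params(), gene = NA_character_) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(params, "hvsm_params"))
  terms <- sort(unique(as.character(terms)))
  if (!length(terms)) stop("empty term set")
  unknown <- setdiff(terms, graph$terms$id)
  if (length(unknown)) stop("term(s) not in graph: ", paste(unknown, collapse = ", "))
  nsp <- unique(unname(graph$ns[terms]))
  if (length(nsp) != 1L) stop("annotated terms span multiple namespaces")
  root <- tryCatch(namespace_root(graph, nsp), error = function(e) NA_character_)
  if (!is.na(root) && root %in% terms) stop("namespace root among annotated terms")

  w <- new.env(parent = emptyenv())
  getw <- function(t) {
    v <- w[[t]]
    if (is.null(v)) 0 else v
  }
  for (t in terms) w[[t]] <- 1

  # one update of a component: new-value branch when currently zero,
  # capped increment otherwise
  touch <- function(node, newval, incre) {
    cur <- getw(node)
    w[[node]] <- if (cur == 0) newval else min(1, cur + incre)
  }

  run_stage <- function(relation, w_rel) {
    up1 <- function(t) sort(graph$up[[relation]][[t]] %||% character())
    down1 <- function(t) sort(graph$down[[relation]][[t]] %||% character())
    if (relation == "part_of") {
      up2 <- function(t) sort(.two_step_mixed_part_of(graph, t, "up"))
      down2 <- function(t) sort(.two_step_mixed_part_of(graph, t, "down"))
    } else {
      up2 <- function(t) sort(.two_step_same(graph, t, relation, "up"))
      down2 <- function(t) sort(.two_step_same(graph, t, relation, "down"))
    }
    # step i: direct parents, one update per (annotated term, parent)
    for (t in terms) {
      for (p in up1(t)) {
        touch(p, params$w_parent * w_rel, params$w_incre * w_rel)
      }
    }
    # step ii: grandparents, scaled by w_r_g
    for (t in terms) {
      for (g in up2(t)) {
        touch(g, params$w_r_g * params$w_parent * w_rel,
              params$w_r_g * params$w_incre * w_rel)
      }
    }
    # step iii: children of >= 2 distinct annotated terms, one update each
    kids <- unlist(lapply(terms, down1), use.names = FALSE)
    common <- sort(unique(kids[duplicated(kids)]))
    for (cc in common) {
      touch(cc, params$w_child * w_rel,
            params$w_child * params$w_incre * w_rel)
    }
    # step iv: grandchildren of >= 2 distinct annotated terms
    gkids <- unlist(lapply(terms, down2), use.names = FALSE)
    gcommon <- sort(unique(gkids[duplicated(gkids)]))
    for (gc in gcommon) {
      touch(gc, params$w_r_g * params$w_child * w_rel,
            params$w_r_g * params$w_child * params$w_incre * w_rel)
    }
  }

  run_stage("is_a", params$w_is_a)
  run_stage("part_of", params$w_part_of)

  ids <- ls(w)
  weights <- vapply(ids, function(t) w[[t]], numeric(1))
  weights <- weights[weights > 0]
  weights <- weights[order(names(weights))]

  structure(
    list(gene = gene, namespace = nsp, weights = weights,
         direct_count = length(terms)),
    class = "gene_vector"
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.gene_vector <- function(x, ...) {
  cat("gene_vector:", if (is.na(x$gene)) "<anonymous>" else x$gene,
      "|", x$namespace, "|", x$direct_count, "direct term(s),",
      length(x$weights), "nonzero component(s)\n")
  invisible(x)
}

#' Certainty factor calibrating gene-pair similarity
#'
#' \code{ln(S1 + S2)} where \code{S1}, \code{S2} are the two genes' counts
#' of directly annotated (pre-expansion) terms. Gene pairs with richer
#' annotation give a more certain similarity estimate, so their cosine is
#' scaled up. Strictly increasing in each argument; the base of the
#' logarithm does not affect similarity rankings.
#'
#' @param s1,s2 positive integer counts of directly annotated terms.
#' @return a nonnegative scalar.
#' @export
certainty_factor <- function(s1, s2) {
  if (s1 < 1 || s2 < 1) stop("annotation counts must be >= 1")
  log(s1 + s2)
}

#' Certainty-factor-calibrated cosine similarity of two gene vectors
#'
#' \code{ln(S1+S2) * (v1 . v2) / (|v1| |v2|)}, computed over the union of
#' nonzero components only (the common zero dimensions of the sparse
#' vectors contribute nothing to either the dot product or the norms).
#' Because of the calibration the score may exceed 1; it is rank-based use
#' (ROC) that the measure is designed for.
#'
#' @param v1,v2 \code{gene_vector} objects over the same namespace.
#' @return a nonnegative scalar, symmetric in its arguments.
#' @export
hvsm_similarity <- function(v1, v2) {
  stopifnot(inherits(v1, "gene_vector"), inherits(v2, "gene_vector"))
  if (v1$namespace != v2$namespace) stop("gene vectors from different namespaces")
  common <- intersect(names(v1$weights), names(v2$weights))
  dot <- if (length(common)) sum(v1$weights[common] * v2$weights[common]) else 0
  n1 <- sqrt(sum(v1$weights^2))
  n2 <- sqrt(sum(v2$weights^2))
  lambda <- certainty_factor(v1$direct_count, v2$direct_count)
  lambda * dot / (n1 * n2)
}

#' Similarity of a gene pair with sentinel handling
#'
#' Dataset-scale wrapper around vector construction and
#' \code{\link{hvsm_similarity}}: a pair whose genes cannot both be resolved
#' in the annotation set scores the sentinel -1, and a pair whose
#' computation fails internally scores the sentinel -2 (with a warning), so
#' large benchmark runs never abort. Sentinels rank below every real score
#' in ROC analysis.
#'
#' @param geneA,geneB gene ids.
#' @param ann an \code{\link{annotation_set}}.
#' @param graph an \code{\link{ontology_graph}}.
#' @param params an \code{\link{hvsm_params}} object.
#' @return a similarity score, or -1 / -2.
#' @export
pair_similarity <- function(geneA, geneB, ann, graph, params = hvsm_params()) {
  t1 <- annotation_lookup(ann, geneA)
  t2 <- annotation_lookup(ann, geneB)
  if (is.null(t1) || is.null(t2)) return(-1)
  tryCatch({
    v1 <- build_vector(t1, graph, params, gene = geneA)
    v2 <- build_vector(t2, graph, params, gene = geneB)
    hvsm_similarity(v1, v2)
  }, error = function(e) {
    warning("pair (", geneA, ", ", geneB, ") failed: ", conditionMessage(e))
    -2
  })
}
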