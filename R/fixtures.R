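#' Specification of a synthetic benchmark
#'
#' Describes a seeded synthetic ontology, annotation set and labelled
#' gene-pair benchmark: a single-namespace layered random DAG with typed
#' edges, genes annotated to small uniform-random term sets, and
#' positive/negative pairs where the positives carry planted annotation
#' relatedness. Identical spec and seed give byte-identical outputs.
#'
#' @param n_terms number of terms including the root.
#' @param max_parents maximum number of parents drawn for a non-root term
#'   (each non-root term gets at least one, keeping the DAG single-rooted).
#' @param p_part_of probability an edge is part_of rather than is_a (forced
#'   to 0 in the MF namespace, which has no part_of relations).
#' @param n_genes number of synthetic genes.
#' @param terms_per_gene integer range (min, max) of direct annotations per
#'   gene.
#' @param signal how positive pairs are related: \code{"shared-term"}
#'   (overlapping annotation sets), \code{"sibling-term"} (disjoint sets
#'   containing terms with a common direct parent — the situation where the
#'   hierarchical model scores what the flat model misses), or
#'   \code{"none"} (positives random; a null benchmark).
#' @param n_pos,n_neg numbers of positive and negative pairs.
#' @param namespace GO namespace of the synthetic ontology.
#' @param seed mandatory integer seed; all generator randomness derives
#'   from it and global RNG state is left untouched.
#' @return an object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_terms = 200L, max_parents = 3L, p_part_of = 0.2,
                         n_genes = 100L, terms_per_gene = c(2L, 6L),
                         signal = c("shared-term", "sibling-term", "none"),
                         n_pos = 300L, n_neg = 300L,
                         namespace = c("CC", "BP", "MF"), seed) {
  signal <- match.arg(signal)
  namespace <- match.arg(namespace)
  if (missing(seed)) stop("a seed is mandatory")
  stopifnot(n_terms >= 1L, max_parents >= 1L, p_part_of >= 0, p_part_of <= 1,
            n_genes >= 1L, length(terms_per_gene) == 2L,
            terms_per_gene[1] >= 1L, terms_per_gene[2] >= terms_per_gene[1],
            n_pos >= 1L, n_neg >= 1L)
  structure(
    list(n_terms = as.integer(n_terms), max_parents = as.integer(max_parents),
         p_part_of = if (namespace == "MF") 0 else p_part_of,
         n_genes = as.integer(n_genes),
         terms_per_gene = as.integer(terms_per_gene), signal = signal,
         n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
         namespace = namespace, seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

# run code under a derived seed without disturbing the caller's RNG
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Generate a synthetic ontology
#'
#' Layered random DAG over one namespace. Term k (in id order) sits on
#' layer \code{floor(log2(k))} — a geometrically widening hierarchy like
#' the real GO's fan-out — and draws 1 to \code{max_parents} parents
#' uniformly from the layer above, so the graph is acyclic by construction,
#' single-rooted, and every non-root term has at least one parent. Each
#' edge is part_of with probability \code{p_part_of}, independently (never
#' in MF).
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return an \code{\link{ontology_graph}}.
#' @export
generate_ontology <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  .with_seed(spec$seed + 1L, {
    ids <- sprintf("GO:%07d", seq_len(spec$n_terms))
    terms <- data.frame(id = ids,
                        name = sprintf("synthetic term %d", seq_len(spec$n_terms)),
                        namespace = spec$namespace, stringsAsFactors = FALSE)
    layer <- floor(log2(seq_len(spec$n_terms)))
    child <- character(); parent <- character(); rel <- character()
    for (k in seq_len(spec$n_terms)[-1]) {
      above <- which(layer == layer[k] - 1L)
      np <- sample.int(min(spec$max_parents, length(above)), 1L)
      ps <- above[sample.int(length(above), np)]
      child <- c(child, rep(ids[k], np))
      parent <- c(parent, ids[ps])
      rel <- c(rel, ifelse(stats::runif(np) < spec$p_part_of, "part_of", "is_a"))
    }
    ontology_graph(terms,
                   data.frame(child = child, parent = parent, relation = rel,
                              stringsAsFactors = FALSE))
  })
}

#' Generate synthetic annotations
#'
#' Each synthetic gene receives a uniform-random set of non-root terms of
#' size drawn uniformly from \code{terms_per_gene}.
#'
#' @param graph an \code{\link{ontology_graph}} (from
#'   \code{\link{generate_ontology}}).
#' @param spec the same \code{\link{fixture_spec}}.
#' @return an \code{\link{annotation_set}}.
#' @export
generate_annotations <- function(graph, spec) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(spec, "fixture_spec"))
  root <- namespace_root(graph, spec$namespace)
  pool <- setdiff(graph$terms$id[graph$terms$namespace == spec$namespace], root)
  if (!length(pool)) stop("ontology has no non-root terms to annotate")
  .with_seed(spec$seed + 2L, {
    genes <- sprintf("G%04d", seq_len(spec$n_genes))
    sizes <- sample(seq(spec$terms_per_gene[1], spec$terms_per_gene[2]),
                    spec$n_genes, replace = TRUE)
    sizes <- pmin(sizes, length(pool))
    gene_terms <- lapply(sizes, function(s) sample(pool, s))
    names(gene_terms) <- genes
    annotation_set(gene_terms, spec$namespace, "IEA+", graph)
  })
}

#' Generate a labelled gene-pair benchmark
#'
#' Positive pairs are sampled from the gene pairs qualifying under the
#' spec's signal mode; negative pairs are uniform random unordered pairs
#' not selected as positive (mirroring benchmarks built from curated
#' interactions plus random non-interacting pairs).
#'
#' Signal modes: \code{"shared-term"} pairs share at least one direct
#' annotation; \code{"sibling-term"} pairs share no term but some term of
#' one gene has a common direct parent (either relation) with a term of the
#' other — functionally related yet invisible to flat set overlap;
#' \code{"none"} admits every pair (null benchmark).
#'
#' @param graph an \code{\link{ontology_graph}}.
#' @param ann an \code{\link{annotation_set}}.
#' @param spec the same \code{\link{fixture_spec}}.
#' @return a \code{\link{pair_dataset}} with \code{n_pos + n_neg} rows.
#' @export
generate_pair_benchmark <- function(graph, ann, spec) {
  stopifnot(inherits(graph, "ontology_graph"), inherits(ann, "annotation_set"),
            inherits(spec, "fixture_spec"))
  genes <- names(ann$gene_terms)
  if (length(genes) < 2L) stop("need at least two annotated genes")
  idx <- utils::combn(length(genes), 2L)
  a <- genes[idx[1L, ]]; b <- genes[idx[2L, ]]

  parents_of_set <- function(ts) {
    unique(unlist(lapply(ts, function(t)
      c(graph$up$is_a[[t]], graph$up$part_of[[t]])), use.names = FALSE))
  }
  qualifies <- switch(spec$signal,
    "shared-term" = {
      mapply(function(x, y) length(intersect(ann$gene_terms[[x]],
                                             ann$gene_terms[[y]])) > 0L,
             a, b, USE.NAMES = FALSE)
    },
    "sibling-term" = {
      par <- lapply(ann$gene_terms, parents_of_set)
      mapply(function(x, y) {
        length(intersect(ann$gene_terms[[x]], ann$gene_terms[[y]])) == 0L &&
          length(intersect(par[[x]], par[[y]])) > 0L
      }, a, b, USE.NAMES = FALSE)
    },
    "none" = rep(TRUE, length(a))
  )
  qual_idx <- which(qualifies)
  if (length(qual_idx) < spec$n_pos) {
    stop("insufficient genes: only ", length(qual_idx), " ", spec$signal,
         " pair(s) available, need ", spec$n_pos)
  }
  .with_seed(spec$seed + 3L, {
    pos <- sample(qual_idx, spec$n_pos)
    neg_pool <- setdiff(seq_along(a), pos)
    if (length(neg_pool) < spec$n_neg) {
      stop("insufficient genes: only ", length(neg_pool),
           " non-positive pair(s) available, need ", spec$n_neg)
    }
    neg <- sample(neg_pool, spec$n_neg)
    sel <- c(pos, neg)
    pair_dataset(a[sel], b[sel], c(rep(1L, spec$n_pos), rep(0L, spec$n_neg)),
                 spec$namespace)
  })
}

#' Write a full synthetic benchmark to disk
#'
#' Generates ontology, annotations and pair benchmark from a spec and
#' writes them as OBO, GAF and TSV files consumable by the command-line
#' interface unchanged.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @param out_dir output directory (created if absent).
#' @return invisibly, a list with the three file paths and the generated
#'   objects.
#' @export
simulate_benchmark <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  graph <- generate_ontology(spec)
  ann <- generate_annotations(graph, spec)
  ds <- generate_pair_benchmark(graph, ann, spec)
  paths <- list(obo = file.path(out_dir, "ontology.obo"),
                gaf = file.path(out_dir, "annotations.gaf"),
                pairs = file.path(out_dir, "pairs.tsv"))
  write_obo(graph, paths$obo)
  write_gaf(ann, paths$gaf)
  write_pairs(ds, paths$pairs)
  invisible(list(paths = paths, graph = graph, ann = ann, dataset = ds))
}
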