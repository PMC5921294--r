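#' Construct a labelled gene-pair dataset
#'
#' @param geneA,geneB character vectors of gene ids.
#' @param label optional 0/1 vector (1 = positive interaction); may be
#'   \code{NULL} for unlabelled score-export collections.
#' @param namespace the GO namespace the pairs will be scored in.
#' @return an object of class \code{pair_dataset}. Duplicate unordered
#'   pairs are collapsed to their first occurrence with a warning.
#' @export
pair_dataset <- function(geneA, geneB, label = NULL,
                         namespace = c("BP", "CC", "MF")) {
  namespace <- match.arg(namespace)
  geneA <- as.character(geneA); geneB <- as.character(geneB)
  stopifnot(length(geneA) == length(geneB))
  if (!is.null(label)) {
    label <- as.integer(label)
    stopifnot(length(label) == length(geneA), all(label %in% c(0L, 1L)))
  }
  key <- paste(pmin(geneA, geneB), pmax(geneA, geneB))
  dup <- duplicated(key)
  if (any(dup)) {
    warning("collapsed ", sum(dup), " duplicate unordered pair(s), keeping first occurrence")
    geneA <- geneA[!dup]; geneB <- geneB[!dup]
    if (!is.null(label)) label <- label[!dup]
  }
  structure(
    list(pairs = data.frame(geneA = geneA, geneB = geneB,
                            label = if (is.null(label)) NA_integer_ else label,
                            stringsAsFactors = FALSE),
         namespace = namespace),
    class = "pair_dataset"
  )
}

#' @export
print.pair_dataset <- function(x, ...) {
  lab <- x$pairs$label
  cat("pair_dataset:", nrow(x$pairs), "pairs (", x$namespace, ")")
  if (!all(is.na(lab))) cat(";", sum(lab == 1L), "positive,", sum(lab == 0L), "negative")
  cat("\n")
  invisible(x)
}

#' Read a gene-pair file
#'
#' Tab-separated, two gene-id columns and an optional third 0/1 label
#' column; lines starting with \code{#} are comments. This covers both
#' labelled interaction benchmarks and unlabelled CESSM-style pair lists.
#'
#' @param path input file path.
#' @param namespace the GO namespace the pairs will be scored in.
#' @return a \code{\link{pair_dataset}}.
#' @export
read_pairs <- function(path, namespace = c("BP", "CC", "MF")) {
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("cannot read pair file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) return(pair_dataset(character(), character(), NULL, namespace))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) stop("pair file rows must have at least two columns")
  a <- vapply(fields, `[[`, character(1), 1L)
  b <- vapply(fields, `[[`, character(1), 2L)
  lab <- if (all(nf >= 3L)) as.integer(vapply(fields, `[[`, character(1), 3L)) else NULL
  pair_dataset(a, b, lab, namespace)
}

#' Write a gene-pair dataset as TSV
#'
#' @param ds a \code{\link{pair_dataset}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_pairs <- function(ds, path) {
  stopifnot(inherits(ds, "pair_dataset"))
  rows <- if (all(is.na(ds$pairs$label))) {
    paste(ds$pairs$geneA, ds$pairs$geneB, sep = "\t")
  } else {
    paste(ds$pairs$geneA, ds$pairs$geneB, ds$pairs$label, sep = "\t")
  }
  writeLines(rows, path)
  invisible(path)
}

#' Available similarity measures
#'
#' @return character vector of the measure names accepted by
#'   \code{\link{score_dataset}} and the command-line interface.
#' @export
similarity_measures <- function() {
  c("hvsm", "vsm", "resnik", "lin", "jiang", "schlicker", "simgic",
    "jaccard", "dice", "intelligo")
}

#' Score every pair of a dataset with a chosen measure
#'
#' Applies one similarity measure to each gene pair, preserving input
#' order. Pairs with an unresolvable gene score the sentinel -1; pairs
#' whose computation fails internally score -2. HVSM vectors and IC tables
#' are computed once per gene / corpus and reused across pairs.
#'
#' @param ds a \code{\link{pair_dataset}}.
#' @param measure one of \code{\link{similarity_measures}()}.
#' @param ann an \code{\link{annotation_set}} (same namespace as \code{ds}).
#' @param graph an \code{\link{ontology_graph}}.
#' @param params \code{\link{hvsm_params}} (used by measure \code{"hvsm"}).
#' @param combine combination strategy for the term-level measures
#'   (resnik/lin/jiang/schlicker): \code{"max"} (default), \code{"avg"} or
#'   \code{"bma"}.
#' @param ic optional precomputed \code{\link{compute_ic}} table; computed
#'   from \code{ann} when needed and absent.
#' @param cfg \code{\link{intelligo_config}} for measure
#'   \code{"intelligo"}.
#' @return a data.frame \code{geneA, geneB, label, score}.
#' @export
score_dataset <- function(ds, measure, ann, graph, params = hvsm_params(),
                          combine = c("max", "avg", "bma"), ic = NULL,
                          cfg = intelligo_config()) {
  stopifnot(inherits(ds, "pair_dataset"), inherits(ann, "annotation_set"),
            inherits(graph, "ontology_graph"))
  measure <- match.arg(measure, similarity_measures())
  combine <- match.arg(combine)
  if (ds$namespace != ann$namespace) stop("dataset and annotations disagree on namespace")
  if (measure %in% c("resnik", "lin", "jiang", "schlicker", "simgic") && is.null(ic)) {
    ic <- compute_ic(ann, graph)
  }
  vec_cache <- new.env(parent = emptyenv())
  hvsm_vec <- function(g, ts) {
    v <- vec_cache[[g]]
    if (is.null(v)) {
      v <- build_vector(ts, graph, params, gene = g)
      vec_cache[[g]] <- v
    }
    v
  }
  score_one <- function(a, b) {
    t1 <- annotation_lookup(ann, a)
    t2 <- annotation_lookup(ann, b)
    if (is.null(t1) || is.null(t2)) return(-1)
    tryCatch(
      switch(measure,
        hvsm = hvsm_similarity(hvsm_vec(a, t1), hvsm_vec(b, t2)),
        vsm = vsm_similarity(t1, t2),
        jaccard = set_similarity(t1, t2, "jaccard"),
        dice = set_similarity(t1, t2, "dice"),
        simgic = simgic_similarity(t1, t2, ic, graph),
        intelligo = intelligo_similarity(a, b, ann, graph, cfg),
        combine_pairwise(t1, t2,
                         function(x, y) term_similarity(x, y, ic, graph, measure),
                         combine)
      ),
      error = function(e) {
        warning("pair (", a, ", ", b, ") failed: ", conditionMessage(e))
        -2
      }
    )
  }
  n <- nrow(ds$pairs)
  score <- numeric(n)
  for (i in seq_len(n)) score[i] <- score_one(ds$pairs$geneA[i], ds$pairs$geneB[i])
  out <- ds$pairs
  out$score <- score
  out
}

#' ROC curve and trapezoidal AUC for scored, labelled pairs
#'
#' Sweeps the classification threshold over the distinct score values in
#' descending order; tied scores move as one block, producing diagonal ROC
#' segments whose trapezoidal area matches the rank-statistic (Mann-Whitney,
#' ties one half) value. Sentinel scores rank below every real score, -1
#' above -2, so complete-dataset runs are well defined. Use
#' \code{mode = "partial"} to drop sentinel-scored pairs first.
#'
#' @param scores numeric scores (higher = more likely positive; -1/-2 are
#'   the sentinels for unresolvable/failed pairs).
#' @param labels 0/1 vector of the same length.
#' @param mode \code{"complete"} (sentinels kept, ranked at the bottom) or
#'   \code{"partial"} (sentinel pairs removed before the sweep).
#' @return an object of class \code{roc_result}: list with \code{points}
#'   (data.frame \code{fpr}, \code{tpr} from (0,0) to (1,1)), \code{auc},
#'   \code{n_pos}, \code{n_neg}, \code{n_sentinel}.
#' @export
roc_auc <- function(scores, labels, mode = c("complete", "partial")) {
  mode <- match.arg(mode)
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  n_sentinel <- sum(scores %in% c(-1, -2))
  if (mode == "partial") {
    keep <- !(scores %in% c(-1, -2))
    scores <- scores[keep]; labels <- labels[keep]
  }
  n_pos <- sum(labels == 1L)
  n_neg <- sum(labels == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("need at least one positive and one negative label")
  }
  # descending sweep; numeric order already puts -1 above -2 and both below
  # every real (nonnegative) score
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; l <- labels[ord]
  blocks <- cumsum(rle(s)$lengths)
  tp <- cumsum(l)[blocks]
  fp <- (blocks - cumsum(l)[blocks])
  fpr <- c(0, fp / n_neg)
  tpr <- c(0, tp / n_pos)
  if (fpr[length(fpr)] != 1 || tpr[length(tpr)] != 1) {
    fpr <- c(fpr, 1); tpr <- c(tpr, 1)   # defensive; blocks always end at n
  }
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(
    list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc,
         n_pos = n_pos, n_neg = n_neg, n_sentinel = n_sentinel),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("roc_result: AUC = %.4f (%d pos, %d neg, %d sentinel)\n",
              x$auc, x$n_pos, x$n_neg, x$n_sentinel))
  invisible(x)
}

#' Export scored pairs
#'
#' Three tab-separated columns \code{geneA geneB score}, score printed with
#' six decimals, no header — the layout CESSM-style evaluation services
#' accept. Sentinel scores are written as-is (\code{-1.000000} /
#' \code{-2.000000}); downstream consumers decide their fate.
#'
#' @param scored data.frame from \code{\link{score_dataset}} (needs columns
#'   \code{geneA}, \code{geneB}, \code{score}).
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"cessm"} (identical three-column
#'   layout; the name records intent).
#' @return \code{path}, invisibly.
#' @export
export_scores <- function(scored, path, format = c("tsv", "cessm")) {
  format <- match.arg(format)
  stopifnot(all(c("geneA", "geneB", "score") %in% names(scored)))
  rows <- sprintf("%s\t%s\t%.6f", scored$geneA, scored$geneB, scored$score)
  writeLines(rows, path)
  invisible(path)
}
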