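#' Construct an annotation set
#'
#' A per-namespace map from gene (or gene-product) identifiers to the set of
#' GO terms directly annotated to them. Direct means explicitly present in
#' the annotation file: propagation over the hierarchy is the job of the
#' similarity measures, not of this container.
#'
#' @param gene_terms named list, gene id -> character vector of term ids.
#' @param namespace \code{"BP"}, \code{"CC"} or \code{"MF"}.
#' @param evidence_policy \code{"IEA+"} (electronic annotations kept) or
#'   \code{"IEA-"} (dropped).
#' @param graph optional \code{\link{ontology_graph}} used to validate that
#'   every term exists and carries the declared namespace, and to strip the
#'   namespace root from every set.
#' @param evidence optional named list mirroring \code{gene_terms}: gene id
#'   -> named character vector term id -> evidence code (used by IntelliGO
#'   weighting).
#' @return an object of class \code{annotation_set}. Genes whose sets end up
#'   empty are removed.
#' @export
annotation_set <- function(gene_terms, namespace = c("BP", "CC", "MF"),
                           evidence_policy = c("IEA+", "IEA-"),
                           graph = NULL, evidence = NULL) {
  namespace <- match.arg(namespace)
  evidence_policy <- match.arg(evidence_policy)
  stopifnot(is.list(gene_terms))
  gene_terms <- lapply(gene_terms, function(x) sort(unique(as.character(x))))
  if (!is.null(graph)) {
    stopifnot(inherits(graph, "ontology_graph"))
    ok <- graph$terms$id[graph$terms$namespace == namespace]
    root <- tryCatch(namespace_root(graph, namespace), error = function(e) NA_character_)
    gene_terms <- lapply(gene_terms, function(x) setdiff(intersect(x, ok), root))
  }
  keep <- vapply(gene_terms, length, integer(1)) > 0L
  gene_terms <- gene_terms[keep]
  if (!is.null(evidence)) evidence <- evidence[names(gene_terms)]
  structure(
    list(namespace = namespace, gene_terms = gene_terms,
         evidence_policy = evidence_policy, evidence = evidence),
    class = "annotation_set"
  )
}

#' @export
print.annotation_set <- function(x, ...) {
  nt <- vapply(x$gene_terms, length, integer(1))
  cat("annotation_set:", length(x$gene_terms), "genes,",
      length(unique(unlist(x$gene_terms, use.names = FALSE))), "distinct",
      x$namespace, "terms, policy", x$evidence_policy, "\n")
  if (length(nt)) cat("  terms per gene: median", stats::median(nt),
                      "range", min(nt), "-", max(nt), "\n")
  invisible(x)
}

#' Parse a GAF 2.x gene association file
#'
#' Reads the standard tab-separated GO annotation format into an
#' \code{\link{annotation_set}} for one namespace. Rows are kept when their
#' aspect column matches the requested namespace (P/C/F for BP/CC/MF), their
#' qualifier carries no NOT, their term (after \code{alt_id} resolution)
#' exists in the companion graph, and — under the \code{"IEA-"} policy —
#' their evidence code is not IEA. The namespace root is removed from every
#' set and genes left without terms are dropped, matching the convention
#' that such genes are unresolvable for similarity purposes.
#'
#' @param path path to a GAF 2.0/2.1/2.2 file (comment lines start with
#'   \code{!}).
#' @param graph an \code{\link{ontology_graph}}.
#' @param namespace \code{"BP"}, \code{"CC"} or \code{"MF"}.
#' @param evidence_policy \code{"IEA+"} (default, keep electronic
#'   annotations) or \code{"IEA-"}.
#' @param id_column which GAF column identifies the gene: \code{"id"}
#'   (column 2, DB object ID — default), or \code{"symbol"} (column 3).
#' @return an \code{\link{annotation_set}}.
#' @export
parse_gaf <- function(path, graph, namespace = c("BP", "CC", "MF"),
                      evidence_policy = c("IEA+", "IEA-"),
                      id_column = c("id", "symbol")) {
  namespace <- match.arg(namespace)
  evidence_policy <- match.arg(evidence_policy)
  id_column <- match.arg(id_column)
  stopifnot(inherits(graph, "ontology_graph"))
  if (!file.exists(path)) stop("cannot read GAF file: ", path)

  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  if (!length(lines)) {
    return(annotation_set(list(), namespace, evidence_policy, graph))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nfield <- lengths(fields)
  malformed <- nfield < 15L   # GAF 2.x defines 17 columns; 16/17 may be empty
  if (any(malformed)) {
    warning("parse_gaf: skipped ", sum(malformed), " malformed row(s)")
    fields <- fields[!malformed]
  }
  if (!length(fields)) {
    return(annotation_set(list(), namespace, evidence_policy, graph))
  }
  col <- function(i) vapply(fields, function(f) f[[i]], character(1))
  gene <- col(if (id_column == "id") 2L else 3L)
  qualifier <- col(4L)
  go_id <- col(5L)
  evidence <- col(7L)
  aspect <- col(9L)

  want_aspect <- c(BP = "P", CC = "C", MF = "F")[[namespace]]
  keep <- aspect == want_aspect
  keep <- keep & !grepl("(^|\\|)NOT($|\\|)", qualifier)
  if (evidence_policy == "IEA-") keep <- keep & evidence != "IEA"

  gene <- gene[keep]; go_id <- go_id[keep]; evidence <- evidence[keep]
  go_id <- resolve_term(graph, go_id)
  known <- !is.na(go_id)
  n_unknown <- sum(!known)
  if (n_unknown) {
    message("parse_gaf: dropped ", n_unknown, " row(s) with terms absent from the ontology")
  }
  gene <- gene[known]; go_id <- go_id[known]; evidence <- evidence[known]

  gene_terms <- lapply(split(go_id, gene), unique)
  ev <- Map(function(t, e) stats::setNames(e, t)[!duplicated(t)],
            split(go_id, gene), split(evidence, gene))
  annotation_set(gene_terms, namespace, evidence_policy, graph, evidence = ev)
}

#' Look up a gene's direct annotations
#'
#' @param ann an \code{\link{annotation_set}}.
#' @param gene a gene id.
#' @return character vector of term ids, or \code{NULL} when the gene is
#'   unknown (the missing-marker that dataset scoring maps to the sentinel
#'   score -1).
#' @export
annotation_lookup <- function(ann, gene) {
  stopifnot(inherits(ann, "annotation_set"))
  ann$gene_terms[[gene]]
}

#' Write an annotation set as a GAF 2.1 file
#'
#' The converse of \code{\link{parse_gaf}}, used by the fixture generator.
#' Synthetic rows carry DB \code{"synthetic"}, evidence code \code{IDA} and
#' a placeholder taxon.
#'
#' @param ann an \code{\link{annotation_set}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_gaf <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_set"))
  aspect <- c(BP = "P", CC = "C", MF = "F")[[ann$namespace]]
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines("!gaf-version: 2.1", con)
  for (g in names(ann$gene_terms)) {
    for (t in ann$gene_terms[[g]]) {
      ev <- if (!is.null(ann$evidence)) unname(ann$evidence[[g]][t]) else NA
      if (is.null(ev) || is.na(ev)) ev <- "IDA"
      row <- c("synthetic", g, g, "", t, "SYN:0000001", ev, "", aspect,
               "", "", "gene", "taxon:0", "20260101", "synthetic", "", "")
      writeLines(paste(row, collapse = "\t"), con)
    }
  }
  invisible(path)
}
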