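# shared corpus: chain root gid3 <- gid2 <- gid1, plus a sibling branch
# root gid3 <- gid4; genes g1 {gid1}, g2 {gid2}, g3 {gid4}, g4 {gid4}
ic_fixture <- function() {
  g <- toy_graph(child = gid(c(1, 2, 4)), parent = gid(c(2, 3, 3)),
                 relation = rep("is_a", 3))
  ann <- annotation_set(list(g1 = gid(1), g2 = gid(2), g3 = gid(4), g4 = gid(4)),
                        namespace = "CC", graph = g)
  list(graph = g, ann = ann, ic = compute_ic(ann, g))
}

test_that("IC propagates counts to ancestors and anchors the root at zero", {
  fx <- ic_fixture()
  ic <- fx$ic
  root <- gid(3)
  expect_equal(unname(ic$p[root]), 1)
  expect_equal(unname(ic$ic[root]), 0)
  # gid2 covers g1 and g2 -> p = 1/2, ic = ln 2
  expect_equal(unname(ic$p[gid(2)]), 0.5)
  expect_equal(unname(ic$ic[gid(2)]), log(2))
  # chain propagation: genes only on the leaf still count for its ancestor
  g2 <- chain_graph(3)
  ann2 <- annotation_set(list(a = gid(1), b = gid(1)), "CC", graph = g2)
  ic2 <- compute_ic(ann2, g2)
  expect_equal(unname(ic2$p[gid(1)]), 1)
  expect_equal(unname(ic2$p[gid(2)]), 1)
  expect_equal(unname(ic2$ic[gid(2)]), 0)
})

test_that("annotation probability is monotone along every edge", {
  spec <- fixture_spec(n_terms = 60, n_genes = 40, seed = 21)
  g <- generate_ontology(spec)
  ann <- generate_annotations(g, spec)
  ic <- compute_ic(ann, g)
  e <- g$edges
  known <- e$child %in% names(ic$p) & e$parent %in% names(ic$p)
  expect_true(all(ic$p[e$parent[known]] >= ic$p[e$child[known]]))
  # a reached child implies a reached parent (ancestor propagation)
  expect_true(all(!(e$child %in% names(ic$p)) | e$parent %in% names(ic$p)))
  expect_equal(ic$ic, -log(ic$p))
})

test_that("term similarities satisfy the self and root identities", {
  fx <- ic_fixture()
  t <- gid(1)   # ic > 0
  expect_equal(term_similarity(t, t, fx$ic, fx$graph, "resnik"),
               unname(fx$ic$ic[t]))
  expect_equal(term_similarity(t, t, fx$ic, fx$graph, "lin"), 1)
  expect_equal(term_similarity(t, t, fx$ic, fx$graph, "jiang"), 1)
  # gid1 and gid4 share only the root
  expect_equal(term_similarity(gid(1), gid(4), fx$ic, fx$graph, "resnik"), 0)
  expect_equal(term_similarity(gid(1), gid(4), fx$ic, fx$graph, "schlicker"), 0)
  expect_error(term_similarity(gid(1), "GO:9999999", fx$ic, fx$graph, "lin"),
               "no IC entry")
})

test_that("MICA agrees with brute-force ancestor-set intersection on small DAGs", {
  for (seed in c(2, 13, 31, 44)) {
    spec <- fixture_spec(n_terms = 3 + seed %% 10, max_parents = 2,
                         p_part_of = 0.3, n_genes = 15,
                         terms_per_gene = c(1, 3), seed = seed)
    g <- generate_ontology(spec)
    ann <- generate_annotations(g, spec)
    ic <- compute_ic(ann, g)
    terms <- names(ic$ic)
    for (t1 in terms) {
      for (t2 in terms) {
        expect_equal(term_similarity(t1, t2, ic, g, "resnik"),
                     oracle_mica_ic(t1, t2, ic, g),
                     info = paste(seed, t1, t2))
      }
    }
  }
})

test_that("pairwise combination strategies follow their formulas", {
  score <- matrix(c(1, 0, 0, 1), 2, 2)
  fn <- function(a, b) score[as.integer(a), as.integer(b)]
  expect_equal(combine_pairwise(c("1", "2"), c("1", "2"), fn, "max"), 1)
  expect_equal(combine_pairwise(c("1", "2"), c("1", "2"), fn, "avg"), 0.5)
  expect_equal(combine_pairwise(c("1", "2"), c("1", "2"), fn, "bma"), 1)
  # singletons: all strategies collapse to the term score
  one <- function(a, b) 0.42
  for (s in c("max", "avg", "bma")) {
    expect_equal(combine_pairwise("1", "2", one, s), 0.42)
  }
})

test_that("MAX >= BMA >= min cross score and AVG <= MAX on random matrices", {
  set.seed(5)
  for (i in 1:20) {
    m <- matrix(runif(12), 3, 4)
    fn <- function(a, b) m[as.integer(a), as.integer(b)]
    r <- as.character(1:3); c <- as.character(1:4)
    mx <- combine_pairwise(r, c, fn, "max")
    av <- combine_pairwise(r, c, fn, "avg")
    bm <- combine_pairwise(r, c, fn, "bma")
    expect_gte(mx, bm)
    expect_gte(bm, min(m))
    expect_lte(av, mx)
  }
})

test_that("SimGIC is 1 on identical sets, 0 on root-only overlap, and reduces to Jaccard under flat IC", {
  fx <- ic_fixture()
  expect_equal(simgic_similarity(gid(1), gid(1), fx$ic, fx$graph), 1)
  expect_equal(simgic_similarity(gid(c(1, 2)), gid(c(1, 2)), fx$ic, fx$graph), 1)
  expect_equal(simgic_similarity(gid(1), gid(4), fx$ic, fx$graph), 0)
  # flat unit IC turns the IC-weighted Jaccard into the plain one
  g <- small_dag(17)
  ids <- g$terms$id
  flat_ic <- structure(list(namespace = "CC",
                            p = stats::setNames(rep(exp(-1), length(ids)), ids),
                            ic = stats::setNames(rep(1, length(ids)), ids)),
                       class = "ic_table")
  pool <- non_root_terms(g)
  ts1 <- pool[1:2]
  ts2 <- pool[2:3]
  ext <- function(ts) unique(unlist(lapply(ts, term_ancestors, graph = g,
                                           include_self = TRUE)))
  expect_equal(simgic_similarity(ts1, ts2, flat_ic, g),
               length(intersect(ext(ts1), ext(ts2))) /
                 length(union(ext(ts1), ext(ts2))))
})

test_that("basic VSM and the set measures follow their closed forms", {
  expect_equal(vsm_similarity(c("a", "b"), c("a", "b")), 1)
  expect_equal(vsm_similarity(c("a", "b"), c("b", "c")), 0.5)
  expect_equal(vsm_similarity("a", "b"), 0)
  expect_error(vsm_similarity(character(), "a"), "empty")
  expect_equal(set_similarity(c("a", "b"), c("b", "c"), "jaccard"), 1 / 3)
  expect_equal(set_similarity(c("a", "b"), c("b", "c"), "dice"), 0.5)
  expect_equal(set_similarity(c("a", "b"), c("c", "d"), "jaccard"), 0)
  expect_equal(set_similarity(c("a", "b"), c("a", "b"), "dice"), 1)
})

test_that("IntelliGO matches its closed forms on depth-controlled cases", {
  # root gid4; gid3 at depth 1; siblings gid1, gid2 under gid3 (depth 2)
  g <- toy_graph(child = gid(c(3, 1, 2)), parent = gid(c(4, 3, 3)),
                 relation = rep("is_a", 3))
  ann <- annotation_set(list(a = gid(1), b = gid(2), c = gid(1)),
                        namespace = "CC", graph = g)
  # identical genes: self-cosine is exactly 1
  expect_equal(intelligo_similarity("a", "c", ann, g), 1)
  # siblings: single-term genes, e = d/(1+d) with LCA depth d = 1, MinSPL = 2
  expect_equal(intelligo_similarity("a", "b", ann, g), 1 / 2)
  # genes whose terms share only the root: e = 0
  g2 <- toy_graph(child = gid(c(1, 2)), parent = gid(c(3, 3)),
                  relation = rep("is_a", 2))
  ann2 <- annotation_set(list(a = gid(1), b = gid(2)), "CC", graph = g2)
  expect_equal(intelligo_similarity("a", "b", ann2, g2), 0)
  expect_error(intelligo_config(evidence_weights = c(IEA = -1)), "positive")
})

test_that("bounded measures stay in [0,1] and all measures are symmetric", {
  spec <- fixture_spec(n_terms = 40, n_genes = 25, seed = 33)
  g <- generate_ontology(spec)
  ann <- generate_annotations(g, spec)
  ic <- compute_ic(ann, g)
  genes <- names(ann$gene_terms)
  set.seed(8)
  pick <- replicate(12, sample(genes, 2), simplify = FALSE)
  bounded <- c("vsm", "lin", "jiang", "schlicker", "simgic", "jaccard", "dice",
               "intelligo")
  for (pr in pick) {
    t1 <- ann$gene_terms[[pr[1]]]
    t2 <- ann$gene_terms[[pr[2]]]
    for (m in bounded) {
      s <- switch(m,
        vsm = vsm_similarity(t1, t2),
        jaccard = set_similarity(t1, t2, "jaccard"),
        dice = set_similarity(t1, t2, "dice"),
        simgic = simgic_similarity(t1, t2, ic, g),
        intelligo = intelligo_similarity(pr[1], pr[2], ann, g),
        combine_pairwise(t1, t2,
                         function(x, y) term_similarity(x, y, ic, g, m), "max")
      )
      rev <- switch(m,
        vsm = vsm_similarity(t2, t1),
        jaccard = set_similarity(t2, t1, "jaccard"),
        dice = set_similarity(t2, t1, "dice"),
        simgic = simgic_similarity(t2, t1, ic, g),
        intelligo = intelligo_similarity(pr[2], pr[1], ann, g),
        combine_pairwise(t2, t1,
                         function(x, y) term_similarity(x, y, ic, g, m), "max")
      )
      expect_gte(s, 0)
      expect_lte(s, 1 + 1e-9)
      expect_equal(s, rev, info = m)
    }
  }
})
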