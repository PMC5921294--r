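test_that("contribution factors validate and expose the published defaults", {
  p <- hvsm_params()
  expect_equal(unclass(p),
               list(w_is_a = 1, w_part_of = 0.7, w_parent = 0.5, w_child = 0.2,
                    w_incre = 1 / 6, w_r_g = 0.5))
  expect_equal(hvsm_params(profile = "cessm")$w_child, 0.05)
  expect_error(hvsm_params(w_parent = 1.2), "\\[0, 1\\]")
  expect_warning(hvsm_params(w_part_of = 1), "w_is_a > w_part_of")
  expect_warning(hvsm_params(w_child = 0.6), "w_parent > w_child")

  f <- withr::local_tempfile(fileext = ".cfg")
  writeLines(c("# config", "w_parent = 0.4", "w_child=0.1"), f)
  q <- read_hvsm_params(f)
  expect_equal(q$w_parent, 0.4)
  expect_equal(q$w_child, 0.1)
  expect_equal(q$w_is_a, 1)
})

test_that("vector expansion reproduces the worked one-step and two-step weights", {
  # chain t -> p -> g via is_a
  g <- chain_graph(3)
  v <- build_vector(gid(1), g)
  expect_equal(v$weights[[gid(1)]], 1)
  expect_equal(v$weights[[gid(2)]], 0.5)      # parent: w_parent * w_is_a
  expect_equal(v$weights[[gid(3)]], 0.25)     # grandparent: * w_r_g

  # part_of parent
  gp <- chain_graph(2, relation = "part_of")
  expect_equal(build_vector(gid(1), gp)$weights[[gid(2)]], 0.35)  # 0.5 * 0.7

  # shared parent: new value then one increment
  gs <- toy_graph(child = gid(c(1, 2)), parent = gid(c(3, 3)),
                  relation = c("is_a", "is_a"))
  expect_equal(build_vector(gid(1:2), gs)$weights[[gid(3)]], 0.5 + 1 / 6)

  # common direct child of two annotated terms: one new-value update
  gc <- toy_graph(child = gid(c(4, 4, 1, 2)), parent = gid(c(1, 2, 5, 5)),
                  relation = rep("is_a", 4))
  vc <- build_vector(gid(1:2), gc)
  expect_equal(vc$weights[[gid(4)]], 0.2)
  expect_equal(vc$weights[[gid(5)]], 0.5 + 1 / 6)
})

test_that("a child of only one annotated term contributes nothing", {
  g <- chain_graph(4)            # gid1 -> gid2 -> gid3 -> gid4
  v <- build_vector(gid(3), g)   # gid2 is a child of just one annotated term
  expect_false(gid(2) %in% names(v$weights))
  expect_false(gid(1) %in% names(v$weights))
  expect_equal(v$weights[[gid(4)]], 0.5)
})

test_that("mixed-relation two-step paths are handled by the part_of stage", {
  # t -is_a-> p -part_of-> g
  g <- toy_graph(child = gid(c(1, 2)), parent = gid(c(2, 3)),
                 relation = c("is_a", "part_of"))
  v <- build_vector(gid(1), g)
  expect_equal(v$weights[[gid(2)]], 0.5)            # is_a parent
  # grandparent reached only in the part_of stage: w_r_g * w_parent * w_part_of
  expect_equal(v$weights[[gid(3)]], 0.5 * 0.5 * 0.7)

  # t -part_of-> p -is_a-> g also belongs to the part_of stage
  g2 <- toy_graph(child = gid(c(1, 2)), parent = gid(c(2, 3)),
                  relation = c("part_of", "is_a"))
  v2 <- build_vector(gid(1), g2)
  expect_equal(v2$weights[[gid(2)]], 0.35)
  expect_equal(v2$weights[[gid(3)]], 0.5 * 0.5 * 0.7)
})

test_that("directly annotated terms stay frozen at weight 1", {
  # gid1 -> gid2 -> gid3 with both gid1 and gid2 annotated
  g <- chain_graph(3)
  v <- build_vector(gid(1:2), g)
  expect_equal(v$weights[[gid(1)]], 1)
  expect_equal(v$weights[[gid(2)]], 1)
  expect_equal(v$direct_count, 2L)
})

test_that("build_vector rejects bad inputs", {
  g <- chain_graph(3)
  expect_error(build_vector(character(), g), "empty")
  expect_error(build_vector("GO:9999999", g), "not in graph")
  expect_error(build_vector(gid(2), chain_graph(2)), "root")
})

test_that("certainty factor is ln(S1+S2), increasing, and guards its domain", {
  expect_equal(certainty_factor(1, 1), log(2))
  expect_equal(certainty_factor(5, 1), log(6))
  expect_equal(certainty_factor(10, 10), log(20))
  expect_gt(certainty_factor(6, 1), certainty_factor(5, 1))
  expect_error(certainty_factor(0, 1), ">= 1")
})

test_that("similarity is the calibrated cosine over nonzero dimensions", {
  g <- flat_graph(10)
  v1 <- build_vector(gid(1:3), g)
  v2 <- build_vector(gid(4:6), g)
  expect_equal(hvsm_similarity(v1, v2), 0)          # disjoint supports
  expect_equal(hvsm_similarity(v1, v1), log(6))     # identical: cosine 1, ln(2n)
  v3 <- build_vector(gid(2:4), g)
  expect_equal(hvsm_similarity(v1, v3), hvsm_similarity(v3, v1))
  vb <- build_vector(gid(1:3), flat_graph(10, ns = "BP"))
  expect_error(hvsm_similarity(v1, vb), "namespace")
})

test_that("scores can exceed 1 through the certainty factor", {
  g <- flat_graph(12)
  v <- build_vector(gid(1:6), g)
  expect_gt(hvsm_similarity(v, v), 1)
})

test_that("sparse result equals the dense full-dimension computation", {
  for (seed in c(3, 14, 27)) {
    g <- small_dag(seed)
    pool <- non_root_terms(g)
    ts1 <- pool[seq(1, length(pool), by = 2)]
    ts2 <- pool[seq(2, length(pool), by = 2)]
    if (!length(ts1) || !length(ts2)) next
    v1 <- build_vector(ts1, g)
    v2 <- build_vector(ts2, g)
    d1 <- oracle_build_vector(ts1, g, hvsm_params())
    d2 <- oracle_build_vector(ts2, g, hvsm_params())
    dense <- certainty_factor(length(ts1), length(ts2)) *
      sum(d1 * d2) / (sqrt(sum(d1^2)) * sqrt(sum(d2^2)))
    expect_equal(hvsm_similarity(v1, v2), dense, tolerance = 1e-12)
  }
})

test_that("no component ever exceeds 1 for any parameters in the unit cube", {
  set.seed(99)
  for (i in 1:20) {
    g <- small_dag(i + 100)
    pool <- non_root_terms(g)
    ts <- sample(pool, min(length(pool), sample(1:3, 1)))
    p <- suppressWarnings(hvsm_params(
      w_is_a = runif(1), w_part_of = runif(1), w_parent = runif(1),
      w_child = runif(1), w_incre = runif(1), w_r_g = runif(1)))
    v <- build_vector(ts, g, p)
    expect_true(all(v$weights <= 1))
    expect_true(all(v$weights > 0))
  }
})

test_that("adding a shared term never decreases the uncalibrated cosine", {
  set.seed(7)
  for (i in 1:10) {
    g <- small_dag(i + 200, n_terms = 12)
    pool <- non_root_terms(g)
    ts1 <- sample(pool, min(4, length(pool) - 1))
    ts2 <- sample(pool, min(4, length(pool) - 1))
    extra <- sample(setdiff(pool, union(ts1, ts2)), 1)
    if (!length(extra)) next
    cosine <- function(a, b) {
      va <- build_vector(a, g); vb <- build_vector(b, g)
      hvsm_similarity(va, vb) / certainty_factor(va$direct_count, vb$direct_count)
    }
    expect_gte(cosine(union(ts1, extra), union(ts2, extra)) + 1e-12,
               cosine(ts1, ts2))
  }
})

test_that("pair scoring maps missing genes and internal failures to sentinels", {
  g <- chain_graph(3)
  ann <- annotation_set(list(a = gid(1), b = gid(2), broken = "GO:9999999"),
                        namespace = "CC")
  expect_gt(pair_similarity("a", "b", ann, g), 0)
  expect_equal(pair_similarity("a", "b", ann, g),
               pair_similarity("b", "a", ann, g))
  expect_equal(pair_similarity("a", "nobody", ann, g), -1)
  expect_warning(s <- pair_similarity("a", "broken", ann, g), "failed")
  expect_equal(s, -2)
})
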