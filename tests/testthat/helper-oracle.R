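# Independent oracles kept deliberately naive: dense vectors, direct edge
# scans, quadratic rank statistics. They share no code with the package
# internals they check.

# literal straight-line hierarchical expansion over an explicit full vector
oracle_build_vector <- function(terms, graph, p) {
  ids <- graph$terms$id
  v <- stats::setNames(numeric(length(ids)), ids)
  terms <- sort(unique(terms))
  v[terms] <- 1
  E <- graph$edges
  pa <- function(t, rels) sort(unique(E$parent[E$child == t & E$relation %in% rels]))
  ch <- function(t, rels) sort(unique(E$child[E$parent == t & E$relation %in% rels]))
  touch <- function(node, newval, inc) {
    v[node] <<- if (v[node] == 0) newval else min(1, v[node] + inc)
  }
  for (rel in c("is_a", "part_of")) {
    wrel <- if (rel == "is_a") p$w_is_a else p$w_part_of
    up2 <- function(t) {
      g <- if (rel == "is_a") {
        unlist(lapply(pa(t, "is_a"), pa, "is_a"))
      } else {
        c(unlist(lapply(pa(t, "is_a"), pa, "part_of")),
          unlist(lapply(pa(t, "part_of"), pa, c("is_a", "part_of"))))
      }
      sort(setdiff(unique(g), t))
    }
    dn2 <- function(t) {
      g <- if (rel == "is_a") {
        unlist(lapply(ch(t, "is_a"), ch, "is_a"))
      } else {
        c(unlist(lapply(ch(t, "is_a"), ch, "part_of")),
          unlist(lapply(ch(t, "part_of"), ch, c("is_a", "part_of"))))
      }
      sort(setdiff(unique(g), t))
    }
    for (t in terms) for (x in pa(t, rel)) {
      touch(x, p$w_parent * wrel, p$w_incre * wrel)
    }
    for (t in terms) for (x in up2(t)) {
      touch(x, p$w_r_g * p$w_parent * wrel, p$w_r_g * p$w_incre * wrel)
    }
    kids <- unlist(lapply(terms, ch, rel))
    for (x in sort(unique(kids[duplicated(kids)]))) {
      touch(x, p$w_child * wrel, p$w_child * p$w_incre * wrel)
    }
    gkids <- unlist(lapply(terms, dn2))
    for (x in sort(unique(gkids[duplicated(gkids)]))) {
      touch(x, p$w_r_g * p$w_child * wrel, p$w_r_g * p$w_child * p$w_incre * wrel)
    }
  }
  v
}

# Mann-Whitney formulation of the AUC: probability a random positive
# outranks a random negative, ties counted one half
rank_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

# brute-force MICA: intersect explicitly enumerated ancestor sets
oracle_mica_ic <- function(t1, t2, ic, graph) {
  anc_of <- function(t) {
    out <- t
    frontier <- t
    E <- graph$edges
    repeat {
      nxt <- setdiff(unique(E$parent[E$child %in% frontier]), out)
      if (!length(nxt)) break
      out <- c(out, nxt)
      frontier <- nxt
    }
    out
  }
  common <- intersect(anc_of(t1), anc_of(t2))
  vals <- ic$ic[common]
  vals <- vals[!is.na(vals)]
  if (!length(vals)) 0 else max(vals)
}
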