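# Fixture generators and independently coded oracles. The oracles deliberately
# avoid the package's computational paths: mapping costs are recomputed from
# link-key sets, the exact GED is re-enumerated via subsets x permutations, and
# the expected MI is averaged over explicitly enumerated permutations.

random_web <- function(n, p = 0.25, name = "w", prefix = "n") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  pairs <- expand.grid(src = nodes, tgt = nodes, stringsAsFactors = FALSE)
  keep <- runif(nrow(pairs)) < p
  foodweb(links = as.matrix(pairs[keep, , drop = FALSE]), nodes = nodes,
          name = name)
}

# set-based re-implementation of the edit cost of a node correspondence
oracle_mapping_cost <- function(g1, g2, m, costs) {
  del <- m$deleted
  ins <- m$inserted
  total <- costs$node * (length(del) + length(ins))
  if (nrow(g1$links)) {
    total <- total + costs$link *
      sum(g1$links[, 1] %in% del | g1$links[, 2] %in% del)
  }
  if (nrow(g2$links)) {
    total <- total + costs$link *
      sum(g2$links[, 1] %in% ins | g2$links[, 2] %in% ins)
  }
  k1 <- link_keys(g1)
  k2 <- link_keys(g2)
  has1 <- function(u, v) paste(u, "->", v) %in% k1
  has2 <- function(u, v) paste(u, "->", v) %in% k2
  flip_price <- min(costs$flip, 2 * costs$link)
  mapped <- names(m$pairs)
  for (u in mapped) {
    if (has1(u, u) != has2(m$pairs[[u]], m$pairs[[u]])) {
      total <- total + costs$link
    }
  }
  if (length(mapped) >= 2) {
    cmb <- combn(mapped, 2)
    for (q in seq_len(ncol(cmb))) {
      u <- cmb[1, q]; v <- cmb[2, q]
      mu <- m$pairs[[u]]; mv <- m$pairs[[v]]
      s1 <- c(has1(u, v), has1(v, u))
      s2 <- c(has2(mu, mv), has2(mv, mu))
      d <- sum(s1 != s2)
      if (d == 0) next
      if (d == 2 && sum(s1) == 1 && all(s1 == rev(s2))) {
        total <- total + flip_price            # pure reversal
      } else if (d == 2) {
        total <- total + 2 * costs$link        # none <-> both
      } else {
        total <- total + costs$link
      }
    }
  }
  total
}

all_perms <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in all_perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# independent minimum over all injective partial correspondences
oracle_exact_cost <- function(g1, g2, costs) {
  V1 <- g1$nodes; V2 <- g2$nodes
  best <- Inf
  for (k in 0:min(length(V1), length(V2))) {
    s1s <- if (k == 0) list(character(0)) else combn(V1, k, simplify = FALSE)
    s2s <- if (k == 0) list(character(0)) else combn(V2, k, simplify = FALSE)
    for (s1 in s1s) for (s2 in s2s) for (p in all_perms(s2)) {
      m <- node_mapping(pairs = stats::setNames(p, s1),
                        deleted = setdiff(V1, s1),
                        inserted = setdiff(V2, p))
      best <- min(best, oracle_mapping_cost(g1, g2, m, costs))
    }
  }
  best
}

# exact expected MI by averaging plug-in MI over every permutation of one
# labeling (the permutation model itself, no hypergeometric shortcut)
oracle_emi_permutations <- function(lu, lv) {
  stopifnot(length(lu) == length(lv), length(lu) <= 8)
  perms <- all_perms(seq_along(lv))
  mean(vapply(perms, function(p) mutual_information(lu, lv[p]), numeric(1)))
}
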