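#' Search parameters for the evolutionary GED heuristic
#'
#' @param population_size chromosomes per generation (>= 2).
#' @param mutation_rate per-gene swap probability in `[0, 1]`.
#' @param elite_fraction proportion of the population copied unchanged.
#' @param stall_limit generations without improvement before stopping; the
#'   evolutionary search has no closed-form stopping rule, so termination is
#'   by stagnation (default 1000 generations).
#' @param max_iterations hard cap on generations per restart.
#' @param seed integer seed; `NULL` draws one from the session RNG so runs are
#'   still reproducible under `set.seed()`.
#' @param restarts independent searches; the best result over restarts is kept.
#' @param seed_with_identity inject the taxon-identity correspondence into the
#'   initial population, so shared composition is never missed by the
#'   label-free search.
#' @return object of class `"search_params"`.
#' @export
search_params <- function(population_size = 128, mutation_rate = 0.05,
                          elite_fraction = 0.1, stall_limit = 1000,
                          max_iterations = 50000, seed = NULL, restarts = 1,
                          seed_with_identity = TRUE) {
  stopifnot(population_size >= 2, mutation_rate >= 0, mutation_rate <= 1,
            elite_fraction >= 0, elite_fraction <= 1, stall_limit >= 1,
            max_iterations >= 1, restarts >= 1)
  structure(list(population_size = as.integer(population_size),
                 mutation_rate = mutation_rate,
                 elite_fraction = elite_fraction,
                 stall_limit = as.integer(stall_limit),
                 max_iterations = as.integer(max_iterations),
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 restarts = as.integer(restarts),
                 seed_with_identity = isTRUE(seed_with_identity)),
            class = "search_params")
}

# deterministic FNV-style hash of arbitrary key parts onto [1, 2^31 - 1],
# used to derive independent per-pair seeds from one master seed
seed_hash <- function(...) {
  s <- paste(unlist(list(...)), collapse = "|")
  h <- 2166136261 %% 2147483648
  for (k in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), as.integer(k))
    h <- (h * 16777619) %% 2147483648
  }
  as.integer(h %% 2147483646) + 1L
}

#' Classify an unordered node pair by link presence
#'
#' @param g a [foodweb].
#' @param u,v two distinct taxon labels present in `g`.
#' @return `"none"`, `"forward"` (u -> v only), `"backward"` (v -> u only), or
#'   `"both"`.
#' @export
pair_state <- function(g, u, v) {
  u <- canonical_taxon(u); v <- canonical_taxon(v)
  if (identical(u, v)) stop("u and v must differ; self-loops are handled separately")
  if (!(u %in% g$nodes) || !(v %in% g$nodes)) stop("u and v must both be nodes of g")
  k <- link_keys(g)
  fwd <- paste(u, "->", v) %in% k
  bwd <- paste(v, "->", u) %in% k
  if (fwd && bwd) "both" else if (fwd) "forward" else if (bwd) "backward" else "none"
}

#' Construct a node correspondence between two webs
#'
#' @param pairs named character vector: names are `g1` taxa, values their
#'   images in `g2`. Must be injective.
#' @param deleted `g1` taxa with no image.
#' @param inserted `g2` taxa with no preimage.
#' @return object of class `"node_mapping"`.
#' @export
node_mapping <- function(pairs = character(0), deleted = character(0),
                         inserted = character(0)) {
  pairs <- stats::setNames(canonical_taxon(pairs), canonical_taxon(names(pairs)))
  m <- structure(list(pairs = pairs, deleted = canonical_taxon(deleted),
                      inserted = canonical_taxon(inserted)),
                 class = "node_mapping")
  if (anyDuplicated(unname(m$pairs)) || anyDuplicated(names(m$pairs))) {
    stop("mapping must be injective")
  }
  m
}

validate_mapping <- function(g1, g2, m) {
  if (!inherits(m, "node_mapping")) stop("`m` must be a node_mapping")
  dom <- c(names(m$pairs), m$deleted)
  img <- c(unname(m$pairs), m$inserted)
  if (anyDuplicated(dom) || !setequal(dom, g1$nodes)) {
    stop("mapping domain must partition the nodes of g1 into mapped and deleted")
  }
  if (anyDuplicated(img) || !setequal(img, g2$nodes)) {
    stop("mapping image plus inserted must partition the nodes of g2")
  }
  invisible(m)
}

# integer encoding of a node_mapping: position i = index of g1 node i's image
# in g2's node order, 0 when deleted
encode_mapping <- function(g1, g2, m) {
  enc <- integer(n_nodes(g1))
  if (length(m$pairs)) {
    i1 <- match(names(m$pairs), g1$nodes)
    enc[i1] <- match(unname(m$pairs), g2$nodes)
  }
  enc
}

decode_mapping <- function(g1, g2, enc) {
  mapped <- enc > 0
  node_mapping(pairs = stats::setNames(g2$nodes[enc[mapped]], g1$nodes[mapped]),
               deleted = g1$nodes[!mapped],
               inserted = setdiff(g2$nodes, g2$nodes[enc[mapped]]))
}

#' Edit cost induced by a node correspondence
#'
#' Total cost of the edit path a correspondence encodes: deleted and inserted
#' species cost `node` each; every link incident to a deleted or inserted
#' species costs `link`; each mapped unordered pair whose link state differs
#' between the webs costs `link` per arc added or removed, except a pure
#' reversal, priced `min(flip, 2 * link)` because deleting and re-inserting
#' the link is always an admissible alternative to flipping it; a self-loop
#' presence mismatch on a mapped species costs `link`.
#'
#' @param g1,g2 [foodweb] objects.
#' @param m a [node_mapping] valid for `(g1, g2)`.
#' @param costs a [cost_scheme].
#' @return nonnegative edit cost.
#' @export
mapping_cost <- function(g1, g2, m, costs) {
  validate_mapping(g1, g2, m)
  ged_mapping_cost_cpp(adjacency_matrix(g1), adjacency_matrix(g2),
                       encode_mapping(g1, g2, m),
                       costs$flip, costs$node, costs$link)
}

#' Normalize a raw edit cost to a [0, 1] dissimilarity score
#'
#' The raw cost is divided by the cost of the trivial edit path that deletes
#' every species and interaction of one web and inserts every one of the
#' other: `C_max = node * (|V1| + |V2|) + link * (|E1| + |E2|)`. 0 means the
#' webs are identical under the best correspondence found; 1 means total
#' replacement. If `C_max` is 0 the score is 0.
#'
#' @param raw_cost nonnegative edit cost.
#' @param g1,g2 the compared webs.
#' @param costs the [cost_scheme] used.
#' @return score in `[0, 1]`.
#' @export
normalize_score <- function(raw_cost, g1, g2, costs) {
  if (raw_cost < 0) stop("raw_cost must be nonnegative")
  cmax <- costs$node * (n_nodes(g1) + n_nodes(g2)) +
    costs$link * (n_links(g1) + n_links(g2))
  if (cmax == 0) return(0)
  min(1, raw_cost / cmax)
}

ged_result <- function(g1, g2, costs, raw_cost, enc, evaluations, seed, exact,
                       method) {
  structure(list(raw_cost = raw_cost,
                 score = normalize_score(raw_cost, g1, g2, costs),
                 mapping = decode_mapping(g1, g2, enc),
                 evaluations = evaluations,
                 seed = seed, exact = exact, method = method,
                 costs = costs, webs = c(g1$name, g2$name)),
            class = "ged")
}

#' @export
print.ged <- function(x, ...) {
  cat(sprintf("Graph edit distance (%s%s) between '%s' and '%s'\n",
              x$method, if (x$exact) ", exact" else "", x$webs[1], x$webs[2]))
  cat(sprintf("  raw cost %.4f, normalized score %.4f  (0 = identical, 1 = total replacement)\n",
              x$raw_cost, x$score))
  cat(sprintf("  %d mapped, %d deleted, %d inserted taxa; %s evaluations\n",
              length(x$mapping$pairs), length(x$mapping$deleted),
              length(x$mapping$inserted), format(x$evaluations, big.mark = ",")))
  invisible(x)
}

# all injective partial maps {1..n1} -> {0, 1..n2} in lexicographic order
# (0 = deleted first); ties in cost are therefore broken lexicographically
enumerate_mappings <- function(n1, n2) {
  res <- vector("list", 0)
  rec <- function(i, cur, used) {
    if (i > n1) {
      res[[length(res) + 1L]] <<- cur
      return(invisible(NULL))
    }
    cur[i] <- 0L
    rec(i + 1L, cur, used)
    for (j in seq_len(n2)) {
      if (!used[j]) {
        cur[i] <- j
        used[j] <- TRUE
        rec(i + 1L, cur, used)
        used[j] <- FALSE
      }
    }
  }
  rec(1L, integer(n1), logical(n2))
  if (length(res) == 0) list(integer(0)) else res
}

#' Exact graph edit distance by exhaustive enumeration
#'
#' Enumerates every injective partial correspondence between the node sets
#' (including the empty one) and returns the minimum-cost edit path. Feasible
#' only for very small webs; the enumeration grows super-factorially.
#'
#' @param g1,g2 [foodweb] objects.
#' @param costs a [cost_scheme].
#' @param size_cap refuse webs larger than this (default 6 nodes).
#' @return object of class `"ged"` with `exact = TRUE`.
#' @export
exact_ged <- function(g1, g2, costs, size_cap = 6) {
  if (n_nodes(g1) > size_cap || n_nodes(g2) > size_cap) {
    stop(sprintf("webs exceed the exact-solver cap (%d nodes); use evolutionary_ged()",
                 size_cap))
  }
  maps <- enumerate_mappings(n_nodes(g1), n_nodes(g2))
  M <- do.call(rbind, maps)
  if (is.null(M)) M <- matrix(integer(0), nrow = 1, ncol = 0)
  cc <- ged_mapping_costs_cpp(adjacency_matrix(g1), adjacency_matrix(g2), M,
                              costs$flip, costs$node, costs$link)
  best <- which.min(cc)
  ged_result(g1, g2, costs, cc[best], M[best, ], length(cc), NA_integer_,
             TRUE, "enumeration")
}

identity_encoding <- function(g1, g2) {
  enc <- match(g1$nodes, g2$nodes)
  enc[is.na(enc)] <- 0L
  as.integer(enc)
}

#' Graph edit distance under the fixed taxon-identity correspondence
#'
#' Evaluates the single correspondence that pairs equal taxon codes and
#' deletes/inserts everything else; no search. This is the label-honouring
#' alternative to the label-free (topology-driven) search.
#'
#' @inheritParams exact_ged
#' @return object of class `"ged"` with `exact = FALSE`.
#' @export
identity_ged <- function(g1, g2, costs) {
  enc <- identity_encoding(g1, g2)
  rc <- ged_mapping_cost_cpp(adjacency_matrix(g1), adjacency_matrix(g2), enc,
                             costs$flip, costs$node, costs$link)
  ged_result(g1, g2, costs, rc, enc, 1, NA_integer_, FALSE, "identity")
}

#' Graph edit distance by evolutionary search
#'
#' Label-free error-tolerant matching: a population of complete node
#' correspondences (the smaller web padded with null partners) is evolved by
#' elitist selection, pairwise assignment crossover and swap mutation, with
#' the induced edit cost as fitness. The search stops after `stall_limit`
#' generations without improvement. The delete-all/insert-all correspondence
#' is always in the initial population, so the returned raw cost never exceeds
#' `C_max`; with `seed_with_identity` the taxon-identity correspondence is too,
#' so identical webs score 0. Deterministic given the seed.
#'
#' @inheritParams exact_ged
#' @param params a [search_params].
#' @return object of class `"ged"` with `exact = FALSE`.
#' @export
evolutionary_ged <- function(g1, g2, costs, params = search_params()) {
  seed <- params$seed
  if (is.null(seed)) seed <- sample.int(2147483646L, 1)
  idm <- if (params$seed_with_identity) identity_encoding(g1, g2) else integer(0)
  res <- ged_evolve_cpp(adjacency_matrix(g1), adjacency_matrix(g2),
                        costs$flip, costs$node, costs$link,
                        params$population_size, params$mutation_rate,
                        params$elite_fraction, params$stall_limit,
                        params$max_iterations, params$restarts,
                        seed, idm)
  ged_result(g1, g2, costs, res$cost, res$map, res$evaluations, seed, FALSE,
             "evolutionary")
}

#' Compare two food webs by graph edit distance
#'
#' Front end dispatching to the evolutionary heuristic (default), the exact
#' enumerator (tiny webs only) or the fixed taxon-identity correspondence.
#'
#' @inheritParams exact_ged
#' @param mode `"evolve"`, `"exact"` or `"identity"`.
#' @param params [search_params] for the evolutionary mode.
#' @param size_cap node cap for the exact mode.
#' @return object of class `"ged"`: raw cost, normalized score in `[0, 1]`,
#'   the best node correspondence found, evaluation count, seed and an
#'   exactness flag.
#' @examples
#' w1 <- foodweb(rbind(c("a", "b"), c("b", "c")), name = "w1")
#' w2 <- foodweb(rbind(c("a", "b"), c("c", "b")), name = "w2")
#' ged(w1, w2, cost_scheme(0.75, 0.5, 0.25), mode = "exact")
#' @export
ged <- function(g1, g2, costs, mode = c("evolve", "exact", "identity"),
                params = search_params(), size_cap = 6) {
  mode <- match.arg(mode)
  switch(mode,
         evolve = evolutionary_ged(g1, g2, costs, params),
         exact = exact_ged(g1, g2, costs, size_cap),
         identity = identity_ged(g1, g2, costs))
}
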