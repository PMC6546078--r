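#' @useDynLib ecoged, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats cor runif rbeta
#' @importFrom utils read.csv write.csv combn
NULL

#' Canonicalize taxon labels
#'
#' Taxon identity is compared after trimming surrounding whitespace and case
#' folding, so that trivially misspelled duplicates ("Deleatidium " vs
#' "deleatidium") collapse to one taxon.
#'
#' @param x character vector of raw labels.
#' @return character vector of canonical taxon codes.
#' @export
canonical_taxon <- function(x) {
  x <- tolower(trimws(as.character(x)))
  x
}

#' Construct a directed food web
#'
#' A food web is a named directed graph: a set of taxon codes (nodes) and a set
#' of consumer-resource links, oriented resource -> consumer (the direction of
#' energy flow). Self-loops (cannibalism) are permitted; duplicate links are
#' collapsed silently and counted.
#'
#' @param links two-column matrix or data.frame (source, target), or `NULL` for
#'   a web without links.
#' @param nodes character vector of taxon labels; defaults to the labels
#'   appearing in `links`. Isolated nodes may be added here.
#' @param name single string naming the web.
#' @return object of class `"foodweb"` with elements `name`, `nodes` (canonical
#'   codes) and `links` (two-column character matrix). The number of duplicate
#'   link rows collapsed is stored in attribute `"duplicates_collapsed"`.
#' @examples
#' w <- foodweb(rbind(c("algae", "mayfly"), c("mayfly", "trout")), name = "demo")
#' w
#' @export
foodweb <- function(links = NULL, nodes = NULL, name = "") {
  if (is.null(links)) {
    lm <- matrix(character(0), ncol = 2)
  } else {
    lm <- as.matrix(links)
    if (length(lm) == 0) lm <- matrix(character(0), ncol = 2)
    if (ncol(lm) != 2) stop("`links` must have exactly two columns (source, target)")
    lm <- cbind(canonical_taxon(lm[, 1]), canonical_taxon(lm[, 2]))
  }
  nodes <- unique(c(canonical_taxon(nodes), as.vector(t(lm))))
  if (any(!nzchar(nodes))) stop("empty taxon label")
  ndup <- 0L
  if (nrow(lm) > 0) {
    key <- paste(lm[, 1], lm[, 2], sep = "\r")
    dup <- duplicated(key)
    ndup <- sum(dup)
    lm <- lm[!dup, , drop = FALSE]
  }
  colnames(lm) <- c("source", "target")
  w <- structure(list(name = as.character(name), nodes = nodes, links = lm),
                 class = "foodweb")
  attr(w, "duplicates_collapsed") <- ndup
  w
}

#' @export
print.foodweb <- function(x, ...) {
  cat(sprintf("Food web '%s': %d taxa, %d directed links (resource -> consumer)\n",
              x$name, length(x$nodes), nrow(x$links)))
  invisible(x)
}

#' @rdname foodweb
#' @param w object to test.
#' @export
is.foodweb <- function(w) inherits(w, "foodweb")

n_nodes <- function(w) length(w$nodes)
n_links <- function(w) nrow(w$links)

#' Link keys of a web
#'
#' Identifies each directed interaction by its endpoint taxon codes so links
#' can be compared across webs.
#'
#' @param w a `foodweb`.
#' @return character vector, one `"source -> target"` key per link.
#' @export
link_keys <- function(w) {
  if (nrow(w$links) == 0) return(character(0))
  paste(w$links[, 1], w$links[, 2], sep = " -> ")
}

#' Adjacency matrix of a web
#'
#' @param w a `foodweb`.
#' @return logical `|V| x |V|` matrix; `[i, j]` is `TRUE` when there is a link
#'   node i -> node j. Row/column order follows `w$nodes`.
#' @export
adjacency_matrix <- function(w) {
  n <- n_nodes(w)
  A <- matrix(FALSE, n, n, dimnames = list(w$nodes, w$nodes))
  if (nrow(w$links) > 0) {
    A[cbind(match(w$links[, 1], w$nodes), match(w$links[, 2], w$nodes))] <- TRUE
  }
  A
}

resolve_lines <- function(source) {
  if (inherits(source, "connection")) return(readLines(source, warn = FALSE))
  if (!is.character(source)) stop("`source` must be a file path, literal text, or connection")
  if (length(source) != 1) return(source)
  if (grepl("\n", source, fixed = TRUE)) {
    return(strsplit(source, "\n", fixed = TRUE)[[1]])
  }
  if (!file.exists(source)) stop("file not found: ", source)
  readLines(source, warn = FALSE)
}

#' Read a food web from an edge list
#'
#' Expects a header line `source,target` (comma- or tab-separated) followed by
#' one link per row. Rows with a single field declare an isolated taxon.
#' Duplicate link rows are collapsed. An empty input yields an empty web.
#'
#' @param source file path, literal text containing newlines, character vector
#'   of lines, or connection.
#' @param name name for the resulting web.
#' @return a [foodweb].
#' @export
read_edgelist <- function(source, name = "") {
  lines <- resolve_lines(source)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) return(foodweb(name = name))
  sep <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  body <- lines[-1]
  if (length(body) == 0) return(foodweb(name = name))
  parts <- strsplit(body, sep, fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf > 2)) {
    bad <- which(nf > 2)[1]
    stop(sprintf("malformed edge-list row at line %d: expected at most 2 fields, got %d",
                 bad + 1L, nf[bad]))
  }
  iso <- vapply(parts, function(p) length(p) == 1 || !nzchar(trimws(p[2])), logical(1))
  singles <- vapply(parts[iso], `[[`, character(1), 1)
  edges <- parts[!iso]
  lm <- if (length(edges)) do.call(rbind, edges) else NULL
  foodweb(links = lm, nodes = singles, name = name)
}

#' Read a food web from a labelled 0/1 adjacency matrix
#'
#' The common distribution format for empirical webs is a presence matrix with
#' taxon labels on both margins. Because the matrix convention (who eats whom)
#' is often undocumented, `orientation` must be supplied explicitly; there is
#' deliberately no default, since a wrong guess silently reverses every link.
#'
#' @param source file path, literal text, character vector of lines, or
#'   connection holding a CSV whose first column and first row are labels and
#'   whose cells are 0/1.
#' @param name name for the resulting web.
#' @param orientation `"rows-eat-columns"` (cell `[r, c] = 1` means row taxon r
#'   consumes column taxon c, producing link c -> r) or `"columns-eat-rows"`
#'   (link r -> c). Links are always stored resource -> consumer.
#' @return a [foodweb]; the node set is the union of row and column labels.
#' @export
read_adjacency <- function(source, name = "", orientation) {
  if (missing(orientation)) {
    stop("`orientation` must be given explicitly: \"rows-eat-columns\" or \"columns-eat-rows\"")
  }
  orientation <- match.arg(orientation, c("rows-eat-columns", "columns-eat-rows"))
  lines <- resolve_lines(source)
  df <- read.csv(text = paste(lines, collapse = "\n"), check.names = FALSE,
                 stringsAsFactors = FALSE)
  row_labs <- canonical_taxon(df[[1]])
  col_labs <- canonical_taxon(names(df)[-1])
  if (anyDuplicated(row_labs)) stop("duplicated row label in adjacency matrix")
  if (anyDuplicated(col_labs)) stop("duplicated column label in adjacency matrix")
  M <- as.matrix(df[, -1, drop = FALSE])
  suppressWarnings(storage.mode(M) <- "numeric")
  if (anyNA(M) || !all(M %in% c(0, 1))) stop("adjacency cells must be 0 or 1")
  idx <- which(M == 1, arr.ind = TRUE)
  lm <- NULL
  if (nrow(idx) > 0) {
    r <- row_labs[idx[, 1]]
    co <- col_labs[idx[, 2]]
    lm <- if (orientation == "rows-eat-columns") cbind(co, r) else cbind(r, co)
  }
  foodweb(links = lm, nodes = c(row_labs, col_labs), name = name)
}

#' Serialize a food web
#'
#' @param web a [foodweb].
#' @param format `"edgelist"` (CSV, header `source,target`, isolated taxa as
#'   one-field rows) or `"graphml"` (via igraph; node attribute `taxon`, graph
#'   attribute `name`).
#' @param file optional path; when given the text is also written there.
#' @return character vector of lines (invisibly when `file` is given).
#' @seealso [read_edgelist()], [read_graphml()] for the inverse operations;
#'   round trips restore the same node and link sets.
#' @export
write_web <- function(web, format = c("edgelist", "graphml"), file = NULL) {
  format <- match.arg(format)
  if (format == "edgelist") {
    iso <- setdiff(web$nodes, as.vector(web$links))
    out <- c("source,target",
             if (nrow(web$links)) paste(web$links[, 1], web$links[, 2], sep = ","),
             iso)
  } else {
    g <- as_igraph(web)
    tmp <- tempfile(fileext = ".graphml")
    on.exit(unlink(tmp), add = TRUE)
    igraph::write_graph(g, tmp, format = "graphml")
    out <- readLines(tmp, warn = FALSE)
  }
  if (!is.null(file)) {
    writeLines(out, file)
    return(invisible(out))
  }
  out
}

#' Convert a food web to an igraph object
#'
#' @param web a [foodweb].
#' @return directed `igraph` graph with vertex attribute `taxon` and graph
#'   attribute `name`.
#' @export
as_igraph <- function(web) {
  g <- igraph::make_empty_graph(n = 0, directed = TRUE)
  g <- igraph::add_vertices(g, length(web$nodes), name = web$nodes,
                            taxon = web$nodes)
  if (nrow(web$links) > 0) {
    g <- igraph::add_edges(g, rbind(match(web$links[, 1], web$nodes),
                                    match(web$links[, 2], web$nodes)))
  }
  igraph::graph_attr(g, "name") <- web$name
  g
}

#' Read a food web from GraphML
#'
#' @param source file path or character vector of GraphML lines.
#' @param name optional name overriding the graph attribute.
#' @return a [foodweb].
#' @export
read_graphml <- function(source, name = NULL) {
  if (is.character(source) && (length(source) > 1 || grepl("\n", source[1], fixed = TRUE))) {
    tmp <- tempfile(fileext = ".graphml")
    on.exit(unlink(tmp), add = TRUE)
    writeLines(source, tmp)
    source <- tmp
  }
  g <- igraph::read_graph(source, format = "graphml")
  labs <- igraph::vertex_attr(g, "taxon")
  if (is.null(labs)) labs <- igraph::vertex_attr(g, "name")
  if (is.null(labs)) labs <- as.character(seq_len(igraph::vcount(g)))
  el <- igraph::as_edgelist(g, names = FALSE)
  lm <- if (nrow(el)) cbind(labs[el[, 1]], labs[el[, 2]]) else NULL
  if (is.null(name)) {
    name <- tryCatch(igraph::graph_attr(g, "name"), error = function(e) "")
    if (is.null(name) || length(name) != 1) name <- ""
  }
  foodweb(links = lm, nodes = labs, name = name)
}

#' Bundle food webs into a community set
#'
#' @param webs list of [foodweb] objects with distinct names.
#' @return object of class `"community_set"`: the list of webs plus a `pool`
#'   attribute holding the union of all taxon codes.
#' @export
community_set <- function(webs) {
  if (!length(webs) || !all(vapply(webs, is.foodweb, logical(1)))) {
    stop("`webs` must be a non-empty list of foodweb objects")
  }
  nms <- vapply(webs, function(w) w$name, character(1))
  if (anyDuplicated(nms)) stop("web names must be unique")
  names(webs) <- nms
  structure(webs, class = "community_set",
            pool = sort(unique(unlist(lapply(webs, `[[`, "nodes")))))
}

#' @export
print.community_set <- function(x, ...) {
  sizes <- vapply(x, n_nodes, integer(1))
  links <- vapply(x, n_links, integer(1))
  cat(sprintf("Community set: %d webs, %d taxa in the regional pool\n",
              length(x), length(attr(x, "pool"))))
  cat(sprintf("  richness %d-%d, links %d-%d\n",
              min(sizes), max(sizes), min(links), max(links)))
  invisible(x)
}

#' Apply a synonym table to taxon labels
#'
#' Implements the data-cleaning step of harmonizing scientific names and
#' typographical variants before comparison. Labels are first canonicalized,
#' then replaced via `synonyms` (a named character vector, raw label ->
#' canonical label). Nodes that merge have their links unioned; duplicates are
#' dropped. Applying the same table twice is a no-op.
#'
#' @param x a [foodweb] or [community_set].
#' @param synonyms named character vector; names are raw labels, values the
#'   canonical label. Labels absent from the table are left as-is (after
#'   canonicalization).
#' @return object of the same class with a `"substitutions"` attribute: a
#'   data.frame of the replacements performed (per web for a community set).
#' @export
clean_taxa <- function(x, synonyms = character(0)) {
  if (inherits(x, "community_set")) {
    cleaned <- lapply(unclass(x), clean_taxa, synonyms = synonyms)
    subs <- do.call(rbind, lapply(cleaned, attr, "substitutions"))
    out <- community_set(cleaned)
    attr(out, "substitutions") <- subs
    return(out)
  }
  stopifnot(is.foodweb(x))
  map_from <- canonical_taxon(names(synonyms))
  map_to <- canonical_taxon(unname(synonyms))
  rename <- function(v) {
    i <- match(v, map_from)
    ifelse(is.na(i), v, map_to[i])
  }
  new_nodes <- rename(x$nodes)
  new_links <- x$links
  if (nrow(new_links) > 0) {
    new_links <- cbind(rename(new_links[, 1]), rename(new_links[, 2]))
  }
  changed <- new_nodes != x$nodes
  subs <- data.frame(web = rep(x$name, sum(changed)),
                     raw = x$nodes[changed], canonical = new_nodes[changed],
                     stringsAsFactors = FALSE)
  out <- foodweb(links = new_links, nodes = new_nodes, name = x$name)
  attr(out, "substitutions") <- subs
  out
}

#' Compositional overlap counts between two webs
#'
#' @param w1,w2 [foodweb] objects.
#' @return named integer vector `c(a, b, c)`: taxa only in `w1`, only in `w2`,
#'   and shared.
#' @export
composition_counts <- function(w1, w2) {
  shared <- intersect(w1$nodes, w2$nodes)
  c(a = length(w1$nodes) - length(shared),
    b = length(w2$nodes) - length(shared),
    c = length(shared))
}
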