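#' Equal-frequency discretization
#'
#' Bins a numeric vector into `nbins` classes of (near-)equal occupancy,
#' boundaries at empirical quantiles. Ties are kept together: points with
#' equal values always share a label (so a constant vector collapses to a
#' single bin, whatever `nbins` says); within distinct values, assignment
#' follows the stable sort order of (value, original index). Labels are
#' consecutive integers `1..k` with `k <= nbins`.
#'
#' @param x numeric vector, length `n >= nbins`.
#' @param nbins number of bins, `>= 1`.
#' @return integer vector of bin labels, with attribute `"k"` giving the
#'   number of distinct labels actually used.
#' @examples
#' table(discretize_equal_frequency(1:12, 3))
#' @export
discretize_equal_frequency <- function(x, nbins) {
  n <- length(x)
  nbins <- as.integer(nbins)
  if (nbins < 1) stop("nbins must be >= 1")
  if (nbins > n) stop("nbins exceeds the number of observations")
  ord <- order(x)                       # stable: ties keep original index order
  bounds <- round(seq(0, n, length.out = nbins + 1))
  sl <- integer(n)
  for (i in seq_len(nbins)) {
    if (bounds[i + 1] > bounds[i]) sl[(bounds[i] + 1):bounds[i + 1]] <- i
  }
  # ties never straddle a boundary: a run of equal values takes the label of
  # its first element in sorted order
  xv <- x[ord]
  run_start <- c(TRUE, xv[-1] != xv[-n])
  sl <- sl[which(run_start)[cumsum(run_start)]]
  # relabel to consecutive 1..k
  sl <- match(sl, sort(unique(sl)))
  lab <- integer(n)
  lab[ord] <- sl
  attr(lab, "k") <- max(sl)
  lab
}

#' Plug-in entropy of a labeling (nats)
#'
#' @param l vector of discrete labels.
#' @return `-sum(p * log(p))` over the empirical label frequencies, with
#'   `0 * log(0) = 0`.
#' @export
entropy <- function(l) {
  if (length(l) == 0) return(0)
  p <- as.numeric(table(l)) / length(l)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Plug-in mutual information between two labelings (nats)
#'
#' @param lu,lv equal-length label vectors.
#' @return `sum p(u,v) log(p(u,v) / (p(u) p(v)))`, nonnegative and at most
#'   `min(H(U), H(V))` up to rounding.
#' @export
mutual_information <- function(lu, lv) {
  if (length(lu) != length(lv)) stop("labelings must have equal length")
  tab <- table(lu, lv)
  mi_from_table(tab)
}

mi_from_table <- function(tab) {
  N <- sum(tab)
  if (N == 0) return(0)
  a <- rowSums(tab); b <- colSums(tab)
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + (nij / N) * log(N * nij / (a[i] * b[j]))
  }
  max(0, mi)
}

#' Expected mutual information under the fixed-margin permutation model
#'
#' Exact expectation of the plug-in MI over all contingency tables with the
#' observed row and column margins, each weighted by its hypergeometric
#' probability (the distribution induced by randomly permuting one labeling).
#' Computed in log-factorial space for numerical stability; exact for the
#' table sizes arising here (N up to 1e4).
#'
#' @param tab contingency table (matrix of counts).
#' @return expected MI in nats.
#' @export
expected_mi <- function(tab) {
  tab <- as.matrix(tab)
  a <- rowSums(tab); b <- colSums(tab); N <- sum(tab)
  if (N == 0) return(0)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - N)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      term <- (nij / N) * log(N * nij / (ai * bj))
      lw <- lfactorial(ai) + lfactorial(bj) +
        lfactorial(N - ai) + lfactorial(N - bj) - lfactorial(N) -
        lfactorial(nij) - lfactorial(ai - nij) - lfactorial(bj - nij) -
        lfactorial(N - ai - bj + nij)
      emi <- emi + sum(term * exp(lw))
    }
  }
  emi
}

ami_from_labels <- function(lu, lv) {
  if (length(lu) != length(lv)) stop("labelings must have equal length")
  tab <- table(lu, lv)
  mi <- mi_from_table(tab)
  h_u <- entropy(lu)
  h_v <- entropy(lv)
  emi <- expected_mi(tab)
  denom <- max(h_u, h_v) - emi
  ami <- if (abs(denom) < 1e-14) {
    if (all(lu == lu[1]) && all(lv == lv[1])) 1 else 0
  } else {
    (mi - emi) / denom
  }
  structure(list(mi = mi, h_u = h_u, h_v = h_v, emi = emi, ami = ami),
            class = "ami")
}

#' Adjusted mutual information between two numeric vectors
#'
#' Discretizes both vectors into `nbins` equal-frequency classes, then returns
#' the chance-adjusted, max-normalized mutual information
#' `(I - E\{I\}) / (max(H(U), H(V)) - E\{I\})`, where the expectation is over
#' random permutations with the margins fixed. AMI is ~0 for unrelated
#' vectors (whatever their marginal entropies) and 1 when the discretized
#' vectors carry identical information. When both labelings collapse to a
#' single bin the ratio is degenerate; identical constant labelings score 1.
#'
#' @param x,y equal-length numeric vectors (length >= 2), or integer labelings
#'   when `discretize = FALSE`.
#' @param nbins bins for the equal-frequency discretization; default
#'   `round(n^(1/3))` (5 at n = 120).
#' @param discretize set to `FALSE` to treat `x` and `y` as ready-made labels.
#' @return object of class `"ami"`: list with `mi`, `h_u`, `h_v`, `emi` (all
#'   nats) and `ami`.
#' @examples
#' set.seed(1)
#' x <- runif(120)
#' ami(x, x)$ami          # identical information: 1
#' ami(x, runif(120))$ami # unrelated: near 0
#' @export
ami <- function(x, y, nbins = NULL, discretize = TRUE) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 2) stop("need at least two observations")
  if (discretize) {
    if (is.null(nbins)) nbins <- max(1L, as.integer(round(length(x)^(1 / 3))))
    lu <- discretize_equal_frequency(x, nbins)
    lv <- discretize_equal_frequency(y, nbins)
  } else {
    lu <- x; lv <- y
  }
  ami_from_labels(lu, lv)
}

#' @export
print.ami <- function(x, ...) {
  cat(sprintf("Adjusted mutual information: %.4f\n", x$ami))
  cat(sprintf("  MI %.4f, H(U) %.4f, H(V) %.4f, E{MI} %.4f (nats)\n",
              x$mi, x$h_u, x$h_v, x$emi))
  invisible(x)
}
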