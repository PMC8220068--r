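#' Convert per-subject similarity ratings to an average distance matrix
#'
#' Each subject rates the semantic similarity of every class pair on a
#' 0-10 scale (0 = unrelated, 10 = equivalent). Ratings are transformed
#' to distances by complement and rescaled by the scale maximum,
#' `d = (10 - s) / 10` — division by 10 rather than observed min-max,
#' preserving the scale anchors — then averaged across subjects.
#'
#' @param ratings a list of symmetric per-subject similarity matrices
#'   in `[0, 10]` with matching dimnames.
#' @return A symmetric matrix in `[0, 1]` with zero diagonal, class
#'   `semantic_distance`.
#' @export
similarity_to_distance <- function(ratings) {
  if (!is.list(ratings) || length(ratings) == 0L)
    stop("ratings must be a non-empty list of matrices")
  labels <- rownames(ratings[[1]])
  mats <- lapply(seq_along(ratings), function(i) {
    s <- as.matrix(ratings[[i]])
    if (nrow(s) != ncol(s)) stop("similarity matrix ", i, " is not square")
    if (any(!is.finite(s)) || any(s < 0 | s > 10))
      stop("similarity ratings must lie in [0, 10] (subject ", i, ")")
    if (max(abs(s - t(s))) > 1e-8)
      stop("similarity matrix ", i, " is not symmetric")
    (10 - s) / 10
  })
  D <- Reduce(`+`, mats) / length(mats)
  diag(D) <- 0
  dimnames(D) <- list(labels, labels)
  structure(D, class = c("semantic_distance", "matrix"))
}

.check_distance_matrix <- function(D) {
  D <- unclass(as.matrix(D))
  if (nrow(D) != ncol(D)) stop("distance matrix must be square")
  if (any(!is.finite(D))) stop("distance matrix must be finite")
  if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
  if (any(abs(diag(D)) > 1e-12)) stop("distance matrix diagonal must be 0")
  D
}

#' Non-metric multidimensional scaling of a class-distance matrix
#'
#' Kruskal's non-metric MDS (monotone-regression disparities, stress-1
#' criterion) via [MASS::isoMDS()], with multiple seeded restarts: the
#' first initialization is the classical-scaling solution, the rest are
#' random; the embedding with the lowest stress is kept and centred at
#' the origin. Zero off-diagonal distances are floored at `1e-6`
#' (the optimizer requires positive dissimilarities).
#'
#' @param D symmetric distance matrix with zero diagonal.
#' @param dims embedding dimensionality (default 2).
#' @param n_restarts number of initializations (default 20).
#' @param seed integer seed for the random restarts.
#' @return A list with `points` (matrix, rows named like `D`) and
#'   `stress` (Kruskal stress-1, a fraction in `[0, 1]`).
#' @export
nonmetric_mds <- function(D, dims = 2L, n_restarts = 20L, seed = 1L) {
  D <- .check_distance_matrix(D)
  if (all(D == 0)) stop("degenerate input: all distances are zero")
  n <- nrow(D)
  if (n <= dims) stop("need more objects than embedding dimensions")
  Dpos <- D
  Dpos[Dpos == 0] <- 1e-6
  diag(Dpos) <- 0
  dd <- stats::as.dist(Dpos)
  best <- NULL
  set.seed(seed)
  for (r in seq_len(n_restarts)) {
    init <- if (r == 1L) {
      stats::cmdscale(dd, k = dims)
    } else {
      matrix(stats::rnorm(n * dims), n, dims)
    }
    if (ncol(init) < dims)  # degenerate classical solution
      init <- cbind(init, matrix(stats::rnorm(n * (dims - ncol(init))),
                                 n, dims - ncol(init)))
    sol <- tryCatch(MASS::isoMDS(dd, y = init, k = dims, trace = FALSE),
                    error = function(e) NULL)
    if (!is.null(sol) && (is.null(best) || sol$stress < best$stress))
      best <- sol
  }
  if (is.null(best)) stop("non-metric MDS failed for all restarts")
  pts <- scale(best$points, center = TRUE, scale = FALSE)
  attr(pts, "scaled:center") <- NULL
  rownames(pts) <- rownames(D)
  list(points = pts, stress = best$stress / 100)
}

#' Ward clustering of interaction classes
#'
#' Agglomerative hierarchical clustering of the semantic distance
#' matrix with Ward's linkage, cut at the threshold
#' `tau = 0.7 * M_WD`, where `M_WD` is the maximum observed merge
#' height: clusters are the connected components left after removing
#' every merge higher than `tau`.
#'
#' @param D symmetric distance matrix with zero diagonal and class
#'   dimnames.
#' @return An object of class `ward_clusters`: list with `tree`
#'   (the `hclust` object), `cutoff`, `assignments` (named integer
#'   vector) and `n_clusters`.
#' @export
ward_clusters <- function(D) {
  D <- .check_distance_matrix(D)
  if (nrow(D) < 2L) stop("need at least 2 classes")
  hc <- stats::hclust(stats::as.dist(D), method = "ward.D2")
  cutoff <- 0.7 * max(hc$height)
  assignments <- stats::cutree(hc, h = cutoff)
  structure(list(tree = hc, cutoff = cutoff, assignments = assignments,
                 n_clusters = length(unique(assignments))),
            class = "ward_clusters")
}

#' @export
print.ward_clusters <- function(x, ...) {
  cat("Ward clustering: ", x$n_clusters, " cluster(s) at cutoff ",
      format(x$cutoff, digits = 4), " (0.7 x max merge height)\n",
      sep = "")
  print(x$assignments)
  invisible(x)
}

#' Correlation between mislabeling probability and semantic distance
#'
#' Pearson correlation across all unordered class pairs between the
#' mislabeling probability from the labeling experiment and the average
#' semantic distance from the similarity survey;
#' `t = r * sqrt((n - 2) / (1 - r^2))` with `df = n - 2`, `n` the
#' number of unordered pairs (66 pairs of 12 classes give df = 64).
#'
#' @param P symmetric mislabeling-probability matrix
#'   (see [mislabeling_probability()]).
#' @param D symmetric semantic distance matrix; dimnames must match
#'   `P`'s.
#' @return A list with `r`, `t`, `df`, `p`, `n_pairs`.
#' @export
mislabeling_distance_correlation <- function(P, D) {
  P <- unclass(as.matrix(P)); D <- .check_distance_matrix(D)
  if (!identical(dim(P), dim(D)))
    stop("P and D must have identical dimensions")
  if (!is.null(rownames(P)) && !is.null(rownames(D)) &&
      !identical(rownames(P), rownames(D)))
    stop("P and D label sets do not match")
  up <- upper.tri(P)
  pv <- P[up]; dv <- D[up]
  n <- length(pv)
  if (n < 3L) stop("insufficient data: need at least 3 class pairs")
  ct <- stats::cor.test(pv, dv, method = "pearson")
  list(r = unname(ct$estimate), t = unname(ct$statistic),
       df = unname(ct$parameter), p = ct$p.value, n_pairs = n)
}
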