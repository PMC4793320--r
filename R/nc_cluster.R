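#' Linear discriminant projection with nest samples as groups
#'
#' The first step of nest-centroid (NC) clustering: a cumulative LDA in
#' which the grouping variable is the nest sample, not a species
#' hypothesis. Workers from one nest are close kin (often sisters), so
#' nests are legitimate a-priori groups even when species limits are
#' unknown. All `min(G - 1, p)` discriminant axes are retained ("cumulative"
#' — no truncation), ordered by decreasing discriminant eigenvalue.
#'
#' Scores follow the sphering convention: the pooled within-group sample
#' covariance of the scores is the identity, so Euclidean distance in score
#' space is a Mahalanobis-type distance with respect to within-nest
#' variation.
#'
#' @param x Numeric specimen-by-trait matrix (or all-numeric data frame).
#' @param groups Per-specimen group (nest) ids.
#' @param ridge Optional ridge regularization of the pooled within-group
#'   covariance: `ridge * mean(diag(Sw))` is added to the diagonal.
#'   Default 0 (none); required when `n - G < p`.
#' @return An `ld_projection`: list with `scores` (specimen x axis),
#'   `loadings` (trait x axis), `axis_count`, `groups`, `trait_order`,
#'   `center`, `eigenvalues`.
#' @export
fit_group_lda <- function(x, groups, ridge = 0) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("missing values in trait matrix")
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(x))
  if (any(!nzchar(groups) | is.na(groups))) stop("empty group id")
  n <- nrow(x); p <- ncol(x)
  g <- factor(groups)
  G <- nlevels(g)
  if (G < 2) stop("need at least 2 groups")
  if (n - G < p && ridge <= 0)
    stop("within-group scatter is singular (n - G = ", n - G, " < p = ", p,
         "); enable ridge regularization (ridge > 0)")
  center <- colMeans(x)
  xc <- sweep(x, 2, center)
  means <- rowsum(xc, g) / as.vector(table(g))
  resid <- xc - means[as.integer(g), , drop = FALSE]
  Sw <- crossprod(resid) / max(n - G, 1)
  if (ridge > 0) Sw <- Sw + diag(ridge * mean(diag(Sw)), p)
  ew <- eigen(Sw, symmetric = TRUE)
  tol <- max(ew$values) * 1e-10
  if (any(ew$values < tol) && ridge <= 0)
    stop("within-group scatter is numerically singular; ",
         "enable ridge regularization (ridge > 0)")
  W_half_inv <- ew$vectors %*% diag(1 / sqrt(pmax(ew$values, tol)), p) %*%
    t(ew$vectors)
  ng <- as.vector(table(g))
  B <- crossprod(sqrt(ng) * means)           # between-group scatter
  Bs <- W_half_inv %*% B %*% W_half_inv
  eb <- eigen((Bs + t(Bs)) / 2, symmetric = TRUE)
  r <- min(G - 1, p)
  A <- W_half_inv %*% eb$vectors[, seq_len(r), drop = FALSE]
  # deterministic sign: largest-|loading| entry positive on each axis
  for (j in seq_len(r)) {
    i <- which.max(abs(A[, j]))
    if (A[i, j] < 0) A[, j] <- -A[, j]
  }
  dimnames(A) <- list(colnames(x), paste0("LD", seq_len(r)))
  scores <- xc %*% A
  rownames(scores) <- rownames(x)
  structure(list(scores = scores, loadings = A, axis_count = r,
                 groups = as.character(g), trait_order = colnames(x),
                 center = center, eigenvalues = eb$values[seq_len(r)],
                 ridge = ridge),
            class = "ld_projection")
}

#' Project new specimens into an existing discriminant space
#' @param object An `ld_projection`.
#' @param newdata Numeric matrix with the same trait columns.
#' @param ... Unused.
#' @return Score matrix.
#' @export
predict.ld_projection <- function(object, newdata, ...) {
  nd <- as.matrix(newdata)[, object$trait_order, drop = FALSE]
  sweep(nd, 2, object$center) %*% object$loadings
}

#' @export
print.ld_projection <- function(x, ...) {
  cat("Group LDA projection: ", length(unique(x$groups)), " groups, ",
      length(x$trait_order), " traits, ", x$axis_count, " axes\n", sep = "")
  invisible(x)
}

#' Per-nest centroids in discriminant space
#'
#' The "nest centroid" of NC clustering: the arithmetic mean of each
#' nest's specimen score rows.
#'
#' @param proj An `ld_projection` from [fit_group_lda()].
#' @return A `nest_centroids` object: `coords` (nest x axis matrix, rows
#'   named by nest id) and `n_individuals`.
#' @export
nest_centroids <- function(proj) {
  stopifnot(inherits(proj, "ld_projection"))
  g <- factor(proj$groups, levels = unique(proj$groups))
  counts <- as.vector(table(g)[levels(g)])
  coords <- rowsum(proj$scores, g)[levels(g), , drop = FALSE] / counts
  structure(list(coords = coords,
                 n_individuals = stats::setNames(counts, levels(g))),
            class = "nest_centroids")
}

#' Pairwise Euclidean distances between nest centroids
#'
#' Computed in the full discriminant space. Because of the sphering
#' convention this is a Mahalanobis-like distance with respect to
#' within-nest variation.
#'
#' @param centroids A `nest_centroids` object (or a plain coordinate
#'   matrix with ids as row names).
#' @return A [stats::dist] object labeled by nest id.
#' @export
centroid_distances <- function(centroids) {
  coords <- if (inherits(centroids, "nest_centroids")) centroids$coords
            else as.matrix(centroids)
  if (nrow(coords) < 2) stop("need at least 2 centroids")
  stats::dist(coords, method = "euclidean")
}

#' Agglomerative dendrogram of nest centroids
#'
#' Hierarchical clustering of the centroid distance matrix. Leaves are
#' ordered lexicographically by id before linkage so that ties merge the
#' smallest-id pair first, making the tree deterministic.
#'
#' @param d A [stats::dist] object (e.g. from [centroid_distances()]).
#' @param linkage One of `"ward"` (Ward's method on Euclidean distances,
#'   `ward.D2`), `"average"`, `"complete"`, `"single"`.
#' @return An [stats::hclust] tree with `$linkage` recording the tag.
#' @export
build_dendrogram <- function(d, linkage = c("ward", "average", "complete",
                                            "single")) {
  linkage <- match.arg(linkage)
  stopifnot(inherits(d, "dist"))
  ids <- labels(d)
  if (is.null(ids)) ids <- as.character(seq_len(attr(d, "Size")))
  ord <- order(ids)
  m <- as.matrix(d)[ord, ord, drop = FALSE]
  hc <- stats::hclust(stats::as.dist(m),
                      method = if (linkage == "ward") "ward.D2" else linkage)
  hc$linkage <- linkage
  hc
}

#' Export a dendrogram as Newick text
#'
#' Branch lengths derive from merge heights: a leaf branch spans its
#' parent's height, an internal branch the height difference between
#' parent and child. Optional per-leaf annotations (e.g. the final species
#' hypothesis) are prepended to the leaf id with a separator, giving
#' labels like `exiguus-CASENT0077581`. Labels containing Newick-reserved
#' characters are quoted.
#'
#' @param dend An [stats::hclust] tree.
#' @param annotations Optional named character vector, names = leaf ids.
#' @param sep Separator between annotation and id (default `"-"`).
#' @return A single Newick string (terminated by `";"`).
#' @export
to_newick <- function(dend, annotations = NULL, sep = "-") {
  stopifnot(inherits(dend, "hclust"))
  labs <- dend$labels
  if (is.null(labs)) labs <- as.character(seq_along(dend$order))
  if (!is.null(annotations)) {
    hit <- labs %in% names(annotations)
    labs[hit] <- paste0(annotations[labs[hit]], sep, labs[hit])
  }
  quote_lab <- function(s) {
    if (grepl("[](),:;' \t[]", s))
      paste0("'", gsub("'", "''", s), "'")
    else s
  }
  labs <- vapply(labs, quote_lab, character(1))
  node_txt <- function(i, parent_h) {
    # i < 0: leaf -i ; i > 0: merge row i
    if (i < 0)
      return(paste0(labs[-i], ":", format(parent_h, digits = 15)))
    h <- dend$height[i]
    kids <- dend$merge[i, ]
    paste0("(", node_txt(kids[1], h), ",", node_txt(kids[2], h), ")",
           if (!is.na(parent_h))
             paste0(":", format(parent_h - h, digits = 15)))
  }
  n <- length(labs)
  if (n == 1) return(paste0(labs, ";"))
  paste0(node_txt(nrow(dend$merge), NA), ";")
}
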