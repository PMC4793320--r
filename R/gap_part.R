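#' Within-cluster dispersion W
#'
#' The pooled within-cluster sum of squared distances to cluster
#' centroids, `W = sum_r sum_{i in C_r} ||x_i - mean(C_r)||^2`. This is
#' algebraically identical to the pairwise form
#' `sum_r D_r / (2 n_r)` with `D_r` the sum over both ordered pairs of
#' squared Euclidean distances within cluster `r`.
#'
#' @param x Numeric row-by-coordinate matrix.
#' @param labels Per-row cluster labels; every cluster must be non-empty.
#' @return Non-negative scalar.
#' @export
within_dispersion <- function(x, labels) {
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  g <- if (is.factor(labels)) labels else factor(labels)
  if (any(table(g) == 0)) stop("empty cluster")
  cent <- rowsum(x, g) / as.vector(table(g))
  sum((x - cent[as.integer(g), , drop = FALSE])^2)
}

# Cluster x into k groups for every k in 1..kmax; returns n x kmax label
# matrix. hclust builds one tree and cuts it; kmeans (Lloyd, nstart
# restarts, best W kept) runs per k.
cluster_all_k <- function(x, kmax, clusterer = c("hclust", "kmeans"),
                          linkage = "ward", nstart = 10) {
  clusterer <- match.arg(clusterer)
  n <- nrow(x)
  stopifnot(kmax <= n)
  if (clusterer == "hclust") {
    if (n == 1) return(matrix(1L, 1, kmax))
    hc <- stats::hclust(stats::dist(x),
                        method = if (linkage == "ward") "ward.D2" else linkage)
    out <- stats::cutree(hc, k = seq_len(kmax))
    return(matrix(as.integer(out), n, kmax))
  }
  out <- matrix(1L, n, kmax)
  if (kmax >= 2) for (k in 2:kmax) {
    if (k == n) { out[, k] <- seq_len(n); next }
    km <- suppressWarnings(
      stats::kmeans(x, centers = k, nstart = nstart,
                    algorithm = "Lloyd", iter.max = 50))
    out[, k] <- km$cluster
  }
  out
}

#' Gap statistic profile
#'
#' Estimates the number of clusters by comparing the observed
#' `log W_k` against its expectation under `B` reference datasets drawn
#' uniformly over the data's range in the PCA-rotated frame (with a plain
#' feature-range box as option). The selected `khat` is the smallest `k`
#' with `gap_k >= gap_{k+1} - s_{k+1}`, where
#' `s_k = sd_k * sqrt(1 + 1/B)` and `sd_k` is the (population) SD of the
#' reference `log W*` values; if no `k` qualifies, `khat = kmax`.
#'
#' @param x Numeric data matrix.
#' @param kmax Largest number of clusters tried.
#' @param B Number of reference datasets (the protocol default is 1000).
#' @param clusterer `"hclust"` or `"kmeans"`.
#' @param seed Optional integer seed; the profile is fully reproducible
#'   given it.
#' @param linkage Linkage for the hclust clusterer.
#' @param reference `"pca"` (rotated bounding box) or `"range"`.
#' @return A `gap_profile`: data frame with `k`, `logW`, `ElogW`, `gap`,
#'   `SE`, plus attributes `khat`, `B`, `clusterer`, `seed`.
#' @export
gap_statistic <- function(x, kmax = 15, B = 1000,
                          clusterer = c("hclust", "kmeans"), seed = NULL,
                          linkage = "ward", reference = c("pca", "range")) {
  x <- as.matrix(x)
  clusterer <- match.arg(clusterer)
  reference <- match.arg(reference)
  n <- nrow(x)
  if (kmax < 1) stop("kmax must be >= 1")
  if (kmax > n) stop("kmax (", kmax, ") exceeds number of rows (", n, ")")
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  logW_of <- function(m) {
    lab <- cluster_all_k(m, kmax, clusterer, linkage)
    log(vapply(seq_len(kmax), function(k) within_dispersion(m, lab[, k]),
               numeric(1)))
  }
  logW <- logW_of(x)
  # reference box in the (optionally PCA-rotated) frame
  ctr <- colMeans(x)
  xc <- sweep(x, 2, ctr)
  V <- if (reference == "pca" && n > 1) svd(xc, nu = 0)$v else diag(ncol(x))
  xr <- xc %*% V
  lo <- apply(xr, 2, min); hi <- apply(xr, 2, max)
  ref_logW <- matrix(NA_real_, B, kmax)
  for (b in seq_len(B)) {
    z <- sapply(seq_along(lo), function(j) stats::runif(n, lo[j], hi[j]))
    z <- matrix(z, n) %*% t(V)
    ref_logW[b, ] <- logW_of(z)
  }
  ElogW <- colMeans(ref_logW)
  sdk <- sqrt(colMeans(sweep(ref_logW, 2, ElogW)^2))
  SE <- sdk * sqrt(1 + 1 / B)
  gap <- ElogW - logW
  khat <- kmax
  if (kmax > 1) for (k in seq_len(kmax - 1)) {
    if (gap[k] >= gap[k + 1] - SE[k + 1]) { khat <- k; break }
  }
  if (is.infinite(logW[1])) khat <- 1L  # all points identical
  structure(data.frame(k = seq_len(kmax), logW = logW, ElogW = ElogW,
                       gap = gap, SE = SE),
            class = c("gap_profile", "data.frame"),
            khat = khat, B = B, clusterer = clusterer, seed = seed,
            linkage = linkage, reference = reference)
}

#' @export
print.gap_profile <- function(x, ...) {
  cat("Gap statistic (", attr(x, "clusterer"), ", B = ", attr(x, "B"),
      "): khat = ", attr(x, "khat"), "\n", sep = "")
  print.data.frame(x, digits = 4)
  invisible(x)
}

#' Recursive Gap-statistic partitioning (PART)
#'
#' Runs the Gap statistic on the data; if more than one cluster is
#' returned, the data are split accordingly and the statistic is
#' re-optimized on each subset, recursively, until a subset has fewer than
#' `2 * minSize` rows or the Gap statistic returns one cluster. This finds
#' both top-level clusters and sub-clusters nested within them. Final
#' clusters smaller than `minSize` are relabeled `"OUTLIER"`; the rest are
#' renumbered 1..K in order of first appearance.
#'
#' @inheritParams gap_statistic
#' @param minSize Smallest admissible cluster (default 3); subsets with
#'   fewer than `2 * minSize` rows are never re-split.
#' @return A `part_partition`: `labels` (character vector named by row id,
#'   `"1"..."K"` or `"OUTLIER"`), `method`, `minSize`, `trace` (data frame
#'   of recursion nodes: subset size, khat, whether re-split).
#' @export
part <- function(x, kmax = 15, minSize = 3, B = 1000,
                 clusterer = c("hclust", "kmeans"), seed = NULL,
                 linkage = "ward", reference = c("pca", "range")) {
  x <- as.matrix(x)
  clusterer <- match.arg(clusterer)
  reference <- match.arg(reference)
  stopifnot(minSize >= 1)
  ids <- rownames(x)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(x)))
  if (anyDuplicated(ids)) stop("duplicate row ids")
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  labels <- stats::setNames(rep(NA_character_, nrow(x)), ids)
  trace <- list()
  leaf_counter <- 0L
  rec <- function(idx, node) {
    n_sub <- length(idx)
    k_cap <- min(kmax, floor(n_sub / minSize), n_sub)
    split_done <- FALSE
    khat <- 1L
    if (n_sub >= 2 * minSize && k_cap >= 2) {
      gp <- gap_statistic(x[idx, , drop = FALSE], kmax = k_cap, B = B,
                          clusterer = clusterer, linkage = linkage,
                          reference = reference)
      khat <- attr(gp, "khat")
      if (khat > 1) {
        lab <- cluster_all_k(x[idx, , drop = FALSE], khat, clusterer,
                             linkage)[, khat]
        split_done <- TRUE
        trace[[length(trace) + 1]] <<-
          data.frame(node = node, n = n_sub, khat = khat, split = TRUE)
        for (s in seq_len(khat)) {
          sub <- idx[lab == s]
          if (length(sub) >= 2 * minSize)
            rec(sub, paste0(node, ".", s))
          else {
            leaf_counter <<- leaf_counter + 1L
            labels[sub] <<- as.character(leaf_counter)
            trace[[length(trace) + 1]] <<-
              data.frame(node = paste0(node, ".", s), n = length(sub),
                         khat = NA_integer_, split = FALSE)
          }
        }
      }
    }
    if (!split_done) {
      leaf_counter <<- leaf_counter + 1L
      labels[idx] <<- as.character(leaf_counter)
      trace[[length(trace) + 1]] <<-
        data.frame(node = node, n = n_sub, khat = khat, split = FALSE)
    }
  }
  rec(seq_len(nrow(x)), "root")
  # outlier relabeling, then renumber surviving clusters by first appearance
  sizes <- table(labels)
  labels[labels %in% names(sizes)[sizes < minSize]] <- "OUTLIER"
  keep <- unique(labels[labels != "OUTLIER"])
  remap <- stats::setNames(as.character(seq_along(keep)), keep)
  labels[labels != "OUTLIER"] <- remap[labels[labels != "OUTLIER"]]
  structure(list(labels = labels,
                 method = paste0("part-", clusterer),
                 minSize = minSize, kmax = kmax, B = B, seed = seed,
                 trace = do.call(rbind, trace)),
            class = "part_partition")
}

#' @export
print.part_partition <- function(x, ...) {
  tab <- table(x$labels)
  cat(x$method, ": ", sum(names(tab) != "OUTLIER"), " cluster(s)",
      if ("OUTLIER" %in% names(tab))
        paste0(", ", tab[["OUTLIER"]], " outlier(s)"),
      " over ", length(x$labels), " ids\n", sep = "")
  print(tab)
  invisible(x)
}

#' Number of clusters in a partition
#' @param p A `part_partition`.
#' @return Integer count of non-outlier clusters.
#' @export
n_clusters <- function(p) {
  stopifnot(inherits(p, "part_partition"))
  length(setdiff(unique(p$labels), "OUTLIER"))
}

# Hungarian algorithm (min-cost assignment, square matrix, O(n^3)).
# Returns for each row the assigned column.
hungarian <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1); v <- numeric(n + 1)
  p_ <- integer(n + 1); way <- integer(n + 1)
  for (i in seq_len(n)) {
    p_[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p_[j0 + 1]; delta <- Inf; j1 <- 0L
      for (j in seq_len(n)) if (!used[j + 1]) {
        cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
        if (cur < minv[j + 1]) { minv[j + 1] <- cur; way[j + 1] <- j0 }
        if (minv[j + 1] < delta) { delta <- minv[j + 1]; j1 <- j }
      }
      for (j in 0:n) {
        if (used[j + 1]) { u[p_[j + 1] + 1] <- u[p_[j + 1] + 1] + delta
                           v[j + 1] <- v[j + 1] - delta }
        else minv[j + 1] <- minv[j + 1] - delta
      }
      j0 <- j1
      if (p_[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p_[j0 + 1] <- p_[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p_[j + 1] > 0) assign[p_[j + 1]] <- j
  assign
}

#' Congruence between two partitions
#'
#' Matches the cluster labels of `p2` to those of `p1` by
#' maximum-agreement (Hungarian) assignment on their contingency table.
#' Ids whose matched labels agree and that are outliers in neither
#' partition are congruent; all others — incongruently classified or
#' outlying in either method — are wildcards, to be left without an
#' imposed hypothesis in the confirmatory analysis.
#'
#' @param p1,p2 `part_partition` objects over the same ids.
#' @return A `congruence_set`: `congruent` ids, `wildcard` ids, and
#'   `mapping` (named vector, p2 label -> p1 label).
#' @export
congruence <- function(p1, p2) {
  stopifnot(inherits(p1, "part_partition"), inherits(p2, "part_partition"))
  ids <- names(p1$labels)
  if (!setequal(ids, names(p2$labels)))
    stop("partitions cover different id sets")
  l1 <- p1$labels[ids]; l2 <- p2$labels[ids]
  c1 <- setdiff(unique(l1), "OUTLIER")
  c2 <- setdiff(unique(l2), "OUTLIER")
  m <- max(length(c1), length(c2))
  counts <- matrix(0, m, m,
                   dimnames = list(c(c2, rep("", m - length(c2))),
                                   c(c1, rep("", m - length(c1)))))
  for (a in c2) for (b in c1)
    counts[a, b] <- sum(l2 == a & l1 == b)
  sol <- hungarian(max(counts) - counts)
  mapping <- stats::setNames(colnames(counts)[sol], rownames(counts))
  mapping <- mapping[names(mapping) %in% c2 & mapping %in% c1]
  matched2 <- ifelse(l2 %in% names(mapping), mapping[l2], NA)
  congruent <- ids[!is.na(matched2) & matched2 == l1 &
                     l1 != "OUTLIER" & l2 != "OUTLIER"]
  structure(list(congruent = congruent,
                 wildcard = setdiff(ids, congruent),
                 mapping = mapping),
            class = "congruence_set")
}

#' @export
print.congruence_set <- function(x, ...) {
  cat("Congruence: ", length(x$congruent), " congruent, ",
      length(x$wildcard), " wildcard id(s)\n", sep = "")
  invisible(x)
}
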