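test_that("within_dispersion: analytic cases and the pairwise identity", {
  x <- matrix(1, 5, 3)
  expect_equal(within_dispersion(x, rep(1, 5)), 0)
  two <- rbind(c(0, 0), c(3, 4))                  # distance 5
  expect_equal(within_dispersion(two, c(1, 1)), 25 / 2)
  expect_error(within_dispersion(two, factor(c(1, 1), levels = 1:2)),
               "empty")

  # pairwise-sum form (oracle) equals centroid form to 1e-10
  set.seed(4)
  for (rep in 1:5) {
    x <- matrix(rnorm(40 * 3), 40, 3)
    lab <- sample(1:4, 40, replace = TRUE)
    D <- as.matrix(dist(x))^2
    W_pair <- sum(vapply(unique(lab), function(r) {
      idx <- lab == r
      sum(D[idx, idx]) / (2 * sum(idx))
    }, numeric(1)))
    expect_equal(within_dispersion(x, lab), W_pair, tolerance = 1e-10)
  }
})

test_that("kmeans logW is non-increasing in k on tiny exhaustive instances", {
  # brute-force oracle: minimal W over all partitions into k non-empty
  # clusters must be non-increasing; exhaustive restarts approximate it
  set.seed(6)
  x <- matrix(rnorm(8 * 2), 8, 2)
  all_parts <- function(n, k) {
    grid <- expand.grid(rep(list(seq_len(k)), n))
    grid[apply(grid, 1, function(r) length(unique(r)) == k), , drop = FALSE]
  }
  brute <- vapply(1:4, function(k)
    min(apply(all_parts(8, k), 1, function(lab)
      within_dispersion(x, unlist(lab)))), numeric(1))
  expect_true(all(diff(brute) <= 1e-12))
  lab <- ncpart:::cluster_all_k(x, 4, "kmeans", nstart = 50)
  logW <- vapply(1:4, function(k) within_dispersion(x, lab[, k]), numeric(1))
  expect_true(all(diff(logW) <= 1e-8))
  expect_equal(logW[1], brute[1], tolerance = 1e-10)
})

test_that("gap profile obeys the SE formula, B=1 edge, determinism", {
  set.seed(13)
  x <- make_blobs(2, n_per = 15, sep = 12)$x
  g1 <- gap_statistic(x, kmax = 4, B = 1, clusterer = "hclust", seed = 5)
  expect_equal(g1$SE, rep(0, 4))            # sd of one ref value is 0
  g <- gap_statistic(x, kmax = 4, B = 20, clusterer = "hclust", seed = 5)
  expect_true(all(g$SE >= 0))
  g2 <- gap_statistic(x, kmax = 4, B = 20, clusterer = "hclust", seed = 5)
  expect_identical(g, g2)                   # byte-identical rerun
  expect_error(gap_statistic(x, kmax = 1000, B = 2), "exceeds")
  expect_error(gap_statistic(x, kmax = 2, B = 0), "B")
})

test_that("gap selects k = 1 for one Gaussian, k = 2 for two far ones", {
  khat_of <- function(seed, K) {
    set.seed(seed)
    x <- if (K == 1) matrix(rnorm(200), 100, 2)
         else make_blobs(2, n_per = 50, sep = 10)$x
    attr(gap_statistic(x, kmax = 5, B = 50, clusterer = "hclust",
                       seed = seed), "khat")
  }
  expect_gte(mean(vapply(1:10, khat_of, numeric(1), K = 1) == 1), 0.9)
  expect_gte(mean(vapply(1:10, khat_of, numeric(1), K = 2) == 2), 0.95)
})

test_that("part respects the 2*minSize stopping rule", {
  # a subset below 2*minSize is returned intact even if clearly bimodal
  set.seed(21)
  x <- rbind(matrix(rnorm(10, 0, .1), 5, 2),
             matrix(rnorm(10, 50, .1), 5, 2))
  rownames(x) <- letters[1:10]
  p <- part(x, kmax = 3, minSize = 6, B = 20, clusterer = "hclust",
            seed = 1)
  expect_equal(n_clusters(p), 1)            # 10 < 2*6: never split
  expect_true(all(p$labels == "1"))
})

test_that("part: single Gaussian is one cluster with an unsplit trace", {
  set.seed(22)
  x <- matrix(rnorm(120), 60, 2)
  rownames(x) <- sprintf("s%02d", 1:60)
  p <- part(x, kmax = 5, minSize = 3, B = 50, clusterer = "hclust", seed = 2)
  expect_equal(n_clusters(p), 1)
  expect_false(any(p$trace$split))
})

test_that("part flags final clusters below minSize as outliers", {
  set.seed(23)
  x <- rbind(matrix(rnorm(40), 20, 2),
             matrix(rnorm(6, 0, .3) + 40, 3, 2))   # tiny far-off blob
  rownames(x) <- sprintf("r%03d", 1:23)
  p <- part(x, kmax = 4, minSize = 4, B = 50, clusterer = "hclust", seed = 3)
  expect_equal(n_clusters(p), 1)
  expect_equal(unname(p$labels[21:23]), rep("OUTLIER", 3))
})

test_that("part recovers multi-level blob structure with both clusterers", {
  set.seed(24)
  y <- rbind(matrix(rnorm(60), 30, 2),
             sweep(matrix(rnorm(30), 15, 2), 2, c(100, 0), "+"),
             sweep(matrix(rnorm(30), 15, 2), 2, c(100, 12), "+"))
  rownames(y) <- sprintf("s%03d", 1:60)
  truth <- rep(1:3, c(30, 15, 15))
  for (clusterer in c("hclust", "kmeans")) {
    p <- part(y, kmax = 5, minSize = 3, B = 50, clusterer = clusterer,
              seed = 5)
    expect_equal(n_clusters(p), 3)
    expect_equal(length(unique(paste(p$labels, truth))), 3)
  }
})

test_that("part labels are invariant to row order up to renaming", {
  set.seed(24)
  blobs <- make_blobs(3, n_per = 12, sep = 20)
  x <- blobs$x
  p1 <- part(x, kmax = 5, minSize = 3, B = 30, clusterer = "hclust", seed = 9)
  perm <- sample(nrow(x))
  p2 <- part(x[perm, ], kmax = 5, minSize = 3, B = 30, clusterer = "hclust",
             seed = 9)
  ids <- rownames(x)
  tab <- table(p1$labels[ids], p2$labels[ids])
  expect_equal(sum(tab > 0), 3)   # one-to-one label correspondence
})

test_that("hungarian matcher equals brute-force optimal assignment", {
  set.seed(25)
  perms <- function(v) if (length(v) == 1) list(v) else
    do.call(c, lapply(seq_along(v), function(i)
      lapply(perms(v[-i]), function(p) c(v[i], p))))
  for (n in c(2, 3, 5)) for (rep in 1:5) {
    cost <- matrix(runif(n * n), n)
    best <- min(vapply(perms(seq_len(n)), function(p)
      sum(cost[cbind(seq_len(n), p)]), numeric(1)))
    sol <- ncpart:::hungarian(cost)
    expect_equal(sum(cost[cbind(seq_len(n), sol)]), best, tolerance = 1e-12)
    expect_equal(sort(sol), seq_len(n))
  }
})

test_that("congruence matches permuted labels, isolates moved ids and
           outliers", {
  lab1 <- setNames(rep(c("1", "2", "3"), each = 4), sprintf("id%02d", 1:12))
  mkpart <- function(labels, method = "part-hclust")
    structure(list(labels = labels, method = method, minSize = 3,
                   trace = NULL), class = "part_partition")
  p1 <- mkpart(lab1)
  # permuted labels, zero wildcards
  relab <- c("1" = "3", "2" = "1", "3" = "2")
  p2 <- mkpart(setNames(relab[lab1], names(lab1)), "part-kmeans")
  cg <- congruence(p1, p2)
  expect_equal(length(cg$wildcard), 0)
  # one id moved: exactly that id is wildcard
  moved <- p2$labels
  moved["id01"] <- "1"   # belongs to matched cluster "3"
  cg2 <- congruence(p1, mkpart(moved))
  expect_equal(cg2$wildcard, "id01")
  # outlier in one partition only is a wildcard
  outl <- p2$labels
  outl["id05"] <- "OUTLIER"
  cg3 <- congruence(p1, mkpart(outl))
  expect_equal(cg3$wildcard, "id05")
  expect_error(congruence(p1, mkpart(lab1[-1])), "id set")
})
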