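two_class_check <- function(labels) {
  lev <- levels(factor(labels))
  if (length(lev) != 2)
    stop("exactly two classes required, got ", length(lev))
  lev
}

ratio_vec <- function(x, numerator, denominator) {
  if (numerator == denominator) stop("numerator must differ from denominator")
  for (tc in c(numerator, denominator))
    if (!tc %in% colnames(x)) stop("trait '", tc, "' not present")
  x[, numerator] / x[, denominator]
}

#' Classification power of a single trait ratio between two taxa
#'
#' Computes the dimensionless ratio per specimen and measures how well it
#' separates the two classes by leave-one-out cross-validated 1-D LDA
#' ("classification power" of the key couplet). Per-class mean and
#' [min, max] are reported in the key's format.
#'
#' @param x Numeric specimen-by-trait matrix (raw micrometre values; ratios
#'   are scale-free so standardization is immaterial here).
#' @param labels Per-specimen class; exactly two classes.
#' @param numerator,denominator Trait codes.
#' @return A `ratio_power` object: ratio name, per-class summaries,
#'   `percent` correct, and a ready-made `key_text` line.
#' @export
ratio_power <- function(x, labels, numerator, denominator) {
  x <- as.matrix(x)
  lev <- two_class_check(labels)
  r <- ratio_vec(x, numerator, denominator)
  keep <- !is.na(r)
  res <- loocv_lda(matrix(r[keep], ncol = 1), labels[keep])
  summ <- do.call(rbind, lapply(lev, function(cl) {
    v <- r[keep][labels[keep] == cl]
    data.frame(class = cl, mean = mean(v), min = min(v), max = max(v))
  }))
  name <- paste0(numerator, "/", denominator)
  structure(list(numerator = numerator, denominator = denominator,
                 ratio = name, classes = lev, summary = summ,
                 percent = res$overall_percent,
                 key_text = sprintf("%s = %.3f [%.3f, %.3f] (%.1f%%)",
                                    name, summ$mean[1], summ$min[1],
                                    summ$max[1], res$overall_percent)),
            class = "ratio_power")
}

#' @export
print.ratio_power <- function(x, ...) {
  cat("Ratio ", x$ratio, ": ", sprintf("%.1f%%", x$percent),
      " LOOCV classification power\n", sep = "")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Joint classification power of two trait ratios
#'
#' 2-D LOOCV-LDA on a pair of ratios, the "combination of best ratios"
#' quoted in key couplets. If the two ratios are numerically collinear the
#' computation falls back to the single ratio with a warning.
#'
#' @inheritParams ratio_power
#' @param ratio1,ratio2 Length-2 character vectors
#'   `c(numerator, denominator)`.
#' @return A `ratio_pair_power` object: `percent` correct plus the
#'   scatter-ready per-specimen coordinates (`coords`) for plotting.
#' @export
ratio_pair_power <- function(x, labels, ratio1, ratio2) {
  x <- as.matrix(x)
  lev <- two_class_check(labels)
  r1 <- ratio_vec(x, ratio1[1], ratio1[2])
  r2 <- ratio_vec(x, ratio2[1], ratio2[2])
  keep <- !is.na(r1) & !is.na(r2)
  nm <- c(paste0(ratio1[1], "/", ratio1[2]), paste0(ratio2[1], "/", ratio2[2]))
  cc <- suppressWarnings(stats::cor(r1[keep], r2[keep]))
  if (!is.na(cc) && abs(cc) > 1 - 1e-10) {
    warning("ratios are collinear; falling back to single-ratio power")
    rp <- ratio_power(x, labels, ratio1[1], ratio1[2])
    return(structure(list(ratios = nm, percent = rp$percent,
                          coords = cbind(r1, r2), classes = lev,
                          collinear = TRUE),
                     class = "ratio_pair_power"))
  }
  res <- loocv_lda(cbind(r1[keep], r2[keep]), labels[keep])
  structure(list(ratios = nm, percent = res$overall_percent,
                 coords = stats::setNames(data.frame(r1, r2, labels),
                                          c(nm, "class")),
                 classes = lev, collinear = FALSE),
            class = "ratio_pair_power")
}

#' @export
print.ratio_pair_power <- function(x, ...) {
  cat("Ratio pair (", paste(x$ratios, collapse = " and "), "): ",
      sprintf("%.1f%%", x$percent), " LOOCV classification power\n", sep = "")
  invisible(x)
}

#' Exhaustive search for the best diagnostic ratios
#'
#' Enumerates every unordered pair of candidate traits, orients each ratio
#' so that the first class has the larger mean (the key's
#' "longer/shorter" phrasing), scores it with [ratio_power()], and ranks
#' by LOOCV percent correct, breaking ties by the larger standardized mean
#' separation. This is an operational surrogate for the full multivariate
#' ratio analysis machinery: the paper-facing outputs — ratio identities
#' and percent-correct values — are what it reproduces.
#'
#' @inheritParams ratio_power
#' @param traits Candidate trait codes (>= 3).
#' @return A data frame ranked best-first: `ratio`, `numerator`,
#'   `denominator`, `percent`, `separation` (standardized mean distance),
#'   with the `ratio_power` objects as attribute `"powers"`.
#' @export
best_ratio_search <- function(x, labels, traits = NULL) {
  x <- as.matrix(x)
  lev <- two_class_check(labels)
  if (is.null(traits)) traits <- colnames(x)
  if (length(traits) < 3) stop("need at least 3 candidate traits")
  pairs <- utils::combn(traits, 2)
  rows <- list(); powers <- list()
  for (q in seq_len(ncol(pairs))) {
    a <- pairs[1, q]; b <- pairs[2, q]
    # orientation rule: class-1 mean of the ratio is the larger one
    r <- x[, a] / x[, b]
    m1 <- mean(r[labels == lev[1]], na.rm = TRUE)
    m2 <- mean(r[labels == lev[2]], na.rm = TRUE)
    if (m1 < m2) { tmp <- a; a <- b; b <- tmp }
    rp <- ratio_power(x, labels, a, b)
    r <- x[, a] / x[, b]
    v1 <- r[labels == lev[1]]; v2 <- r[labels == lev[2]]
    sp <- sqrt(((length(v1) - 1) * stats::var(v1) +
                  (length(v2) - 1) * stats::var(v2)) /
                 (length(v1) + length(v2) - 2))
    rows[[q]] <- data.frame(ratio = rp$ratio, numerator = a, denominator = b,
                            percent = rp$percent,
                            separation = abs(mean(v1) - mean(v2)) / sp)
    powers[[rp$ratio]] <- rp
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$percent, -out$separation, out$ratio), ]
  rownames(out) <- NULL
  attr(out, "powers") <- powers
  out
}

#' Reduced linear discriminant function on raw traits
#'
#' Fits a two-class LDA restricted to a small trait subset and packages it
#' as an explicit linear identification formula
#' `score = sum(coef_i * trait_i) + intercept` — the form printed in
#' species diagnoses (a "D4" when four traits are used). The coefficient
#' vector is scaled to unit pooled within-class variance of the scores,
#' the sign is chosen so the first class scores positive, and the
#' intercept puts the midpoint of the two class score means at zero, so
#' the score's sign identifies the class.
#'
#' @param x Numeric specimen-by-trait matrix in micrometres.
#' @param labels Per-specimen class; exactly two classes (the first factor
#'   level scores positive).
#' @param traits Trait subset to use (>= 1).
#' @param ridge Optional ridge regularization (fraction of mean diagonal).
#' @return A `dfunction`: `traits`, `coefficients` (per µm), `intercept`,
#'   `class_summary` (per-class mean/min/max score), `percent` (LOOCV
#'   percent correct on the same trait subset).
#' @export
reduced_discriminant <- function(x, labels, traits, ridge = 0) {
  x <- as.matrix(x)
  lev <- two_class_check(labels)
  stopifnot(length(traits) >= 1)
  m <- x[, traits, drop = FALSE]
  if (anyNA(m)) stop("missing values in selected traits")
  g <- factor(labels)
  ng <- as.vector(table(g))
  means <- rowsum(m, g) / ng
  resid <- m - means[as.integer(g), , drop = FALSE]
  Sw <- crossprod(resid) / (nrow(m) - 2)
  if (ridge > 0) Sw <- Sw + diag(ridge * mean(diag(Sw)), ncol(m))
  w <- tryCatch(solve(Sw, means[1, ] - means[2, ]), error = function(e)
    stop("singular within-class scatter; enable ridge regularization",
         call. = FALSE))
  w <- w / sqrt(drop(t(w) %*% Sw %*% w))      # unit within-class SD
  intercept <- -sum(w * (means[1, ] + means[2, ]) / 2)
  scores <- drop(m %*% w) + intercept
  summ <- do.call(rbind, lapply(lev, function(cl) {
    v <- scores[labels == cl]
    data.frame(class = cl, mean = mean(v), min = min(v), max = max(v))
  }))
  res <- loocv_lda(m, labels, ridge = ridge)
  structure(list(traits = traits,
                 coefficients = stats::setNames(as.numeric(w), traits),
                 intercept = intercept,
                 positive_class = lev[1],
                 class_summary = summ,
                 percent = res$overall_percent),
            class = "dfunction")
}

#' Evaluate a reduced discriminant function
#'
#' @param df A `dfunction` (fitted by [reduced_discriminant()] or frozen,
#'   e.g. [d4_printed()]).
#' @param newdata Numeric matrix/data frame containing all of `df$traits`
#'   in micrometres (a single specimen may be a named vector).
#' @return Numeric score vector; positive scores indicate
#'   `df$positive_class`.
#' @export
evaluate_dfunction <- function(df, newdata) {
  stopifnot(inherits(df, "dfunction"))
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  newdata <- as.data.frame(newdata)
  miss <- setdiff(df$traits, names(newdata))
  if (length(miss))
    stop("missing trait(s): ", paste(miss, collapse = ", "))
  m <- as.matrix(newdata[, df$traits, drop = FALSE])
  if (anyNA(m)) stop("missing values in required traits")
  drop(m %*% df$coefficients) + df$intercept
}

#' @export
print.dfunction <- function(x, ...) {
  terms <- sprintf("%+.6f %s", x$coefficients, x$traits)
  cat("D", length(x$traits), " = ", paste(terms, collapse = " "),
      sprintf(" %+.6f", x$intercept), "\n", sep = "")
  cat("positive class:", x$positive_class, "\n")
  if (!is.null(x$class_summary)) print(x$class_summary, digits = 4)
  invisible(x)
}

#' The published reduced discriminant function for the bidentatus/fragilis
#' pair
#'
#' The four-trait identification formula printed in the *N. bidentatus*
#' diagnosis, frozen verbatim for verification and for field use:
#' `D4 = 0.062581 ML - 0.052596 CW - 0.095374 SPBA - 0.042818 SPST
#' + 6.642672`, with positive scores indicating *N. bidentatus* and
#' negative *N. fragilis*.
#'
#' @return A `dfunction` with the frozen coefficients (no fitted class
#'   summaries).
#' @export
d4_printed <- function() {
  structure(list(
    traits = c("ML", "CW", "SPBA", "SPST"),
    coefficients = c(ML = 0.062581, CW = -0.052596,
                     SPBA = -0.095374, SPST = -0.042818),
    intercept = 6.642672,
    positive_class = "bidentatus",
    class_summary = NULL,
    percent = NA_real_), class = "dfunction")
}
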