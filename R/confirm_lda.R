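# Plug-in Gaussian LDA with pooled covariance: train once, predict
# posteriors. Equal class priors by default so species hypotheses are not
# size-weighted.
lda_train <- function(x, y, prior = c("equal", "proportional"), ridge = 0) {
  prior <- match.arg(prior)
  x <- as.matrix(x); storage.mode(x) <- "double"
  g <- factor(y)
  if (nlevels(g) < 2) stop("need at least 2 classes")
  ng <- as.vector(table(g))
  if (any(ng < 2))
    stop("class(es) with a single specimen: ",
         paste(levels(g)[ng < 2], collapse = ", "),
         " (cannot leave one out)")
  n <- nrow(x); p <- ncol(x); G <- nlevels(g)
  means <- rowsum(x, g) / ng
  resid <- x - means[as.integer(g), , drop = FALSE]
  Sw <- crossprod(resid) / (n - G)
  if (ridge > 0) Sw <- Sw + diag(ridge * mean(diag(Sw)), p)
  Swi <- tryCatch(solve(Sw), error = function(e)
    stop("singular within-class scatter; enable ridge regularization ",
         "(ridge > 0)", call. = FALSE))
  pri <- if (prior == "equal") rep(1 / G, G) else ng / n
  list(levels = levels(g), means = means, Swi = Swi,
       log_prior = log(pri))
}

lda_posterior <- function(fit, x) {
  x <- as.matrix(x)
  d2 <- sapply(seq_along(fit$levels), function(gi) {
    dx <- sweep(x, 2, fit$means[gi, ])
    rowSums((dx %*% fit$Swi) * dx)
  })
  d2 <- matrix(d2, nrow(x))
  lp <- sweep(-d2 / 2, 2, fit$log_prior, "+")
  lp <- lp - apply(lp, 1, max)
  post <- exp(lp) / rowSums(exp(lp))
  colnames(post) <- fit$levels
  rownames(post) <- rownames(x)
  post
}

make_classification_result <- function(truth, predicted, posterior,
                                       wildcards = NULL) {
  lev <- levels(factor(truth))
  cm <- table(factor(truth, lev), factor(predicted, lev))
  per_class <- 100 * diag(cm) / rowSums(cm)
  structure(list(classes = lev,
                 confusion = unclass(cm),
                 per_class_percent = per_class,
                 overall_percent = 100 * sum(diag(cm)) / sum(cm),
                 posterior = posterior,
                 wildcards = wildcards),
            class = "classification_result")
}

#' Leave-one-out cross-validated LDA confirmation
#'
#' For every specimen, a linear discriminant classifier (pooled within-
#' class covariance, equal class priors by default) is trained on all
#' other specimens and used to predict the held-out one. The resulting
#' confusion matrix — imposed hypotheses in rows, predictions in columns,
#' percent correct as the final column — is the confirmation table of the
#' delimitation protocol.
#'
#' @param x Numeric specimen-by-trait matrix.
#' @param labels Per-specimen class (imposed species hypothesis); every
#'   class needs at least 2 specimens.
#' @param prior `"equal"` (default) or `"proportional"`.
#' @param ridge Optional ridge regularization passed to the pooled
#'   covariance (fraction of its mean diagonal).
#' @return A `classification_result`: confusion matrix, per-class and
#'   overall percent correct, and the per-specimen LOOCV posterior matrix.
#' @export
loocv_lda <- function(x, labels, prior = c("equal", "proportional"),
                      ridge = 0) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  stopifnot(length(labels) == nrow(x))
  if (anyNA(x)) stop("missing values in trait matrix")
  lda_train(x, labels, prior, ridge)  # validates classes up front
  n <- nrow(x)
  lev <- levels(factor(labels))
  post <- matrix(NA_real_, n, length(lev), dimnames = list(rownames(x), lev))
  for (i in seq_len(n)) {
    fit <- lda_train(x[-i, , drop = FALSE], labels[-i], prior, ridge)
    post[i, fit$levels] <- lda_posterior(fit, x[i, , drop = FALSE])
  }
  predicted <- lev[max.col(post, ties.method = "first")]
  make_classification_result(labels, predicted, post)
}

#' Confirmatory LDA with wildcard assignment
#'
#' Specimens with an imposed hypothesis are evaluated by leave-one-out
#' cross-validation as in [loocv_lda()]; specimens marked `"WILDCARD"` (or
#' `NA`) carry no prior hypothesis and are assigned by posterior
#' probability from a classifier trained on all labeled specimens.
#' Wildcards are excluded from the confusion matrix.
#'
#' @param x Numeric specimen-by-trait matrix.
#' @param labels Per-specimen class, with `"WILDCARD"`/`NA` for samples
#'   without an imposed hypothesis.
#' @inheritParams loocv_lda
#' @return A `classification_result` whose `wildcards` element is a data
#'   frame (id, predicted class, max posterior) with the full posterior
#'   matrix as attribute `"posterior"`.
#' @export
wildcard_assign <- function(x, labels, prior = c("equal", "proportional"),
                            ridge = 0) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  labels <- as.character(labels)
  labels[is.na(labels)] <- "WILDCARD"
  wc <- labels == "WILDCARD"
  if (!any(wc)) return(loocv_lda(x, labels, prior, ridge))
  if (sum(!wc) < 4 || length(unique(labels[!wc])) < 2)
    stop("need at least 2 labeled classes to assign wildcards")
  res <- loocv_lda(x[!wc, , drop = FALSE], labels[!wc], prior, ridge)
  fit <- lda_train(x[!wc, , drop = FALSE], labels[!wc], prior, ridge)
  wpost <- lda_posterior(fit, x[wc, , drop = FALSE])
  ids <- rownames(x)[wc]
  if (is.null(ids)) ids <- as.character(which(wc))
  wdf <- data.frame(
    id = ids,
    predicted = fit$levels[max.col(wpost, ties.method = "first")],
    posterior = apply(wpost, 1, max),
    row.names = NULL)
  attr(wdf, "posterior") <- wpost
  res$wildcards <- wdf
  res
}

#' @export
print.classification_result <- function(x, ...) {
  cm <- cbind(as.data.frame.matrix(x$confusion),
              `percent.correct` = round(x$per_class_percent, 1))
  cat("LOOCV-LDA classification matrix\n")
  print(cm)
  cat(sprintf("Overall classification success: %.1f%%\n", x$overall_percent))
  if (!is.null(x$wildcards)) {
    cat("Wildcard assignments:\n")
    print(x$wildcards, digits = 3)
  }
  invisible(x)
}

#' Write a classification result as CSV + JSON
#' @param x A `classification_result`.
#' @param stem Output path stem; writes `<stem>.csv` (confusion matrix with
#'   percent.correct column) and `<stem>.json`.
#' @export
write_classification_result <- function(x, stem) {
  cm <- cbind(as.data.frame.matrix(x$confusion),
              percent.correct = x$per_class_percent)
  utils::write.csv(cm, paste0(stem, ".csv"))
  jsonlite::write_json(
    list(classes = x$classes, confusion = x$confusion,
         per_class_percent = x$per_class_percent,
         overall_percent = x$overall_percent,
         wildcards = x$wildcards),
    paste0(stem, ".json"), auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(stem)
}
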