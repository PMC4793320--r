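pipeline_defaults <- function() {
  list(input = NULL, out = NULL, traits = NULL,
       include_partial = FALSE, screen_threshold = 0.2,
       linkage = "ward", kmax = 15, minSize = 3, B = 1000,
       clusterers = c("hclust", "kmeans"), prior = "equal",
       ridge = 0, key = TRUE, seed = NULL)
}

# tiny polynomial hash over the deparsed config, for the manifest
config_hash <- function(cfg) {
  bytes <- utf8ToInt(paste(deparse(cfg), collapse = "\n"))
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Read a flat key=value run configuration file
#'
#' Lines of the form `key = value`; `#` starts a comment. Values holding
#' commas become vectors; numeric-looking values become numbers.
#'
#' @param path Config file path.
#' @return Named list merged over the pipeline defaults.
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines)])
  cfg <- pipeline_defaults()
  for (ln in lines) {
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    if (grepl(",", val)) val <- trimws(strsplit(val, ",")[[1]])
    suppressWarnings(num <- as.numeric(val))
    if (!anyNA(num)) val <- num
    cfg[[key]] <- val
  }
  cfg
}

stage_fail <- function(stage, e)
  stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
       call. = FALSE)

#' Run the full delimitation protocol
#'
#' Orchestrates clean -> nest-centroid LDA -> recursive Gap partitioning
#' with both base clusterers -> congruence -> confirmatory LOOCV-LDA with
#' wildcards -> diagnostic ratio extraction, writing every stage artifact
#' plus a machine-readable manifest (seed, config hash, per-stage files)
#' into the output directory.
#'
#' @param config Named list (see `read_run_config()`); unset keys take the
#'   package defaults. Either `config$input` (CSV path) or `table` must
#'   provide the data.
#' @param table Optional [morpho_table] overriding `config$input`.
#' @return Invisibly, a list with the in-memory stage results and
#'   `out` (the run directory) if one was written.
#' @export
run_pipeline <- function(config = list(), table = NULL) {
  cfg <- utils::modifyList(pipeline_defaults(), config)
  out_dir <- cfg$out
  artifacts <- list()
  save_json <- function(name, obj) {
    if (is.null(out_dir)) return(invisible(NULL))
    path <- file.path(out_dir, paste0(name, ".json"))
    jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                         force = TRUE, na = "null")
    artifacts[[name]] <<- basename(path)
  }
  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)

  ## 1 clean ----------------------------------------------------------
  res <- tryCatch({
    tab <- if (!is.null(table)) table else read_morpho_table(cfg$input)
    if (all(c("CL", "CWb") %in% names(tab))) tab <- derive_cs(tab)
    traits <- cfg$traits
    if (is.null(traits)) {
      traits <- intersect(analysis_traits(cfg$include_partial), names(tab))
      traits <- traits[vapply(traits, function(tc) !anyNA(tab[[tc]]),
                              logical(1))]
    }
    screen <- tryCatch(
      correlation_screen(tab, threshold = cfg$screen_threshold,
                         traits = traits),
      error = function(e) NULL)
    dropped <- if (!is.null(screen)) screen$trait[screen$flagged] else character(0)
    traits <- setdiff(traits, dropped)
    list(table = tab, traits = traits, screen = screen, dropped = dropped)
  }, error = function(e) stage_fail("clean", e))
  tab <- res$table; traits <- res$traits
  save_json("screen", list(
    dropped = res$dropped, threshold = cfg$screen_threshold,
    report = if (!is.null(res$screen)) as.data.frame(res$screen)))
  if (!is.null(out_dir)) {
    write_morpho_table(tab, file.path(out_dir, "table_clean.csv"))
    artifacts$table_clean <- "table_clean.csv"
  }

  ## 2 nest-centroid LDA ----------------------------------------------
  nc <- tryCatch({
    X <- as.matrix(as.data.frame(tab)[, traits, drop = FALSE])
    rownames(X) <- tab$specimen_id
    proj <- fit_group_lda(X, tab$nest_id, ridge = cfg$ridge)
    cent <- nest_centroids(proj)
    d <- centroid_distances(cent)
    dend <- build_dendrogram(d, linkage = cfg$linkage)
    list(proj = proj, centroids = cent, dist = d, dend = dend)
  }, error = function(e) stage_fail("nc", e))
  if (!is.null(out_dir)) {
    utils::write.csv(nc$centroids$coords,
                     file.path(out_dir, "nest_centroids.csv"))
    utils::write.csv(as.matrix(nc$dist), file.path(out_dir, "distances.csv"))
    writeLines(to_newick(nc$dend), file.path(out_dir, "dendrogram.nwk"))
    artifacts$nest_centroids <- "nest_centroids.csv"
    artifacts$distances <- "distances.csv"
    artifacts$dendrogram <- "dendrogram.nwk"
  }

  ## 3 PART with both clusterers --------------------------------------
  parts <- tryCatch({
    out <- list()
    for (i in seq_along(cfg$clusterers)) {
      cl <- cfg$clusterers[i]
      out[[cl]] <- part(nc$centroids$coords, kmax = cfg$kmax,
                        minSize = cfg$minSize, B = cfg$B, clusterer = cl,
                        linkage = cfg$linkage,
                        seed = if (!is.null(cfg$seed)) cfg$seed + i)
    }
    out
  }, error = function(e) stage_fail("part", e))
  for (cl in names(parts)) {
    p <- parts[[cl]]
    save_json(paste0("part_", cl),
              list(method = p$method, minSize = p$minSize, kmax = p$kmax,
                   B = p$B, seed = p$seed,
                   labels = as.list(p$labels), trace = p$trace))
    if (!is.null(out_dir)) {
      utils::write.csv(data.frame(id = names(p$labels), label = p$labels),
                       file.path(out_dir, paste0("part_", cl, ".csv")),
                       row.names = FALSE)
      artifacts[[paste0("part_", cl, "_csv")]] <- paste0("part_", cl, ".csv")
    }
  }

  ## 4 congruence ------------------------------------------------------
  cong <- tryCatch({
    if (length(parts) >= 2) congruence(parts[[1]], parts[[2]])
    else structure(list(congruent = names(parts[[1]]$labels),
                        wildcard = character(0), mapping = NULL),
                   class = "congruence_set")
  }, error = function(e) stage_fail("congruence", e))
  save_json("congruence", list(congruent = cong$congruent,
                               wildcard = cong$wildcard,
                               mapping = as.list(cong$mapping)))

  ## 5 confirmatory LOOCV-LDA with wildcards ---------------------------
  confirm <- tryCatch({
    nest_lab <- parts[[1]]$labels
    hyp <- ifelse(tab$nest_id %in% cong$congruent,
                  nest_lab[tab$nest_id], "WILDCARD")
    X <- as.matrix(as.data.frame(tab)[, traits, drop = FALSE])
    rownames(X) <- tab$specimen_id
    res <- if (any(hyp == "WILDCARD"))
      wildcard_assign(X, hyp, prior = cfg$prior, ridge = cfg$ridge)
    else loocv_lda(X, hyp, prior = cfg$prior, ridge = cfg$ridge)
    list(result = res, hypotheses = stats::setNames(hyp, tab$specimen_id))
  }, error = function(e) stage_fail("confirm", e))
  if (!is.null(out_dir)) {
    write_classification_result(confirm$result, file.path(out_dir, "confirm"))
    artifacts$confirm_csv <- "confirm.csv"
    artifacts$confirm_json <- "confirm.json"
  }

  ## 6 diagnostic ratios per cluster pair ------------------------------
  key <- if (isTRUE(cfg$key)) tryCatch({
    lab <- confirm$hypotheses
    final <- ifelse(lab == "WILDCARD" & !is.null(confirm$result$wildcards),
                    NA, lab)
    if (!is.null(confirm$result$wildcards)) {
      wdf <- confirm$result$wildcards
      final[wdf$id] <- wdf$predicted
    }
    classes <- sort(unique(final[!is.na(final)]))
    X <- as.matrix(as.data.frame(tab)[, traits, drop = FALSE])
    rownames(X) <- tab$specimen_id
    couplets <- list()
    if (length(classes) >= 2) {
      prs <- utils::combn(classes, 2)
      for (q in seq_len(ncol(prs))) {
        sel <- final %in% prs[, q]
        br <- best_ratio_search(X[sel, , drop = FALSE], final[sel],
                                traits = traits)
        top2 <- br[1:2, ]
        pp <- ratio_pair_power(X[sel, , drop = FALSE], final[sel],
                               c(top2$numerator[1], top2$denominator[1]),
                               c(top2$numerator[2], top2$denominator[2]))
        couplets[[paste(prs[, q], collapse = " vs ")]] <-
          list(best = utils::head(as.data.frame(br), 5),
               best_ratio = top2$ratio[1],
               best_percent = top2$percent[1],
               pair = pp$ratios, pair_percent = pp$percent)
      }
    }
    couplets
  }, error = function(e) stage_fail("key", e)) else NULL
  if (!is.null(key)) save_json("key", key)

  ## manifest ----------------------------------------------------------
  manifest <- list(
    package = "ncpart",
    version = as.character(utils::packageVersion("ncpart")),
    seed = cfg$seed,
    config_hash = config_hash(cfg[setdiff(names(cfg), c("input", "out"))]),
    config = cfg[setdiff(names(cfg), c("input", "out"))],
    n_specimens = nrow(tab), n_nests = length(unique(tab$nest_id)),
    traits = traits,
    n_clusters = stats::setNames(lapply(parts, n_clusters), names(parts)),
    overall_percent = confirm$result$overall_percent,
    artifacts = artifacts)
  if (!is.null(out_dir))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         na = "null")
  invisible(list(table = tab, traits = traits, screen = res$screen, nc = nc,
                 parts = parts, congruence = cong, confirm = confirm$result,
                 hypotheses = confirm$hypotheses, key = key,
                 manifest = manifest, out = out_dir))
}
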