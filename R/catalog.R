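#' Catalog of continuous morphometric traits
#'
#' Returns the catalog of worker-caste trait codes handled by the package:
#' 23 measured linear dimensions (in micrometres) plus the derived absolute
#' cephalic size `CS`, defined as the arithmetic mean of cephalic length
#' `CL` and head-capsule width `CWb`.
#'
#' Two traits, the antero-median clypeal depression `Cdep` and the apical
#' distance of the pronotal spines `PSTI`, are scored only in a subset of
#' taxa; by default they are excluded from multivariate analyses (see
#' [analysis_traits()]).
#'
#' @return A data frame with columns `code`, `description` and `kind`
#'   (`"measured"` or `"derived"`).
#' @export
#' @examples
#' trait_catalog()
trait_catalog <- function() {
  measured <- c(
    CL    = "Maximum cephalic length in median line",
    CW    = "Maximum width of the head including compound eyes",
    CWb   = "Maximum width of head capsule without the compound eyes",
    Cdep  = "Antero-median clypeal depression depth",
    EL    = "Maximum diameter of the compound eye",
    FRS   = "Frontal carina distance",
    ML    = "Mesosoma length (Weber length)",
    MW    = "Mesosoma width (pronotal width, dorsal view)",
    MPST  = "Propodeal stigma to anteroventral metapleural corner distance",
    NOH   = "Maximum height of the petiolar node",
    NOL   = "Length of the petiolar node",
    PEH   = "Maximum petiole height",
    PEL   = "Diagonal petiolar length in lateral view",
    PEW   = "Maximum width of petiole in dorsal view",
    PoOC  = "Postocular distance",
    PPH   = "Maximum height of the postpetiole in lateral view",
    PPL   = "Postpetiole length",
    PPW   = "Postpetiole width in dorsal view",
    PSTI  = "Apical distance of pronotal spines in dorsal view",
    SL    = "Maximum straight-line scape length",
    SPBA  = "Minimum distance of propodeal spines at their base",
    SPST  = "Spine length from propodeal stigma centre to spine tip",
    SPTI  = "Apical distance of propodeal spine tips in dorsal view"
  )
  out <- data.frame(
    code = c(names(measured), "CS"),
    description = c(unname(measured),
                    "Absolute cephalic size: arithmetic mean of CL and CWb"),
    kind = c(rep("measured", length(measured)), "derived"),
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(out$code))
  out
}

#' Trait codes usable in overall multivariate analyses
#'
#' The measured trait codes minus the partially scored ones (`Cdep`,
#' `PSTI`), which are recorded only in a small subset of taxa and are
#' therefore kept out of pooled multivariate analyses by default.
#'
#' @param include_partial Include `Cdep` and `PSTI`.
#' @return Character vector of trait codes.
#' @export
analysis_traits <- function(include_partial = FALSE) {
  cat <- trait_catalog()
  codes <- cat$code[cat$kind == "measured"]
  if (!include_partial) codes <- setdiff(codes, c("Cdep", "PSTI"))
  codes
}

partial_traits <- function() c("Cdep", "PSTI")
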