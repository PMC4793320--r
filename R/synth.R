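# Frozen per-species parameters: head size CS (micrometres) and
# dimensionless trait ratios, mean / SD / printed range, for the eight
# species of the revised group. Ratios are trait/CS except CL/CWb (head
# shape) and PoOC/CL. PSTI is scored only in angulatus and clypeatus,
# the clypeal depression Cdep (absolute, micrometres) only in clypeatus.
.t2_species <- c("angulatus", "bidentatus", "clypeatus", "devius",
                 "exiguus", "fragilis", "gracilis", "hirtellus")
.t2_n <- c(33, 60, 12, 27, 84, 42, 44, 75)

.t2_rows <- list(
  #                 angulatus            bidentatus           clypeatus            devius               exiguus              fragilis             gracilis             hirtellus
  "CS"      = list(c(691, 28.49, 630, 727), c(510, 27.4, 419, 569), c(898, 34, 850, 946),  c(593, 18.7, 562, 620), c(586, 26.2, 528, 644), c(539, 31.4, 469, 614), c(620, 38.0, 508, 699), c(592, 26.5, 525, 641)),
  "CL/CWb"  = list(c(1.259, .03, 1.218, 1.327), c(1.277, .03, 1.204, 1.352), c(1.076, .01, 1.057, 1.105), c(1.188, .02, 1.147, 1.259), c(1.213, .02, 1.174, 1.255), c(1.229, .02, 1.189, 1.278), c(1.199, .02, 1.154, 1.246), c(1.187, .02, 1.142, 1.242)),
  "PoOC/CL" = list(c(.370, .01, .355, .386), c(.416, .01, .398, .440), c(.434, .01, .423, .444), c(.394, .01, .375, .408), c(.408, .01, .391, .428), c(.404, .01, .389, .421), c(.387, .01, .372, .406), c(.387, .01, .366, .404)),
  "FRS/CS"  = list(c(.325, .01, .310, .343), c(.399, .01, .376, .419), c(.310, .01, .300, .328), c(.415, .01, .400, .428), c(.413, .01, .397, .431), c(.409, .01, .379, .430), c(.413, .01, .390, .436), c(.412, .01, .385, .427)),
  "SL/CS"   = list(c(.815, .02, .757, .866), c(.665, .02, .634, .708), c(.758, .03, .736, .835), c(.632, .01, .616, .661), c(.656, .01, .615, .683), c(.659, .02, .615, .694), c(.647, .01, .622, .685), c(.667, .02, .611, .705)),
  "EL/CS"   = list(c(.281, .01, .262, .317), c(.264, .02, .233, .311), c(.210, .01, .193, .225), c(.263, .01, .248, .279), c(.249, .01, .228, .266), c(.260, .01, .239, .276), c(.252, .01, .228, .274), c(.272, .01, .249, .289)),
  "MW/CS"   = list(c(.673, .02, .643, .699), c(.647, .01, .621, .678), c(.699, .02, .671, .732), c(.687, .01, .658, .712), c(.684, .01, .656, .728), c(.664, .01, .627, .688), c(.693, .02, .659, .726), c(.692, .01, .664, .730)),
  "PEW/CS"  = list(c(.407, .03, .344, .451), c(.391, .02, .330, .426), c(.460, .03, .428, .512), c(.447, .01, .422, .481), c(.437, .02, .387, .480), c(.407, .02, .363, .460), c(.454, .02, .390, .487), c(.460, .02, .409, .522)),
  "PPW/CS"  = list(c(.486, .03, .427, .546), c(.456, .01, .425, .491), c(.493, .02, .472, .521), c(.499, .02, .464, .534), c(.516, .01, .481, .548), c(.470, .02, .429, .507), c(.500, .02, .453, .539), c(.525, .02, .475, .585)),
  "SPBA/CS" = list(c(.323, .02, .265, .354), c(.346, .02, .303, .372), c(.349, .02, .326, .386), c(.371, .01, .347, .402), c(.390, .02, .352, .454), c(.369, .02, .327, .405), c(.393, .02, .350, .433), c(.389, .02, .345, .427)),
  "SPTI/CS" = list(c(.332, .02, .251, .375), c(.335, .02, .303, .367), c(.463, .02, .438, .489), c(.430, .01, .401, .460), c(.436, .02, .377, .493), c(.377, .02, .337, .424), c(.489, .02, .448, .536), c(.460, .02, .418, .504)),
  "ML/CS"   = list(c(1.390, .03, 1.302, 1.444), c(1.338, .02, 1.280, 1.379), c(1.307, .03, 1.257, 1.347), c(1.256, .02, 1.223, 1.285), c(1.298, .02, 1.214, 1.342), c(1.308, .03, 1.231, 1.345), c(1.267, .02, 1.201, 1.301), c(1.315, .02, 1.261, 1.379)),
  "PEL/CS"  = list(c(.522, .02, .482, .557), c(.571, .02, .537, .605), c(.589, .02, .558, .642), c(.543, .01, .513, .565), c(.578, .02, .496, .623), c(.567, .03, .519, .717), c(.574, .02, .541, .639), c(.585, .02, .487, .645)),
  "NOL/CS"  = list(c(.383, .02, .317, .418), c(.321, .02, .277, .362), c(.317, .02, .290, .336), c(.304, .01, .281, .332), c(.327, .01, .279, .353), c(.317, .01, .292, .347), c(.324, .01, .278, .347), c(.324, .02, .299, .407)),
  "PPL/CS"  = list(c(.285, .01, .250, .319), c(.280, .01, .255, .305), c(.259, .01, .231, .278), c(.298, .01, .276, .313), c(.302, .01, .274, .330), c(.286, .01, .265, .308), c(.301, .01, .280, .332), c(.315, .01, .266, .333)),
  "SPST/CS" = list(c(.271, .02, .223, .304), c(.264, .02, .220, .335), c(.361, .01, .335, .385), c(.340, .01, .304, .356), c(.382, .02, .317, .430), c(.310, .02, .257, .356), c(.399, .03, .301, .446), c(.375, .01, .332, .416)),
  "MPST/CS" = list(c(.434, .01, .385, .456), c(.428, .01, .391, .458), c(.389, .01, .353, .405), c(.395, .01, .378, .416), c(.420, .01, .394, .445), c(.420, .02, .384, .449), c(.407, .01, .374, .425), c(.425, .02, .391, .463)),
  "PEH/CS"  = list(c(.401, .02, .362, .446), c(.387, .01, .366, .424), c(.389, .02, .348, .434), c(.419, .01, .395, .439), c(.436, .01, .406, .469), c(.406, .01, .378, .431), c(.435, .01, .417, .459), c(.436, .01, .402, .479)),
  "NOH/CS"  = list(c(.231, .01, .203, .251), c(.219, .01, .189, .249), c(.243, .02, .226, .278), c(.244, .01, .227, .268), c(.261, .01, .236, .292), c(.235, .01, .210, .257), c(.272, .01, .250, .292), c(.273, .01, .240, .310)),
  "PPH/CS"  = list(c(.357, .01, .333, .380), c(.355, .01, .327, .381), c(.332, .02, .275, .365), c(.370, .01, .350, .384), c(.388, .01, .356, .411), c(.364, .01, .329, .394), c(.385, .01, .354, .410), c(.400, .01, .378, .438)),
  "PSTI/CS" = list(c(.689, .03, .584, .736), NULL, c(.773, .02, .733, .801), NULL, NULL, NULL, NULL, NULL),
  "Cdep"    = list(NULL, NULL, c(19.245, 2.80, 15.385, 23.077), NULL, NULL, NULL, NULL, NULL)
)

#' Published per-species distribution parameters
#'
#' The eight species' head size (`CS`, µm) and dimensionless ratio
#' parameters (mean, SD, printed minimum and maximum), as used by the
#' synthetic generator. The partially scored characters are present only
#' for the species that carry them.
#'
#' @return A list of 8 `species_params` objects (name, `n_printed`, `cs`,
#'   `ratios` data frame, nest-effect fraction `rho`, default 0.3).
#' @export
#' @examples
#' p <- table2_params()
#' p[["clypeatus"]]$cs
table2_params <- function() {
  out <- lapply(seq_along(.t2_species), function(s) {
    rows <- Filter(Negate(is.null), lapply(.t2_rows, `[[`, s))
    tab <- do.call(rbind, lapply(rows, function(v)
      data.frame(mean = v[1], sd = v[2], min = v[3], max = v[4])))
    tab <- cbind(name = names(rows), tab)
    rownames(tab) <- NULL
    p <- structure(list(
      species = .t2_species[s],
      n_printed = .t2_n[s],
      cs = tab[tab$name == "CS", -1],
      ratios = tab[tab$name != "CS", , drop = FALSE],
      rho = 0.3), class = "species_params")
    validate_species_params(p)
    p
  })
  stats::setNames(out, .t2_species)
}

validate_species_params <- function(p) {
  stopifnot(inherits(p, "species_params"))
  with(p, {
    stopifnot(cs$sd > 0, cs$mean > 0, rho >= 0, rho < 1,
              all(ratios$sd > 0), all(ratios$mean > 0))
    stopifnot(all(ratios$mean >= ratios$min & ratios$mean <= ratios$max))
    stopifnot(cs$mean >= cs$min, cs$mean <= cs$max)
  })
  invisible(p)
}

#' @export
print.species_params <- function(x, ...) {
  cat("Species parameters: ", x$species, " (printed n = ", x$n_printed,
      "), CS ", x$cs$mean, " +/- ", x$cs$sd, " um, ", nrow(x$ratios),
      " ratio traits, rho = ", x$rho, "\n", sep = "")
  invisible(x)
}

# normal draw truncated at 0 by resampling (preserves shape for the small
# coefficients of variation seen here; truncation is almost never hit)
rnorm_pos <- function(n, mean, sd) {
  v <- stats::rnorm(n, mean, sd)
  for (it in seq_len(50)) {
    bad <- v <= 0
    if (!any(bad)) return(v)
    v[bad] <- stats::rnorm(sum(bad), mean, sd)
  }
  abs(v) + .Machine$double.eps
}

#' Simulate a nest-structured morphometric dataset
#'
#' Draws specimens species by species: head size `CS` is normal (truncated
#' at zero); each trait ratio is normal around its species mean with a
#' nest-level random effect contributing fraction `rho` of the variance
#' (workers from one nest are close kin, hence more alike than their
#' species at large); the micrometre trait is ratio times `CS`. `CL` and
#' `CWb` are reconstructed from `CS` and the head-shape ratio `q = CL/CWb`
#' via `CL = 2 CS q / (1 + q)`, `CWb = 2 CS / (1 + q)`, so the `CS`
#' identity holds exactly; the postocular distance uses its printed
#' denominator `CL`. Ratios are drawn independently given `CS` unless
#' `trait_cor > 0` adds an equicorrelated within-specimen component.
#'
#' @param params List of `species_params` (default [table2_params()]).
#' @param nests_per_species Nests per species (default 15).
#' @param nest_size Workers per nest (default 2).
#' @param rho Nest-effect variance fraction in `[0, 1)`; default `NULL`
#'   uses each species' own `rho` field (0.3).
#' @param trait_cor Optional equicorrelation of ratio residuals within a
#'   specimen (default 0, independent).
#' @param seed Optional integer seed for full reproducibility.
#' @return List with `table` (a [morpho_table]; columns `specimen_id`,
#'   `nest_id`, traits incl. derived `CS`), `labels` (named character
#'   vector of true species per specimen), `params`, `seed`.
#' @export
simulate_dataset <- function(params = table2_params(),
                             nests_per_species = 15, nest_size = 2,
                             rho = NULL, trait_cor = 0, seed = NULL) {
  stopifnot(nests_per_species >= 1, nest_size >= 1,
            trait_cor >= 0, trait_cor < 1)
  lapply(params, validate_species_params)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  all_ratio_names <- unique(unlist(lapply(params, function(p) p$ratios$name)))
  spec_rows <- list(); labels <- character(0)
  spec_count <- 0L
  for (si in seq_along(params)) {
    p <- params[[si]]
    r <- if (is.null(rho)) p$rho else rho
    stopifnot(r >= 0, r < 1)
    nr <- nrow(p$ratios)
    for (j in seq_len(nests_per_species)) {
      nest_id <- sprintf("N%s_%02d", p$species, j)
      u <- stats::rnorm(nr, 0, sqrt(r) * p$ratios$sd)  # shared in nest
      for (w in seq_len(nest_size)) {
        spec_count <- spec_count + 1L
        cs <- rnorm_pos(1, p$cs$mean, p$cs$sd)
        e <- if (trait_cor > 0) {
          z <- stats::rnorm(1)
          (sqrt(trait_cor) * z + sqrt(1 - trait_cor) * stats::rnorm(nr)) *
            sqrt(1 - r) * p$ratios$sd
        } else stats::rnorm(nr, 0, sqrt(1 - r) * p$ratios$sd)
        rat <- p$ratios$mean + u + e
        bad <- rat <= 0
        if (any(bad)) rat[bad] <- rnorm_pos(sum(bad), p$ratios$mean[bad],
                                            sqrt(1 - r) * p$ratios$sd[bad])
        names(rat) <- p$ratios$name
        q <- rat[["CL/CWb"]]
        cl <- 2 * cs * q / (1 + q)
        cwb <- 2 * cs / (1 + q)
        row <- c(CL = cl, CWb = cwb, CS = (cl + cwb) / 2)
        for (rn in setdiff(p$ratios$name, "CL/CWb")) {
          den <- sub("^.*/", "", rn)
          num <- sub("/.*$", "", rn)
          row[[num]] <- if (rn == "Cdep") rat[[rn]]
            else rat[[rn]] * (if (den == "CL") cl else cs)
        }
        id <- sprintf("IND%04d", spec_count)
        spec_rows[[spec_count]] <- c(list(specimen_id = id,
                                          nest_id = nest_id), as.list(row))
        labels[id] <- p$species
      }
    }
  }
  trait_names <- unique(unlist(lapply(spec_rows, function(r)
    setdiff(names(r), c("specimen_id", "nest_id")))))
  df <- data.frame(
    specimen_id = vapply(spec_rows, `[[`, "", "specimen_id"),
    nest_id = vapply(spec_rows, `[[`, "", "nest_id"),
    stringsAsFactors = FALSE)
  for (tn in trait_names)
    df[[tn]] <- vapply(spec_rows, function(r)
      if (is.null(r[[tn]])) NA_real_ else r[[tn]], numeric(1))
  list(table = as_morpho_table(df), labels = labels, params = params,
       seed = seed)
}
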