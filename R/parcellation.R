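#' Default grey-matter parcellation scheme
#'
#' The measure set used throughout the package: six cortical lobes
#' (frontal, temporal, parietal, occipital, cingulate, insula) per
#' hemisphere, seven subcortical structures (hippocampus, amygdala,
#' caudate, putamen, accumbens, pallidum, thalamus) per hemisphere, and
#' the cerebellum as a single bilateral measure — 27 measures in total.
#'
#' @return A `parcellation_scheme`: a data frame with columns `measure`
#'   (unique name), `hemisphere` (`"left"`, `"right"` or `"bilateral"`),
#'   `class` (`"cortical"`, `"subcortical"` or `"cerebellar"`) and
#'   `structure` (the hemisphere-free anatomical label).
#' @examples
#' sch <- default_parcellation()
#' nrow(sch)          # 27
#' homologue_pairs(sch)
#' @export
default_parcellation <- function() {
  cortical <- c("frontal", "temporal", "parietal", "occipital",
                "cingulate", "insula")
  subcortical <- c("hippocampus", "amygdala", "caudate", "putamen",
                   "accumbens", "pallidum", "thalamus")
  rows <- rbind(
    expand.grid(structure = cortical, hemisphere = c("left", "right"),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    expand.grid(structure = subcortical, hemisphere = c("left", "right"),
                stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE),
    data.frame(structure = "cerebellum", hemisphere = "bilateral")
  )
  rows$class <- ifelse(rows$structure %in% cortical, "cortical",
                ifelse(rows$structure %in% subcortical, "subcortical",
                       "cerebellar"))
  suffix <- c(left = "_l", right = "_r", bilateral = "")
  rows$measure <- paste0(rows$structure, suffix[rows$hemisphere])
  scheme <- rows[, c("measure", "hemisphere", "class", "structure")]
  rownames(scheme) <- NULL
  validate_parcellation(scheme)
}

#' Validate a parcellation scheme
#'
#' Checks measure-name uniqueness and that every left measure has exactly
#' one right homologue (and vice versa).
#'
#' @param scheme A data frame with columns `measure`, `hemisphere`,
#'   `class`, `structure`.
#' @return The scheme, invisibly classed as `parcellation_scheme`.
#' @export
validate_parcellation <- function(scheme) {
  stopifnot(is.data.frame(scheme),
            all(c("measure", "hemisphere", "class", "structure") %in%
                  names(scheme)))
  if (anyDuplicated(scheme$measure))
    stop("duplicate measure names in parcellation scheme")
  if (!all(scheme$hemisphere %in% c("left", "right", "bilateral")))
    stop("hemisphere must be left, right or bilateral")
  left  <- scheme$structure[scheme$hemisphere == "left"]
  right <- scheme$structure[scheme$hemisphere == "right"]
  if (!setequal(left, right) || anyDuplicated(left) || anyDuplicated(right))
    stop("every left measure needs exactly one right homologue")
  class(scheme) <- c("parcellation_scheme", "data.frame")
  scheme
}

#' Left-right homologue pairs of a scheme
#'
#' @param scheme A `parcellation_scheme`.
#' @return Data frame with columns `left` and `right` holding paired
#'   measure names; bilateral measures are omitted.
#' @export
homologue_pairs <- function(scheme) {
  scheme <- validate_parcellation(scheme)
  l <- scheme[scheme$hemisphere == "left", ]
  r <- scheme[scheme$hemisphere == "right", ]
  data.frame(left  = l$measure,
             right = r$measure[match(l$structure, r$structure)],
             structure = l$structure,
             stringsAsFactors = FALSE)
}
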