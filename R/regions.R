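# Region vocabulary for the cortico-basal ganglia-thalamo-cortical (CBTC)
# circuits.
#
# Five frontal cortical regions project into the loops: medial prefrontal
# cortex (MPFC), dorsolateral prefrontal cortex (DLPFC), primary motor cortex
# (M1), premotor cortex (PMC) and orbitofrontal cortex (OFC).  Four
# subcortical structures participate: caudate (CAU), putamen (PUT), pallidum
# (PAL) and thalamus (THA).  Connectivity-based parcellation subdivides each
# subcortical structure into territories named after the cortical region they
# connect to most strongly, written `CAU_M1`, `THA_DLPFC`, etc.

CORTICAL_REGIONS <- c("MPFC", "DLPFC", "M1", "PMC", "OFC")
SUBCORTICAL_REGIONS <- c("CAU", "PUT", "PAL", "THA")
HEMISPHERES <- c("L", "R")

#' Region label table for the CBTC circuits
#'
#' Enumerates every region label the pipeline knows about for one or both
#' hemispheres: the five cortical regions, the four subcortical parent
#' structures, and the twenty connectivity-defined subdivisions (one per
#' parent x cortical target).
#'
#' @param hemisphere `"L"`, `"R"`, or both (default).
#' @param kinds Subset of `c("cortical", "subcortical", "subdivision")` to
#'   return.
#' @return A data frame with columns `name`, `kind`, `hemisphere`, `parent`
#'   and `tag`.  `parent` and `tag` are `NA` except for subdivisions, where
#'   `name == paste(parent, tag, sep = "_")`.
#' @examples
#' head(cbtc_regions("L"))
#' subset(cbtc_regions(), kind == "subdivision" & parent == "CAU")
#' @export
cbtc_regions <- function(hemisphere = c("L", "R"),
                         kinds = c("cortical", "subcortical", "subdivision")) {
  hemisphere <- match.arg(hemisphere, HEMISPHERES, several.ok = TRUE)
  kinds <- match.arg(kinds, several.ok = TRUE)
  one <- function(h) {
    cort <- data.frame(name = CORTICAL_REGIONS, kind = "cortical",
                       hemisphere = h, parent = NA_character_,
                       tag = NA_character_, stringsAsFactors = FALSE)
    sub <- data.frame(name = SUBCORTICAL_REGIONS, kind = "subcortical",
                      hemisphere = h, parent = NA_character_,
                      tag = NA_character_, stringsAsFactors = FALSE)
    grid <- expand.grid(tag = CORTICAL_REGIONS, parent = SUBCORTICAL_REGIONS,
                        stringsAsFactors = FALSE)
    div <- data.frame(name = paste(grid$parent, grid$tag, sep = "_"),
                      kind = "subdivision", hemisphere = h,
                      parent = grid$parent, tag = grid$tag,
                      stringsAsFactors = FALSE)
    rbind(cort, sub, div)
  }
  out <- do.call(rbind, lapply(hemisphere, one))
  out <- out[out$kind %in% kinds, , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Region names valid inside a manifest (any hemisphere; names are
# hemisphere-free, the edge row carries the hemisphere).
region_name_set <- function() {
  unique(cbtc_regions("L")$name)
}

# Regions simulated by the synthetic cohort generator and used for FC
# extraction: cortical regions plus all subdivisions, per hemisphere,
# prefixed "L:"/"R:".  Parent-structure series are derived as subdivision
# means, not simulated separately.
sim_region_names <- function() {
  fine <- cbtc_regions(kinds = c("cortical", "subdivision"))
  paste(fine$hemisphere, fine$name, sep = ":")
}

#' Canonical edge identifier
#'
#' Edges are intrahemispheric unordered region pairs tagged with the edge set
#' they belong to.  The identifier is `"<loop>:<hemisphere>:<a>-<b>"` with the
#' two region names in the order given (manifest order is preserved; use
#' [edge_key()] for an order-free key).
#'
#' @param loop `"short"`, `"long"` or `"atlas"`.
#' @param hemisphere `"L"` or `"R"`.
#' @param a,b Region names.
#' @return Character vector of edge ids.
#' @export
edge_id <- function(loop, hemisphere, a, b) {
  paste0(loop, ":", hemisphere, ":", a, "-", b)
}

# Order-free uniqueness key for an unordered pair within (loop, hemisphere).
edge_key <- function(loop, hemisphere, a, b) {
  lo <- pmin(a, b)
  hi <- pmax(a, b)
  paste0(loop, ":", hemisphere, ":", lo, "-", hi)
}
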