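# Functional connectivity extraction: Pearson correlation between mean
# region time series, Fisher r-to-z transformed, for the loop manifest
# (40 edges per hemisphere) and the whole-structure atlas edge set (26 per
# hemisphere).

#' Mean region time series
#'
#' Volume mode: averages a 4D array over the voxels of a nonempty mask,
#' returning one value per timepoint.  Matrix mode: returns the stored row
#' of a region x time matrix.
#'
#' @param x 4D array (x, y, z, t) or region x time matrix with rownames.
#' @param region Mask (logical/0-1 3D array, volume mode) or region name
#'   (matrix mode).
#' @param name Region name used in error messages (volume mode).
#' @return Numeric time series.
#' @export
mean_region_series <- function(x, region, name = "region") {
  d <- dim(x)
  if (length(d) == 4L) {
    mask <- region != 0
    if (!any(mask)) stop_cbtc("empty mask for region '", name, "'")
    vox <- which(mask)
    mat <- matrix(x, prod(d[1:3]), d[4L])[vox, , drop = FALSE]
    colMeans(mat)
  } else if (length(d) == 2L) {
    if (!region %in% rownames(x)) {
      stop_cbtc("region '", region, "' not present in the series matrix")
    }
    x[region, ]
  } else {
    stop_cbtc("expected a 4D volume or a region x time matrix")
  }
}

#' Pearson correlation of two series
#'
#' @param x,y Numeric series of equal length >= 3 with nonzero variance.
#' @return Sample Pearson correlation in `[-1, 1]`.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop_cbtc("series lengths differ")
  if (length(x) < 3L) stop_cbtc("need at least 3 timepoints")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_cbtc("constant series: correlation undefined")
  }
  stats::cor(x, y)
}

#' Fisher r-to-z transformation
#'
#' `z = atanh(r)` with `r` clipped to `[-1 + 1e-7, 1 - 1e-7]` so the result
#' is always finite (a sample correlation of exactly +/-1 can arise on
#' degenerate synthetic inputs).
#'
#' @param r Correlation value(s), `|r| <= 1`.
#' @return Fisher z value(s), finite.
#' @examples
#' fisher_z(0.5)  # 0.5493
#' @export
fisher_z <- function(r) {
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) {
    stop_cbtc("|r| > 1: not a correlation")
  }
  eps <- 1e-7
  atanh(pmin(pmax(r, -1 + eps), 1 - eps))
}

#' Extract per-subject Fisher-z FC vectors
#'
#' Computes, for every subject, one Fisher-z value per manifest edge of the
#' requested scheme from the subject's region x time series matrix:
#'
#' * `scheme = "loops"`: the 19 + 21 loop edges per hemisphere between
#'   cortical regions and subcortical subdivisions (80 values per subject).
#' * `scheme = "atlas"`: the 26 whole-structure edges per hemisphere
#'   (52 values).  Parent-structure series are the mean of the structure's
#'   subdivision series (subdivisions are equally sized in the synthetic
#'   cohort, so this equals the voxel mean).
#'
#' @param cohort A `cbtc_cohort`, or a named list of region x time matrices
#'   whose rownames follow `"<hemisphere>:<region>"`.
#' @param manifest A `cbtc_manifest`; defaults to the cohort's own.
#' @param scheme `"loops"` or `"atlas"`.
#' @return Subjects x edges numeric matrix of Fisher-z values, with subject
#'   ids as rownames, edge ids as colnames, and attributes `scheme` and
#'   `edge_table` (the manifest rows in column order).
#' @export
extract_fc_vector <- function(cohort, manifest = NULL,
                              scheme = c("loops", "atlas")) {
  scheme <- match.arg(scheme)
  if (inherits(cohort, "cbtc_cohort")) {
    series <- cohort$series
    manifest <- manifest %||% cohort$manifest
  } else {
    series <- cohort
    manifest <- manifest %||% default_loop_manifest()
  }
  edges <- manifest_edges(manifest, scheme)
  n <- length(series)
  out <- matrix(NA_real_, n, nrow(edges),
                dimnames = list(names(series), edges$edge))
  for (i in seq_len(n)) {
    s <- subject_region_series(series[[i]], scheme)
    a <- paste(edges$hemisphere, edges$region_a, sep = ":")
    b <- paste(edges$hemisphere, edges$region_b, sep = ":")
    miss <- setdiff(unique(c(a, b)), rownames(s))
    if (length(miss)) {
      stop_cbtc("region '", miss[1L], "' unresolvable for subject ",
                names(series)[i] %||% i)
    }
    sds <- apply(s, 1L, stats::sd)
    if (any(sds == 0)) {
      stop_cbtc("constant series for region '",
                rownames(s)[sds == 0][1L], "'")
    }
    C <- stats::cor(t(s))
    out[i, ] <- fisher_z(C[cbind(match(a, rownames(s)),
                                 match(b, rownames(s)))])
  }
  if (!all(is.finite(out))) stop_cbtc("non-finite FC value produced")
  attr(out, "scheme") <- scheme
  attr(out, "edge_table") <- edges
  out
}

# For the atlas scheme, append parent-structure series (mean of the
# structure's subdivisions) to the subject matrix.
subject_region_series <- function(s, scheme) {
  if (scheme == "loops") return(s)
  parents <- expand.grid(h = HEMISPHERES, p = SUBCORTICAL_REGIONS,
                         stringsAsFactors = FALSE)
  extra <- t(vapply(seq_len(nrow(parents)), function(i) {
    rows <- paste0(parents$h[i], ":", parents$p[i], "_", CORTICAL_REGIONS)
    rows <- intersect(rows, rownames(s))
    if (!length(rows)) {
      stop_cbtc("no subdivision series for ", parents$p[i])
    }
    colMeans(s[rows, , drop = FALSE])
  }, numeric(ncol(s))))
  rownames(extra) <- paste(parents$h, parents$p, sep = ":")
  rbind(s, extra)
}

#' Write an FC matrix to TSV
#'
#' One row per subject, one column per edge (header uses the edge ids).
#'
#' @param fc Subjects x edges matrix from [extract_fc_vector()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fc_table <- function(fc, path) {
  df <- data.frame(id = rownames(fc), fc, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
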