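# Connectivity-profile-based parcellation: each subcortical voxel is
# assigned to the cortical target with the maximal connection probability
# (winner-take-all), yielding subdivisions such as CAU_M1 (caudate territory
# connected to M1).  The assignment rule is deliberately simple and fully
# deterministic: hard argmax with a minimum-probability threshold and an
# explicit tie rule; no spatial regularisation by default.

#' Winner-take-all parcellation of voxel connectivity profiles
#'
#' Assigns each voxel to the cortical target with maximal connection
#' probability, provided that maximum reaches `tau`; otherwise the voxel is
#' left unassigned.  Exact ties are resolved deterministically by `tie_rule`:
#' `"first-target"` takes the earliest target in the recorded column order,
#' `"unassigned"` leaves tied voxels unassigned.  The argmax is
#' scale-invariant in each voxel's profile; the `tau` comparison applies to
#' the raw probabilities and is therefore scale-sensitive by design.
#'
#' @param profiles Voxel x target matrix of nonnegative finite connection
#'   probabilities (e.g. `simulate_voxel_profiles()$profiles`, or per-target
#'   probabilistic-tractography maps flattened to rows), or the list
#'   returned by [simulate_voxel_profiles()].
#' @param structure Subcortical structure name used to form subdivision
#'   labels (`"<structure>_<target>"`); taken from the profile list when one
#'   is supplied.
#' @param tau Minimum winning probability in `[0, 1]` (default 0.01).
#' @param tie_rule `"first-target"` (default) or `"unassigned"`.
#' @return A `cbtc_parcel_map`: list with `assignments` (character vector of
#'   subdivision labels, `NA` = unassigned, named by voxel), `structure`,
#'   `targets`, `tau`, `tie_rule`.
#' @examples
#' p <- rbind(v1 = c(M1 = 0.7, DLPFC = 0.2, MPFC = 0.1),
#'            v2 = c(M1 = 0.03, DLPFC = 0.02, MPFC = 0.01))
#' winner_take_all(p, structure = "CAU", tau = 0.1)$assignments
#' @export
winner_take_all <- function(profiles, structure = NULL, tau = 0.01,
                            tie_rule = c("first-target", "unassigned")) {
  tie_rule <- match.arg(tie_rule)
  if (is.list(profiles) && !is.null(profiles$profiles)) {
    structure <- structure %||% profiles$structure
    profiles <- profiles$profiles
  }
  if (is.null(structure)) stop_cbtc("`structure` is required")
  if (!is.matrix(profiles) || nrow(profiles) == 0L) {
    stop_cbtc("empty profile set")
  }
  if (is.null(colnames(profiles))) {
    stop_cbtc("profiles must have target names as colnames")
  }
  if (any(!is.finite(profiles))) stop_cbtc("non-finite connection probability")
  if (any(profiles < 0)) stop_cbtc("negative connection probability")
  if (tau < 0 || tau > 1) stop_cbtc("tau must lie in [0, 1]")

  targets <- colnames(profiles)
  top <- apply(profiles, 1L, max)
  win <- max.col(profiles, ties.method = "first")
  tied <- rowSums(profiles == top) > 1L
  lab <- paste(structure, targets[win], sep = "_")
  lab[top < tau] <- NA_character_
  if (tie_rule == "unassigned") lab[tied] <- NA_character_
  names(lab) <- rownames(profiles) %||% sprintf("v%04d", seq_along(lab))
  structure(list(assignments = lab, structure = structure,
                 targets = targets, tau = tau, tie_rule = tie_rule),
            class = "cbtc_parcel_map")
}

#' Voxels of one subdivision
#'
#' @param parcel_map A `cbtc_parcel_map`.
#' @param structure Subcortical structure name; must match the map's.
#' @param tag Cortical target name.
#' @return Character vector of voxel ids assigned the label
#'   `<structure>_<tag>` (possibly empty).
#' @export
subdivision_mask <- function(parcel_map, structure, tag) {
  stopifnot(inherits(parcel_map, "cbtc_parcel_map"))
  if (!identical(structure, parcel_map$structure)) {
    stop_cbtc("parcel map was built for structure '", parcel_map$structure,
              "', not '", structure, "'")
  }
  if (!tag %in% parcel_map$targets) {
    stop_cbtc("unknown cortical target '", tag, "'")
  }
  lab <- paste(structure, tag, sep = "_")
  a <- parcel_map$assignments
  names(a)[!is.na(a) & a == lab]
}

#' Dice overlap coefficient of two voxel sets
#'
#' `2|A n B| / (|A| + |B|)`; defined as 1 when both sets are empty.
#'
#' @param mask_a,mask_b Voxel id vectors (treated as sets).
#' @return Value in `[0, 1]`.
#' @examples
#' dice(c("v1", "v2"), c("v2", "v3"))  # 0.5
#' @export
dice <- function(mask_a, mask_b) {
  a <- unique(mask_a)
  b <- unique(mask_b)
  if (length(a) == 0L && length(b) == 0L) return(1)
  2 * length(intersect(a, b)) / (length(a) + length(b))
}

#' Per-subdivision Dice against ground truth
#'
#' Convenience wrapper comparing a parcel map with planted labels.
#'
#' @param parcel_map A `cbtc_parcel_map`.
#' @param truth Character vector of planted labels, aligned with the map's
#'   voxels.
#' @return Named numeric vector of Dice coefficients, one per target.
#' @export
parcellation_dice <- function(parcel_map, truth) {
  stopifnot(inherits(parcel_map, "cbtc_parcel_map"))
  if (length(truth) != length(parcel_map$assignments)) {
    stop_cbtc("truth length does not match the number of voxels")
  }
  vox <- names(parcel_map$assignments)
  vapply(parcel_map$targets, function(t) {
    lab <- paste(parcel_map$structure, t, sep = "_")
    got <- subdivision_mask(parcel_map, parcel_map$structure, t)
    want <- vox[truth == lab]
    dice(got, want)
  }, numeric(1))
}

#' Majority-filter a parcel map on a voxel grid (optional smoothing)
#'
#' Reassigns each voxel to the modal label among its 6-neighbourhood
#' (face-adjacent voxels on a 3D grid) when that mode is strictly more
#' frequent than the voxel's own label count.  Off by default everywhere in
#' the pipeline; provided for users who want light spatial regularisation.
#'
#' @param parcel_map A `cbtc_parcel_map`.
#' @param coords Voxel x 3 integer matrix of grid coordinates, rows aligned
#'   with the map's voxels.
#' @return A new `cbtc_parcel_map`.
#' @export
majority_filter <- function(parcel_map, coords) {
  stopifnot(inherits(parcel_map, "cbtc_parcel_map"))
  a <- parcel_map$assignments
  if (nrow(coords) != length(a)) stop_cbtc("coords rows must match voxels")
  key <- function(m) paste(m[, 1], m[, 2], m[, 3], sep = ",")
  lookup <- stats::setNames(seq_along(a), key(coords))
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  new <- a
  for (i in seq_along(a)) {
    nb <- lookup[key(sweep(offs, 2L, as.numeric(coords[i, ]), `+`))]
    nb <- nb[!is.na(nb)]
    labs <- a[nb]
    labs <- labs[!is.na(labs)]
    if (!length(labs)) next
    tab <- sort(table(labs), decreasing = TRUE)
    own <- if (is.na(a[i])) 0L else sum(labs == a[i])
    if (tab[1L] > own) new[i] <- names(tab)[1L]
  }
  out <- parcel_map
  out$assignments <- new
  out
}

#' Nearest-neighbour label resampling between integer-scaled grids
#'
#' Resamples a 3D integer label array onto a grid whose dimensions differ by
#' a positive integer factor: upsampling replicates labels, downsampling
#' takes every `factor`-th voxel.  Intended only for parcel maps produced on
#' a grid that is an integer multiple of the BOLD grid.
#'
#' @param labels 3D array of labels.
#' @param factor Positive integer scale factor.
#' @param direction `"up"` or `"down"`.
#' @return Resampled 3D array.
#' @export
resample_labels <- function(labels, factor, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(is.array(labels), length(dim(labels)) == 3L)
  factor <- as.integer(factor)
  if (factor < 1L) stop_cbtc("factor must be a positive integer")
  d <- dim(labels)
  if (direction == "up") {
    idx <- lapply(d, function(k) rep(seq_len(k), each = factor))
  } else {
    if (any(d %% factor != 0L)) {
      stop_cbtc("grid dimensions are not divisible by factor")
    }
    idx <- lapply(d, function(k) seq(1L, k, by = factor))
  }
  labels[idx[[1L]], idx[[2L]], idx[[3L]], drop = FALSE]
}

#' @export
print.cbtc_parcel_map <- function(x, ...) {
  n <- length(x$assignments)
  cat("Winner-take-all parcel map for ", x$structure, ": ", n, " voxels, ",
      sum(is.na(x$assignments)), " unassigned (tau = ", x$tau,
      ", tie rule '", x$tie_rule, "')\n", sep = "")
  print(table(x$assignments, useNA = "ifany"))
  invisible(x)
}
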