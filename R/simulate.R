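# Synthetic cohort generator.
#
# Emulates the data structure of a two-group resting-state study of the CBTC
# circuits: region-level BOLD series drawn from a multivariate normal whose
# correlation matrix carries the loop structure (manifest edges correlated at
# rho0, everything else uncorrelated), an ipsilesional connectivity decrement
# (rho0 - delta) on designated edges in patients, upper-limb motor scores
# (UE-FMA, integer, 0-66) linearly coupled to designated edges, and Dirichlet
# voxel connectivity profiles with planted cortical-target subdivisions for
# the parcellation stage.

#' Simulation configuration
#'
#' Collects and validates every knob of the synthetic cohort generator.
#' Defaults encode the study conditions the generator emulates: 64 patients
#' and 64 controls, 200 timepoints, a baseline edge correlation of 0.4 with a
#' 0.15 ipsilesional decrement on the three loop edges reported as reduced in
#' patients, and behaviour coupled (with the reported signs) to the four loop
#' edges reported as predictive of UE-FMA.
#'
#' @param n_patients,n_controls Group sizes.
#' @param n_timepoints Series length per subject.
#' @param rho0 Baseline correlation on manifest loop edges, in (0, 1).
#' @param affected_edges Character vector of manifest loop edge ids carrying
#'   the patient decrement (ipsilesional by convention: hemisphere `R`).
#' @param delta Correlation decrement on `affected_edges` in patients,
#'   `0 <= delta < rho0`.
#' @param behavior_edges Data frame with columns `edge` (manifest loop edge
#'   id) and `weight` (signed real): UE-FMA is an affine function of the
#'   weighted sum of these edges' Fisher-z values.
#' @param behavior_noise_sd,behavior_offset,behavior_scale Parameters of the
#'   affine score model (see [simulate_behavior()]).
#' @param profile_concentration Dirichlet concentration `kappa` of the
#'   planted target in voxel connectivity profiles.
#' @param voxels_per_subdivision Voxels planted per cortical target and
#'   subcortical structure.
#' @param prop_left_lesion Proportion of patients with a left-sided lesion
#'   (these are recorded as flipped; series are stored post-flip, so the
#'   ipsilesional hemisphere is `R` for every patient).
#' @param seed Integer seed; the whole cohort is reproducible from it.
#' @param manifest A `cbtc_manifest`; defaults to the shipped manifest.
#' @return A `cbtc_sim_config` list.
#' @export
sim_config <- function(n_patients = 64L,
                       n_controls = 64L,
                       n_timepoints = 200L,
                       rho0 = 0.4,
                       affected_edges = c("short:R:M1-CAU_M1",
                                          "short:R:DLPFC-PUT_DLPFC",
                                          "long:R:THA_DLPFC-DLPFC"),
                       delta = 0.15,
                       behavior_edges = data.frame(
                         edge = c("short:R:M1-CAU_M1",
                                  "short:R:M1-PUT_M1",
                                  "short:L:DLPFC-PUT_DLPFC",
                                  "short:L:MPFC-CAU_MPFC"),
                         weight = c(1, 1, 1, -1),
                         stringsAsFactors = FALSE),
                       behavior_noise_sd = 6,
                       behavior_offset = -15,
                       behavior_scale = 60,
                       profile_concentration = 50,
                       voxels_per_subdivision = 50L,
                       prop_left_lesion = 15 / 64,
                       seed = 1L,
                       manifest = default_loop_manifest()) {
  stopifnot(inherits(manifest, "cbtc_manifest"))
  if (!(rho0 > 0 && rho0 < 1)) stop_cbtc("rho0 must lie in (0, 1)")
  if (!(delta >= 0 && delta < rho0)) {
    stop_cbtc("delta must satisfy 0 <= delta < rho0")
  }
  if (behavior_noise_sd < 0) stop_cbtc("behavior_noise_sd must be >= 0")
  if (profile_concentration <= 0) {
    stop_cbtc("profile_concentration must be > 0")
  }
  loop_ids <- manifest_edges(manifest, "loops")$edge
  bad <- setdiff(c(affected_edges, behavior_edges$edge), loop_ids)
  if (length(bad)) {
    stop_cbtc("edge not in manifest loop edge set: ", bad[1L])
  }
  structure(list(
    n_patients = as.integer(n_patients),
    n_controls = as.integer(n_controls),
    n_timepoints = as.integer(n_timepoints),
    rho0 = rho0, affected_edges = affected_edges, delta = delta,
    behavior_edges = behavior_edges,
    behavior_noise_sd = behavior_noise_sd,
    behavior_offset = behavior_offset,
    behavior_scale = behavior_scale,
    profile_concentration = profile_concentration,
    voxels_per_subdivision = as.integer(voxels_per_subdivision),
    prop_left_lesion = prop_left_lesion,
    seed = as.integer(seed),
    manifest = manifest), class = "cbtc_sim_config")
}

#' Target region correlation matrix for one group
#'
#' Builds the generative correlation matrix over the simulated regions (five
#' cortical regions plus twenty subdivisions per hemisphere): unit diagonal,
#' `rho0` on manifest loop edges (`rho0 - delta` on `affected_edges` when
#' `group = "patient"`), zero elsewhere, then repaired to the nearest
#' positive semidefinite correlation matrix by eigenvalue clipping (floor
#' 1e-8) and diagonal re-normalisation.  The largest absolute change the
#' repair makes to any targeted entry is recorded in the `"repair_delta"`
#' attribute; if it exceeds `max_repair` the function errors and advises a
#' lower `rho0`.
#'
#' @param manifest A `cbtc_manifest`.
#' @param rho0 Baseline edge correlation in (0, 1).
#' @param group `"patient"` or `"control"`.
#' @param affected_edges Loop edge ids decremented in patients.
#' @param delta Decrement in `[0, rho0)`.
#' @param max_repair Largest tolerated repair perturbation on a targeted
#'   entry (default 0.05).
#' @return Correlation matrix with dimnames `"<hemisphere>:<region>"` and
#'   attribute `repair_delta`.
#' @export
build_target_correlation <- function(manifest, rho0,
                                     group = c("control", "patient"),
                                     affected_edges = character(),
                                     delta = 0, max_repair = 0.05) {
  group <- match.arg(group)
  if (!(rho0 > 0 && rho0 < 1)) stop_cbtc("rho0 must lie in (0, 1)")
  regions <- sim_region_names()
  p <- length(regions)
  R <- diag(p)
  dimnames(R) <- list(regions, regions)
  e <- manifest_edges(manifest, "loops")
  ia <- match(paste(e$hemisphere, e$region_a, sep = ":"), regions)
  ib <- match(paste(e$hemisphere, e$region_b, sep = ":"), regions)
  if (anyNA(ia) || anyNA(ib)) {
    stop_cbtc("manifest loop edge references a region outside the simulated ",
              "region set")
  }
  val <- rep(rho0, nrow(e))
  if (group == "patient" && length(affected_edges)) {
    val[e$edge %in% affected_edges] <- rho0 - delta
  }
  # the same region pair can appear in both loops; the decrement targets the
  # physical pair, so the decremented value wins
  pair <- paste(pmin(ia, ib), pmax(ia, ib))
  val <- stats::ave(val, pair, FUN = min)
  R[cbind(ia, ib)] <- val
  R[cbind(ib, ia)] <- val
  repaired <- nearest_psd_corr(R)
  targeted <- cbind(ia, ib)
  repair_delta <- max(abs(repaired[targeted] - R[targeted]))
  if (repair_delta > max_repair) {
    stop_cbtc("positive-semidefinite repair changed a targeted correlation ",
              "by ", format(repair_delta, digits = 3),
              " (> ", max_repair, "); lower rho0")
  }
  attr(repaired, "repair_delta") <- repair_delta
  repaired
}

# Nearest-PSD repair by eigenvalue clipping at `floor`, then re-normalising
# the diagonal to 1.
nearest_psd_corr <- function(R, floor = 1e-8) {
  ed <- eigen(R, symmetric = TRUE)
  if (min(ed$values) >= floor) return(R)
  lam <- pmax(ed$values, floor)
  X <- ed$vectors %*% (lam * t(ed$vectors))
  d <- sqrt(diag(X))
  X <- X / tcrossprod(d)
  diag(X) <- 1
  dimnames(X) <- dimnames(R)
  X
}

#' Simulate a region x time BOLD-like series
#'
#' Draws `n_timepoints` independent samples from a zero-mean, unit-variance
#' multivariate normal with the given correlation matrix.  The same seed
#' yields a bit-identical matrix.
#'
#' @param corr Positive semidefinite correlation matrix.
#' @param n_timepoints Number of timepoints.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return `nrow(corr)` x `n_timepoints` matrix with `rownames(corr)`.
#' @export
simulate_timeseries <- function(corr, n_timepoints, seed = NULL) {
  p <- nrow(corr)
  ed <- eigen(corr, symmetric = TRUE)
  if (min(ed$values) < -1e-8 * max(abs(ed$values))) {
    stop_cbtc("correlation matrix is not positive semidefinite")
  }
  A <- ed$vectors %*% diag(sqrt(pmax(ed$values, 0)), p)
  draw <- function() {
    Z <- matrix(stats::rnorm(p * n_timepoints), p, n_timepoints)
    out <- A %*% Z
    rownames(out) <- rownames(corr)
    out
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a UE-FMA score from edge-wise connectivity
#'
#' `score = clip(round(offset + scale * sum(weight * z[edge]) + eps), 0, 66)`
#' with `eps ~ Normal(0, noise_sd)`.  The instrument is integer-valued
#' (33 items, two points each), hence the rounding and the 0-66 range.
#'
#' @param z Named numeric vector of Fisher-z edge values.
#' @param behavior_edges Data frame with columns `edge`, `weight`.
#' @param noise_sd,offset,scale Affine model parameters.
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return Integer score in `[0, 66]`.
#' @export
simulate_behavior <- function(z, behavior_edges, noise_sd = 0,
                              offset = 0, scale = 1, seed = NULL) {
  miss <- setdiff(behavior_edges$edge, names(z))
  if (length(miss)) {
    stop_cbtc("behaviour edge not present in the FC vector: ", miss[1L])
  }
  lin <- offset + scale * sum(behavior_edges$weight * z[behavior_edges$edge])
  eps <- if (noise_sd > 0) {
    if (is.null(seed)) stats::rnorm(1L, 0, noise_sd)
    else with_seed(seed, stats::rnorm(1L, 0, noise_sd))
  } else 0
  as.integer(min(66L, max(0L, round(lin + eps))))
}

#' Simulate planted voxel connectivity profiles for one structure
#'
#' For each cortical target `t`, draws `voxels_per_subdivision` voxels from
#' `Dirichlet(alpha)` with `alpha[t] = kappa` and `alpha[other] = 1`: the
#' planted subdivision label of those voxels is `t`.  Large `kappa` gives
#' near-deterministic profiles; `kappa = 1` is uninformative (uniform
#' Dirichlet), so recovery falls to chance.
#'
#' @param structure Subcortical structure name (e.g. `"CAU"`).
#' @param cortical_targets Target order (columns of the profile matrix).
#' @param voxels_per_subdivision Voxels per planted target.
#' @param kappa Concentration of the planted target (> 0).
#' @param seed Integer seed, or `NULL` to draw from the current RNG stream.
#' @return List with `profiles` (voxel x target probability matrix, rows sum
#'   to 1), `truth` (planted subdivision label per voxel, e.g. `"CAU_M1"`),
#'   `structure`, and `targets`.
#' @export
simulate_voxel_profiles <- function(structure,
                                    cortical_targets = CORTICAL_REGIONS,
                                    voxels_per_subdivision = 50L,
                                    kappa = 50,
                                    seed = NULL) {
  if (kappa <= 0) stop_cbtc("kappa must be > 0")
  k <- length(cortical_targets)
  n <- voxels_per_subdivision * k
  draw <- function() {
    alpha <- matrix(1, n, k)
    planted <- rep(seq_len(k), each = voxels_per_subdivision)
    alpha[cbind(seq_len(n), planted)] <- kappa
    g <- matrix(stats::rgamma(n * k, shape = alpha), n, k)
    profiles <- g / rowSums(g)
    colnames(profiles) <- cortical_targets
    rownames(profiles) <- sprintf("v%04d", seq_len(n))
    list(profiles = profiles,
         truth = paste(structure, cortical_targets[planted], sep = "_"),
         structure = structure, targets = cortical_targets)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate a full synthetic cohort
#'
#' Generates subjects (phenotype records), per-subject region time series
#' (patients drawn under the patient correlation matrix), UE-FMA scores for
#' patients computed from each patient's own realised connectivity on the
#' designated behaviour edges, and planted voxel connectivity profiles for
#' each subcortical structure.  Entirely reproducible from `config$seed`.
#'
#' Patient series are stored post-flip: the ipsilesional hemisphere is `R`
#' for every patient, and the recorded `flipped` flag marks the patients
#' (left-sided lesions) whose native data would have been mirrored.
#'
#' @param config A `cbtc_sim_config` from [sim_config()].
#' @return A `cbtc_cohort`: list with `subjects` (data frame `id`, `group`,
#'   `age`, `sex`, `lesion_side`, `ue_fma`, `flipped`), `series` (named list
#'   of region x time matrices), `profiles` (per structure, see
#'   [simulate_voxel_profiles()]), `manifest`, and `truth` (the config).
#' @examples
#' cfg <- sim_config(n_patients = 4, n_controls = 4, n_timepoints = 50,
#'                   voxels_per_subdivision = 5, seed = 7)
#' coh <- simulate_cohort(cfg)
#' table(coh$subjects$group)
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "cbtc_sim_config"))
  with_seed(config$seed, {
    np <- config$n_patients
    nc <- config$n_controls
    n <- np + nc
    corr_pat <- build_target_correlation(config$manifest, config$rho0,
                                         "patient", config$affected_edges,
                                         config$delta)
    corr_ctl <- build_target_correlation(config$manifest, config$rho0,
                                         "control")
    group <- rep(c("patient", "control"), c(np, nc))
    age <- round(rtruncnorm(n, mean = 57, sd = 12, lo = 30, hi = 80))
    sex <- ifelse(stats::runif(n) < 0.55, "male", "female")
    lesion <- ifelse(group == "patient",
                     ifelse(stats::runif(n) < config$prop_left_lesion,
                            "L", "R"),
                     "none")
    subjects <- data.frame(
      id = sprintf("sub%03d", seq_len(n)),
      group = group, age = age, sex = sex, lesion_side = lesion,
      ue_fma = NA_integer_,
      flipped = group == "patient" & lesion == "L",
      stringsAsFactors = FALSE)

    series <- vector("list", n)
    names(series) <- subjects$id
    be <- config$behavior_edges
    edge_tab <- manifest_edges(config$manifest, "loops")
    be_rows <- match(be$edge, edge_tab$edge)
    regs <- rownames(corr_ctl)
    ba <- match(paste(edge_tab$hemisphere, edge_tab$region_a,
                      sep = ":")[be_rows], regs)
    bb <- match(paste(edge_tab$hemisphere, edge_tab$region_b,
                      sep = ":")[be_rows], regs)
    for (i in seq_len(n)) {
      corr <- if (group[i] == "patient") corr_pat else corr_ctl
      s <- simulate_timeseries(corr, config$n_timepoints, seed = NULL)
      series[[i]] <- s
      if (group[i] == "patient") {
        z <- vapply(seq_along(be_rows), function(j) {
          fisher_z(pearson_r(s[ba[j], ], s[bb[j], ]))
        }, numeric(1))
        names(z) <- be$edge
        subjects$ue_fma[i] <- simulate_behavior(
          z, be, noise_sd = config$behavior_noise_sd,
          offset = config$behavior_offset, scale = config$behavior_scale,
          seed = NULL)
      }
    }

    profiles <- lapply(SUBCORTICAL_REGIONS, function(st) {
      simulate_voxel_profiles(
        st, CORTICAL_REGIONS,
        voxels_per_subdivision = config$voxels_per_subdivision,
        kappa = config$profile_concentration, seed = NULL)
    })
    names(profiles) <- SUBCORTICAL_REGIONS

    structure(list(subjects = subjects, series = series,
                   profiles = profiles, manifest = config$manifest,
                   truth = config), class = "cbtc_cohort")
  })
}

# Truncated normal by rejection; the truncation interval is wide relative to
# sd, so rejection is cheap.
rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- stats::rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  while (length(bad)) {
    out[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

#' @export
print.cbtc_cohort <- function(x, ...) {
  tab <- table(x$subjects$group)
  cat("Synthetic CBTC cohort: ", tab[["patient"]], " patients, ",
      tab[["control"]], " controls, ",
      x$truth$n_timepoints, " timepoints\n", sep = "")
  cat("rho0 = ", x$truth$rho0, ", delta = ", x$truth$delta, " on ",
      length(x$truth$affected_edges), " affected edge(s)\n", sep = "")
  invisible(x)
}
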