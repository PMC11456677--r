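# Loop manifests: the edge lists defining the two parallel CBTC loops
# (the "short" cortico-striato-thalamo-cortical loop, 19 edges per
# hemisphere, and the "long" cortico-striato-pallido-thalamo-cortical loop,
# 21 edges per hemisphere, 40 in total) plus the whole-structure "atlas"
# edge set (26 per hemisphere).  The manifest is data, not code: a default
# reconstruction ships with the package and users may substitute their own
# TSV.

LOOP_COUNTS <- c(short = 19L, long = 21L, atlas = 26L)

#' Default loop manifest (reconstruction)
#'
#' Builds the default edge lists for the two CBTC loops by rule.  The exact
#' published edge composition is not publicly archived, so this manifest is a
#' documented reconstruction with the correct counts (19 short + 21 long per
#' hemisphere) that contains every loop edge reported in the source analyses:
#'
#' * Short loop (cortex-striatum-thalamus-cortex): for every cortical target
#'   `t`, the caudate route `t-CAU_t`, `CAU_t-THA_t`, `THA_t-t` (15 edges),
#'   plus the putamen branch `t-PUT_t`, `PUT_t-THA_t` for the two targets
#'   whose putamen territories carry the motor/associative circuits of
#'   interest, M1 and DLPFC (4 edges).
#' * Long loop (cortex-striatum-pallidum-thalamus-cortex): for every target
#'   `t`, the chain `t-CAU_t`, `CAU_t-PAL_t`, `PAL_t-THA_t`, `THA_t-t`
#'   (20 edges) minus the `THA_OFC-OFC` closure, plus the M1 putamen branch
#'   `M1-PUT_M1`, `PUT_M1-PAL_M1` (net 21 edges).
#'
#' The atlas edge set is generated by [enumerate_atlas_edges()].
#'
#' @param include_atlas Include the 26 atlas edges per hemisphere (default
#'   `TRUE`).
#' @return A `cbtc_manifest` object; see [load_loop_manifest()].
#' @examples
#' m <- default_loop_manifest()
#' table(m$edges$loop, m$edges$hemisphere)
#' @export
default_loop_manifest <- function(include_atlas = TRUE) {
  one_hemi <- function(h) {
    short <- list()
    for (t in CORTICAL_REGIONS) {
      short[[t]] <- rbind(
        c(t, paste0("CAU_", t)),
        c(paste0("CAU_", t), paste0("THA_", t)),
        c(paste0("THA_", t), t))
    }
    for (t in c("M1", "DLPFC")) {
      short[[paste0(t, "_put")]] <- rbind(
        c(t, paste0("PUT_", t)),
        c(paste0("PUT_", t), paste0("THA_", t)))
    }
    short <- do.call(rbind, short)

    long <- list()
    for (t in CORTICAL_REGIONS) {
      chain <- rbind(
        c(t, paste0("CAU_", t)),
        c(paste0("CAU_", t), paste0("PAL_", t)),
        c(paste0("PAL_", t), paste0("THA_", t)),
        c(paste0("THA_", t), t))
      if (t == "OFC") chain <- chain[-4L, , drop = FALSE]  # trimmed closure
      long[[t]] <- chain
    }
    long[["M1_put"]] <- rbind(
      c("M1", "PUT_M1"),
      c("PUT_M1", "PAL_M1"))
    long <- do.call(rbind, long)

    df <- rbind(
      data.frame(loop = "short", hemisphere = h, region_a = short[, 1],
                 region_b = short[, 2], stringsAsFactors = FALSE),
      data.frame(loop = "long", hemisphere = h, region_a = long[, 1],
                 region_b = long[, 2], stringsAsFactors = FALSE))
    if (include_atlas) df <- rbind(df, enumerate_atlas_edges(h))
    df
  }
  edges <- rbind(one_hemi("L"), one_hemi("R"))
  new_manifest(edges, provenance = "built-in default (reconstructed by rule)")
}

#' Enumerate the atlas edge set for one hemisphere
#'
#' The whole-structure ("atlas") edge set treats each subcortical structure
#' as undivided: all 5 x 4 = 20 cortico-subcortical pairs plus the
#' C(4,2) = 6 subcortical-subcortical pairs, all intrahemispheric, 26 edges.
#'
#' @param hemisphere `"L"` or `"R"`.
#' @return Data frame with columns `loop` (`"atlas"`), `hemisphere`,
#'   `region_a`, `region_b`.
#' @examples
#' nrow(enumerate_atlas_edges("L"))  # 26
#' @export
enumerate_atlas_edges <- function(hemisphere = c("L", "R")) {
  hemisphere <- match.arg(hemisphere)
  cs <- expand.grid(region_a = CORTICAL_REGIONS,
                    region_b = SUBCORTICAL_REGIONS,
                    stringsAsFactors = FALSE)
  ss <- t(utils::combn(SUBCORTICAL_REGIONS, 2L))
  ss <- data.frame(region_a = ss[, 1], region_b = ss[, 2],
                   stringsAsFactors = FALSE)
  out <- rbind(cs, ss)
  data.frame(loop = "atlas", hemisphere = hemisphere,
             region_a = out$region_a, region_b = out$region_b,
             stringsAsFactors = FALSE)
}

new_manifest <- function(edges, provenance) {
  edges$edge <- edge_id(edges$loop, edges$hemisphere,
                        edges$region_a, edges$region_b)
  rownames(edges) <- NULL
  structure(list(edges = edges, provenance = provenance),
            class = "cbtc_manifest")
}

#' Load and validate a loop manifest from TSV
#'
#' Reads a tab-separated manifest with header
#' `loop  hemisphere  region_a  region_b` (`#` comments allowed) and
#' validates it: known loops and hemispheres, resolvable region names, no
#' self-pairs, unordered pairs unique within `(loop, hemisphere)`, and the
#' canonical counts per hemisphere (19 short, 21 long, and 26 atlas when
#' atlas rows are present).
#'
#' @param path Path to the manifest TSV.  The default is the manifest
#'   shipped with the package.
#' @return A `cbtc_manifest`: a list with `edges` (data frame with columns
#'   `loop`, `hemisphere`, `region_a`, `region_b`, `edge`) and `provenance`
#'   (path plus MD5 checksum).
#' @seealso [default_loop_manifest()], [write_loop_manifest()]
#' @export
load_loop_manifest <- function(path = system.file("extdata",
                                                  "loop_manifest.tsv",
                                                  package = "cbtcloops")) {
  if (!nzchar(path) || !file.exists(path)) {
    stop_cbtc("manifest file not found: '", path, "'")
  }
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  raw <- lines[keep]
  lineno <- which(keep)
  if (length(raw) < 2L) stop_cbtc("manifest '", path, "': no data rows")
  fields <- strsplit(raw, "\t", fixed = TRUE)
  header <- fields[[1L]]
  want <- c("loop", "hemisphere", "region_a", "region_b")
  if (!identical(header[seq_along(want)], want)) {
    stop_cbtc("manifest '", path, "': header must be '",
              paste(want, collapse = "\t"), "'")
  }
  bad <- which(lengths(fields[-1L]) < 4L)
  if (length(bad)) {
    stop_cbtc("manifest '", path, "': malformed row at line ",
              lineno[bad[1L] + 1L], " (expected 4 tab-separated fields)")
  }
  body <- fields[-1L]
  edges <- data.frame(
    loop = vapply(body, `[[`, "", 1L),
    hemisphere = vapply(body, `[[`, "", 2L),
    region_a = vapply(body, `[[`, "", 3L),
    region_b = vapply(body, `[[`, "", 4L),
    stringsAsFactors = FALSE)
  m <- new_manifest(edges, provenance = paste0(path, " (md5 ",
                                               unname(tools::md5sum(path)),
                                               ")"))
  validate_loop_manifest(m)
  m
}

#' Validate manifest invariants
#'
#' @param manifest A `cbtc_manifest`.
#' @return The manifest, invisibly, if valid; otherwise an error naming the
#'   violated invariant (loop, hemisphere, observed vs expected count).
#' @export
validate_loop_manifest <- function(manifest) {
  stopifnot(inherits(manifest, "cbtc_manifest"))
  e <- manifest$edges
  bad_loop <- setdiff(unique(e$loop), names(LOOP_COUNTS))
  if (length(bad_loop)) stop_cbtc("unknown loop label: ", bad_loop[1L])
  bad_h <- setdiff(unique(e$hemisphere), HEMISPHERES)
  if (length(bad_h)) stop_cbtc("unknown hemisphere: ", bad_h[1L])
  known <- region_name_set()
  bad_r <- setdiff(unique(c(e$region_a, e$region_b)), known)
  if (length(bad_r)) stop_cbtc("unresolvable region name: ", bad_r[1L])
  if (any(e$region_a == e$region_b)) {
    stop_cbtc("self-pair in manifest: ", e$edge[e$region_a == e$region_b][1L])
  }
  keys <- edge_key(e$loop, e$hemisphere, e$region_a, e$region_b)
  if (anyDuplicated(keys)) {
    stop_cbtc("duplicated unordered pair in manifest: ",
              keys[duplicated(keys)][1L])
  }
  for (h in intersect(HEMISPHERES, unique(e$hemisphere))) {
    for (lp in intersect(names(LOOP_COUNTS), unique(e$loop))) {
      n <- sum(e$loop == lp & e$hemisphere == h)
      if (n != LOOP_COUNTS[[lp]]) {
        stop_cbtc("manifest count violation: ", lp, ", ", h, ": ",
                  n, " != ", LOOP_COUNTS[[lp]])
      }
    }
  }
  invisible(manifest)
}

#' Write a manifest to TSV
#'
#' @param manifest A `cbtc_manifest`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loop_manifest <- function(manifest, path) {
  stopifnot(inherits(manifest, "cbtc_manifest"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# CBTC loop manifest (reconstructed edge lists; see package docs)",
               paste(c("loop", "hemisphere", "region_a", "region_b"),
                     collapse = "\t")), con)
  e <- manifest$edges
  writeLines(paste(e$loop, e$hemisphere, e$region_a, e$region_b, sep = "\t"),
             con)
  invisible(path)
}

# Subset of manifest edges for a scheme, preserving manifest row order.
manifest_edges <- function(manifest, scheme = c("loops", "atlas")) {
  scheme <- match.arg(scheme)
  e <- manifest$edges
  if (scheme == "loops") e[e$loop %in% c("short", "long"), , drop = FALSE]
  else e[e$loop == "atlas", , drop = FALSE]
}

#' @export
print.cbtc_manifest <- function(x, ...) {
  cat("CBTC loop manifest\n")
  tab <- table(x$edges$loop, x$edges$hemisphere)
  print(tab)
  cat("provenance:", x$provenance, "\n")
  invisible(x)
}
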