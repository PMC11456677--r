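# Orchestration: one configured run that simulates (or loads) a cohort,
# parcellates the planted voxel profiles, extracts both FC schemes, and runs
# group statistics, SVM classification and CPM prediction, writing all stage
# outputs plus a machine-readable summary JSON.  Identical configuration and
# seeds give a byte-identical summary.

#' Pipeline run configuration
#'
#' All stage seeds are derived deterministically from the single master
#' `seed`, so a whole run is reproducible from one integer.  Stage toggles
#' let partial runs skip the expensive stages.
#'
#' @param mode `"simulate"` (generate a synthetic cohort) or `"load"` (read
#'   a phenotype table and per-subject series from disk).
#' @param outdir Output directory (created if needed).
#' @param seed Master integer seed.
#' @param sim A `cbtc_sim_config` for simulate mode; its own `seed` is
#'   overridden by the derived simulation seed.  Defaults to `sim_config()`.
#' @param phenotype_path,series_dir Inputs for load mode: a phenotype TSV
#'   (`id  group  age  sex  lesion_side  ue_fma`) and a directory of
#'   per-subject series TSVs named `<id>.tsv` (first column `region`, one
#'   column per timepoint).
#' @param stages Which stages to run (subset of `"segment"`, `"fc"`,
#'   `"compare"`, `"classify"`, `"predict"`).
#' @param n_perm_svm,n_perm_cpm Permutation counts for the inference stages.
#' @param svm_k_grid Optional `k` grid for the SVM accuracy curve.
#' @param tau,tie_rule Parcellation settings (see [winner_take_all()]).
#' @param p_sel,corr_type,combined_form CPM settings (see [cpm_predict()]).
#' @return A `cbtc_run_config` list.
#' @export
run_config <- function(mode = c("simulate", "load"),
                       outdir = tempfile("cbtc_run_"),
                       seed = 1L,
                       sim = NULL,
                       phenotype_path = NULL,
                       series_dir = NULL,
                       stages = c("segment", "fc", "compare", "classify",
                                  "predict"),
                       n_perm_svm = 200L,
                       n_perm_cpm = 200L,
                       svm_k_grid = NULL,
                       tau = 0.01,
                       tie_rule = "first-target",
                       p_sel = 0.05,
                       corr_type = "pearson",
                       combined_form = "two-predictor") {
  mode <- match.arg(mode)
  stages <- match.arg(stages, c("segment", "fc", "compare", "classify",
                                "predict"), several.ok = TRUE)
  seed <- as.integer(seed)
  if (mode == "simulate") {
    sim <- sim %||% sim_config()
    sim$seed <- derive_seed(seed, "simulate")
  } else {
    if (is.null(phenotype_path) || is.null(series_dir)) {
      stop_cbtc("load mode requires `phenotype_path` and `series_dir`")
    }
  }
  structure(list(mode = mode, outdir = outdir, seed = seed, sim = sim,
                 phenotype_path = phenotype_path, series_dir = series_dir,
                 stages = stages, n_perm_svm = as.integer(n_perm_svm),
                 n_perm_cpm = as.integer(n_perm_cpm),
                 svm_k_grid = svm_k_grid, tau = tau, tie_rule = tie_rule,
                 p_sel = p_sel, corr_type = corr_type,
                 combined_form = combined_form),
            class = "cbtc_run_config")
}

#' Read a run configuration from a flat YAML file
#'
#' Keys mirror the arguments of [run_config()]; nested `sim:` keys mirror
#' [sim_config()].  Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `cbtc_run_config`.
#' @export
run_config_from_yaml <- function(path) {
  if (!file.exists(path)) stop_cbtc("config file not found: '", path, "'")
  y <- yaml::read_yaml(path)
  sim_keys <- y$sim
  y$sim <- NULL
  known <- names(formals(run_config))
  bad <- setdiff(names(y), known)
  if (length(bad)) stop_cbtc("unknown config key: ", bad[1L])
  if (!is.null(sim_keys)) {
    bad <- setdiff(names(sim_keys), names(formals(sim_config)))
    if (length(bad)) stop_cbtc("unknown sim config key: ", bad[1L])
    y$sim <- do.call(sim_config, sim_keys)
  }
  do.call(run_config, y)
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (simulate/load, segment, fc,
#' compare, classify, predict), writes every stage output under
#' `config$outdir` (TSV/JSON), and returns the summary invisibly.  Any
#' stage failure aborts with the stage name; partial outputs are kept along
#' with a `FAILED` marker file naming the stage.
#'
#' @param config A `cbtc_run_config` from [run_config()].
#' @return The summary list (also written to `summary.json`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "cbtc_run_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  logfile <- file.path(config$outdir, "pipeline.log")
  cat("", file = logfile)
  stage_log <- function(stage, msg) {
    line <- paste0("[", stage, "] ", msg)
    message(line)
    cat(line, "\n", file = logfile, append = TRUE)
  }
  run_stage <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      writeLines(paste0("FAILED at stage '", stage, "': ",
                        conditionMessage(e)),
                 file.path(config$outdir, "FAILED"))
      stop_cbtc("stage '", stage, "' failed: ", conditionMessage(e))
    })
    stage_log(stage, sprintf("done in %.1fs", proc.time()[["elapsed"]] - t0))
    out
  }
  summary <- list(package_version = as.character(utils::packageVersion("cbtcloops")),
                  seed = config$seed, mode = config$mode)

  cohort <- run_stage("input", {
    if (config$mode == "simulate") {
      simulate_cohort(config$sim)
    } else {
      load_cohort(config$phenotype_path, config$series_dir)
    }
  })
  write_phenotype(cohort$subjects, file.path(config$outdir, "phenotype.tsv"))
  summary$n_patients <- sum(cohort$subjects$group == "patient")
  summary$n_controls <- sum(cohort$subjects$group == "control")

  if ("segment" %in% config$stages && length(cohort$profiles)) {
    seg <- run_stage("segment", {
      lapply(cohort$profiles, function(pr) {
        pm <- winner_take_all(pr, tau = config$tau,
                              tie_rule = config$tie_rule)
        d <- if (!is.null(pr$truth)) parcellation_dice(pm, pr$truth) else NULL
        list(map = pm, dice = d)
      })
    })
    seg_tab <- do.call(rbind, lapply(names(seg), function(st) {
      pm <- seg[[st]]$map
      data.frame(structure = st,
                 subdivision = paste(st, pm$targets, sep = "_"),
                 n_voxels = as.numeric(table(factor(pm$assignments,
                   paste(st, pm$targets, sep = "_")))),
                 dice_vs_truth = if (is.null(seg[[st]]$dice)) NA_real_
                                 else unname(seg[[st]]$dice),
                 stringsAsFactors = FALSE)
    }))
    utils::write.table(seg_tab, file.path(config$outdir, "parcellation.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    summary$parcellation <- list(
      mean_dice = if (all(is.na(seg_tab$dice_vs_truth))) NULL
                  else mean(seg_tab$dice_vs_truth, na.rm = TRUE),
      unassigned = sum(vapply(seg, function(s) {
        sum(is.na(s$map$assignments))
      }, numeric(1))))
  }

  fc <- NULL
  if (any(c("fc", "compare", "classify", "predict") %in% config$stages)) {
    fc <- run_stage("fc", {
      list(loops = extract_fc_vector(cohort, scheme = "loops"),
           atlas = extract_fc_vector(cohort, scheme = "atlas"))
    })
    write_fc_table(fc$loops, file.path(config$outdir, "fc_loops.tsv"))
    write_fc_table(fc$atlas, file.path(config$outdir, "fc_atlas.tsv"))
    summary$edges_per_subject <- list(loops = ncol(fc$loops),
                                      atlas = ncol(fc$atlas))
  }

  if ("compare" %in% config$stages) {
    cmp <- run_stage("compare", {
      lapply(fc, function(m) compare_groups(m, cohort$subjects$group))
    })
    for (sc in names(cmp)) {
      utils::write.table(as.data.frame(cmp[[sc]]),
                         file.path(config$outdir,
                                   paste0("group_stats_", sc, ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    demo <- demographic_stats(cohort$subjects)
    summary$demographics <- list(chi2 = demo$chi2$chi2, chi2_p = demo$chi2$p,
                                 mw_z = demo$mw$z, mw_p = demo$mw$p)
    summary$group_stats <- lapply(cmp, function(tab) {
      list(n_edges = nrow(tab),
           significant_edges = tab$edge[tab$significant],
           direction = tab$direction[tab$significant])
    })
  }

  if ("classify" %in% config$stages) {
    cls <- run_stage("classify", {
      lapply(fc, function(m) {
        svm_classify(m, cohort$subjects$group,
                     k_grid = config$svm_k_grid,
                     n_perm = config$n_perm_svm,
                     seed = derive_seed(config$seed, "svm-perm"))
      })
    })
    for (sc in names(cls)) {
      utils::write.table(
        data.frame(k = as.integer(names(cls[[sc]]$accuracy_by_k)),
                   accuracy = cls[[sc]]$accuracy_by_k),
        file.path(config$outdir, paste0("svm_accuracy_curve_", sc, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cls[[sc]]$roc,
        file.path(config$outdir, paste0("svm_roc_", sc, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary$classification <- lapply(cls, function(r) {
      list(best_k = r$best_k, accuracy = r$accuracy,
           sensitivity = r$sensitivity, specificity = r$specificity,
           auc = r$auc, permutation_p = r$permutation_p,
           n_perm = r$n_perm)
    })
  }

  if ("predict" %in% config$stages) {
    pat <- cohort$subjects$group == "patient"
    beh <- cohort$subjects$ue_fma[pat]
    cpm <- run_stage("predict", {
      lapply(fc, function(m) {
        cpm_predict(m[pat, , drop = FALSE], beh,
                    p_sel = config$p_sel, corr_type = config$corr_type,
                    combined_form = config$combined_form,
                    n_perm = config$n_perm_cpm,
                    seed = derive_seed(config$seed, "cpm-perm"))
      })
    })
    for (sc in names(cpm)) {
      utils::write.table(
        data.frame(id = cohort$subjects$id[pat], observed = beh,
                   do.call(cbind, lapply(cpm[[sc]]$modes,
                                         `[[`, "predicted"))),
        file.path(config$outdir, paste0("cpm_predictions_", sc, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(cpm[[sc]]$well_represented,
        file.path(config$outdir, paste0("cpm_stability_", sc, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
    }
    summary$cpm <- lapply(cpm, function(r) {
      out <- lapply(r$modes, function(m) {
        list(spearman_r = m$spearman_r, permutation_p = m$permutation_p,
             flagged_folds = m$flagged_folds)
      })
      out$well_represented <- r$well_represented$edge
      out
    })
  }

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  stage_log("summary", paste0("written to ",
                              file.path(config$outdir, "summary.json")))
  invisible(summary)
}

#' Write / read a phenotype table
#'
#' TSV with header `id  group  age  sex  lesion_side  ue_fma  flipped`.
#'
#' @param subjects Phenotype data frame.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_phenotype <- function(subjects, path) {
  utils::write.table(subjects, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotype
#' @export
read_phenotype <- function(path) {
  if (!file.exists(path)) {
    stop_cbtc("phenotype file not found: '", path, "'")
  }
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("id", "group", "age", "sex", "lesion_side", "ue_fma")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop_cbtc("phenotype file missing column(s): ",
              paste(miss, collapse = ", "))
  }
  bad <- df$ue_fma[!is.na(df$ue_fma)]
  if (any(bad < 0 | bad > 66)) stop_cbtc("ue_fma outside [0, 66]")
  if (any(df$group == "control" & !is.na(df$ue_fma))) {
    stop_cbtc("controls must not carry a ue_fma score")
  }
  if (any(df$group == "control" & df$lesion_side != "none")) {
    stop_cbtc("controls must have lesion_side = none")
  }
  df
}

# Load-mode cohort: phenotype TSV plus a directory of per-subject series
# TSVs (<id>.tsv, first column `region`).
load_cohort <- function(phenotype_path, series_dir) {
  subjects <- read_phenotype(phenotype_path)
  if (!dir.exists(series_dir)) {
    stop_cbtc("series directory not found: '", series_dir, "'")
  }
  series <- lapply(subjects$id, function(id) {
    f <- file.path(series_dir, paste0(id, ".tsv"))
    if (!file.exists(f)) stop_cbtc("series file not found: '", f, "'")
    df <- utils::read.delim(f, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1, drop = FALSE])
    rownames(m) <- df[[1L]]
    m
  })
  names(series) <- subjects$id
  structure(list(subjects = subjects, series = series, profiles = list(),
                 manifest = default_loop_manifest(), truth = NULL),
            class = "cbtc_cohort")
}

#' Write a cohort's series to a directory of per-subject TSVs
#'
#' The on-disk format matches what load mode reads back.
#'
#' @param cohort A `cbtc_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_series_dir <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(cohort$series)) {
    m <- cohort$series[[id]]
    df <- data.frame(region = rownames(m), m, check.names = FALSE)
    colnames(df) <- c("region", sprintf("t%03d", seq_len(ncol(m))))
    utils::write.table(df, file.path(dir, paste0(id, ".tsv")), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(dir)
}
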