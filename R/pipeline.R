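# End-to-end orchestration: simulate -> fit -> solve -> features -> stats.

#' Pipeline configuration
#'
#' Collects every knob of the five pipeline stages with defaults that
#' match the package's study conditions: the default acquisition protocol,
#' the brain-tissue physical parameters, 1 mm solver spacing with a 20 mm
#' normal-tissue margin, per-slice-mean feature reduction, and two-sided
#' Wilcoxon statistics at alpha 0.05. The configuration round-trips
#' through YAML ([write_pipeline_config()] / [read_pipeline_config()]).
#'
#' @param out_dir output directory for volumes, tables and the manifest.
#' @param cohort a [cohort_spec()] describing the synthetic cohort.
#' @param protocol a [acquisition_protocol()].
#' @param props a [tissue_properties()] parameter set.
#' @param pk_mode `"fit"` (convert signal and fit the extended Tofts
#'   model) or `"truth"` (use the generator's ground-truth K-trans maps;
#'   useful when benchmarking the fluid stages in isolation).
#' @param t10,hematocrit signal conversion and AIF plasma correction.
#' @param spacing,margin,tolerance solver grid spacing (mm), domain
#'   margin (mm), relative residual target.
#' @param source_normal_tissue source the normal-tissue compartment too.
#' @param feature_mode `"per_slice_mean"` or `"whole_voi"`.
#' @param min_slice_voxels slice inclusion threshold for features.
#' @param alpha significance level for the group comparison.
#' @param adjust Benjamini-Hochberg flag for the group comparison.
#' @param seed global seed (drives the cohort generator).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("dceflow_run_"),
                            cohort = cohort_spec(),
                            protocol = acquisition_protocol(),
                            props = tissue_properties(),
                            pk_mode = c("fit", "truth"),
                            t10 = NULL, hematocrit = 0.45,
                            spacing = 1, margin = 20, tolerance = 1e-10,
                            source_normal_tissue = TRUE,
                            feature_mode = "per_slice_mean",
                            min_slice_voxels = 8,
                            alpha = 0.05, adjust = FALSE,
                            seed = 1L) {
  pk_mode <- match.arg(pk_mode)
  stopifnot(spacing > 0, margin >= 2 * spacing, tolerance > 0,
            hematocrit >= 0, hematocrit < 1, alpha > 0, alpha < 1)
  cohort$seed <- as.integer(seed)
  structure(list(out_dir = out_dir, cohort = cohort, protocol = protocol,
                 props = props, pk_mode = pk_mode, t10 = t10,
                 hematocrit = hematocrit, spacing = spacing, margin = margin,
                 tolerance = tolerance,
                 source_normal_tissue = source_normal_tissue,
                 feature_mode = feature_mode,
                 min_slice_voxels = min_slice_voxels,
                 alpha = alpha, adjust = adjust, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Serialise / restore a pipeline configuration
#'
#' YAML round trip of a [pipeline_config()]; object classes are restored
#' on read so `read_pipeline_config(write_pipeline_config(cfg, f))` is
#' lossless.
#'
#' @param config a `pipeline_config`.
#' @param path YAML file path.
#' @return `path` / the restored `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  stopifnot(inherits(config, "pipeline_config"))
  yaml::write_yaml(strip_classes(config), path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  restore <- function(x, cls) { class(x) <- cls; x }
  raw$protocol <- restore(raw$protocol, "dce_protocol")
  raw$props <- restore(raw$props, "tissue_properties")
  for (nm in c("pre_spec", "post_or_spec", "post_non_or_spec"))
    raw$cohort[[nm]] <- restore(numify(raw$cohort[[nm]]), "phantom_spec")
  raw$cohort <- restore(raw$cohort, "cohort_spec")
  restore(raw, "pipeline_config")
}

strip_classes <- function(x) {
  if (is.list(x)) { x <- lapply(x, strip_classes); attributes(x) <- list(names = names(x)) }
  x
}
numify <- function(sp) {
  for (nm in c("grid_shape", "voxel_size", "center", "radii"))
    sp[[nm]] <- as.numeric(unlist(sp[[nm]]))
  sp
}

#' Run the full synthetic pipeline
#'
#' Executes, per lesion and timepoint: phantom generation, (optionally)
#' signal-to-concentration conversion and voxelwise extended Tofts
#' fitting, domain construction and the steady-state IFP solve, the Darcy
#' velocity field, and the per-lesion histogram features; then the group
#' statistics over the cohort. A lesion whose processing fails is
#' recorded and skipped without aborting the run. Deterministic for a
#' fixed configuration: rerunning reproduces byte-identical feature
#' tables.
#'
#' Outputs written under `config$out_dir`: `features.csv` (one row per
#' lesion x timepoint), `delta_features.csv`, `cohort_features.csv` (wide
#' per-lesion table), `group_stats.csv`, and `manifest.json`.
#'
#' @param config a [pipeline_config()].
#' @param keep_volumes if `TRUE`, write per-lesion NIfTI maps (IFP in Pa,
#'   IFV magnitude in m/s) under `out_dir/volumes`.
#' @param verbose print per-stage progress.
#' @return A `run_manifest` list (also written as JSON): per-lesion
#'   records, stage status, file checksums, package version, config hash.
#' @export
run_pipeline <- function(config, keep_volumes = FALSE, verbose = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  t_start <- Sys.time()
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (verbose) message(sprintf(...))

  say("stage simulate: generating %d + %d lesions",
      config$cohort$n_or, config$cohort$n_non_or)
  coh <- generate_cohort(config$cohort, config$protocol,
                         maps_only = (config$pk_mode == "truth"))
  aif <- generate_aif(config$protocol)

  rows <- list(); lesion_status <- list()
  for (les in coh$lesions) {
    status <- "ok"
    for (tp in c("pre", "post")) {
      ph <- les[[tp]]
      res <- tryCatch({
        kt <- pipeline_ktrans(ph, config, aif, say)
        sol <- pipeline_solve(ph, kt, config)
        fr <- feature_row(sol$ifp, sol$ifv, sol$tumor,
                          mode = config$feature_mode,
                          min_slice_voxels = config$min_slice_voxels)
        if (keep_volumes) {
          vdir <- file.path(config$out_dir, "volumes")
          dir.create(vdir, showWarnings = FALSE)
          aff <- diag(c(rep(config$spacing, 3), 1))
          write_nifti_volume(sol$ifp, aff,
                             file.path(vdir, sprintf("%s_%s_ifp_pa.nii", les$id, tp)))
          write_nifti_volume(sol$ifv, aff,
                             file.path(vdir, sprintf("%s_%s_ifv_mps.nii", les$id, tp)))
        }
        cbind(data.frame(lesion_id = les$id, group = les$group,
                         timepoint = tp, stringsAsFactors = FALSE),
              fr, data.frame(solver_residual = sol$residual,
                             n_failed_fits = kt$n_failed))
      }, error = function(e) {
        warning(sprintf("lesion %s %s failed: %s", les$id, tp,
                        conditionMessage(e)))
        NULL
      })
      if (is.null(res)) status <- paste0("failed_", tp) else
        rows[[paste(les$id, tp)]] <- res
    }
    lesion_status[[les$id]] <- status
  }
  features <- do.call(rbind, rows)
  rownames(features) <- NULL
  f_feat <- file.path(config$out_dir, "features.csv")
  write.csv(num_round(features), f_feat, row.names = FALSE)

  say("stage features: computing deltas")
  wide <- build_wide_table(features)
  f_wide <- file.path(config$out_dir, "cohort_features.csv")
  write.csv(num_round(wide), f_wide, row.names = FALSE)
  deltas <- wide[, c("lesion_id", "group",
                     grep("^delta_", names(wide), value = TRUE))]
  f_delta <- file.path(config$out_dir, "delta_features.csv")
  write.csv(num_round(deltas), f_delta, row.names = FALSE)

  say("stage stats: group comparison")
  gstats <- group_comparison(wide, alpha = config$alpha,
                             adjust = config$adjust)
  f_stats <- file.path(config$out_dir, "group_stats.csv")
  write.csv(num_round(gstats), f_stats, row.names = FALSE)

  files <- c(features = f_feat, cohort_features = f_wide,
             delta_features = f_delta, group_stats = f_stats)
  manifest <- list(
    package_version = as.character(utils::packageVersion("dceflow")),
    config_hash = config_hash(config),
    seed = config$seed,
    n_lesions = nrow(coh$manifest),
    groups = as.list(table(coh$manifest$group)),
    lesion_status = lesion_status,
    files = as.list(files),
    checksums = as.list(tools::md5sum(unname(files))),
    n_significant = sum(gstats$significant),
    significant_rows = paste(gstats$set[gstats$significant],
                             gstats$feature[gstats$significant]),
    max_solver_residual = max(features$solver_residual),
    total_failed_fits = sum(features$n_failed_fits),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")))
  class(manifest) <- "run_manifest"
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# K-trans map for one phantom: ground truth or voxelwise ETM fit
pipeline_ktrans <- function(ph, config, aif, say) {
  if (config$pk_mode == "truth") {
    return(list(ktrans = ph$truth$ktrans, n_failed = 0L))
  }
  t10 <- if (is.null(config$t10)) ph$spec$T10 else config$t10
  conc <- signal_to_concentration(ph$signal, config$protocol, T10 = t10)
  maps <- suppressMessages(fit_etm_volume(conc, aif, ph$mask))
  kt <- maps$ktrans
  kt[!maps$fit_success] <- 0 # failed voxels fall back to background
  kt[is.na(kt)] <- 0
  list(ktrans = kt, n_failed = maps$n_failed)
}

# domain + IFP/IFV solve for one phantom's K-trans map
pipeline_solve <- function(ph, kt, config) {
  vox <- ph$spec$voxel_size
  dom <- build_domain(ph$mask, vox, target_spacing = config$spacing,
                      margin = config$margin)
  dom <- make_ktrans_ratio(kt$ktrans, vox, dom)
  sys <- assemble_system(dom, config$props,
                         source_normal_tissue = config$source_normal_tissue)
  fld <- solve_ifp(sys, tolerance = config$tolerance)
  ifv <- compute_ifv(fld, dom, config$props)
  list(ifp = fld$p, ifv = ifv$magnitude, tumor = dom$tissue == 1L,
       residual = fld$residual)
}

build_wide_table <- function(features) {
  ids <- unique(features$lesion_id)
  fn <- feature_names()
  out <- lapply(ids, function(id) {
    pre <- features[features$lesion_id == id & features$timepoint == "pre", ]
    post <- features[features$lesion_id == id & features$timepoint == "post", ]
    if (nrow(pre) != 1 || nrow(post) != 1) return(NULL)
    row <- data.frame(lesion_id = id, group = pre$group,
                      stringsAsFactors = FALSE)
    for (f in fn) {
      row[[paste0("pre_", f)]] <- pre[[f]]
      row[[paste0("post_", f)]] <- post[[f]]
      row[[paste0("delta_", f)]] <- post[[f]] - pre[[f]]
    }
    row
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

# fixed-precision numeric formatting so reruns are byte-identical
num_round <- function(df) {
  for (nm in names(df)) if (is.numeric(df[[nm]]))
    df[[nm]] <- signif(df[[nm]], 12)
  df
}

config_hash <- function(config) {
  f <- tempfile(fileext = ".yaml")
  on.exit(unlink(f))
  write_pipeline_config(config, f)
  unname(tools::md5sum(f))
}

#' Human-readable summary of a pipeline run
#'
#' Regenerates the run report from the manifest alone (no volumes are
#' read), so the same manifest always yields the same text.
#'
#' @param manifest a `run_manifest` from [run_pipeline()], or the path of
#'   a `manifest.json`.
#' @return Character vector of report lines, invisibly; printed.
#' @export
summarize_run <- function(manifest) {
  if (is.character(manifest)) manifest <- jsonlite::read_json(manifest)
  if (is.null(manifest$n_lesions) || manifest$n_lesions == 0)
    stop("empty manifest: nothing to report")
  g <- manifest$groups
  lines <- c(
    sprintf("dceflow run (package %s, seed %s)", manifest$package_version,
            manifest$seed),
    sprintf("%d lesions (%s)", manifest$n_lesions,
            paste(names(g), unlist(g), sep = "=", collapse = ", ")),
    sprintf("failed lesions: %d",
            sum(unlist(manifest$lesion_status) != "ok")),
    sprintf("total failed voxel fits: %s", manifest$total_failed_fits),
    sprintf("max solver residual: %.2e",
            as.numeric(manifest$max_solver_residual)),
    sprintf("significant feature rows (of 24): %s",
            manifest$n_significant),
    if (length(manifest$significant_rows))
      paste("  -", unlist(manifest$significant_rows)))
  cat(lines, sep = "\n")
  invisible(lines)
}
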