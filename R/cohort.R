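# Paired pre/post synthetic cohorts with a controllable response effect.

#' Cohort specification
#'
#' Describes a paired pre/post-treatment cohort of synthetic lesions in
#' two response groups (OR = objective response, non-OR = stable or
#' progressive disease). All lesions share the `pre_spec` template at the
#' pre-treatment timepoint (with per-lesion seeds and mild size
#' variation); post-treatment lesions follow `post_or_spec` or
#' `post_non_or_spec`. The default group sizes, 31 OR and 22 non-OR
#' lesions, match the cohort the statistics stage is meant to mimic.
#'
#' The default designed effect encodes the treatment-response rationale
#' that responding lesions develop a poorly-perfused (necrotic) core and a
#' smoother perfusion field: `post_or_spec` lowers the K-trans spatial SD
#' (x 0.3) and multiplies a concentric core (60% of the radii) by 0.15,
#' which through the fluid model raises interstitial fluid velocity and
#' flattens the interstitial-pressure histogram (lower kurtosis).
#' Non-responding lesions stay at the pre-treatment template. Magnitudes
#' are configuration, not constants.
#'
#' @param n_or,n_non_or lesions per group (>= 1).
#' @param pre_spec [phantom_spec()] template for all pre-treatment lesions.
#' @param post_or_spec,post_non_or_spec templates for the post-treatment
#'   timepoint per group.
#' @param radius_jitter multiplicative SD of per-lesion radius variation
#'   (lognormal; 0 disables).
#' @param seed integer master seed.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_or = 31, n_non_or = 22,
                        pre_spec = phantom_spec(grid_shape = c(14, 14, 7),
                                                voxel_size = c(2, 2, 4),
                                                radii = c(8, 8, 8),
                                                ktrans_spatial_sd = 0.12,
                                                ktrans_correlation_length = 2),
                        post_or_spec = or_response_spec(pre_spec),
                        post_non_or_spec = pre_spec,
                        radius_jitter = 0.1,
                        seed = 1L) {
  stopifnot(n_or >= 1, n_non_or >= 1,
            inherits(pre_spec, "phantom_spec"),
            inherits(post_or_spec, "phantom_spec"),
            inherits(post_non_or_spec, "phantom_spec"),
            radius_jitter >= 0)
  structure(list(n_or = as.integer(n_or), n_non_or = as.integer(n_non_or),
                 pre_spec = pre_spec, post_or_spec = post_or_spec,
                 post_non_or_spec = post_non_or_spec,
                 radius_jitter = radius_jitter, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Default responder post-treatment template
#'
#' Applies the designed objective-response effect to a pre-treatment
#' template. Radiosurgery response is modelled as (i) smoothing of the
#' vascular pattern — K-trans spatial SD scaled by `sd_factor` — which
#' flattens the interstitial-pressure histogram (lower kurtosis), (ii)
#' lesion shrinkage by `shrink_factor` (objective response is defined by
#' size reduction), which raises the rim fraction of tumor voxels and
#' with it the mean interstitial fluid velocity, and (iii) a mild
#' low-K-trans concentric core (`radius_frac`, `ktrans_factor`),
#' reflecting treatment-induced central devascularisation.
#'
#' @param pre_spec the pre-treatment [phantom_spec()].
#' @param sd_factor multiplier on `ktrans_spatial_sd`.
#' @param shrink_factor multiplier on the tumor radii.
#' @param core_radius_frac core radius as a fraction of the tumor radii.
#' @param core_ktrans_factor K-trans multiplier inside the core.
#' @return A modified `phantom_spec`.
#' @export
or_response_spec <- function(pre_spec, sd_factor = 0.15,
                             shrink_factor = 0.75,
                             core_radius_frac = 0.5,
                             core_ktrans_factor = 0.5) {
  s <- pre_spec
  s$ktrans_spatial_sd <- pre_spec$ktrans_spatial_sd * sd_factor
  s$radii <- pre_spec$radii * shrink_factor
  s$core <- list(radius_frac = core_radius_frac,
                 ktrans_factor = core_ktrans_factor)
  s
}

# deterministic per-lesion, per-timepoint seed below 2^31
lesion_seed <- function(master, index, timepoint) {
  tp <- switch(timepoint, pre = 0L, post = 1L, field = 2L)
  as.integer((as.numeric(master) * 7919 + index * 104729 + tp * 15485863) %%
               2147483629)
}

#' Generate a paired pre/post synthetic cohort
#'
#' For each lesion, draws a per-lesion radius factor (shared by pre and
#' post so the pair describes the same lesion), then generates the pre and
#' post phantoms from the group templates with deterministic per-lesion
#' seeds derived from `(seed, lesion index, timepoint)`. OR and non-OR
#' lesions differ only through their post-treatment templates.
#'
#' @param spec a [cohort_spec()].
#' @param protocol a [acquisition_protocol()].
#' @param maps_only passed to [generate_phantom()] (skip 4D signal).
#' @param out_dir optional directory: phantoms are written as NIfTI files
#'   and the manifest as `manifest.csv` there.
#' @return A `dce_cohort`: list with `lesions` (per lesion: `id`, `group`,
#'   `pre`, `post` phantoms) and `manifest` (data.frame: lesion_id, group,
#'   seed, pre/post paths when written).
#' @export
generate_cohort <- function(spec, protocol = acquisition_protocol(),
                            maps_only = FALSE, out_dir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("OR", spec$n_or), rep("non-OR", spec$n_non_or))
  n <- length(groups)
  lesions <- vector("list", n)
  rows <- vector("list", n)
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  for (i in seq_len(n)) {
    set.seed(lesion_seed(spec$seed, i, "pre") %% 1000003L + 7L)
    rf <- if (spec$radius_jitter > 0)
      exp(rnorm(1, sd = spec$radius_jitter)) else 1
    pre_s <- spec$pre_spec
    post_s <- if (groups[i] == "OR") spec$post_or_spec else spec$post_non_or_spec
    pre_s$radii <- pre_s$radii * rf
    post_s$radii <- post_s$radii * rf
    pre_s$seed <- lesion_seed(spec$seed, i, "pre")
    post_s$seed <- lesion_seed(spec$seed, i, "post")
    # the lesion's vascular pattern persists between imaging sessions
    pre_s$field_seed <- post_s$field_seed <- lesion_seed(spec$seed, i, "field")
    pre <- generate_phantom(pre_s, protocol, maps_only = maps_only)
    post <- generate_phantom(post_s, protocol, maps_only = maps_only)
    lesions[[i]] <- list(id = sprintf("lesion%03d", i), group = groups[i],
                         pre = pre, post = post)
    pre_path <- post_path <- NA_character_
    if (!is.null(out_dir)) {
      pre_path <- file.path(out_dir, sprintf("lesion%03d_pre", i))
      post_path <- file.path(out_dir, sprintf("lesion%03d_post", i))
      write_phantom(pre, pre_path)
      write_phantom(post, post_path)
    }
    rows[[i]] <- data.frame(lesion_id = lesions[[i]]$id, group = groups[i],
                            seed = pre_s$seed, pre_path = pre_path,
                            post_path = post_path,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  if (!is.null(out_dir))
    write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  structure(list(lesions = lesions, manifest = manifest, spec = spec),
            class = "dce_cohort")
}

# write one phantom's volumes as NIfTI beside a common prefix
write_phantom <- function(ph, prefix) {
  write_nifti_volume(ph$truth$ktrans, ph$affine, paste0(prefix, "_ktrans.nii"))
  write_nifti_volume(ph$mask * 1, ph$affine, paste0(prefix, "_mask.nii"))
  if (!is.null(ph$signal))
    write_nifti_volume(ph$signal, ph$affine, paste0(prefix, "_dce.nii"))
  invisible(prefix)
}

#' @export
print.dce_cohort <- function(x, ...) {
  tb <- table(x$manifest$group)
  cat(sprintf("Synthetic cohort: %d lesions (%s)\n", nrow(x$manifest),
              paste(names(tb), tb, sep = "=", collapse = ", ")))
  invisible(x)
}
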