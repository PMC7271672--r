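# Per-lesion histogram features of the IFP / IFV maps.

#' Histogram statistics of a sample
#'
#' Mean, population standard deviation (n denominator), Fisher-Pearson
#' skewness \eqn{g_1 = m_3/m_2^{3/2}} and Pearson (non-excess) kurtosis
#' \eqn{m_4/m_2^2}, so a normal sample has kurtosis near 3. For a constant
#' sample the shape statistics are undefined and returned as `NA`.
#'
#' @param values numeric vector, length >= 1, no NAs.
#' @param excess_kurtosis if `TRUE`, report kurtosis - 3.
#' @return Named list `mean`, `sd`, `skewness`, `kurtosis`.
#' @export
histogram_stats <- function(values, excess_kurtosis = FALSE) {
  values <- as.numeric(values)
  if (length(values) == 0) stop("empty sample")
  stopifnot(all(is.finite(values)))
  m <- mean(values)
  d <- values - m
  m2 <- mean(d^2)
  if (m2 <= 0) {
    return(list(mean = m, sd = 0, skewness = NA_real_,
                kurtosis = NA_real_))
  }
  kurt <- mean(d^4) / m2^2
  list(mean = m, sd = sqrt(m2), skewness = mean(d^3) / m2^1.5,
       kurtosis = if (excess_kurtosis) kurt - 3 else kurt)
}

#' Per-lesion histogram features of a parametric map
#'
#' Reduces a 3D map (IFP or IFV magnitude) over the tumor mask to four
#' histogram features. Default mode `per_slice_mean` computes the four
#' statistics on each axial slice holding at least `min_slice_voxels`
#' tumor voxels, then averages each statistic across slices (unweighted);
#' `whole_voi` pools all tumor voxels. If no slice reaches the voxel
#' minimum the function falls back to `whole_voi` with a warning.
#'
#' @param map 3D numeric array (the caller chooses units; the pipeline
#'   passes IFP in kPa and IFV in m/s).
#' @param mask logical/0-1 3D array, non-empty.
#' @param mode `"per_slice_mean"` (default) or `"whole_voi"`.
#' @param min_slice_voxels minimum tumor voxels for a slice to count.
#' @param slice_axis axis indexing slices (default 3, the axial axis of
#'   the resliced grid).
#' @param scale multiplier applied to map values before statistics (e.g.
#'   1e-3 for Pa to kPa).
#' @return A `lesion_features` list: `mean`, `sd`, `skewness`, `kurtosis`,
#'   plus `mode` and `n_voxels`.
#' @export
lesion_features <- function(map, mask, mode = c("per_slice_mean", "whole_voi"),
                            min_slice_voxels = 8, slice_axis = 3, scale = 1) {
  mode <- match.arg(mode)
  mask <- array(as.logical(mask), dim(map))
  if (!any(mask)) stop("empty mask")
  vals <- map * scale
  pooled <- function() histogram_stats(vals[mask])
  out <- NULL
  if (mode == "per_slice_mean") {
    ns <- dim(map)[slice_axis]
    counts <- apply(mask, slice_axis, sum)
    use <- which(counts >= min_slice_voxels)
    if (length(use) == 0) {
      warning("no slice reaches min_slice_voxels; falling back to whole_voi")
      mode <- "whole_voi"
      out <- pooled()
    } else {
      per <- lapply(use, function(s) {
        sl <- slice_index(vals, slice_axis, s)
        ms <- slice_index(mask, slice_axis, s)
        histogram_stats(sl[ms])
      })
      avg <- function(f) mean(vapply(per, function(p) p[[f]], 0.0))
      out <- list(mean = avg("mean"), sd = avg("sd"),
                  skewness = avg("skewness"), kurtosis = avg("kurtosis"))
    }
  } else {
    out <- pooled()
  }
  out$mode <- mode
  out$n_voxels <- sum(mask)
  class(out) <- "lesion_features"
  out
}

slice_index <- function(arr, axis, s) {
  if (axis == 1) arr[s, , ] else if (axis == 2) arr[, s, ] else arr[, , s]
}

#' Pre-to-post change in lesion features
#'
#' Element-wise `post - pre` for each of the four statistics of each map.
#' `NA` (undefined shape statistics) propagates.
#'
#' @param pre,post feature lists (or any named lists/vectors sharing the
#'   statistic names `mean`, `sd`, `skewness`, `kurtosis`).
#' @return Named list of deltas.
#' @export
delta_features <- function(pre, post) {
  keys <- c("mean", "sd", "skewness", "kurtosis")
  stopifnot(all(keys %in% names(pre)), all(keys %in% names(post)))
  out <- lapply(keys, function(k) as.numeric(post[[k]]) - as.numeric(pre[[k]]))
  names(out) <- keys
  out
}

# Eight-feature row (IFP in kPa + IFV in m/s) for the cohort table.
feature_row <- function(ifp_map_pa, ifv_mag, mask, ...) {
  fp <- lesion_features(ifp_map_pa, mask, scale = 1e-3, ...)
  fv <- lesion_features(ifv_mag, mask, ...)
  data.frame(ifp_mean_kpa = fp$mean, ifp_sd_kpa = fp$sd,
             ifp_skew = fp$skewness, ifp_kurt = fp$kurtosis,
             ifv_mean_mps = fv$mean, ifv_sd_mps = fv$sd,
             ifv_skew = fv$skewness, ifv_kurt = fv$kurtosis)
}
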