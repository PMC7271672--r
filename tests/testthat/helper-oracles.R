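# Independent oracles used by the test suite.  These deliberately avoid the
# package's own numerical paths: quadrature on refined grids, closed forms,
# full enumeration, and exhaustive scans.

# Extended-Tofts forward model by plain trapezoidal quadrature of the
# convolution on a `refine`-times finer grid, with the continuous AIF
# function evaluated on the fine grid (not interpolated).
etm_fine_grid_oracle <- function(ktrans, ve, vp, times, aif_fun, refine = 10) {
  tf <- sort(unique(c(seq(0, max(times), by = diff(times)[1] / refine), times)))
  cpf <- aif_fun(tf)
  kep_s <- if (ktrans > 0) (ktrans / ve) / 60 else 0
  conv <- vapply(times, function(tt) {
    sel <- tf <= tt + 1e-9
    if (sum(sel) < 2) return(0)
    ker <- exp(-kep_s * (tt - tf[sel])) * cpf[sel]
    sum(diff(tf[sel]) * (head(ker, -1) + tail(ker, -1)) / 2)
  }, 0.0)
  (ktrans / 60) * conv + vp * aif_fun(times)
}

# Exact two-sided Wilcoxon rank-sum p-value by full enumeration of all
# choose(nx+ny, nx) assignments of the pooled ranks (no ties assumed).
enum_wilcox_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  splits <- utils::combn(nx + ny, nx)
  u_all <- apply(splits, 2, function(ix) sum(r[ix]) - nx * (nx + 1) / 2)
  pu <- mean(u_all <= u_obs)
  po <- mean(u_all >= u_obs)
  list(U = u_obs, p = min(1, 2 * min(pu, po)))
}

# Exhaustive ROC scan: every midpoint threshold and both directions; AUC by
# trapezoidal integration of the empirical ROC curve (not the rank identity).
brute_roc <- function(scores, labels, positive) {
  pos <- labels == positive
  np <- sum(pos); nn <- sum(!pos)
  su <- sort(unique(scores))
  cuts <- c(-Inf, if (length(su) > 1) (head(su, -1) + tail(su, -1)) / 2, Inf)
  best <- list(j = -Inf, sens = -Inf)
  for (dir in c(">=", "<=")) {
    for (ct in cuts) {
      pred <- if (dir == ">=") scores >= ct else scores <= ct
      sens <- sum(pred & pos) / np
      spec <- sum(!pred & !pos) / nn
      j <- sens + spec - 1
      if (j > best$j + 1e-12 ||
          (abs(j - best$j) <= 1e-12 && sens > best$sens + 1e-12)) {
        best <- list(j = j, sens = sens, spec = spec, dir = dir, cutoff = ct)
      }
    }
  }
  # empirical ROC for the ">= predicts positive" direction
  ths <- c(Inf, rev(su), -Inf)
  tpr <- vapply(ths, function(t) sum(scores >= t & pos) / np, 0.0)
  fpr <- vapply(ths, function(t) sum(scores >= t & !pos) / nn, 0.0)
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(auc = auc, youden_j = best$j, sensitivity = best$sens,
       specificity = best$spec, direction = best$dir, cutoff = best$cutoff)
}

# Conservation check: total transvascular source of the solved field vs the
# net flux through the Dirichlet boundary, from the assembled stencil.
flux_balance <- function(system, p) {
  d <- system$dims
  h3 <- system$h^3
  interior <- system$interior
  src <- sum(((system$src - system$c_coef * p) * h3)[interior])
  # boundary flux: over faces between interior and Dirichlet voxels
  flux <- 0
  step <- c(1L, d[1], d[1] * d[2])
  tarr <- list(system$tx, system$ty, system$tz)
  idx_ar <- arrayInd(seq_len(prod(d)), d)
  for (axis in 1:3) {
    keep <- idx_ar[, axis] < d[axis]
    v1 <- which(keep); v2 <- v1 + step[axis]
    bf <- which(interior[v1] != interior[v2])
    vin <- ifelse(interior[v1[bf]], v1[bf], v2[bf])
    vout <- ifelse(interior[v1[bf]], v2[bf], v1[bf])
    flux <- flux + sum(tarr[[axis]][v1[bf]] * (p[vin] - p[vout])) * h3
  }
  list(source = src, flux = flux,
       rel_diff = abs(src - flux) / max(abs(src), 1e-300))
}

# small analysis-ready cohort spec used by pipeline tests
tiny_cohort_spec <- function(n_or = 2, n_non_or = 2, seed = 7) {
  cohort_spec(n_or = n_or, n_non_or = n_non_or,
              pre_spec = phantom_spec(grid_shape = c(12, 12, 6),
                                      voxel_size = c(2, 2, 4),
                                      radii = c(7, 7, 7),
                                      ktrans_correlation_length = 2),
              seed = seed)
}

default_test_protocol <- function() acquisition_protocol()
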