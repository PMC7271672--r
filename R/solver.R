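# Finite-volume discretisation and solution of the steady-state
# interstitial continuity equation
#   -div(K_H grad p) + c p = c P_eff,   c = (Ktrans/<Ktrans>) L_p S/V,
# on the isotropic domain grid, Dirichlet boundary (p = boundary value).
# Rows are scaled per unit volume, so on a homogeneous interior row the
# off-diagonal entries are -K_H/h^2 and the diagonal sum(K_face)/h^2 + c.

#' Assemble the finite-volume system for the IFP equation
#'
#' Builds the 7-point stencil with harmonic-mean face conductivities
#' (flux continuity across the tumor/normal discontinuity), the reaction
#' coefficient `c = ratio * L_p * S/V`, and the source `c * P_eff`.
#' Dirichlet voxels (the domain's boundary set) are eliminated: their
#' known value is folded into the right-hand side and only interior
#' voxels are unknowns. The resulting operator is symmetric positive
#' definite.
#'
#' @param domain an `ifp_domain`; if it has no `ratio` field the ratio is
#'   taken as 1 everywhere.
#' @param props a [tissue_properties()] object.
#' @param source_normal_tissue if `FALSE`, the transvascular source term
#'   is disabled (c = 0) in normal tissue, leaving only the tumor sourced.
#' @return An `ifp_system`: stencil arrays (`diag`, face conductance
#'   arrays `tx`, `ty`, `tz` in units of 1/(Pa s) per volume scaling),
#'   `rhs`, `interior` mask, grid metadata.
#' @export
assemble_system <- function(domain, props = tissue_properties(),
                            source_normal_tissue = TRUE) {
  stopifnot(inherits(domain, "ifp_domain"),
            inherits(props, "tissue_properties"))
  d <- domain$dims
  h <- domain$spacing * 1e-3 # m
  tum <- domain$tissue == 1L
  K <- array(props$normal$K_H, d); K[tum] <- props$tumor$K_H
  cc <- array(if (source_normal_tissue)
    props$normal$L_p * props$normal$S_over_V else 0, d)
  cc[tum] <- props$tumor$L_p * props$tumor$S_over_V
  Peff <- array(props$normal$P_eff, d); Peff[tum] <- props$tumor$P_eff
  ratio <- if (is.null(domain$ratio)) 1 else domain$ratio
  cc <- cc * ratio

  harm <- function(a, b) 2 * a * b / (a + b)
  tx <- array(0, d); ty <- array(0, d); tz <- array(0, d)
  n1 <- d[1]; n2 <- d[2]; n3 <- d[3]
  tx[-n1, , ] <- harm(K[-n1, , ], K[-1, , ]) / h^2
  ty[, -n2, ] <- harm(K[, -n2, ], K[, -1, ]) / h^2
  tz[, , -n3] <- harm(K[, , -n3], K[, , -1]) / h^2

  interior <- !domain$boundary
  src <- cc * Peff
  if (!is.null(domain$geometry) && domain$geometry$type == "sphere") {
    corr <- sphere_corrections(domain, props, K, ratio,
                               source_normal_tissue, tx, ty, tz, cc, src, h)
    tx <- corr$tx; ty <- corr$ty; tz <- corr$tz
    cc <- corr$cc; src <- corr$src
  }
  rhs <- src
  # face sums for the diagonal (all six faces; array-edge voxels are
  # always Dirichlet so missing faces never reach the interior operator)
  dsum <- array(0, d)
  dsum[-n1, , ] <- dsum[-n1, , ] + tx[-n1, , ]
  dsum[-1, , ]  <- dsum[-1, , ]  + tx[-n1, , ]
  dsum[, -n2, ] <- dsum[, -n2, ] + ty[, -n2, ]
  dsum[, -1, ]  <- dsum[, -1, ]  + ty[, -n2, ]
  dsum[, , -n3] <- dsum[, , -n3] + tz[, , -n3]
  dsum[, , -1]  <- dsum[, , -1]  + tz[, , -n3]
  diagv <- dsum + cc
  # fold Dirichlet neighbours into the rhs
  bv <- domain$boundary_value
  if (bv != 0) {
    bmask <- domain$boundary * 1
    add <- array(0, d)
    add[-n1, , ] <- add[-n1, , ] + tx[-n1, , ] * bmask[-1, , ]
    add[-1, , ]  <- add[-1, , ]  + tx[-n1, , ] * bmask[-n1, , ]
    add[, -n2, ] <- add[, -n2, ] + ty[, -n2, ] * bmask[, -1, ]
    add[, -1, ]  <- add[, -1, ]  + ty[, -n2, ] * bmask[, -n2, ]
    add[, , -n3] <- add[, , -n3] + tz[, , -n3] * bmask[, , -1]
    add[, , -1]  <- add[, , -1]  + tz[, , -n3] * bmask[, , -n3]
    rhs <- rhs + add * bv
  }
  structure(list(dims = d, h = h, diag = diagv, tx = tx, ty = ty, tz = tz,
                 c_coef = cc, Peff = Peff, K = K, src = src, rhs = rhs,
                 interior = interior, boundary_value = bv,
                 domain = domain),
            class = "ifp_system")
}

# Embedded-geometry corrections for spherical benchmark domains, where the
# exact tumor radius and outer boundary radius are known:
#  * faces whose center-to-center segment crosses the tumor surface get the
#    distance-weighted harmonic conductivity 1/(theta/K1 + (1-theta)/K2);
#  * cells cut by the tumor surface get volume-fraction-mixed reaction and
#    source coefficients (subcell sampling);
#  * links from interior cells to Dirichlet cells across the spherical
#    outer boundary are shortened to the exact boundary distance theta*h.
# Together these restore second-order accuracy against the radial
# reference, which a staircase representation of the sphere would spoil.
sphere_corrections <- function(domain, props, K, ratio, source_normal_tissue,
                               tx, ty, tz, cc, src, h) {
  d <- domain$dims
  geo <- domain$geometry
  a <- geo$tumor_radius
  s <- domain$spacing
  ctr <- geo$center_vox
  ax <- lapply(1:3, function(q) (seq_len(d[q]) - ctr[q]) * s)
  px <- array(ax[[1]], d)
  py <- aperm(array(ax[[2]], d[c(2, 1, 3)]), c(2, 1, 3))
  pz <- aperm(array(ax[[3]], d[c(3, 2, 1)]), c(3, 2, 1))
  r2 <- px^2 + py^2 + pz^2
  ct <- props$tumor$L_p * props$tumor$S_over_V
  cn <- if (source_normal_tissue) props$normal$L_p * props$normal$S_over_V else 0
  Pt <- props$tumor$P_eff; Pn <- props$normal$P_eff
  Kt <- props$tumor$K_H; Kn <- props$normal$K_H

  # cell mixing: tumor volume fraction by subcell sampling in the cut shell
  shell <- which(abs(sqrt(r2) - a) < s * 0.87)
  if (length(shell)) {
    m <- 6L
    off <- ((seq_len(m) - 0.5) / m - 0.5) * s
    f <- numeric(length(shell))
    for (oz in off) for (oy in off) for (ox in off)
      f <- f + ((px[shell] + ox)^2 + (py[shell] + oy)^2 +
                  (pz[shell] + oz)^2 <= a^2)
    f <- f / m^3
    rat <- if (length(ratio) > 1) ratio[shell] else ratio
    cc[shell] <- (f * ct + (1 - f) * cn) * rat
    src[shell] <- (f * ct * Pt + (1 - f) * cn * Pn) * rat
  }

  # face corrections along each axis
  step <- c(1L, d[1], d[1] * d[2])
  tarr <- list(tx, ty, tz)
  pax <- list(px, py, pz)
  interior <- !domain$boundary
  n <- prod(d)
  idx_ar <- arrayInd(seq_len(n), d)
  tum <- domain$tissue == 1L
  for (axis in 1:3) {
    keep <- idx_ar[, axis] < d[axis]
    v1 <- which(keep); v2 <- v1 + step[axis]
    # crossing parameter along the segment for a sphere of radius rad:
    # |x + t*s*e|^2 = rad^2, x = center of v1; take the root inside (0,1)
    cross_theta <- function(rad, vv) {
      xa <- pax[[axis]][vv]
      sq <- sqrt(pmax(xa^2 + rad^2 - r2[vv], 0))
      t1 <- (-xa - sq) / s
      t2 <- (-xa + sq) / s
      tt <- ifelse(t1 > 0 & t1 < 1, t1, t2)
      pmin(pmax(tt, 0.05), 0.95)
    }
    ifc <- which(tum[v1] != tum[v2])
    if (length(ifc)) {
      vv <- v1[ifc]
      th <- cross_theta(a, vv)
      Keff <- 1 / (th / K[vv] + (1 - th) / K[v2[ifc]])
      tarr[[axis]][vv] <- Keff / h^2
    }
    if (is.finite(geo$outer_radius)) {
      R <- geo$outer_radius
      bfc <- which(interior[v1] != interior[v2])
      if (length(bfc)) {
        vin <- ifelse(interior[v1[bfc]], v1[bfc], v2[bfc])
        # distance fraction from the interior center to the sphere r = R
        xa <- pax[[axis]][vin]
        sgn <- ifelse(interior[v1[bfc]], 1, -1)
        disc <- (sgn * xa)^2 + R^2 - r2[vin]
        th <- pmax((-sgn * xa + sqrt(pmax(disc, 0))) / s, 0.05)
        th <- pmin(th, 1)
        tarr[[axis]][v1[bfc]] <- K[vin] / (th * h^2)
      }
    }
  }
  list(tx = tarr[[1]], ty = tarr[[2]], tz = tarr[[3]], cc = cc, src = src)
}

#' Sparse-matrix form of an assembled system
#'
#' Materialises the interior-voxel operator as a symmetric sparse matrix
#' and the corresponding right-hand side, mainly for direct solves and
#' for checking the iterative solver against dense linear algebra.
#'
#' @param system an `ifp_system`.
#' @return List with `A` (dgCMatrix over interior voxels), `b`, and
#'   `index` (linear voxel indices of the unknowns).
#' @export
as_sparse_system <- function(system) {
  d <- system$dims
  n <- prod(d)
  idx <- which(system$interior)
  map <- integer(n); map[idx] <- seq_along(idx)
  ii <- jj <- list(); vv <- list()
  entry <- function(off_lin, tarr, keep) {
    from <- idx[keep]
    to <- from + off_lin
    ok <- system$interior[to]
    list(i = map[from][ok], j = map[to][ok], x = -tarr[from][ok])
  }
  ar <- arrayInd(idx, d)
  ents <- list(
    entry(1L, system$tx, ar[, 1] < d[1]),
    entry(-1L, shift_arr(system$tx, 1), ar[, 1] > 1),
    entry(d[1], system$ty, ar[, 2] < d[2]),
    entry(-d[1], shift_arr(system$ty, 2), ar[, 2] > 1),
    entry(d[1] * d[2], system$tz, ar[, 3] < d[3]),
    entry(-d[1] * d[2], shift_arr(system$tz, 3), ar[, 3] > 1))
  i <- c(seq_along(idx), unlist(lapply(ents, `[[`, "i")))
  j <- c(seq_along(idx), unlist(lapply(ents, `[[`, "j")))
  x <- c(system$diag[idx], unlist(lapply(ents, `[[`, "x")))
  A <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(idx), length(idx)))
  list(A = A, b = system$rhs[idx], index = idx)
}

# face array shifted so entry at voxel v holds the conductance to v-1
shift_arr <- function(tarr, axis) {
  d <- dim(tarr)
  out <- array(0, d)
  if (axis == 1) out[-1, , ] <- tarr[-d[1], , ]
  if (axis == 2) out[, -1, ] <- tarr[, -d[2], ]
  if (axis == 3) out[, , -1] <- tarr[, , -d[3]]
  out
}

#' Solve the assembled IFP system
#'
#' Jacobi-preconditioned conjugate gradients on the 7-point stencil
#' (compiled kernel), or a direct sparse solve. `method = "auto"` uses CG,
#' which on these well-conditioned reaction-diffusion systems converges in
#' under a couple of hundred iterations at any size; the direct solver is
#' kept for cross-checks and degenerate systems. The returned pressure
#' satisfies the discrete maximum principle (boundary value <= p <=
#' max P_eff) up to the solver tolerance.
#'
#' @param system an `ifp_system` from [assemble_system()].
#' @param tolerance relative residual target (default 1e-10).
#' @param method `"auto"`, `"direct"`, or `"cg"`.
#' @param maxit CG iteration cap.
#' @return An `ifp_field`: `p` (Pa, full grid with boundary values
#'   filled), `residual` (relative), `iterations`, `method`.
#' @export
solve_ifp <- function(system, tolerance = 1e-10,
                      method = c("auto", "direct", "cg"), maxit = 20000L) {
  stopifnot(inherits(system, "ifp_system"))
  method <- match.arg(method)
  idx <- which(system$interior)
  if (method == "auto") method <- "cg"
  p <- array(system$boundary_value, system$dims)
  if (method == "direct") {
    sp <- as_sparse_system(system)
    x <- as.numeric(Matrix::solve(sp$A, sp$b))
    r <- as.numeric(sp$b - sp$A %*% x)
    res <- sqrt(sum(r^2)) / max(sqrt(sum(sp$b^2)), 1e-300)
    p[idx] <- x
    iters <- 1L
  } else {
    out <- pcg_stencil(system$dims, system$diag, system$tx, system$ty,
                       system$tz, system$rhs,
                       as.integer(system$interior), tolerance,
                       as.integer(maxit))
    if (out$residual > tolerance)
      stop(sprintf("CG did not converge: relative residual %.3e after %d iterations",
                   out$residual, out$iterations))
    p[idx] <- out$x[idx]
    res <- out$residual
    iters <- out$iterations
  }
  structure(list(p = p, residual = res, iterations = iters,
                 method = method, domain = system$domain),
            class = "ifp_field")
}

#' @export
print.ifp_field <- function(x, ...) {
  cat(sprintf("IFP field: %s, max %.1f Pa, residual %.2e (%s, %d it)\n",
              paste(dim(x$p), collapse = "x"), max(x$p), x$residual,
              x$method, x$iterations))
  invisible(x)
}

#' Interstitial fluid velocity from the pressure field
#'
#' Darcy's law `u = -K_H grad p` with the voxelwise hydraulic
#' conductivity. The gradient uses central differences in the interior
#' and one-sided differences at the array faces; the magnitude is the
#' Euclidean norm of the components.
#'
#' @param field an `ifp_field` from [solve_ifp()].
#' @param domain the `ifp_domain` (defaults to the one stored in `field`).
#' @param props a [tissue_properties()] object.
#' @return An `ifv_field`: arrays `ux`, `uy`, `uz`, `magnitude` (m/s).
#' @export
compute_ifv <- function(field, domain = field$domain,
                        props = tissue_properties()) {
  stopifnot(inherits(field, "ifp_field"), inherits(domain, "ifp_domain"))
  h <- domain$spacing * 1e-3
  K <- array(props$normal$K_H, domain$dims)
  K[domain$tissue == 1L] <- props$tumor$K_H
  g <- lapply(1:3, function(ax) grad_axis(field$p, ax, h))
  structure(list(ux = -K * g[[1]], uy = -K * g[[2]], uz = -K * g[[3]],
                 magnitude = K * sqrt(g[[1]]^2 + g[[2]]^2 + g[[3]]^2)),
            class = "ifv_field")
}

# central differences along one axis, one-sided at the array faces
grad_axis <- function(p, axis, h) {
  d <- dim(p)
  n <- d[axis]
  perm <- c(axis, setdiff(1:3, axis))
  m <- matrix(aperm(p, perm), nrow = n)
  out <- matrix(0, n, ncol(m))
  if (n >= 2) {
    out[1, ] <- (m[2, ] - m[1, ]) / h
    out[n, ] <- (m[n, ] - m[n - 1, ]) / h
    if (n > 2)
      out[2:(n - 1), ] <- (m[3:n, ] - m[1:(n - 2), ]) / (2 * h)
  }
  aperm(array(out, d[perm]), order(perm))
}

#' Two-region radial reference solution for a spherical tumor
#'
#' Closed-form solution of the spherically symmetric continuity equation
#' `-K p'' - (2K/r) p' + c (p - P_eff) = 0` for a homogeneous spherical
#' tumor (radius `a`) embedded in homogeneous normal tissue out to radius
#' `R` where `p = boundary_pressure`. In each region
#' `p = P_eff + (A sinh(r/l) + B cosh(r/l))/r` with decay length
#' `l = sqrt(K_H / (L_p S/V))`; coefficients follow from regularity at the
#' origin, continuity of pressure and of radial flux `K_H dp/dr` at the
#' interface, and the outer Dirichlet condition. Used as the independent
#' benchmark for the 3D finite-volume solver.
#'
#' @param r radii at which to evaluate, meters.
#' @param tumor_radius tumor radius `a`, meters.
#' @param outer_radius boundary radius `R`, meters.
#' @param props a [tissue_properties()] object.
#' @param boundary_pressure outer Dirichlet value, Pa.
#' @return Pressure (Pa) at `r`.
#' @export
radial_reference_ifp <- function(r, tumor_radius, outer_radius,
                                 props = tissue_properties(),
                                 boundary_pressure = 0) {
  a <- tumor_radius; R <- outer_radius
  stopifnot(a > 0, R > a)
  Kt <- props$tumor$K_H; ct <- props$tumor$L_p * props$tumor$S_over_V
  Pt <- props$tumor$P_eff
  Kn <- props$normal$K_H; cn <- props$normal$L_p * props$normal$S_over_V
  Pn <- props$normal$P_eff
  lt <- sqrt(Kt / ct); ln <- sqrt(Kn / cn)
  f  <- function(r) sinh(r / lt) / r
  df <- function(r) cosh(r / lt) / (lt * r) - sinh(r / lt) / r^2
  # normal region: scaled decaying exponentials (well conditioned for R >> ln)
  e1 <- function(r) exp(-(r - a) / ln) / r
  e2 <- function(r) exp((r - R) / ln) / r
  de1 <- function(r) -e1(r) / ln - e1(r) / r
  de2 <- function(r)  e2(r) / ln - e2(r) / r
  M <- rbind(c(f(a), -e1(a), -e2(a)),
             c(Kt * df(a), -Kn * de1(a), -Kn * de2(a)),
             c(0, e1(R), e2(R)))
  co <- solve(M, c(Pn - Pt, 0, boundary_pressure - Pn))
  p <- numeric(length(r))
  tum <- r <= a
  rr <- pmax(r, 1e-15)
  st <- ifelse(r[tum] < 1e-12 * lt, 1 / lt, sinh(rr[tum] / lt) / rr[tum])
  p[tum] <- Pt + co[1] * st
  p[!tum] <- Pn + co[2] * e1(rr[!tum]) + co[3] * e2(rr[!tum])
  p[r > R] <- boundary_pressure
  p
}
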