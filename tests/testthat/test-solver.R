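props <- tissue_properties()

# hand-built box domain: all-normal tissue, optional tumor block
box_domain <- function(dims, spacing = 1, tumor = NULL) {
  tissue <- array(0L, dims)
  if (!is.null(tumor)) tissue[tumor] <- 1L
  boundary <- array(FALSE, dims)
  boundary[c(1, dims[1]), , ] <- TRUE
  boundary[, c(1, dims[2]), ] <- TRUE
  boundary[, , c(1, dims[3])] <- TRUE
  structure(list(dims = as.integer(dims), spacing = spacing, tissue = tissue,
                 boundary = boundary, boundary_value = 0,
                 origin_mm = c(0, 0, 0), ratio = NULL),
            class = "ifp_domain")
}

test_that("interior stencil rows reduce to the standard Laplacian", {
  dom <- box_domain(c(5, 5, 5))
  sys <- assemble_system(dom, props)
  sp <- as_sparse_system(sys)
  A <- as.matrix(sp$A)
  h <- sys$h
  K <- props$normal$K_H
  # center unknown: 27 interior voxels, center is the 14th
  off <- A[14, -14]
  expect_equal(sort(unique(off[off != 0])), -K / h^2)
  expect_equal(sum(off != 0), 6)
  expect_equal(A[14, 14], 6 * K / h^2 + props$normal$L_p * props$normal$S_over_V)
})

test_that("single interior voxel solves the hand-derived closed form", {
  dom <- box_domain(c(3, 3, 3), spacing = 1,
                    tumor = array(TRUE, c(3, 3, 3)))
  sys <- assemble_system(dom, props)
  fld <- solve_ifp(sys, method = "direct")
  h <- sys$h
  cc <- props$tumor$L_p * props$tumor$S_over_V
  K <- props$tumor$K_H
  p_hand <- cc * props$tumor$P_eff / (cc + 6 * K / h^2)
  expect_equal(fld$p[2, 2, 2], p_hand, tolerance = 1e-12)
})

test_that("zero source gives the zero solution, zero ratio gives zero rhs", {
  dom <- box_domain(c(6, 6, 6))
  dom$ratio <- array(0, dom$dims)
  sys <- assemble_system(dom, props)
  expect_true(all(sys$rhs == 0))
  fld <- solve_ifp(sys)
  expect_true(all(fld$p == 0))
})

test_that("CG agrees with a dense direct solve on a 6^3 system", {
  set.seed(3)
  dom <- box_domain(c(6, 6, 6), tumor = {
    t <- array(FALSE, c(6, 6, 6)); t[3:4, 3:4, 3:4] <- TRUE; t
  })
  dom$ratio <- array(1, dom$dims)
  dom$ratio[dom$tissue == 1L] <- runif(sum(dom$tissue == 1L), 0.3, 2)
  dom$ratio[dom$tissue == 1L] <-
    dom$ratio[dom$tissue == 1L] / mean(dom$ratio[dom$tissue == 1L])
  sys <- assemble_system(dom, props)
  cg <- solve_ifp(sys, method = "cg", tolerance = 1e-12)
  sp <- as_sparse_system(sys)
  dense <- solve(as.matrix(sp$A), sp$b)
  idx <- which(sys$interior)
  rel <- sqrt(sum((cg$p[idx] - dense)^2) / sum(dense^2))
  expect_lt(rel, 1e-9)
})

test_that("maximum principle and source-flux conservation hold", {
  for (seed in 1:3) {
    set.seed(seed)
    dom <- spherical_domain(6, margin = 8, spacing = 2)
    dom$ratio <- array(1, dom$dims)
    tum <- dom$tissue == 1L
    dom$ratio[tum] <- runif(sum(tum), 0.2, 2.5)
    dom$ratio[tum] <- dom$ratio[tum] / mean(dom$ratio[tum])
    sys <- assemble_system(dom, props)
    fld <- solve_ifp(sys, tolerance = 1e-12)
    expect_gte(min(fld$p), 0)
    expect_lte(max(fld$p), props$tumor$P_eff * (1 + 1e-10))
    fb <- flux_balance(sys, fld$p)
    expect_lt(fb$rel_diff, 1e-8)
  }
})

test_that("solution scales linearly with the effective pressures", {
  dom <- spherical_domain(6, margin = 8, spacing = 2)
  sys1 <- assemble_system(dom, props)
  p1 <- solve_ifp(sys1)$p
  lam <- 2.5
  props2 <- tissue_properties(
    normal = modifyList(props$normal, list(P_eff = props$normal$P_eff * lam)),
    tumor = modifyList(props$tumor, list(P_eff = props$tumor$P_eff * lam)))
  p2 <- solve_ifp(assemble_system(dom, props2))$p
  expect_equal(p2, lam * p1, tolerance = 1e-8)
})

test_that("velocity field: zero for uniform pressure, exact for linear fields", {
  dom <- box_domain(c(6, 6, 6), spacing = 2)
  fld <- structure(list(p = array(123, dom$dims), domain = dom),
                   class = "ifp_field")
  v <- compute_ifv(fld, dom, props)
  expect_true(all(v$magnitude == 0))

  s <- 40 # Pa per voxel along x
  h <- dom$spacing * 1e-3
  px <- array(rep(s * (1:6), times = 36), dom$dims)
  fld2 <- structure(list(p = px, domain = dom), class = "ifp_field")
  v2 <- compute_ifv(fld2, dom, props)
  expect_equal(v2$ux, array(-props$normal$K_H * s / h, dom$dims))
  expect_true(all(abs(v2$uy) < 1e-20) && all(abs(v2$uz) < 1e-20))
  expect_equal(v2$magnitude, abs(v2$ux))
})

test_that("spherical phantom flow is outward and peaks at the rim", {
  dom <- spherical_domain(8, margin = 10, spacing = 1)
  sys <- assemble_system(dom, props)
  fld <- solve_ifp(sys)
  v <- compute_ifv(fld, dom, props)
  n <- dom$dims[1]; ctr <- (n + 1) / 2
  g <- (seq_len(n) - ctr) * dom$spacing
  px <- array(g, dom$dims)
  py <- aperm(array(g, dom$dims[c(2, 1, 3)]), c(2, 1, 3))
  pz <- aperm(array(g, dom$dims[c(3, 2, 1)]), c(3, 2, 1))
  r <- dom$radius_mm
  ur <- (v$ux * px + v$uy * py + v$uz * pz) / pmax(r, 1e-9)
  outside_core <- r > 2 & !dom$boundary
  expect_true(mean(ur[outside_core] >= -1e-16) > 0.99)
  # |u| largest in a shell at the tumor rim
  rim <- abs(r - 8) <= 1.5
  inner <- r <= 4
  expect_gt(mean(v$magnitude[rim]), 5 * mean(v$magnitude[inner]))
})

test_that("radial reference solution agrees with an ODE shooting solver", {
  skip_if_not_installed("deSolve")
  a <- 0.010; R <- 0.030
  Kt <- props$tumor$K_H; ct <- props$tumor$L_p * props$tumor$S_over_V
  Kn <- props$normal$K_H; cn <- props$normal$L_p * props$normal$S_over_V
  rhs <- function(r, y, parms) {
    K <- if (r <= a) Kt else Kn
    cc <- if (r <= a) ct else cn
    Pe <- if (r <= a) props$tumor$P_eff else props$normal$P_eff
    list(c(y[2] / (K * max(r, 1e-12)^2), cc * r^2 * (y[1] - Pe)))
  }
  shoot <- function(p0) {
    out <- deSolve::ode(c(p0, 0), seq(1e-8, R, length.out = 20001), rhs,
                        NULL, rtol = 1e-10, atol = 1e-8)
    utils::tail(out[, 2], 1)
  }
  lo <- 0; hi <- 2000
  for (i in 1:35) { m <- (lo + hi) / 2; if (shoot(m) > 0) hi <- m else lo <- m }
  expect_equal(radial_reference_ifp(0, a, R, props), (lo + hi) / 2,
               tolerance = 1e-5)
})

test_that("radial reference solution: asymptotes and boundary condition", {
  # large homogeneous tumor: center approaches the tumor effective pressure
  pc <- radial_reference_ifp(0, 0.05, 0.1, props)
  expect_lt(abs(pc - props$tumor$P_eff) / props$tumor$P_eff, 0.001)
  expect_equal(radial_reference_ifp(0.03, 0.01, 0.03, props), 0,
               tolerance = 1e-9)
})
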