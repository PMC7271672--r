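test_that("Wilcoxon rank-sum: extreme ordering and symmetry", {
  w <- wilcoxon_ranksum(c(1, 2), c(3, 4))
  expect_true(w$exact)
  expect_equal(w$p, 1 / 3) # 2 / choose(4, 2)
  expect_equal(w$U, 0)

  x <- c(5, 9, 13, 2)
  w2 <- wilcoxon_ranksum(x, x)
  expect_equal(w2$U, length(x)^2 / 2)
  expect_gt(w2$p, 0.9)
})

test_that("exact p-values equal full enumeration on random no-tie data", {
  set.seed(15)
  for (i in 1:10) {
    x <- rnorm(5); y <- rnorm(5, mean = runif(1, -2, 2))
    mine <- wilcoxon_ranksum(x, y)
    oracle <- enum_wilcox_p(x, y)
    expect_true(mine$exact)
    expect_equal(mine$U, oracle$U)
    expect_equal(mine$p, oracle$p, tolerance = 1e-12)
  }
})

test_that("p-values are invariant under strictly monotone transforms", {
  set.seed(16)
  x <- rexp(12); y <- rexp(9, rate = 0.5)
  p0 <- wilcoxon_ranksum(x, y)$p
  expect_equal(wilcoxon_ranksum(log(x), log(y))$p, p0)
  expect_equal(wilcoxon_ranksum(x^3, y^3)$p, p0)
  expect_equal(wilcoxon_ranksum(-1 / x, -1 / y)$p, p0)
})

test_that("ROC/Youden: perfect separation and null behaviour", {
  sc <- c(1, 2, 3, 10, 11, 12)
  lb <- c(rep("OR", 3), rep("non-OR", 3))
  r <- roc_youden(sc, lb)
  expect_equal(r$auc, 1)
  expect_equal(r$sensitivity, 1)
  expect_equal(r$specificity, 1)
  expect_equal(r$youden_j, 1)

  set.seed(17)
  sc2 <- rnorm(200)
  lb2 <- sample(c("OR", "non-OR"), 200, replace = TRUE)
  r2 <- roc_youden(sc2, lb2)
  expect_lt(abs(r2$auc - 0.5), 0.05)

  # direction symmetry of the Mann-Whitney AUC
  expect_equal(roc_youden(-sc2, lb2)$auc, 1 - r2$auc, tolerance = 1e-12)
  expect_error(roc_youden(sc, rep("OR", 6)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(44)
  scores <- c(rnorm(15, 1), rnorm(12))
  labels <- rep(c("non-OR", "OR"), c(15, 12))
  mine <- roc_youden(scores, labels)
  ref <- pROC::roc(labels == "non-OR", scores, direction = "<",
                   quiet = TRUE)
  expect_equal(mine$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("ROC/Youden equals the exhaustive threshold scan", {
  set.seed(18)
  for (i in 1:25) {
    n <- sample(8:30, 1)
    scores <- round(rnorm(n), sample(c(1, 2, 8), 1)) # allow ties
    labels <- sample(c("OR", "non-OR"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    mine <- roc_youden(scores, labels)
    oracle <- brute_roc(scores, labels, "non-OR")
    expect_equal(mine$auc, oracle$auc, tolerance = 1e-12)
    expect_equal(mine$youden_j, oracle$youden_j, tolerance = 1e-12)
    expect_equal(mine$sensitivity, oracle$sensitivity, tolerance = 1e-12)
    expect_equal(mine$specificity, oracle$specificity, tolerance = 1e-12)
  }
})

test_that("group comparison produces 24 deterministic rows with ROC on hits", {
  set.seed(19)
  n <- 20
  coh <- data.frame(lesion_id = sprintf("l%02d", 1:n),
                    group = rep(c("OR", "non-OR"), c(12, 8)))
  for (set in c("pre", "post", "delta"))
    for (f in c("ifp_mean_kpa", "ifp_sd_kpa", "ifp_skew", "ifp_kurt",
                "ifv_mean_mps", "ifv_sd_mps", "ifv_skew", "ifv_kurt"))
      coh[[paste(set, f, sep = "_")]] <- rnorm(n)
  # inject a strong designed post effect
  coh$post_ifv_mean_mps <- ifelse(coh$group == "OR",
                                  rnorm(n, 5), rnorm(n, 0))
  res <- group_comparison(coh)
  expect_equal(nrow(res), 24)
  hit <- res[res$set == "post" & res$feature == "ifv_mean_mps", ]
  expect_true(hit$significant)
  expect_gt(hit$mean_or, hit$mean_non_or)
  expect_false(is.na(hit$auc))
  expect_true(all(is.na(res$auc[!res$significant])))
  res2 <- group_comparison(coh)
  expect_identical(res, res2)

  bad <- coh[, !(names(coh) %in% "post_ifp_kurt")]
  expect_error(group_comparison(bad), "post_ifp_kurt")
})

test_that("identical groups yield near-unit p-values", {
  base <- data.frame(lesion_id = sprintf("l%02d", 1:10),
                     group = rep(c("OR", "non-OR"), 5))
  vals <- rep(c(1.2, 3.4, 2.2, 0.7, 1.9), each = 2)
  for (set in c("pre", "post", "delta"))
    for (f in c("ifp_mean_kpa", "ifp_sd_kpa", "ifp_skew", "ifp_kurt",
                "ifv_mean_mps", "ifv_sd_mps", "ifv_skew", "ifv_kurt"))
      base[[paste(set, f, sep = "_")]] <- vals
  res <- group_comparison(base)
  expect_true(all(res$p > 0.9))
  expect_false(any(res$significant))
})
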