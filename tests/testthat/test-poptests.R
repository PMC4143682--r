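test_that("chi-square mixture p-values: exact single weight and identity mixture", {
  expect_equal(pval_chisq_mixture(3.2, 1)$p,
               pchisq(3.2, 1, lower.tail = FALSE), tolerance = 1e-12)
  # lambda = {1, 1}: sum is chi^2_2
  p <- pval_chisq_mixture(5.99, c(1, 1))
  expect_equal(p$method, "davies")
  expect_equal(p$p, pchisq(5.99, 2, lower.tail = FALSE), tolerance = 1e-6)
  # scale invariance
  expect_equal(pval_chisq_mixture(10, c(2, 0.5))$p,
               pval_chisq_mixture(100, 10 * c(2, 0.5))$p, tolerance = 1e-7)
  # moment-matching fallback is available and sane
  pl <- pval_chisq_mixture(5.99, c(1, 1), method = "liu")
  expect_lt(abs(pl$p - pchisq(5.99, 2, lower.tail = FALSE)), 0.01)
})

test_that("single unit-weight marker reduces the kernel test to the chi^2_1 score test", {
  set.seed(21)
  g <- sim_unrelated(150, 0.3, seed = 21)
  y <- rnorm(150) + 0.3 * g$dosage[, 1]
  names(y) <- g$samples
  r <- skat_test(g, y, kernel = kernel_spec(weights = 1))
  # classical score test: Z = g'r / sqrt(s2 * g'P0g)
  gc <- g$dosage[, 1] - mean(g$dosage[, 1])
  rr <- y - mean(y)
  s2 <- sum(lm(y ~ 1)$residuals^2) / 149
  z <- sum(gc * y) / sqrt(s2 * sum(gc^2))
  expect_equal(r$p_value, 2 * pnorm(-abs(z)), tolerance = 1e-6)
})

test_that("kernel score test handles weights, covariates and missing dosages", {
  set.seed(22)
  g <- sim_unrelated(200, c(0.05, 0.1, 0.3, 0.4), seed = 22)
  covar <- cbind(age = rnorm(200, 50, 8))
  rownames(covar) <- g$samples
  y <- rnorm(200) + 0.02 * covar[, 1]
  names(y) <- g$samples
  r <- skat_test(g, y, covariates = covar)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_equal(r$n_markers_used, 4)
  # missing dosages are mean-imputed, not dropped
  d <- g$dosage; d[1:5, 2] <- NA
  g2 <- genotype_matrix(d, g$variants, g$samples)
  r2 <- skat_test(g2, y, covariates = covar)
  expect_equal(r2$n_markers_used, 4)
  # all-monomorphic region is skipped
  g0 <- make_geno(matrix(0, 50, 2, dimnames = list(paste0("s", 1:50), NULL)))
  r0 <- skat_test(g0, rnorm(50))
  expect_true(is.na(r0$p_value))
  expect_match(r0$note, "monomorphic")
})

test_that("IBS and gaussian kernels are symmetric PSD and give valid p-values", {
  set.seed(23)
  g <- sim_unrelated(80, c(0.2, 0.3, 0.4), seed = 23)
  y <- rnorm(80); names(y) <- g$samples
  for (kind in c("IBS", "gaussian")) {
    K <- famregion:::.kernel_matrix(g$dosage, kernel_spec(kind))
    expect_equal(K, t(K), tolerance = 1e-12)
    ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8 * max(ev))
    r <- skat_test(g, y, kernel = kernel_spec(kind))
    expect_true(r$p_value > 0 && r$p_value <= 1)
  }
})

test_that("kernel-test p-values are uniform under the null", {
  set.seed(24)
  pv <- replicate(300, {
    g <- sim_unrelated(100, c(0.05, 0.2, 0.4), seed = sample.int(1e6, 1))
    y <- rnorm(100); names(y) <- g$samples
    skat_test(g, y)$p_value
  })
  expect_gt(suppressWarnings(ks.test(pv, "punif"))$p.value, 0.01)
  rej <- mean(pv < 0.05)
  expect_gt(rej, 0.02); expect_lt(rej, 0.09)
})

test_that("region REML fit recovers null and non-null variance shares", {
  set.seed(25)
  # null: trait independent of genotypes -> small sigma2_g, valid p
  g <- sim_unrelated(300, runif(20, 0.1, 0.5), seed = 25)
  y <- rnorm(300); names(y) <- g$samples
  r <- gcta_region_test(g, y)
  expect_lt(r$sigma2_g, 0.15)
  expect_true(r$p_value > 0 && r$p_value <= 1)
  expect_gte(r$lrt, 0)
  expect_true(r$converged)

  # non-null: h2 = 0.4 region signal is detected and estimated roughly
  est <- replicate(15, {
    s <- sample.int(1e6, 1)
    gg <- sim_unrelated(400, runif(25, 0.1, 0.5), seed = s)
    G <- gg$dosage; p <- colMeans(G) / 2
    Z <- sweep(sweep(G, 2, 2 * p), 2, sqrt(2 * p * (1 - p)), "/")
    b <- rnorm(25, 0, sqrt(0.4 / 25))
    yy <- drop(Z %*% b) + rnorm(400, 0, sqrt(0.6))
    names(yy) <- gg$samples
    gcta_region_test(gg, yy)$sigma2_g
  })
  expect_equal(mean(est), 0.4, tolerance = 0.12)
})

test_that("REML likelihood-ratio p-values use the boundary mixture", {
  set.seed(26)
  g <- sim_unrelated(200, runif(10, 0.1, 0.5), seed = 26)
  y <- rnorm(200); names(y) <- g$samples
  r <- gcta_region_test(g, y)
  if (r$lrt <= 1e-10) {
    expect_equal(r$p_value, 1)
  } else {
    expect_equal(r$p_value, 0.5 * pchisq(r$lrt, 1, lower.tail = FALSE))
  }
  # under repetition, boundary estimates at 0 occur often and give p = 1
  ps <- replicate(40, {
    gg <- sim_unrelated(120, runif(8, 0.1, 0.5), seed = sample.int(1e6, 1))
    yy <- rnorm(120); names(yy) <- gg$samples
    gcta_region_test(gg, yy)$p_value
  })
  expect_gt(mean(ps == 1), 0.2)
  expect_lt(mean(ps < 0.05), 0.15)
})

test_that("genotype principal components separate subpopulations and fix signs", {
  set.seed(27)
  g <- sim_unrelated(120, runif(60, 0.15, 0.35), seed = 27, n_subpop = 2,
                     fst_shift = 0.25)
  pcs <- genotype_pcs(g, 2)
  sil <- cluster::silhouette(attr(g, "subpop"), dist(pcs[, 1, drop = FALSE]))
  expect_gt(mean(sil[, 3]), 0.5)
  # duplicated samples get identical coordinates
  d <- g$dosage; d[2, ] <- d[1, ]
  g2 <- genotype_matrix(d, g$variants, g$samples)
  pcs2 <- genotype_pcs(g2, 2)
  expect_equal(pcs2[1, ], pcs2[2, ], tolerance = 1e-8)
  # k = 0 gives an empty covariate block
  expect_equal(ncol(genotype_pcs(g, 0)), 0)
  # k beyond rank warns and truncates
  small <- make_geno(matrix(c(0, 1, 2, 0, 1, 2, 1, 1), 4, 2,
                            dimnames = list(paste0("s", 1:4), NULL)))
  expect_warning(p2 <- genotype_pcs(small, 4), "rank")
  expect_lte(ncol(p2), 2)
})

test_that("select_unrelated returns pairwise kinship-zero sets under both policies", {
  ped <- sim_pedigrees("trio", 20)
  f <- select_unrelated(ped, "founders_only")
  expect_length(f, 40)
  g <- select_unrelated(ped, "max_unrelated_greedy")
  expect_length(g, 40)

  ext <- sim_pedigrees("threegen", 1)
  sel <- select_unrelated(ext, "max_unrelated_greedy")
  phi <- kinship(ext)
  idx <- match(paste0(ext$persons$fid[1], ":", sel), ext$persons$pid)
  off <- phi[idx, idx]; diag(off) <- 0
  expect_true(all(off == 0))
  # maximality: no further person can be added
  for (i in seq_len(nrow(ext$persons))) {
    if (!(ext$persons$iid[i] %in% sel)) {
      expect_true(any(phi[i, idx] > 0))
    }
  }
  # exhaustive check on the 13-person pedigree: greedy attains the maximum size
  best <- 0
  n <- nrow(ext$persons)
  for (mask in 0:(2^n - 1)) {
    ix <- which(bitwAnd(mask, 2^(0:(n - 1))) > 0)
    if (length(ix) <= best) next
    off <- phi[ix, ix, drop = FALSE]; diag(off) <- 0
    if (all(off == 0)) best <- length(ix)
  }
  expect_equal(length(sel), best)
  empty <- pedigree_set(data.frame(fid = character(0), iid = character(0),
                                   father = character(0), mother = character(0),
                                   sex = character(0), stringsAsFactors = FALSE))
  expect_length(select_unrelated(empty, "founders_only"), 0)
  expect_length(select_unrelated(empty, "max_unrelated_greedy"), 0)
})

test_that("adaptive burden/kernel combination is deterministic and calibrated", {
  set.seed(28)
  g <- sim_unrelated(120, c(0.05, 0.1, 0.3), seed = 28)
  y <- rnorm(120); names(y) <- g$samples
  r1 <- skat_o_test(g, y, n_perm = 200, seed = 9)
  r2 <- skat_o_test(g, y, n_perm = 200, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_true(r1$p_value > 0 && r1$p_value <= 1)
  expect_length(r1$p_per_rho, 5)
  expect_error(skat_o_test(g, y, n_perm = 200), "seed")
  # null rejection rate at 0.05 stays near nominal
  pv <- replicate(120, {
    gg <- sim_unrelated(80, c(0.1, 0.3), seed = sample.int(1e6, 1))
    yy <- rnorm(80); names(yy) <- gg$samples
    skat_o_test(gg, yy, n_perm = 150, seed = sample.int(1e6, 1))$p_value
  })
  expect_gt(mean(pv < 0.05), 0.005)
  expect_lt(mean(pv < 0.05), 0.12)
})
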