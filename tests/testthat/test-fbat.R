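test_that("conditional distribution equals exhaustive transmission enumeration", {
  for (f in 0:2) for (m in 0:2) {
    got <- conditional_distribution(f, m)
    ref <- enumerate_offspring(f, m)
    expect_equal(unname(got$probs), unname(ref$probs), info = paste(f, m))
    expect_equal(got$mean, ref$mean)
    expect_equal(got$var, ref$var)
    expect_equal(got$informative, ref$var > 0)
  }
  # benchmark cases
  expect_equal(conditional_distribution(1, 1)[c("mean", "var")],
               list(mean = 1, var = 0.5))
  expect_equal(conditional_distribution(0, 1)[c("mean", "var")],
               list(mean = 0.5, var = 0.25))
  expect_false(conditional_distribution(0, 0)$informative)
  expect_false(conditional_distribution(NA, 2)$informative)
})

test_that("family scores reproduce the analytic single-trio example", {
  # parents het x het, child dosage 2, child trait 1: U = 1, V = 0.5
  sc <- het_trio_scores(2, 1)
  expect_equal(unname(sc$U_fam[1, 1]), 1)
  expect_equal(unname(sc$V_model), 0.5)
  r <- fbat_v(sc, "model")
  expect_equal(r$statistic, 1 / sqrt(0.5), tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pnorm(-sqrt(2)), tolerance = 1e-12)
  expect_equal(r$n_informative_families, 1)

  # trait sign equivariance
  sc2 <- het_trio_scores(2, -1)
  expect_equal(unname(sc2$U_fam[1, 1]), -1)
  expect_equal(fbat_v(sc2, "model")$p_value, r$p_value)

  # two sibs with opposite transmissions cancel
  ped <- pedigree_set(data.frame(
    fid = "f1", iid = c("dad", "mum", "k1", "k2"),
    father = c(NA, NA, "dad", "dad"), mother = c(NA, NA, "mum", "mum"),
    sex = c("male", "female", "unknown", "unknown"), stringsAsFactors = FALSE))
  dos <- rbind(dad = 1, mum = 1, k1 = 2, k2 = 0)
  tr <- make_trait(c("dad", "mum", "k1", "k2"), c(-1, -1, 1, 1))
  sc3 <- family_scores(decompose_nuclear(ped), make_geno(dos), tr)
  expect_equal(unname(sc3$U_fam[1, 1]), 0)
})

test_that("offspring handling: missing genotypes, Mendel violations, skipped parents", {
  ped <- pedigree_set(data.frame(
    fid = c("f1", "f1", "f1", "f2", "f2", "f2"),
    iid = c("d1", "m1", "k1", "d2", "m2", "k2"),
    father = c(NA, NA, "d1", NA, NA, "d2"),
    mother = c(NA, NA, "m1", NA, NA, "m2"),
    sex = rep(c("male", "female", "unknown"), 2), stringsAsFactors = FALSE))
  fams <- decompose_nuclear(ped)
  # f2's father ungenotyped at all markers -> family skipped
  dos <- rbind(d1 = c(1, 1), m1 = c(1, 0), k1 = c(2, NA),
               d2 = c(NA, NA), m2 = c(1, 1), k2 = c(1, 1))
  tr <- make_trait(rownames(dos), c(0, 0, 1, 0, 0, -1), fid = ped$persons$fid)
  sc <- suppressWarnings(family_scores(fams, make_geno(dos), tr))
  expect_equal(sc$n_families_skipped, 1)
  expect_equal(sc$n_informative, 1)
  # marker 2: k1 missing -> contributes nothing
  expect_equal(unname(sc$U_fam[1, ]), c(1 * (2 - 1), 0))

  # Mendelian violation: parents (0,0) child 1 excluded with warning
  dos2 <- rbind(d1 = c(0, 1), m1 = c(0, 1), k1 = c(1, 2),
                d2 = c(1, 1), m2 = c(1, 1), k2 = c(1, 1))
  expect_warning(sc2 <- family_scores(fams, make_geno(dos2), tr),
                 "Mendelian")
  expect_equal(unname(sc2$U_fam[1, 1]), 0)
})

test_that("empirical variance aggregates by pedigree before the outer product", {
  # two families with U = +1 each: same pedigree -> 4, distinct -> 2
  sc <- het_trio_scores(c(2, 2), c(1, 1))
  expect_equal(unname(empirical_variance(sc)), matrix(2))
  sc_same <- sc
  sc_same$ped <- c("p1", "p1")
  expect_error(empirical_variance(sc_same), "single aggregation unit")
  sc3 <- het_trio_scores(c(2, 2, 0), c(1, 1, 0.5))
  sc3$ped <- c("p1", "p1", "p2")
  U <- rowsum(sc3$U_fam, sc3$ped)
  expect_equal(unname(empirical_variance(sc3)), unname(crossprod(U)))
  expect_equal(unname(empirical_variance(sc3))[1, 1],
               (1 + 1)^2 + (0.5 * (0 - 1))^2)

  # all-zero scores give a zero matrix
  sc0 <- het_trio_scores(c(2, 0), c(0, 0))
  expect_equal(unname(empirical_variance(sc0)), matrix(0))
})

test_that("empirical variance approaches model variance on independent null trios", {
  set.seed(914)
  cfg <- sim_config(template = "trio", n_pedigrees = 800,
                    mafs = rep(0.3, 2), seed = 914)
  rep1 <- sim_replicate(cfg, seed = 914)
  tr <- residualize(rep1$pheno, "y", c("age", "sex"))
  sc <- family_scores(decompose_nuclear(rep1$ped), rep1$geno, tr)
  ve <- diag(empirical_variance(sc))
  vm <- sc$V_model
  expect_equal(unname(ve / vm), c(1, 1), tolerance = 0.15)
})

test_that("fbat_m reduces to Z^2 on one marker and drops rank for duplicated markers", {
  sc <- het_trio_scores(c(2, 0, 2, 2), c(1.2, -0.3, 0.5, 1))
  z <- fbat_v(sc, "model")$statistic
  m <- fbat_m(sc, "model")
  expect_equal(m$statistic, z^2, tolerance = 1e-12)
  expect_equal(m$df, 1)
  expect_equal(m$p_value, fbat_v(sc, "model")$p_value, tolerance = 1e-12)

  # duplicated marker column: empirical variance has rank 1, same p
  sc2 <- het_trio_scores(cbind(c(2, 0, 2, 2), c(2, 0, 2, 2)),
                         c(1.2, -0.3, 0.5, 1), n_markers = 2)
  m2 <- fbat_m(sc2, "empirical")
  m1 <- fbat_m(het_trio_scores(c(2, 0, 2, 2), c(1.2, -0.3, 0.5, 1)), "empirical")
  expect_equal(m2$df, 1)
  expect_equal(m2$p_value, m1$p_value, tolerance = 1e-10)
})

test_that("fbat_m matches an independent pseudoinverse computation on a toy instance", {
  set.seed(41)
  kids <- matrix(sample(0:2, 6, replace = TRUE), 3, 2)
  tr <- c(0.8, -1.1, 0.4)
  sc <- het_trio_scores(kids, tr, n_markers = 2)
  U <- colSums(sc$U_fam)
  V <- diag(sc$V_model)
  Q_ref <- drop(t(U) %*% MASS::ginv(V) %*% U)
  got <- fbat_m(sc, "model")
  expect_equal(got$statistic, Q_ref, tolerance = 1e-10)
  expect_equal(got$df, qr(V)$rank)
  expect_equal(got$p_value, pchisq(Q_ref, got$df, lower.tail = FALSE))
})

test_that("fbat_l with equal weights equals fbat_v; sign flips leave p unchanged", {
  set.seed(42)
  kids <- matrix(sample(0:2, 20, replace = TRUE), 10, 2)
  tr <- rnorm(10)
  sc <- het_trio_scores(kids, tr, n_markers = 2)
  for (vm in c("model", "empirical")) {
    lv <- fbat_l(sc, vm, weights = c(1, 1))
    vv <- fbat_v(sc, vm)
    expect_equal(lv$statistic, vv$statistic, tolerance = 1e-12)
    expect_equal(lv$p_value, vv$p_value, tolerance = 1e-12)
  }
  w <- suppressWarnings(fbat_l(sc, "model"))$weights
  flip <- fbat_l(sc, "model", weights = -w)
  orig <- fbat_l(sc, "model", weights = w)
  expect_equal(abs(flip$statistic), abs(orig$statistic), tolerance = 1e-12)
  expect_equal(flip$p_value, orig$p_value, tolerance = 1e-12)
  # all-zero weights fall back to the unweighted burden
  expect_warning(z0 <- fbat_l(sc, "model", weights = c(0, 0)), "unweighted burden")
  expect_equal(z0$statistic, fbat_v(sc, "model")$statistic, tolerance = 1e-12)
})

test_that("fbat_l weights come from between-family information (conditional means)", {
  # parental genotypes must vary across families for the between-family
  # covariance to carry information
  cfg <- sim_config(template = "trio", n_pedigrees = 200, mafs = c(0.4, 0.2),
                    causal = 1, beta = 0.6, seed = 43)
  rep1 <- sim_replicate(cfg, seed = 43)
  tr <- residualize(rep1$pheno, "y", c("age", "sex"))
  sc <- family_scores(decompose_nuclear(rep1$ped), rep1$geno, tr)
  w <- fbat_l(sc, "model")$weights
  expect_equal(w, as.vector(cov(sc$wdata$e, sc$wdata$trait)), tolerance = 1e-12)
  expect_gt(abs(w[1]), abs(w[2]))  # causal marker earns the larger weight

  # fewer than 10 estimation offspring: proportional shrinkage toward 0
  cfg5 <- sim_config(template = "trio", n_pedigrees = 5, mafs = c(0.4, 0.3),
                     seed = 44)
  rep5 <- sim_replicate(cfg5, seed = 44)
  tr5 <- residualize(rep5$pheno, "y", character(0))
  sc5 <- family_scores(decompose_nuclear(rep5$ped), rep5$geno, tr5)
  w5 <- fbat_l(sc5, "model")$weights
  expect_equal(w5, as.vector(cov(sc5$wdata$e, sc5$wdata$trait)) *
                 length(sc5$wdata$trait) / 10, tolerance = 1e-12)
})

test_that("fbat_lmm follows the add-one permutation rule and is deterministic", {
  set.seed(44)
  # strong concordant signal: observed Q should beat every permutation
  sc <- het_trio_scores(rep(2, 30), rep(1, 30))
  r <- fbat_lmm(sc, n_perm = 1000, seed = 7)
  expect_equal(r$p_value, 1 / 1001, tolerance = 1e-12)
  r2 <- fbat_lmm(sc, n_perm = 1000, seed = 7)
  expect_identical(r$p_value, r2$p_value)
  expect_identical(r$statistic, sum(colSums(sc$U_fam)^2))
  expect_error(fbat_lmm(sc, n_perm = 1000), "seed")
  expect_error(fbat_lmm(sc, n_perm = 50, seed = 1), "n_perm")
})

test_that("region statistics are invariant to family and marker relabeling", {
  set.seed(45)
  kids <- matrix(sample(0:2, 30, replace = TRUE), 15, 2)
  tr <- rnorm(15)
  sc <- het_trio_scores(kids, tr, n_markers = 2)
  perm_f <- sample(15); perm_m <- 2:1
  sc_p <- het_trio_scores(kids[perm_f, perm_m], tr[perm_f], n_markers = 2)
  expect_equal(fbat_m(sc_p, "model")$statistic, fbat_m(sc, "model")$statistic,
               tolerance = 1e-10)
  expect_equal(fbat_v(sc_p, "model")$statistic, fbat_v(sc, "model")$statistic,
               tolerance = 1e-10)
  q1 <- fbat_lmm(sc, n_perm = 200, seed = 5)$statistic
  q2 <- fbat_lmm(sc_p, n_perm = 200, seed = 5)$statistic
  expect_equal(q1, q2, tolerance = 1e-10)
})

test_that("fbat_region wrapper dispatches and handles raw traits with a warning", {
  set.seed(46)
  cfg <- sim_config(template = "trio", n_pedigrees = 60, mafs = c(0.3, 0.2),
                    seed = 46)
  rep1 <- sim_replicate(cfg, seed = 46)
  tr <- residualize(rep1$pheno, "y", c("age", "sex"))
  r <- fbat_region(rep1$geno, rep1$ped, tr, method = "fbat_v",
                   variance_mode = "empirical")
  expect_s3_class(r, "region_test_result")
  expect_true(r$p_value > 0 && r$p_value <= 1)
  raw <- tr; raw$value <- raw$value + 5
  expect_warning(fbat_region(rep1$geno, rep1$ped, raw, method = "fbat_v"),
                 "centered")
})
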