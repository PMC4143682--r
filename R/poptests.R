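#' Tail probability of a weighted mixture of chi-square(1) variables
#'
#' P(sum_k lambda_k chi^2_1 > q) by numerical inversion of the
#' characteristic function (Imhof-type integral, the same quantity the
#' Davies algorithm computes), with a moment-matching (Liu-Tang-Zhang)
#' approximation as fallback when the inversion fails to converge.
#'
#' @param q Observed statistic.
#' @param lambda Positive eigenvalue weights.
#' @param method "davies" (inversion, default) or "liu" (moment matching).
#' @return List with `p` (clamped to (0, 1]) and `method` actually used.
#' @export
pval_chisq_mixture <- function(q, lambda, method = c("davies", "liu")) {
  method <- match.arg(method)
  lambda <- lambda[lambda > 0]
  if (length(lambda) == 0) return(list(p = 1, method = "degenerate"))
  if (length(lambda) == 1) {
    return(list(p = stats::pchisq(q / lambda, df = 1, lower.tail = FALSE),
                method = "exact"))
  }
  if (method == "davies") {
    p <- tryCatch(.imhof_p(q, lambda), error = function(e) NA_real_)
    if (!is.na(p) && p > -1e-6 && p < 1 + 1e-6) {
      return(list(p = min(max(p, 1e-14), 1), method = "davies"))
    }
    method <- "liu"  # fallback
  }
  list(p = min(max(.liu_p(q, lambda), 1e-14), 1), method = "liu")
}

.imhof_p <- function(q, lambda) {
  # scale invariance: normalize by the largest eigenvalue
  s <- max(lambda)
  lam <- lambda / s
  q <- q / s
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lam, u))) - 0.5 * q * u
    rho <- exp(0.25 * colSums(log1p(outer(lam^2, u^2))))
    out <- sin(theta) / (u * rho)
    out[u == 0] <- 0.5 * (sum(lam) - q)
    out
  }
  # truncation point: envelope 1 / (u * prod sqrt(1 + lam^2 u^2)) falls like
  # u^(-1 - k/2); integrating the oscillatory tail by parts bounds the
  # remainder by ~ 4 * envelope(U) / q, which we drive below 1e-7
  envelope <- function(u) exp(-sum(0.25 * log1p(lam^2 * u^2))) / u
  U <- 1
  while (4 * envelope(U) / (pi * max(q, 0.1)) > 1e-7 && U < 1e7) U <- U * 2
  # chunk size keeps the oscillation count per call manageable
  step <- max(min(U / 8, 3000 * pi / max(q, 1)), U / 4096)
  tot <- 0
  lo <- 0
  while (lo < U) {
    I <- stats::integrate(integrand, lo, min(lo + step, U), rel.tol = 1e-10,
                          abs.tol = 1e-13, subdivisions = 2000L,
                          stop.on.error = TRUE)
    tot <- tot + I$value
    lo <- lo + step
  }
  0.5 + tot / pi
}

.liu_p <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2); c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5
  s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    delta <- s1 * a^3 - a^2
    l <- a^2 - 2 * delta
  } else {
    a <- 1 / s1
    delta <- 0
    l <- 1 / s1^2
  }
  tstar <- (q - c1) / sqrt(2 * c2)
  stats::pchisq(tstar * sqrt(2) * a + l + delta, df = l, ncp = delta,
                lower.tail = FALSE)
}

#' Kernel specification for the weighted-kernel score test
#'
#' @param kind "linear_weighted" (default), "IBS" or "gaussian".
#' @param weight_params Beta density shape pair for MAF-based variant
#'   weights (default c(1, 25), the standard rare-variant upweighting).
#' @param bandwidth Gaussian kernel bandwidth; default = number of markers.
#' @param weights Optional explicit per-marker weights overriding the Beta
#'   density (recycled names must match marker order).
#' @return A `kernel_spec` list.
#' @export
kernel_spec <- function(kind = c("linear_weighted", "IBS", "gaussian"),
                        weight_params = c(1, 25), bandwidth = NULL,
                        weights = NULL) {
  kind <- match.arg(kind)
  stopifnot(length(weight_params) == 2, all(weight_params > 0))
  if (!is.null(weights)) stopifnot(all(is.finite(weights)), all(weights >= 0))
  structure(list(kind = kind, weight_params = weight_params,
                 bandwidth = bandwidth, weights = weights),
            class = "kernel_spec")
}

# mean-impute missing dosages per marker and drop monomorphic markers
.impute_poly <- function(G) {
  mu <- colMeans(G, na.rm = TRUE)
  idx <- which(is.na(G), arr.ind = TRUE)
  if (nrow(idx) > 0) G[idx] <- mu[idx[, 2]]
  keep <- apply(G, 2, stats::var) > 0
  list(G = G[, keep, drop = FALSE], kept = keep)
}

.align_trait <- function(geno, trait) {
  if (inherits(trait, "trait_vector") || is.data.frame(trait)) {
    y <- trait$value; names(y) <- trait$iid
  } else {
    y <- trait
    if (is.null(names(y))) {
      stopifnot(length(y) == length(geno$samples))
      names(y) <- geno$samples
    }
  }
  common <- intersect(geno$samples, names(y)[!is.na(y)])
  if (length(common) == 0) stop("no sample with both genotype and trait")
  list(samples = common, y = unname(y[common]))
}

#' Weighted-kernel score test for a region (unrelated individuals)
#'
#' Variance-component score test of the region's genotypes against a
#' quantitative trait: Q = r' K r / (2 s^2) with r the residuals of the
#' trait on the covariates (intercept always included), s^2 the residual
#' variance estimate, and K the region kernel. For the linear weighted
#' kernel K = G W^2 G' with w_m the Beta(a, b) density evaluated at the
#' marker's MAF. The null distribution is a weighted mixture of chi-square
#' variables with weights from the eigenvalues of (1/2) P0 K P0 / s^2;
#' p-values come from [pval_chisq_mixture()]. The caller is responsible for
#' supplying (approximately) unrelated individuals, e.g. via
#' [select_unrelated()].
#'
#' Missing dosages are mean-imputed per marker; monomorphic markers are
#' dropped (test skipped if none remain).
#'
#' @param geno A `genotype_matrix`.
#' @param trait A `trait_vector`, or named numeric vector of phenotypes.
#' @param covariates Optional numeric matrix (rows matched to sample ids by
#'   rowname, or in `geno$samples` order).
#' @param kernel A [kernel_spec()].
#' @param vids Optional marker subset.
#' @return A `region_test_result` with method "skat" (fields `n_subjects`,
#'   `p_method`).
#' @export
skat_test <- function(geno, trait, covariates = NULL,
                      kernel = kernel_spec(), vids = NULL) {
  al <- .align_trait(geno, trait)
  g <- subset_genotypes(geno, samples = al$samples, vids = vids)
  y <- al$y
  n <- length(y)
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) {
      covariates <- covariates[al$samples, , drop = FALSE]
    }
    X <- cbind(X, covariates)
  }
  ip <- .impute_poly(g$dosage)
  if (ncol(ip$G) == 0) {
    return(structure(list(method = "skat", statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, n_subjects = n, n_markers_used = 0,
                          note = "skipped: all markers monomorphic"),
                     class = "region_test_result"))
  }
  G <- ip$G
  M <- ncol(G)
  qrX <- qr(X)
  r <- qr.resid(qrX, y)
  s2 <- sum(r^2) / (n - qrX$rank)
  maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)

  if (kernel$kind == "linear_weighted") {
    w <- if (!is.null(kernel$weights)) kernel$weights[ip$kept] else
      stats::dbeta(maf, kernel$weight_params[1], kernel$weight_params[2])
    GW <- sweep(G, 2, w, `*`)
    Q <- sum(drop(crossprod(GW, r))^2) / (2 * s2)
    A <- qr.resid(qrX, GW)                       # P0 G W
    # null distribution: Q ~ sum lambda_k chi2_1 with lambda the eigenvalues
    # of P0 K P0 / 2 (the 1 / s2 in Q cancels the sigma^2 of y)
    lam <- eigen(crossprod(A), symmetric = TRUE, only.values = TRUE)$values
    lam <- lam[lam > 1e-10 * max(lam, 1e-300)] / 2
  } else {
    K <- .kernel_matrix(G, kernel)
    Q <- drop(t(r) %*% K %*% r) / (2 * s2)
    PK <- qr.resid(qrX, K)
    PKP <- qr.resid(qrX, t(PK))
    lam <- eigen((PKP + t(PKP)) / 2, symmetric = TRUE, only.values = TRUE)$values
    if (min(lam) < -1e-8 * max(abs(lam))) stop("kernel matrix is not PSD")
    lam <- lam[lam > 1e-10 * max(lam, 1e-300)] / 2
  }
  pv <- pval_chisq_mixture(Q, lam)
  structure(list(method = "skat", statistic = Q, df = NA_real_,
                 p_value = pv$p, p_method = pv$method,
                 kernel = kernel$kind, n_subjects = n, n_markers_used = M,
                 lambda = lam, note = if (pv$method == "liu")
                   "inversion fallback: moment-matching p-value" else NULL),
            class = "region_test_result")
}

.kernel_matrix <- function(G, kernel) {
  n <- nrow(G); M <- ncol(G)
  if (kernel$kind == "IBS") {
    K <- matrix(0, n, n)
    for (m in seq_len(M)) {
      K <- K + (2 - abs(outer(G[, m], G[, m], `-`)))
    }
    K / (2 * M)
  } else {  # gaussian
    bw <- if (is.null(kernel$bandwidth)) M else kernel$bandwidth
    sq <- rowSums(G^2)
    D2 <- pmax(outer(sq, sq, `+`) - 2 * tcrossprod(G), 0)
    exp(-D2 / bw)
  }
}

#' Combined burden/kernel region test calibrated by permutation
#'
#' Adaptive combination of the weighted-kernel score test and the weighted
#' burden test: for each mixing weight rho in `rho_grid` the statistic
#' Q_rho = (1 - rho) Q_kernel + rho Q_burden is referred to its own
#' permutation distribution (residuals permuted, covariate fit intact), and
#' the final p-value is the permutation p of the minimum per-rho p. This is
#' an optional sensitivity analysis; the default-weight kernel test
#' ([skat_test()]) is the primary population-design statistic.
#'
#' @inheritParams skat_test
#' @param rho_grid Mixing weights in [0, 1] (default 0, 0.25, 0.5, 0.75, 1).
#' @param n_perm Number of residual permutations (default 500).
#' @param seed Integer seed for the permutation stream (required).
#' @return A `region_test_result` with method "skat_o" (fields `rho_grid`,
#'   `p_per_rho`).
#' @export
skat_o_test <- function(geno, trait, covariates = NULL,
                        kernel = kernel_spec(), vids = NULL,
                        rho_grid = c(0, 0.25, 0.5, 0.75, 1),
                        n_perm = 500, seed) {
  if (missing(seed)) stop("skat_o_test requires an explicit 'seed'")
  stopifnot(all(rho_grid >= 0 & rho_grid <= 1), n_perm >= 100)
  al <- .align_trait(geno, trait)
  g <- subset_genotypes(geno, samples = al$samples, vids = vids)
  y <- al$y
  n <- length(y)
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) covariates <- covariates[al$samples, , drop = FALSE]
    X <- cbind(X, covariates)
  }
  ip <- .impute_poly(g$dosage)
  if (ncol(ip$G) == 0) stop("all markers monomorphic")
  G <- ip$G
  maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
  w <- if (!is.null(kernel$weights)) kernel$weights[ip$kept] else
    stats::dbeta(maf, kernel$weight_params[1], kernel$weight_params[2])
  GW <- sweep(G, 2, w, `*`)
  qrX <- qr(X)
  r <- qr.resid(qrX, y)
  q_rho <- function(res) {
    s <- drop(crossprod(GW, res))          # per-marker weighted scores
    c(kernel = sum(s^2), burden = sum(s)^2)
  }
  obs <- q_rho(r)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  perm <- matrix(0, n_perm, 2)
  for (b in seq_len(n_perm)) perm[b, ] <- q_rho(sample(r))
  Q_obs <- (1 - rho_grid) * obs["kernel"] + rho_grid * obs["burden"]
  Q_perm <- t(sapply(seq_len(n_perm), function(b)
    (1 - rho_grid) * perm[b, 1] + rho_grid * perm[b, 2]))
  # per-rho permutation p for the observation and for every permutation
  p_obs <- vapply(seq_along(rho_grid), function(j)
    (1 + sum(Q_perm[, j] >= Q_obs[j])) / (1 + n_perm), numeric(1))
  ranks <- apply(Q_perm, 2, function(col) rank(-col, ties.method = "max"))
  p_perm_min <- apply(ranks / n_perm, 1, min)
  t_obs <- min(p_obs)
  p <- (1 + sum(p_perm_min <= t_obs)) / (1 + n_perm)
  structure(list(method = "skat_o", statistic = t_obs, df = NA_real_,
                 p_value = p, rho_grid = rho_grid, p_per_rho = p_obs,
                 n_subjects = n, n_markers_used = ncol(G), n_perm = n_perm),
            class = "region_test_result")
}

#' Region-restricted variance-component REML likelihood-ratio test
#'
#' Fits y = X b + u + e with u ~ N(0, sigma2_g A), where A = Z Z' / M is the
#' genetic relationship matrix built from the region's standardized dosages
#' z = (g - 2p) / sqrt(2 p (1 - p)), by REML, and tests H0: sigma2_g = 0
#' with a likelihood-ratio statistic referred to the boundary mixture
#' 0.5 chi^2_0 + 0.5 chi^2_1. The REML profile likelihood is maximized in
#' h2 = sigma2_g / sigma2_total over [0, 1) by a grid search plus local
#' refinement (tolerance 1e-8 on the log-likelihood).
#'
#' @inheritParams skat_test
#' @return A `vc_fit_result`: sigma2_g, sigma2_e, h2, log-likelihoods, LRT,
#'   p-value, convergence flag.
#' @export
gcta_region_test <- function(geno, trait, covariates = NULL, vids = NULL) {
  al <- .align_trait(geno, trait)
  g <- subset_genotypes(geno, samples = al$samples, vids = vids)
  y <- al$y
  n <- length(y)
  X <- matrix(1, n, 1)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    if (!is.null(rownames(covariates))) covariates <- covariates[al$samples, , drop = FALSE]
    X <- cbind(X, covariates)
  }
  if (n <= ncol(X) + 2) stop("too few subjects for the variance-component fit")
  ip <- .impute_poly(g$dosage)
  if (ncol(ip$G) == 0) stop("all markers monomorphic: no region GRM")
  G <- ip$G
  M <- ncol(G)
  p_m <- colMeans(G) / 2
  Z <- sweep(sweep(G, 2, 2 * p_m), 2, sqrt(2 * p_m * (1 - p_m)), `/`)
  sv <- svd(Z, nu = min(n, M), nv = 0)
  d <- sv$d^2 / M                      # nonzero eigenvalues of A = ZZ'/M
  keep <- d > 1e-12 * max(d, 1e-300)
  U <- sv$u[, keep, drop = FALSE]
  d <- d[keep]

  fit <- .reml_profile(y, X, U, d)
  sigma2_total <- fit$sigma2
  res <- structure(list(method = "gcta", h2 = fit$h2,
                        sigma2_g = fit$h2 * sigma2_total,
                        sigma2_e = (1 - fit$h2) * sigma2_total,
                        loglik_null = fit$ll0, loglik_alt = fit$ll1,
                        lrt = fit$lrt, p_value = fit$p,
                        statistic = fit$lrt,
                        converged = fit$converged,
                        n_subjects = n, n_markers_used = M),
                   class = c("vc_fit_result", "region_test_result"))
  res
}

# REML profile likelihood in h2 using the low-rank eigenstructure of A.
.reml_profile <- function(y, X, U, d) {
  n <- length(y); p <- qr(X)$rank
  yu <- drop(crossprod(U, y)); Xu <- crossprod(U, X)
  yy <- sum(y^2); Xy <- drop(crossprod(X, y)); XX <- crossprod(X)
  r <- length(d)
  ll <- function(h) {
    w <- h * d + (1 - h)          # eigenvalues of V on the range of U
    c0 <- 1 - h                   # eigenvalue on the orthogonal complement
    logdet <- sum(log(w)) + (n - r) * log(c0)
    # V^{-1} x = U diag(1/w - 1/c0) U' x + x / c0
    a <- 1 / w - 1 / c0
    XVX <- XX / c0 + crossprod(Xu, a * Xu)
    XVy <- Xy / c0 + drop(crossprod(Xu, a * yu))
    yVy <- yy / c0 + sum(a * yu^2)
    ch <- tryCatch(chol(XVX), error = function(e) NULL)
    if (is.null(ch)) return(-Inf)
    beta_part <- drop(crossprod(backsolve(ch, XVy, transpose = TRUE)))
    yPy <- yVy - beta_part
    if (yPy <= 0) return(-Inf)
    -0.5 * (logdet + 2 * sum(log(diag(ch))) + (n - p) * log(yPy / (n - p)) + (n - p))
  }
  ll0 <- ll(0)
  grid <- seq(0, 0.98, by = 0.049)
  vals <- vapply(grid, ll, numeric(1))
  converged <- any(is.finite(vals))
  i <- which.max(vals)
  lo <- grid[max(1, i - 1)]; hi <- min(grid[min(length(grid), i + 1)], 0.9999)
  opt <- tryCatch(stats::optimize(ll, c(lo, hi), maximum = TRUE, tol = 1e-8),
                  error = function(e) NULL)
  if (is.null(opt)) {
    h2 <- grid[i]; ll1 <- vals[i]
  } else if (opt$objective >= vals[i]) {
    h2 <- opt$maximum; ll1 <- opt$objective
  } else {
    h2 <- grid[i]; ll1 <- vals[i]
  }
  if (ll0 >= ll1) { h2 <- 0; ll1 <- ll0 }
  lrt <- max(2 * (ll1 - ll0), 0)
  p <- if (lrt <= 1e-10) 1 else 0.5 * stats::pchisq(lrt, df = 1, lower.tail = FALSE)
  # residual variance estimate at the optimum
  w <- h2 * d + (1 - h2); c0 <- max(1 - h2, 1e-12)
  a <- 1 / w - 1 / c0
  yu <- drop(crossprod(U, y)); Xu <- crossprod(U, X)
  XVX <- crossprod(X) / c0 + crossprod(Xu, a * Xu)
  XVy <- drop(crossprod(X, y)) / c0 + drop(crossprod(Xu, a * yu))
  yVy <- sum(y^2) / c0 + sum(a * yu^2)
  yPy <- yVy - drop(crossprod(XVy, solve(XVX, XVy)))
  sigma2 <- yPy / (n - qr(X)$rank)
  list(h2 = h2, sigma2 = sigma2, ll0 = ll0, ll1 = ll1, lrt = lrt, p = p,
       converged = converged)
}

#' @method print vc_fit_result
#' @export
print.vc_fit_result <- function(x, ...) {
  cat(sprintf("gcta region VC test: sigma2_g = %.4g, sigma2_e = %.4g (h2 = %.3f), LRT = %.4g, p = %.4g (n = %d, %d markers)\n",
              x$sigma2_g, x$sigma2_e, x$h2, x$lrt, x$p_value,
              x$n_subjects, x$n_markers_used))
  invisible(x)
}

#' Genotype principal components
#'
#' Eigenvectors of the standardized-genotype covariance (missing dosages
#' mean-imputed, monomorphic markers dropped), for use as ancestry
#' covariates in [residualize()]. The sign of each component is fixed by
#' making its largest-magnitude variant loading positive.
#'
#' @param geno A `genotype_matrix`.
#' @param k Number of components (k = 0 returns a zero-column matrix).
#' @return n x k matrix of PC coordinates, rownames = sample ids. Fewer
#'   columns are returned with a warning when k exceeds the rank.
#' @export
genotype_pcs <- function(geno, k = 10) {
  stopifnot(k >= 0)
  if (k == 0) {
    out <- matrix(numeric(0), nrow = length(geno$samples), ncol = 0)
    rownames(out) <- geno$samples
    return(out)
  }
  ip <- .impute_poly(geno$dosage)
  S <- scale(ip$G)
  sv <- svd(S)
  rank <- sum(sv$d > 1e-8 * max(sv$d))
  if (k > rank) {
    warning("requested ", k, " PCs but rank is ", rank, "; returning ", rank)
    k <- rank
  }
  flip <- vapply(seq_len(k), function(j) {
    l <- sv$v[, j]
    sign(l[which.max(abs(l))])
  }, numeric(1))
  scores <- sweep(sv$u[, seq_len(k), drop = FALSE] %*%
                    diag(sv$d[seq_len(k)], k), 2, flip, `*`)
  rownames(scores) <- geno$samples
  colnames(scores) <- paste0("PC", seq_len(k))
  scores
}

#' Select a pairwise-unrelated subset of individuals
#'
#' @param ped A `pedigree_set`.
#' @param policy "founders_only" (all founders; founders are mutually
#'   unrelated by construction) or "max_unrelated_greedy" (greedy maximal
#'   set of pairwise kinship-zero individuals, founders preferred).
#' @return Character vector of iids with pairwise kinship 0.
#' @export
select_unrelated <- function(ped, policy = c("founders_only", "max_unrelated_greedy")) {
  policy <- match.arg(policy)
  p <- ped$persons
  if (nrow(p) == 0) return(character(0))
  if (policy == "founders_only") return(p$iid[p$founder])
  phi <- kinship(ped)
  related_count <- rowSums(phi > 0) - 1
  ord <- order(!p$founder, related_count)
  sel <- integer(0)
  for (i in ord) {
    if (all(phi[i, sel] == 0)) sel <- c(sel, i)
  }
  p$iid[sort(sel)]
}
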