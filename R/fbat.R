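#' Conditional offspring genotype distribution given parental genotypes
#'
#' Under additive minor-allele dosage coding, each parent with dosage d
#' transmits the counted allele with probability d/2, independently. The
#' offspring dosage distribution, mean and variance follow by Mendelian
#' transmission; this conditional distribution is the randomization basis of
#' every family-based test in the package.
#'
#' @param father_dosage,mother_dosage Parental dosages in \{0, 1, 2\}, or NA.
#' @return List with `probs` (P(dosage = 0, 1, 2)), `mean`, `var`, and
#'   `informative` (TRUE iff more than one offspring genotype is possible).
#'   A missing parent yields the noninformative sentinel (all-NA, FALSE).
#' @export
conditional_distribution <- function(father_dosage, mother_dosage) {
  if (is.na(father_dosage) || is.na(mother_dosage)) {
    return(list(probs = rep(NA_real_, 3), mean = NA_real_, var = NA_real_,
                informative = FALSE))
  }
  stopifnot(father_dosage %in% 0:2, mother_dosage %in% 0:2)
  pf <- father_dosage / 2
  pm <- mother_dosage / 2
  probs <- c(`0` = (1 - pf) * (1 - pm),
             `1` = pf * (1 - pm) + (1 - pf) * pm,
             `2` = pf * pm)
  v <- pf * (1 - pf) + pm * (1 - pm)
  list(probs = probs, mean = pf + pm, var = v, informative = v > 0)
}

#' Per-family score components for region-based FBAT statistics
#'
#' For each offspring j in nuclear family i with both parents genotyped, and
#' each polymorphic marker m, the score contribution is
#' T_j (x_jm - e_jm) where T is the adjusted trait residual, x the observed
#' dosage and e the Mendelian conditional mean given the parents. Family
#' score vectors U_i sum these over the family's offspring; the model-based
#' variance sums T_j^2 v_jm with v the conditional variance (cross-marker
#' covariance taken as zero: transmissions are modelled as independent
#' across markers; use the empirical variance when that is in doubt).
#'
#' Families with an ungenotyped parent are skipped at all markers (counted
#' in `n_families_skipped`); offspring with a missing or Mendelian-
#' inconsistent dosage at a marker contribute nothing at that marker;
#' families informative at no marker are omitted.
#'
#' @param families List of `nuclear_family` (from [decompose_nuclear()]).
#' @param geno A `genotype_matrix`.
#' @param trait A `trait_vector` of adjusted residuals (raw traits are
#'   centered with a warning).
#' @param vids Optional marker subset (default: all variants in `geno`).
#' @return An `fbat_scores` object: `U_fam` (informative families x markers),
#'   `V_model` (per-marker model-based variance), `ped` (pedigree id per
#'   family), offspring-level arrays used by the permutation and weighting
#'   machinery, and diagnostics.
#' @export
family_scores <- function(families, geno, trait, vids = NULL) {
  d <- geno$dosage
  if (!is.null(vids)) {
    idx <- match(vids, colnames(d))
    if (anyNA(idx)) stop("unknown variant ids: ", paste(vids[is.na(idx)], collapse = ", "))
    d <- d[, idx, drop = FALSE]
  }
  # drop markers monomorphic among the loaded persons
  poly <- apply(d, 2, function(g) {
    g <- g[!is.na(g)]
    length(g) > 0 && stats::var(g) > 0
  })
  d <- d[, poly, drop = FALSE]
  if (ncol(d) == 0) stop("no polymorphic marker in the region")
  markers <- colnames(d)

  tv <- trait$value
  if (abs(mean(tv)) > 1e-6 * max(stats::sd(tv), 1e-12)) {
    warning("trait does not appear centered; centering before scoring")
    tv <- tv - mean(tv)
  }
  names(tv) <- trait$iid

  have <- rownames(d)
  rows <- list(); fam_id <- character(0); ped_id <- character(0)
  n_skipped <- 0L
  for (k in seq_along(families)) {
    fam <- families[[k]]
    if (!(fam$father %in% have) || !(fam$mother %in% have)) {
      n_skipped <- n_skipped + 1L
      next
    }
    kids <- fam$offspring[fam$offspring %in% have & fam$offspring %in% names(tv)]
    kids <- kids[!is.na(tv[kids])]
    if (length(kids) == 0) next
    rows[[length(rows) + 1L]] <- list(father = fam$father, mother = fam$mother,
                                      kids = kids, fid = fam$fid,
                                      key = paste(fam$fid, fam$father, fam$mother, sep = "\r"))
  }
  if (length(rows) == 0) stop("no scorable family: all families skipped or unphenotyped")

  kids_all <- unlist(lapply(rows, `[[`, "kids"))
  fam_of_kid <- rep(seq_along(rows), vapply(rows, function(r) length(r$kids), 0L))
  fa <- vapply(rows, `[[`, "", "father")[fam_of_kid]
  mo <- vapply(rows, `[[`, "", "mother")[fam_of_kid]

  X <- d[kids_all, , drop = FALSE]
  PF <- d[fa, , drop = FALSE] / 2        # transmission probabilities
  PM <- d[mo, , drop = FALSE] / 2
  E <- PF + PM
  V <- PF * (1 - PF) + PM * (1 - PM)
  Tv <- tv[kids_all]

  # a marker with an ungenotyped parent is noninformative for that family
  parent_ok <- !is.na(E)
  # Mendelian violations: child dosage outside the reachable range
  lo <- (PF == 1) + (PM == 1)
  hi <- 2 - ((PF == 0) + (PM == 0))
  viol <- !is.na(X) & parent_ok & (X < lo | X > hi)
  viol[is.na(viol)] <- FALSE
  if (any(viol)) {
    warning(sum(viol), " Mendelian-inconsistent offspring genotype(s) excluded")
  }
  obs <- !is.na(X) & parent_ok & !viol
  E[!parent_ok] <- 0; V[!parent_ok] <- 0
  PF[!parent_ok] <- 0; PM[!parent_ok] <- 0
  informative_cell <- obs & V > 0

  C <- Tv * (X - E)
  C[!obs] <- 0
  fam_f <- factor(fam_of_kid, levels = seq_along(rows))
  # families whose parents are ungenotyped at every marker join the skip count
  fam_has_parents <- as.vector(rowSums(rowsum(parent_ok + 0, fam_f))) > 0
  n_skipped <- n_skipped + sum(!fam_has_parents)
  U_all <- rowsum(C, fam_f)
  keep_fam <- as.vector(rowSums(rowsum(informative_cell + 0, fam_f))) > 0
  if (!any(keep_fam)) stop("no informative family in the region")

  D <- (Tv^2) * V
  D[!obs] <- 0
  keep_kid <- keep_fam[fam_of_kid]

  structure(list(
    U_fam = U_all[keep_fam, , drop = FALSE],
    V_model = colSums(D[keep_kid, , drop = FALSE]),
    ped = vapply(rows, `[[`, "", "fid")[keep_fam],
    markers = markers,
    n_informative = sum(keep_fam),
    n_families_skipped = n_skipped,
    # offspring-level arrays (informative families only) for permutation
    off = list(trait = Tv[keep_kid], x = X[keep_kid, , drop = FALSE],
               e = E[keep_kid, , drop = FALSE], pf = PF[keep_kid, , drop = FALSE],
               pm = PM[keep_kid, , drop = FALSE], obs = obs[keep_kid, , drop = FALSE]),
    # weight-estimation data: ALL offspring with genotyped parents, including
    # those in families that are noninformative at every marker
    wdata = list(trait = Tv, e = E)
  ), class = "fbat_scores")
}

#' Empirical (robust) variance of the total family score
#'
#' Outer-product variance of the observed scores. With
#' `aggregate_by_pedigree = TRUE` (the "-e" estimator recommended for
#' extended pedigrees and heritable traits), family scores are first summed
#' within each pedigree and the outer products of the per-pedigree sums are
#' accumulated, so arbitrary dependence among nuclear families of one
#' pedigree -- and between transmissions and trait sharing under linkage --
#' is absorbed.
#'
#' @param scores An `fbat_scores` object.
#' @param aggregate_by_pedigree Sum family scores within pedigrees first
#'   (default TRUE).
#' @return Markers x markers empirical covariance matrix of the total score.
#' @export
empirical_variance <- function(scores, aggregate_by_pedigree = TRUE) {
  U <- scores$U_fam
  if (aggregate_by_pedigree) {
    U <- rowsum(U, factor(scores$ped))
  }
  if (nrow(U) < 2) stop("empirical variance undefined with a single aggregation unit")
  crossprod(U)
}

.region_result <- function(method, statistic, df, p, variance_mode, scores,
                           note = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p, variance_mode = variance_mode,
                 n_informative_families = scores$n_informative,
                 n_families_skipped = scores$n_families_skipped,
                 n_markers_used = length(scores$markers), note = note),
            class = "region_test_result")
}

#' @method print region_test_result
#' @export
print.region_test_result <- function(x, ...) {
  tag <- if (identical(x$variance_mode, "empirical")) " -e" else ""
  dftxt <- if (!is.null(x$df) && !is.na(x$df)) sprintf(", df = %g", x$df) else ""
  who <- if (!is.null(x$n_informative_families)) {
    sprintf("%d informative families", x$n_informative_families)
  } else {
    sprintf("%d subjects", x$n_subjects)
  }
  cat(sprintf("%s%s: statistic = %.4g%s, p = %.4g (%s, %d markers)\n",
              x$method, tag, x$statistic, dftxt, x$p_value, who,
              x$n_markers_used))
  if (!is.null(x$note)) cat("  note:", x$note, "\n")
  invisible(x)
}

.variance_matrix <- function(scores, variance_mode) {
  switch(variance_mode,
         model = diag(scores$V_model, nrow = length(scores$V_model)),
         empirical = empirical_variance(scores),
         stop("variance_mode must be 'model' or 'empirical'"))
}

#' FBAT burden (collapsing) region test
#'
#' Markers are collapsed by unweighted sum into a single burden score per
#' offspring before scoring (equivalently, per-marker family scores are
#' summed), giving Z = sum(U) / sqrt(V) with V the model-based or empirical
#' variance of the burden score and a two-sided normal p-value. Powerful
#' when the region's effects share a direction.
#'
#' @param scores An `fbat_scores` object.
#' @param variance_mode "model" or "empirical" (the "-e" estimator).
#' @return A `region_test_result`.
#' @export
fbat_v <- function(scores, variance_mode = c("model", "empirical")) {
  variance_mode <- match.arg(variance_mode)
  U <- sum(scores$U_fam)
  Vm <- .variance_matrix(scores, variance_mode)
  V <- sum(Vm)
  if (V <= 0) {
    return(.region_result("fbat_v", NA_real_, NA_real_, NA_real_, variance_mode,
                          scores, note = "undefined statistic: zero burden variance"))
  }
  z <- U / sqrt(V)
  .region_result("fbat_v", z, NA_real_, 2 * stats::pnorm(-abs(z)), variance_mode, scores)
}

# Moore-Penrose pseudoinverse with relative eigenvalue cutoff; also returns rank
.pinv_sym <- function(V, rtol = 1e-8) {
  eg <- eigen((V + t(V)) / 2, symmetric = TRUE)
  lmax <- max(eg$values, 0)
  keep <- eg$values > rtol * max(lmax, .Machine$double.eps)
  rank <- sum(keep)
  if (rank == 0) return(list(inv = NULL, rank = 0))
  inv <- eg$vectors[, keep, drop = FALSE] %*%
    (t(eg$vectors[, keep, drop = FALSE]) / eg$values[keep])
  list(inv = inv, rank = rank)
}

#' FBAT multimarker (multivariate) region test
#'
#' Quadratic form Q = U' V^- U of the summed per-marker family scores, with
#' V^- the Moore-Penrose pseudoinverse (relative eigenvalue cutoff 1e-8).
#' Degrees of freedom equal the rank of V, i.e. the number of linearly
#' independent markers; p from the upper chi-square tail.
#'
#' @inheritParams fbat_v
#' @return A `region_test_result`.
#' @export
fbat_m <- function(scores, variance_mode = c("model", "empirical")) {
  variance_mode <- match.arg(variance_mode)
  U <- colSums(scores$U_fam)
  V <- .variance_matrix(scores, variance_mode)
  pv <- .pinv_sym(V)
  if (pv$rank == 0) {
    return(.region_result("fbat_m", NA_real_, 0, NA_real_, variance_mode,
                          scores, note = "skipped: variance matrix has rank 0"))
  }
  Q <- drop(t(U) %*% pv$inv %*% U)
  .region_result("fbat_m", Q, pv$rank,
                 stats::pchisq(Q, df = pv$rank, lower.tail = FALSE),
                 variance_mode, scores)
}

#' FBAT linear-combination region test
#'
#' Tests the weighted sum of per-marker scores, Z = w'U / sqrt(w'Vw), with
#' per-marker weights estimated from between-family information only: the
#' sample covariance between the offspring trait residual and the Mendelian
#' conditional-mean genotype e (a function of parental genotypes alone).
#' Because e is fixed given the parents, the weights are independent of the
#' within-family transmissions that drive U under the null, so estimating
#' them from the same sample (noninformative families included) does not
#' bias the test. Weights from fewer than 10 estimation offspring are
#' shrunk proportionally toward zero; if every weight vanishes the test
#' falls back to the unweighted burden with a warning.
#'
#' @inheritParams fbat_v
#' @param weights Optional fixed per-marker weight vector overriding the
#'   estimated weights (equal weights reduce the test to [fbat_v()]).
#' @return A `region_test_result` (the fitted weights in `$weights`).
#' @export
fbat_l <- function(scores, variance_mode = c("model", "empirical"),
                   weights = NULL) {
  variance_mode <- match.arg(variance_mode)
  n_est <- length(scores$wdata$trait)
  if (is.null(weights)) {
    w <- as.vector(stats::cov(scores$wdata$e, scores$wdata$trait))
    w[is.na(w)] <- 0
    if (n_est < 10) w <- w * n_est / 10
  } else {
    stopifnot(length(weights) == ncol(scores$U_fam))
    w <- weights
  }
  fallback <- NULL
  if (max(abs(w)) < 1e-12) {
    warning("all linear-combination weights are zero; falling back to unweighted burden")
    w <- rep(1, ncol(scores$U_fam))
    fallback <- "all weights zero; unweighted burden used"
  }
  U <- colSums(scores$U_fam)
  V <- .variance_matrix(scores, variance_mode)
  denom <- drop(t(w) %*% V %*% w)
  if (denom <= 0) {
    return(.region_result("fbat_l", NA_real_, NA_real_, NA_real_, variance_mode,
                          scores, note = "undefined statistic: zero weighted variance"))
  }
  z <- drop(crossprod(w, U)) / sqrt(denom)
  res <- .region_result("fbat_l", z, NA_real_, 2 * stats::pnorm(-abs(z)),
                        variance_mode, scores, note = fallback)
  res$weights <- w
  res
}

#' FBAT variance-component region test with Mendelian permutation p-values
#'
#' Direction-agnostic statistic Q = sum over markers of (total score)^2, so
#' protective and deleterious effects within a region add rather than
#' cancel. The null distribution is generated by Mendelian re-draws: each
#' permutation resamples every offspring's genotype at every marker from
#' its conditional distribution given the parents (markers redrawn
#' independently per offspring), and Q is recomputed;
#' p = (1 + #\{Q* >= Q\}) / (1 + n_perm), ties counted conservatively.
#'
#' Re-drawing happens at the offspring level within nuclear families, so the
#' permutation null does not absorb dependence between the nuclear families
#' of one extended pedigree; the result carries a diagnostic note whenever a
#' pedigree contributes more than one scored family.
#'
#' @param scores An `fbat_scores` object.
#' @param n_perm Number of Mendelian permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation stream (required).
#' @return A `region_test_result` with `variance_mode = "permutation"`.
#' @export
fbat_lmm <- function(scores, n_perm = 1000, seed) {
  if (missing(seed)) stop("fbat_lmm requires an explicit 'seed'")
  stopifnot(n_perm >= 100)
  off <- scores$off
  Q_obs <- sum(colSums(scores$U_fam)^2)
  n_off <- length(off$trait)
  M <- ncol(off$x)
  Eo <- off$e; Eo[!off$obs] <- 0
  Tv <- off$trait
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  exceed <- 0L
  chunk <- max(1L, min(n_perm, floor(2e6 / max(1, n_off * M))))
  done <- 0L
  while (done < n_perm) {
    b <- min(chunk, n_perm - done)
    u1 <- array(stats::runif(n_off * M * b), dim = c(n_off, M, b))
    u2 <- array(stats::runif(n_off * M * b), dim = c(n_off, M, b))
    for (r in seq_len(b)) {
      Xs <- (u1[, , r] <= off$pf) + (u2[, , r] <= off$pm)
      dim(Xs) <- c(n_off, M)
      Xs[!off$obs] <- 0
      Us <- colSums(Tv * (Xs - Eo))
      if (sum(Us^2) >= Q_obs - 1e-12) exceed <- exceed + 1L
    }
    done <- done + b
  }
  p <- (1 + exceed) / (1 + n_perm)
  note <- NULL
  if (any(table(scores$ped) > 1)) {
    note <- "pedigrees with multiple nuclear families present: permutation null treats them as independent"
  }
  res <- .region_result("fbat_lmm", Q_obs, NA_real_, p, "permutation", scores,
                        note = note)
  res$n_perm <- n_perm
  res
}

.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_seed <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Run a family-based region test end to end
#'
#' Convenience wrapper: decomposes the pedigrees into nuclear families,
#' builds the family scores for the requested markers and dispatches to the
#' chosen statistic.
#'
#' @param geno A `genotype_matrix`.
#' @param ped A `pedigree_set`.
#' @param trait A `trait_vector`.
#' @param method One of "fbat_v", "fbat_l", "fbat_m", "fbat_lmm".
#' @param vids Optional marker subset.
#' @param variance_mode "model" or "empirical" (ignored by fbat_lmm).
#' @param n_perm,seed Passed to [fbat_lmm()].
#' @return A `region_test_result`.
#' @export
fbat_region <- function(geno, ped, trait,
                        method = c("fbat_v", "fbat_l", "fbat_m", "fbat_lmm"),
                        vids = NULL, variance_mode = "model",
                        n_perm = 1000, seed = NULL) {
  method <- match.arg(method)
  fams <- decompose_nuclear(ped)
  scores <- family_scores(fams, geno, trait, vids = vids)
  switch(method,
         fbat_v = fbat_v(scores, variance_mode),
         fbat_l = fbat_l(scores, variance_mode),
         fbat_m = fbat_m(scores, variance_mode),
         fbat_lmm = {
           if (is.null(seed)) seed <- .region_seed(vids)
           fbat_lmm(scores, n_perm = n_perm, seed = seed)
         })
}

# deterministic fallback seed from the marker ids
.region_seed <- function(vids) {
  s <- paste(vids, collapse = ",")
  if (s == "") s <- "region"
  as.integer(sum(utf8ToInt(s) * (seq_len(nchar(s)) %% 97 + 1)) %% 2147483L)
}
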