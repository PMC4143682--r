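#' Build a set of identically structured pedigrees
#'
#' Templates: "trio" (two founders, one offspring), "sibship" (two founders,
#' `n_offspring` full sibs), "threegen" (an extended 13-person pedigree:
#' a grandparent couple with three children, two of whom marry in founder
#' spouses and have three children each -- three nuclear families with
#' sibships of three, and two persons appearing in both offspring and
#' parent roles). Individual ids are globally unique.
#'
#' @param template Pedigree template name.
#' @param n_pedigrees Number of pedigree copies.
#' @param n_offspring Sibship size for the "sibship" template (default 2).
#' @return A `pedigree_set`.
#' @export
sim_pedigrees <- function(template = c("trio", "sibship", "threegen"),
                          n_pedigrees, n_offspring = 2) {
  template <- match.arg(template)
  one <- switch(template,
    trio = data.frame(
      iid = c("fa", "mo", "o1"),
      father = c(NA, NA, "fa"), mother = c(NA, NA, "mo"),
      sex = c("male", "female", "unknown"), stringsAsFactors = FALSE),
    sibship = data.frame(
      iid = c("fa", "mo", paste0("o", seq_len(n_offspring))),
      father = c(NA, NA, rep("fa", n_offspring)),
      mother = c(NA, NA, rep("mo", n_offspring)),
      sex = c("male", "female", rep("unknown", n_offspring)),
      stringsAsFactors = FALSE),
    threegen = data.frame(
      iid = c("gf", "gm", "p1", "p2", "p3", "sp1", "sp2",
              "c1", "c2", "c3", "d1", "d2", "d3"),
      father = c(NA, NA, "gf", "gf", "gf", NA, NA,
                 "p1", "p1", "p1", "p2", "p2", "p2"),
      mother = c(NA, NA, "gm", "gm", "gm", NA, NA,
                 "sp1", "sp1", "sp1", "sp2", "sp2", "sp2"),
      sex = c("male", "female", "male", "male", "female", "female", "female",
              rep("unknown", 6)), stringsAsFactors = FALSE))
  blocks <- lapply(seq_len(n_pedigrees), function(k) {
    b <- one
    pref <- paste0("ped", k, "_")
    b$iid <- paste0(pref, b$iid)
    b$father <- ifelse(is.na(b$father), NA, paste0(pref, b$father))
    b$mother <- ifelse(is.na(b$mother), NA, paste0(pref, b$mother))
    b$fid <- paste0("ped", k)
    b
  })
  pedigree_set(do.call(rbind, blocks))
}

#' Gene-dropping genotype simulation on a pedigree set
#'
#' Founder alleles are drawn independently per locus at the supplied minor
#' allele frequencies; each nonfounder inherits one uniformly chosen allele
#' per parent. With `linked = FALSE` (default) every locus segregates
#' independently (linkage equilibrium and free recombination); with
#' `linked = TRUE` each parent-to-offspring meiosis transmits one of the
#' parent's two haplotypes wholesale, i.e. all loci are completely linked
#' (a single recombination-free chromosome), which is how heritable
#' polygenic backgrounds realized on transmitted genomes are emulated.
#'
#' @param ped A `pedigree_set`.
#' @param mafs Per-locus allele frequencies in [0, 0.5].
#' @param seed Integer seed.
#' @param linked Complete linkage across loci (default FALSE).
#' @param chrom,pos Variant coordinates (defaults: chromosome "3",
#'   positions 1e6 + 1000 * locus index).
#' @return A `genotype_matrix`; `variants$maf` holds the realized cohort
#'   MAF, `variants$maf_true` the generating frequency.
#' @export
gene_drop <- function(ped, mafs, seed, linked = FALSE,
                      chrom = "3", pos = NULL) {
  stopifnot(all(mafs >= 0 & mafs <= 0.5))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  p <- ped$persons
  n <- nrow(p); L <- length(mafs)
  H1 <- matrix(0L, n, L); H2 <- matrix(0L, n, L)
  fo <- which(p$founder)
  H1[fo, ] <- matrix(stats::rbinom(length(fo) * L, 1, rep(mafs, each = length(fo))),
                     length(fo), L)
  H2[fo, ] <- matrix(stats::rbinom(length(fo) * L, 1, rep(mafs, each = length(fo))),
                     length(fo), L)
  fi <- match(ifelse(is.na(p$father), NA, paste(p$fid, p$father, sep = ":")), p$pid)
  mi <- match(ifelse(is.na(p$mother), NA, paste(p$fid, p$mother, sep = ":")), p$pid)
  for (dep in sort(unique(p$depth[!p$founder]))) {
    ix <- which(p$depth == dep & !p$founder)
    m <- length(ix)
    self_f <- if (linked) matrix(stats::rbinom(m, 1, 0.5), m, L) else
      matrix(stats::rbinom(m * L, 1, 0.5), m, L)
    self_m <- if (linked) matrix(stats::rbinom(m, 1, 0.5), m, L) else
      matrix(stats::rbinom(m * L, 1, 0.5), m, L)
    H1[ix, ] <- ifelse(self_f == 0, H1[fi[ix], , drop = FALSE], H2[fi[ix], , drop = FALSE])
    H2[ix, ] <- ifelse(self_m == 0, H1[mi[ix], , drop = FALSE], H2[mi[ix], , drop = FALSE])
  }
  d <- H1 + H2
  storage.mode(d) <- "double"
  if (is.null(pos)) pos <- as.integer(1e6 + 1000 * seq_len(L))
  af <- colMeans(d) / 2
  variants <- data.frame(chrom = chrom, pos = pos,
                         vid = paste0(chrom, "-", pos),
                         ref = "A", alt = "T",
                         maf = pmin(af, 1 - af), maf_true = mafs,
                         flipped = FALSE, stringsAsFactors = FALSE)
  genotype_matrix(d, variants, p$iid)
}

#' Simulation scenario configuration
#'
#' @param template,n_pedigrees,n_offspring Pedigree structure
#'   (see [sim_pedigrees()]).
#' @param mafs Marker allele frequencies.
#' @param causal Indices (into `mafs`) of causal markers (may be empty).
#' @param beta Per-causal-variant allele effects, trait-SD units.
#' @param polygenic_h2 Narrow-sense polygenic heritability of the
#'   non-causal trait component, in [0, 1).
#' @param polygenic_mode "kinship" draws the polygenic effect from a
#'   multivariate normal with covariance proportional to 2 * kinship;
#'   "linked" realizes it through `n_polygenic_loci` gene-dropped loci
#'   completely linked to the markers (transmitted-genome heritability, the
#'   regime in which model-based family-test variances break down).
#' @param n_polygenic_loci Number of background loci for "linked" mode.
#' @param env_sd Standard deviation of the total non-causal trait component
#'   (polygenic + environmental; default 1).
#' @param covar_effects Named vector of covariate effects leaked into the
#'   raw trait (age per year, sex for females); removed again by
#'   residualization.
#' @param n_replicates Replicates for [run_experiment()] (default 200).
#' @param alpha Nominal level (default 0.05).
#' @param n_perm Mendelian permutations for fbat_lmm inside the harness.
#' @param seed Base seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(template = "trio", n_pedigrees = 200, n_offspring = 2,
                       mafs, causal = integer(0), beta = numeric(0),
                       polygenic_h2 = 0, polygenic_mode = c("kinship", "linked"),
                       n_polygenic_loci = 60, env_sd = 1,
                       covar_effects = c(age = 0.02, sex = 0.3),
                       n_replicates = 200, alpha = 0.05, n_perm = 1000,
                       seed = 1) {
  polygenic_mode <- match.arg(polygenic_mode)
  stopifnot(all(mafs >= 0 & mafs <= 0.5),
            polygenic_h2 >= 0, polygenic_h2 < 1,
            length(causal) == length(beta))
  explained <- sum(2 * mafs[causal] * (1 - mafs[causal]) * beta^2)
  if (polygenic_h2 + explained / (explained + env_sd^2) >= 1) {
    stop("polygenic heritability plus causal variance share must stay below 1")
  }
  structure(list(template = template, n_pedigrees = n_pedigrees,
                 n_offspring = n_offspring, mafs = mafs, causal = causal,
                 beta = beta, polygenic_h2 = polygenic_h2,
                 polygenic_mode = polygenic_mode,
                 n_polygenic_loci = n_polygenic_loci, env_sd = env_sd,
                 covar_effects = covar_effects, n_replicates = n_replicates,
                 alpha = alpha, n_perm = n_perm, seed = seed),
            class = "sim_config")
}

#' The 28 prioritized candidate-gene variants shipped with the package
#'
#' Variant ids and minor allele frequencies of the 28 variants retained by
#' the functional screen of the MAP4 candidate gene region, as used by the
#' "map4like" and "q1like" simulation presets.
#'
#' @return data.frame with `vid` and `maf`.
#' @export
map4_variants <- function() {
  path <- system.file("extdata", "map4_snps.tsv", package = "famregion")
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$maf <- as.numeric(df$maf)
  df
}

#' Simulation presets mirroring the evaluation scenarios
#'
#' \describe{
#'   \item{"q1like"}{Null trait with polygenic heritability 0.628 (the
#'     heritability of the null phenotype used for type-I-error
#'     assessment), 170 sibship pedigrees of 5 (850 persons, matching the
#'     family-sample size of the motivating study), the 28 candidate-region
#'     MAFs, no causal effect.}
#'   \item{"q1like_extended"}{Same null trait on 65 extended 13-person
#'     three-generation pedigrees (845 persons) with the polygenic
#'     background realized through completely linked gene-dropped loci:
#'     trait similarity among sibs then tracks their shared transmissions,
#'     the regime where model-based family-test variances inflate and the
#'     empirical ("-e") estimator is required.}
#'   \item{"map4like"}{Power scenario: 28 markers at the candidate-region
#'     MAFs, 8 causal (4 rare at effect 0.5 SD/allele, 4 common at 0.25),
#'     same-sign effects, residual polygenic heritability 0.30, same
#'     850-person sibship design.}
#'   \item{"map4like_mixed"}{As "map4like" with alternating effect signs,
#'     the regime favouring direction-agnostic tests.}
#' }
#'
#' @param name Preset name.
#' @param ... Overrides passed to [sim_config()] (e.g. `n_replicates`,
#'   `seed`, `n_perm`).
#' @return A `sim_config`.
#' @export
sim_preset <- function(name = c("q1like", "q1like_extended", "map4like",
                                "map4like_mixed"), ...) {
  name <- match.arg(name)
  mafs <- map4_variants()$maf
  causal <- c(1, 3, 9, 19, 11, 15, 25, 28)  # 4 rare, 4 common
  beta_mag <- c(0.5, 0.5, 0.5, 0.5, 0.25, 0.25, 0.25, 0.25)
  base <- switch(name,
    q1like = list(template = "sibship", n_offspring = 3, n_pedigrees = 170,
                  mafs = mafs, polygenic_h2 = 0.628,
                  polygenic_mode = "kinship"),
    q1like_extended = list(template = "threegen", n_pedigrees = 65,
                           mafs = mafs, polygenic_h2 = 0.628,
                           polygenic_mode = "linked"),
    map4like = list(template = "sibship", n_offspring = 3, n_pedigrees = 170,
                    mafs = mafs, causal = causal, beta = beta_mag,
                    polygenic_h2 = 0.30, polygenic_mode = "kinship"),
    map4like_mixed = list(template = "sibship", n_offspring = 3,
                          n_pedigrees = 170, mafs = mafs, causal = causal,
                          beta = beta_mag * c(1, -1, 1, -1, 1, -1, 1, -1),
                          polygenic_h2 = 0.30, polygenic_mode = "kinship"))
  do.call(sim_config, utils::modifyList(base, list(...)))
}

#' Simulate one replicate: genotypes, raw trait and covariates
#'
#' Trait model: y = mu + sum_c beta_c g_c + a + e, with the polygenic
#' component a scaled so that Var(a) = polygenic_h2 * env_sd^2 and
#' e ~ N(0, (1 - polygenic_h2) * env_sd^2), plus age and sex effects
#' (see [sim_config()]). Ages decrease by generation; sex is taken from the
#' pedigree (unknown-sex offspring are assigned at random).
#'
#' @param config A `sim_config`.
#' @param ped A `pedigree_set` from [sim_pedigrees()] (built from `config`
#'   if omitted).
#' @param seed Integer seed for this replicate.
#' @param chol2phi Optional pre-computed upper Cholesky factor of
#'   2 * kinship (cached across replicates by [run_experiment()]).
#' @return List with `geno` (test markers only), `pheno` (data.frame `fid`,
#'   `iid`, `y`, `age`, `sex`), and `ped`.
#' @export
sim_replicate <- function(config, ped = NULL, seed = config$seed,
                          chol2phi = NULL) {
  if (is.null(ped)) {
    ped <- sim_pedigrees(config$template, config$n_pedigrees, config$n_offspring)
  }
  p <- ped$persons
  n <- nrow(p)
  linked <- config$polygenic_mode == "linked" && config$polygenic_h2 > 0
  all_mafs <- config$mafs
  n_poly <- 0L
  if (linked) {
    n_poly <- config$n_polygenic_loci
    all_mafs <- c(config$mafs, rep(0.3, n_poly))
  }
  geno_all <- gene_drop(ped, all_mafs, seed = seed, linked = linked)
  M <- length(config$mafs)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed) + 1L)

  age <- stats::rnorm(n, 62 - 18 * p$depth, 6)
  sex <- ifelse(p$sex == "female", 1,
                ifelse(p$sex == "male", 0, stats::rbinom(n, 1, 0.5)))
  h2 <- config$polygenic_h2
  s0 <- config$env_sd
  a <- rep(0, n)
  if (h2 > 0) {
    if (linked) {
      Gp <- geno_all$dosage[, M + seq_len(n_poly), drop = FALSE]
      sdv <- apply(Gp, 2, stats::sd)
      ok <- sdv > 0
      Zp <- scale(Gp[, ok, drop = FALSE])
      b <- stats::rnorm(sum(ok), 0, sqrt(h2 * s0^2 / sum(ok)))
      a <- drop(Zp %*% b)
    } else {
      if (is.null(chol2phi)) chol2phi <- chol(2 * kinship(ped))
      a <- sqrt(h2) * s0 * drop(crossprod(chol2phi, stats::rnorm(n)))
    }
  }
  e <- stats::rnorm(n, 0, sqrt(1 - h2) * s0)
  g_eff <- 0
  if (length(config$causal) > 0) {
    g_eff <- drop(geno_all$dosage[, config$causal, drop = FALSE] %*% config$beta)
  }
  ce <- config$covar_effects
  y <- 10 + g_eff + a + e + ce[["age"]] * (age - mean(age)) + ce[["sex"]] * sex
  geno <- if (n_poly > 0) subset_genotypes(geno_all, vids = geno_all$variants$vid[seq_len(M)]) else geno_all
  list(geno = geno,
       pheno = data.frame(fid = p$fid, iid = p$iid, y = y, age = age,
                          sex = sex, stringsAsFactors = FALSE),
       ped = ped)
}

#' Simulate an unrelated cohort
#'
#' Hardy-Weinberg dosages, independent across loci and individuals: the
#' population-design analogue of [gene_drop()]. With `n_subpop = 2` the
#' cohort is split into two equal subpopulations whose allele frequencies
#' are perturbed apart by `fst_shift` (for exercising ancestry principal
#' components).
#'
#' @param n Number of individuals.
#' @param mafs Per-locus allele frequencies in [0, 0.5].
#' @param seed Integer seed.
#' @param n_subpop 1 (default) or 2.
#' @param fst_shift Absolute frequency shift between the two subpopulations
#'   (default 0.2; ignored for `n_subpop = 1`).
#' @return A `genotype_matrix`; with two subpopulations, attribute
#'   `subpop` holds the 1/2 labels.
#' @export
sim_unrelated <- function(n, mafs, seed, n_subpop = 1, fst_shift = 0.2) {
  stopifnot(all(mafs >= 0 & mafs <= 0.5), n_subpop %in% c(1, 2))
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(as.integer(seed))
  L <- length(mafs)
  if (n_subpop == 1) {
    d <- matrix(stats::rbinom(n * L, 2, rep(mafs, each = n)), n, L)
    subpop <- rep(1L, n)
  } else {
    n1 <- floor(n / 2); n2 <- n - n1
    p1 <- pmin(pmax(mafs - fst_shift / 2, 0.01), 0.99)
    p2 <- pmin(pmax(mafs + fst_shift / 2, 0.01), 0.99)
    d <- rbind(matrix(stats::rbinom(n1 * L, 2, rep(p1, each = n1)), n1, L),
               matrix(stats::rbinom(n2 * L, 2, rep(p2, each = n2)), n2, L))
    subpop <- rep(c(1L, 2L), c(n1, n2))
  }
  storage.mode(d) <- "double"
  pos <- as.integer(1e6 + 1000 * seq_len(L))
  af <- colMeans(d) / 2
  variants <- data.frame(chrom = "3", pos = pos, vid = paste0("3-", pos),
                         ref = "A", alt = "T", maf = pmin(af, 1 - af),
                         maf_true = mafs, flipped = FALSE,
                         stringsAsFactors = FALSE)
  out <- genotype_matrix(d, variants, paste0("ind", seq_len(n)))
  attr(out, "subpop") <- subpop
  out
}

#' Simulated multi-gene chromosome for scan testing
#'
#' Builds a 10-gene chromosome segment (6 markers per gene, allele
#' frequencies 0.005-0.3 within each gene), a family sample from
#' [sim_pedigrees()], and a trait with four causal variants inside one gene
#' ("gene04" by default) whose like-signed allele effects scale inversely
#' with frequency, residual polygenic heritability 0.30. Used to exercise [run_scan()] end to end.
#'
#' @param seed Integer seed.
#' @param n_pedigrees Number of sibship-of-3 pedigrees (default 170).
#' @param causal_gene Index of the causal gene in 1..10 (default 4).
#' @return List: `genes` (gene table), `geno`, `ped`, `trait` (adjusted
#'   residuals), `causal_gene` (gene name).
#' @export
sim_scan_scenario <- function(seed, n_pedigrees = 170, causal_gene = 4) {
  gene_mafs <- c(0.005, 0.01, 0.03, 0.1, 0.2, 0.3)
  mafs <- rep(gene_mafs, 10)
  first <- 6 * (causal_gene - 1)
  config <- sim_config(template = "sibship", n_offspring = 3,
                       n_pedigrees = n_pedigrees, mafs = mafs,
                       causal = first + c(1, 2, 3, 4, 6),
                       beta = c(1.8, 1.4, 1.0, 0.6, 0.4),
                       polygenic_h2 = 0.30, seed = seed)
  rep1 <- sim_replicate(config, seed = seed)
  genes <- data.frame(
    chrom = "3",
    start = as.integer(1e6 + 6000 * (0:9) + 500),
    end = as.integer(1e6 + 6000 * (1:10) + 500),
    name = sprintf("gene%02d", 1:10), stringsAsFactors = FALSE)
  trait <- residualize(rep1$pheno, "y", c("age", "sex"))
  list(genes = genes, geno = rep1$geno, ped = rep1$ped, trait = trait,
       causal_gene = sprintf("gene%02d", causal_gene))
}

# registry of method tags accepted by run_experiment() / run_scan()
.method_registry <- c("fbat_v", "fbat_v_e", "fbat_l", "fbat_l_e",
                      "fbat_m", "fbat_m_e", "fbat_lmm", "skat", "gcta")

# run one method tag on one prepared replicate; returns a p-value
.run_method <- function(tag, scores, geno_unrel, trait_unrel, n_perm, seed) {
  switch(tag,
    fbat_v = fbat_v(scores, "model")$p_value,
    fbat_v_e = fbat_v(scores, "empirical")$p_value,
    fbat_l = fbat_l(scores, "model")$p_value,
    fbat_l_e = fbat_l(scores, "empirical")$p_value,
    fbat_m = fbat_m(scores, "model")$p_value,
    fbat_m_e = fbat_m(scores, "empirical")$p_value,
    fbat_lmm = fbat_lmm(scores, n_perm = n_perm, seed = seed)$p_value,
    skat = skat_test(geno_unrel, trait_unrel)$p_value,
    gcta = gcta_region_test(geno_unrel, trait_unrel)$p_value,
    stop("unknown method tag: ", tag))
}

#' Type-I-error / power evaluation harness
#'
#' Runs the full pipeline per replicate -- regenerate genotypes and trait,
#' residualize the trait on age and sex, score the families, run every
#' requested method -- and reports the rejection rate at the nominal level
#' with an exact binomial 95\% confidence interval. Family-based methods use
#' all pedigrees; population-based methods ("skat", "gcta") use the
#' pedigree founders (a pairwise-unrelated set). Replicate seeds are
#' derived deterministically from the base seed.
#'
#' @param config A `sim_config` (see also [sim_preset()]).
#' @param methods Character vector of method tags: fbat_v, fbat_v_e,
#'   fbat_l, fbat_l_e, fbat_m, fbat_m_e, fbat_lmm, skat, gcta.
#' @param seed Base seed (default `config$seed`).
#' @return A `simulation_report` data.frame: method, n_replicates, n_used
#'   (replicates where the method returned a p-value), rejections, rate,
#'   ci_lo, ci_hi; attribute `pvalues` holds the full replicate x method
#'   p-value matrix.
#' @export
run_experiment <- function(config, methods, seed = config$seed) {
  unknown <- setdiff(methods, .method_registry)
  if (length(unknown) > 0) {
    stop("unknown method tag(s): ", paste(unknown, collapse = ", "))
  }
  ped <- sim_pedigrees(config$template, config$n_pedigrees, config$n_offspring)
  fams <- decompose_nuclear(ped)
  chol2phi <- if (config$polygenic_h2 > 0 && config$polygenic_mode == "kinship")
    chol(2 * kinship(ped)) else NULL
  need_unrel <- any(methods %in% c("skat", "gcta"))
  unrel <- if (need_unrel) select_unrelated(ped, "founders_only") else NULL
  need_fbat <- any(startsWith(methods, "fbat"))

  R <- config$n_replicates
  P <- matrix(NA_real_, R, length(methods), dimnames = list(NULL, methods))
  for (r in seq_len(R)) {
    seed_r <- as.integer(seed) + 7919L * r
    rep_data <- sim_replicate(config, ped = ped, seed = seed_r,
                              chol2phi = chol2phi)
    trait <- residualize(rep_data$pheno, "y", c("age", "sex"))
    scores <- if (need_fbat)
      family_scores(fams, rep_data$geno, trait) else NULL
    if (need_unrel) {
      gu <- subset_genotypes(rep_data$geno, samples = unrel)
      tu <- trait[trait$iid %in% unrel, , drop = FALSE]
    } else {
      gu <- NULL; tu <- NULL
    }
    for (m in methods) {
      P[r, m] <- tryCatch(
        .run_method(m, scores, gu, tu, config$n_perm, seed_r + 13L),
        error = function(e) NA_real_)
    }
  }
  rows <- lapply(methods, function(m) {
    pv <- P[, m]
    used <- sum(!is.na(pv))
    rej <- sum(pv < config$alpha, na.rm = TRUE)
    ci <- if (used > 0) stats::binom.test(rej, used)$conf.int else c(NA, NA)
    data.frame(method = m, n_replicates = R, n_used = used,
               rejections = rej, rate = if (used > 0) rej / used else NA_real_,
               ci_lo = ci[1], ci_hi = ci[2], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "pvalues") <- P
  attr(out, "alpha") <- config$alpha
  attr(out, "seed") <- seed
  class(out) <- c("simulation_report", "data.frame")
  out
}
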