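#' Assign variants to gene windows
#'
#' Gene intervals are 0-based half-open `[start, end)`; a variant at
#' 1-based position p belongs to a gene iff `start <= p - 1 < end`.
#' Overlapping or nested genes each receive the variant (no collapsing to
#' a single transcript).
#'
#' @param genes data.frame from [read_gene_table()].
#' @param variants data.frame with `chrom`, `pos`, `vid` (e.g.
#'   `geno$variants`).
#' @return Named list (gene name -> character vector of vids, possibly
#'   empty).
#' @export
assign_variants <- function(genes, variants) {
  out <- lapply(seq_len(nrow(genes)), function(i) {
    hit <- variants$chrom == genes$chrom[i] &
      variants$pos - 1L >= genes$start[i] &
      variants$pos - 1L < genes$end[i]
    variants$vid[hit]
  })
  names(out) <- genes$name
  out
}

#' Gene-by-gene region scan with Bonferroni correction
#'
#' For each gene window: assign variants, optionally apply the functional
#' prioritization filter, run each requested region test, and flag genes
#' passing the Bonferroni threshold alpha / (number of genes actually
#' tested). Genes with no polymorphic marker after filtering are reported
#' as untested and excluded from the Bonferroni denominator. A failure of
#' one test on one gene is recorded as NA and the scan continues.
#'
#' @param genes data.frame from [read_gene_table()].
#' @param geno A `genotype_matrix` (full chromosome).
#' @param trait A `trait_vector` (already adjusted, including ancestry PCs
#'   if desired).
#' @param methods Character vector of method tags (see [run_experiment()]).
#' @param ped A `pedigree_set`; required for fbat methods.
#' @param alpha Family-wise level (default 0.05).
#' @param annotations,filter Optional annotation table and
#'   [filter_config()]; when supplied, each gene's variants pass through
#'   [functional_filter()] first.
#' @param unrelated Optional iid subset for skat/gcta (default: pedigree
#'   founders when `ped` is given, otherwise all samples).
#' @param n_perm,seed fbat_lmm controls; the per-gene seed is derived from
#'   `seed` and the gene's marker ids when given, else from the marker ids
#'   alone.
#' @return A `scan_result` data.frame: one row per gene with interval,
#'   marker counts, per-method p-values, -log10 p, and Bonferroni flags;
#'   attributes `alpha`, `n_tested`, `threshold`.
#' @export
run_scan <- function(genes, geno, trait, methods, ped = NULL, alpha = 0.05,
                     annotations = NULL, filter = filter_config(),
                     unrelated = NULL, n_perm = 1000, seed = NULL) {
  unknown <- setdiff(methods, .method_registry)
  if (length(unknown) > 0) {
    stop("unknown method tag(s): ", paste(unknown, collapse = ", "))
  }
  need_fbat <- any(startsWith(methods, "fbat"))
  if (need_fbat && is.null(ped)) stop("fbat methods require 'ped'")
  fams <- if (need_fbat) decompose_nuclear(ped) else NULL
  need_unrel <- any(methods %in% c("skat", "gcta"))
  if (need_unrel && is.null(unrelated)) {
    unrelated <- if (!is.null(ped)) select_unrelated(ped, "founders_only")
      else geno$samples
  }
  assign <- assign_variants(genes, geno$variants)

  rows <- list()
  for (i in seq_len(nrow(genes))) {
    vids <- assign[[i]]
    n_total <- length(vids)
    if (!is.null(annotations) && n_total > 0) {
      vids <- functional_filter(vids, annotations, filter)
    }
    n_filt <- length(vids)
    pvals <- stats::setNames(rep(NA_real_, length(methods)), methods)
    n_tested_markers <- 0L
    if (n_filt > 0) {
      gsub_ <- subset_genotypes(geno, vids = vids)
      poly <- gsub_$variants$maf > 0
      n_tested_markers <- sum(poly)
      if (n_tested_markers > 0) {
        scores <- if (need_fbat) tryCatch(
          family_scores(fams, gsub_, trait), error = function(e) NULL) else NULL
        gu <- tu <- NULL
        if (need_unrel) {
          gu <- subset_genotypes(gsub_, samples = intersect(unrelated, gsub_$samples))
          tu <- trait[trait$iid %in% unrelated, , drop = FALSE]
        }
        gene_seed <- if (is.null(seed)) .region_seed(vids) else
          as.integer(seed) + .region_seed(vids) %% 10000L
        for (m in methods) {
          if (startsWith(m, "fbat") && is.null(scores)) next
          pvals[m] <- tryCatch(
            .run_method(m, scores, gu, tu, n_perm, gene_seed),
            error = function(e) NA_real_)
        }
      }
    }
    rows[[i]] <- data.frame(gene = genes$name[i], chrom = genes$chrom[i],
                            start = genes$start[i], end = genes$end[i],
                            midpoint = (genes$start[i] + genes$end[i]) / 2,
                            n_markers_total = n_total,
                            n_markers_after_filter = n_filt,
                            n_markers_tested = n_tested_markers,
                            t(pvals), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  tested <- out$n_markers_tested > 0 &
    apply(out[, methods, drop = FALSE], 1, function(z) any(!is.na(z)))
  n_tested <- sum(tested)
  threshold <- if (n_tested > 0) alpha / n_tested else NA_real_
  for (m in methods) {
    out[[paste0("neglog10_", m)]] <- -log10(out[[m]])
    out[[paste0("significant_", m)]] <- !is.na(out[[m]]) & out[[m]] < threshold
  }
  attr(out, "alpha") <- alpha
  attr(out, "n_tested") <- n_tested
  attr(out, "threshold") <- threshold
  class(out) <- c("scan_result", "data.frame")
  out
}

#' @method print scan_result
#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("region scan: %d genes, %d tested, Bonferroni threshold %.3g (alpha = %g)\n",
              nrow(x), attr(x, "n_tested"), attr(x, "threshold"), attr(x, "alpha")))
  NextMethod()
}
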