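#' Variant prioritization configuration
#'
#' Defaults encode the screening rule used throughout the package: keep
#' splice and stop variants unconditionally, keep nonsynonymous variants
#' whose deleteriousness score exceeds 0.5 (strict), and keep any variant
#' with eQTL evidence of at least 3.4 on the -log10 p scale (inclusive).
#'
#' @param del_score_min Deleteriousness threshold, strict ">" (default 0.5).
#' @param eqtl_neglogp_min eQTL -log10 p cutoff, inclusive ">=" (default 3.4).
#' @param always_keep_classes Functional classes kept unconditionally
#'   (default splice, stop).
#' @param maf_bins Strictly increasing MAF upper bounds in (0, 0.5] used by
#'   [maf_summary()] (default 0.01, 0.05).
#' @return A `filter_config` list.
#' @export
filter_config <- function(del_score_min = 0.5, eqtl_neglogp_min = 3.4,
                          always_keep_classes = c("splice", "stop"),
                          maf_bins = c(0.01, 0.05)) {
  stopifnot(del_score_min >= 0, eqtl_neglogp_min >= 0)
  if (length(maf_bins) > 0) {
    stopifnot(all(diff(maf_bins) > 0), all(maf_bins > 0), all(maf_bins <= 0.5))
  }
  structure(list(del_score_min = del_score_min,
                 eqtl_neglogp_min = eqtl_neglogp_min,
                 always_keep_classes = always_keep_classes,
                 maf_bins = maf_bins),
            class = "filter_config")
}

#' Functional variant prioritization
#'
#' A variant is kept if it qualifies by any route: (a) its functional class
#' is in `always_keep_classes`; (b) it is nonsynonymous with deleteriousness
#' score strictly above `del_score_min`; (c) its eQTL -log10 p is at least
#' `eqtl_neglogp_min`. Variants absent from the annotation table fail.
#'
#' @param vids Character vector of variant ids to screen.
#' @param annotations data.frame from [read_annotation()].
#' @param config A [filter_config()].
#' @return Character vector of kept vids, in input order.
#' @export
functional_filter <- function(vids, annotations, config = filter_config()) {
  idx <- match(vids, annotations$vid)
  cls <- annotations$func_class[idx]
  del <- annotations$del_score[idx]
  eqtl <- annotations$eqtl_neglogp[idx]
  keep <- (!is.na(cls) & cls %in% config$always_keep_classes) |
    (!is.na(cls) & cls == "nonsynonymous" & !is.na(del) & del > config$del_score_min) |
    (!is.na(eqtl) & eqtl >= config$eqtl_neglogp_min)
  vids[keep]
}

#' MAF stratification summary
#'
#' Counts variants with MAF strictly below each bound, as in rare-variant
#' summary tables ("MAF < 1\%", "MAF < 5\%"). Bins are cumulative, not
#' disjoint. Percentages are reported rounded to one decimal.
#'
#' @param mafs Numeric vector of minor allele frequencies in [0, 0.5].
#' @param maf_bins Strictly increasing upper bounds (default 0.01, 0.05).
#' @return data.frame with `bound`, `count`, `percent` plus attribute
#'   `total`; zero rows of counts when `mafs` is empty... total still 0.
#' @export
maf_summary <- function(mafs, maf_bins = c(0.01, 0.05)) {
  stopifnot(all(mafs >= 0 & mafs <= 0.5))
  if (length(maf_bins) > 0) stopifnot(all(diff(maf_bins) > 0))
  total <- length(mafs)
  count <- vapply(maf_bins, function(b) sum(mafs < b), integer(1))
  percent <- if (total == 0) rep(NA_real_, length(maf_bins)) else
    round(100 * count / total, 1)
  out <- data.frame(bound = maf_bins, count = count, percent = percent)
  attr(out, "total") <- total
  out
}
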