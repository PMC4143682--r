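#' Read genotypes from a VCF file into a genotype matrix
#'
#' Parses a VCF 4.x file (GT field only) into a persons-by-variants
#' minor-allele dosage matrix. Multiallelic records are skipped with a
#' warning. The minor allele is defined within the loaded sample set: if the
#' ALT allele frequency exceeds 0.5 the dosage is flipped to count the REF
#' allele (ties keep ALT as the counted allele). Missing genotypes (`./.`)
#' are stored as `NA` and excluded from the allele-frequency computation.
#'
#' @param path Path to a VCF file (plain or gzipped).
#' @param sample_subset Optional character vector of sample ids to load; an
#'   error listing the absentees is raised if any are not present.
#' @return A `genotype_matrix`: list with `dosage` (samples x variants numeric
#'   matrix, entries 0/1/2/NA), `variants` (data.frame with `chrom`, `pos`,
#'   `vid`, `ref`, `alt`, `maf`, `flipped`), and `samples`.
#' @export
read_vcf <- function(path, sample_subset = NULL) {
  if (!file.exists(path)) stop("cannot read VCF: '", path, "' does not exist")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  multi <- grepl(",", alt) | is.na(alt) | alt == "."
  if (any(multi)) {
    warning(sum(multi), " multiallelic/invalid record(s) skipped")
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(NULL, names(gt)))
  samples <- colnames(gt)
  if (!is.null(sample_subset)) {
    absent <- setdiff(sample_subset, samples)
    if (length(absent) > 0) {
      stop("samples not found in VCF: ", paste(absent, collapse = ", "))
    }
    gt <- gt[, sample_subset, drop = FALSE]
    samples <- sample_subset
  }
  keep <- which(!multi)
  chrom <- fix[keep, "CHROM"]
  pos <- as.integer(fix[keep, "POS"])
  vid <- fix[keep, "ID"]
  synth <- is.na(vid) | vid == "."
  vid[synth] <- paste0(chrom[synth], "-", pos[synth])
  dos <- .gt_to_dosage(gt[keep, , drop = FALSE])
  # orient to the minor allele within the loaded cohort
  af <- colMeans(dos, na.rm = TRUE) / 2
  af[is.nan(af)] <- 0
  flip <- af > 0.5
  dos[, flip] <- 2 - dos[, flip]
  maf <- ifelse(flip, 1 - af, af)
  variants <- data.frame(
    chrom = chrom, pos = pos, vid = vid,
    ref = fix[keep, "REF"], alt = alt[keep],
    maf = as.numeric(maf), flipped = as.logical(flip),
    stringsAsFactors = FALSE
  )
  ord <- order(variants$chrom, variants$pos)
  variants <- variants[ord, , drop = FALSE]
  dos <- dos[, ord, drop = FALSE]
  rownames(variants) <- NULL
  if (anyDuplicated(variants$vid)) stop("duplicate variant ids after parsing: vids must be unique")
  colnames(dos) <- variants$vid
  genotype_matrix(dos, variants, samples)
}

# GT strings -> additive ALT dosage matrix (samples x variants)
.gt_to_dosage <- function(gt) {
  d <- matrix(NA_real_, nrow = ncol(gt), ncol = nrow(gt))
  clean <- gsub("\\|", "/", t(gt))
  d[clean == "0/0"] <- 0
  d[clean == "0/1" | clean == "1/0"] <- 1
  d[clean == "1/1"] <- 2
  rownames(d) <- colnames(gt)
  d
}

#' Construct a genotype matrix object
#'
#' @param dosage Numeric samples x variants matrix with entries in
#'   \{0, 1, 2, NA\} counting the minor allele.
#' @param variants data.frame with at least `chrom`, `pos`, `vid`, `maf`.
#' @param samples Character vector of sample ids (defaults to rownames).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosage, variants, samples = rownames(dosage)) {
  stopifnot(is.matrix(dosage), nrow(variants) == ncol(dosage))
  if (is.null(samples)) stop("sample ids required")
  ok <- dosage %in% c(0, 1, 2) | is.na(dosage)
  if (!all(ok)) stop("dosages must be 0, 1, 2 or NA")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (anyDuplicated(variants$vid)) stop("variant ids must be unique")
  rownames(dosage) <- samples
  colnames(dosage) <- variants$vid
  structure(list(dosage = dosage, variants = variants, samples = samples),
            class = "genotype_matrix")
}

#' @method print genotype_matrix
#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$samples), "samples x",
      nrow(x$variants), "variants\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Subset a genotype matrix by samples and/or variant ids
#'
#' @param geno A `genotype_matrix`.
#' @param samples Sample ids to keep (default all).
#' @param vids Variant ids to keep (default all).
#' @return A `genotype_matrix` restricted to the requested entries; per-variant
#'   MAF is recomputed within the retained samples.
#' @export
subset_genotypes <- function(geno, samples = NULL, vids = NULL) {
  d <- geno$dosage
  v <- geno$variants
  if (!is.null(vids)) {
    idx <- match(vids, v$vid)
    if (anyNA(idx)) stop("unknown variant ids: ", paste(vids[is.na(idx)], collapse = ", "))
    d <- d[, idx, drop = FALSE]
    v <- v[idx, , drop = FALSE]
  }
  if (!is.null(samples)) {
    idx <- match(samples, geno$samples)
    if (anyNA(idx)) stop("unknown samples: ", paste(samples[is.na(idx)], collapse = ", "))
    d <- d[idx, , drop = FALSE]
    af <- colMeans(d, na.rm = TRUE) / 2
    af[is.nan(af)] <- 0
    v$maf <- pmin(af, 1 - af)
  }
  rownames(v) <- NULL
  genotype_matrix(d, v, rownames(d))
}

#' Write a genotype matrix to a minimal VCF file
#'
#' Inverse of [read_vcf()] up to allele orientation: dosages are written on
#' the stored (minor-allele) orientation with REF/ALT swapped back for
#' variants that were flipped on input.
#'
#' @param geno A `genotype_matrix`.
#' @param path Output path (".gz" suffix writes gzip).
#' @return `path`, invisibly.
#' @export
write_vcf <- function(geno, path) {
  v <- geno$variants
  ref <- if (!is.null(v$ref)) v$ref else rep("A", nrow(v))
  alt <- if (!is.null(v$alt)) v$alt else rep("T", nrow(v))
  flip <- if (!is.null(v$flipped)) v$flipped else rep(FALSE, nrow(v))
  r <- ifelse(flip, alt, ref)
  a <- ifelse(flip, ref, alt)
  d <- geno$dosage
  if (any(flip)) d[, flip] <- 2 - d[, flip]
  gt_codes <- c("0/0", "0/1", "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", geno$samples), collapse = "\t")
  )
  body <- vapply(seq_len(nrow(v)), function(j) {
    g <- d[, j]
    gs <- ifelse(is.na(g), "./.", gt_codes[g + 1])
    paste(c(v$chrom[j], v$pos[j], v$vid[j], r[j], a[j], ".", "PASS", ".",
            "GT", gs), collapse = "\t")
  }, character(1))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, body), con)
  invisible(path)
}

#' Read a 6-column PED file into a pedigree set
#'
#' Whitespace-delimited pre-makeped PED: family id, individual id, father id,
#' mother id, sex (1 = male, 2 = female, other = unknown), phenotype (ignored
#' here; phenotypes travel in their own table). Parent ids of "0" mean
#' missing. Structural validity (resolvable parents, no individual its own
#' ancestor) is enforced.
#'
#' @param path Path to the PED file (plain or gzipped).
#' @return A `pedigree_set`.
#' @export
read_ped <- function(path) {
  if (!file.exists(path)) stop("cannot read PED: '", path, "' does not exist")
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (ncol(df) < 6) stop("PED requires >= 6 columns, found ", ncol(df))
  sex <- c("1" = "male", "2" = "female")[df[[5]]]
  sex[is.na(sex)] <- "unknown"
  pedigree_set(data.frame(
    fid = df[[1]], iid = df[[2]],
    father = ifelse(df[[3]] == "0", NA_character_, df[[3]]),
    mother = ifelse(df[[4]] == "0", NA_character_, df[[4]]),
    sex = unname(sex), stringsAsFactors = FALSE
  ))
}

#' Write a pedigree set as a 6-column PED file
#'
#' @param ped A `pedigree_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ped <- function(ped, path) {
  p <- ped$persons
  sex <- c(male = "1", female = "2", unknown = "0")[p$sex]
  lines <- paste(p$fid, p$iid,
                 ifelse(is.na(p$father), "0", p$father),
                 ifelse(is.na(p$mother), "0", p$mother),
                 unname(sex), "0", sep = "\t")
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Read a variant annotation table
#'
#' Tab-delimited with header columns `vid`, `func_class`, `del_score`,
#' `eqtl_neglogp`. `func_class` must be one of nonsynonymous, splice, stop,
#' synonymous, noncoding, other. "NA" or empty numeric fields become missing.
#' Duplicate vids: last row wins, with a warning.
#'
#' @param path Path (plain or gzipped).
#' @return data.frame of annotation records keyed by `vid`.
#' @export
read_annotation <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("vid", "func_class", "del_score", "eqtl_neglogp")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("annotation table missing column(s): ", paste(miss, collapse = ", "))
  classes <- c("nonsynonymous", "splice", "stop", "synonymous", "noncoding", "other")
  bad <- !(df$func_class %in% classes)
  if (any(bad)) stop("unknown func_class on line(s) ", paste(which(bad) + 1L, collapse = ", "))
  df$del_score <- .parse_numeric(df$del_score, path, "del_score")
  df$eqtl_neglogp <- .parse_numeric(df$eqtl_neglogp, path, "eqtl_neglogp")
  if (any(df$del_score < 0 | df$del_score > 1, na.rm = TRUE)) {
    stop("del_score outside [0, 1]")
  }
  if (any(df$eqtl_neglogp < 0, na.rm = TRUE)) stop("eqtl_neglogp must be >= 0")
  if (anyDuplicated(df$vid)) {
    warning("duplicate vid(s) in annotation table; keeping the last occurrence")
    df <- df[!duplicated(df$vid, fromLast = TRUE), , drop = FALSE]
  }
  rownames(df) <- NULL
  df[c("vid", "func_class", "del_score", "eqtl_neglogp")]
}

.parse_numeric <- function(x, path, col) {
  blank <- is.na(x) | x == "" | x == "NA" | x == "."
  out <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(out) & !blank)
  if (length(bad) > 0) {
    stop("malformed numeric in column '", col, "' of ", path,
         " at data line(s) ", paste(bad, collapse = ", "))
  }
  out[blank] <- NA_real_
  out
}

#' Write an annotation table
#' @param annot data.frame as returned by [read_annotation()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotation <- function(annot, path) {
  utils::write.table(annot, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}

#' Read a gene interval table (BED3+name dialect)
#'
#' Tab-delimited with header: `chrom`, `start`, `end`, `name`. Intervals are
#' 0-based half-open `[start, end)`; a variant at 1-based position p lies in
#' the gene iff `start <= p - 1 < end`.
#'
#' @param path Path (plain or gzipped).
#' @return data.frame with `chrom`, `start`, `end`, `name`.
#' @export
read_gene_table <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("chrom", "start", "end", "name")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("gene table missing column(s): ", paste(miss, collapse = ", "))
  df$start <- .parse_integer(df$start, path, "start")
  df$end <- .parse_integer(df$end, path, "end")
  if (any(df$end <= df$start)) stop("gene intervals must satisfy start < end")
  df[need]
}

.parse_integer <- function(x, path, col) {
  out <- suppressWarnings(as.integer(x))
  bad <- which(is.na(out))
  if (length(bad) > 0) {
    stop("malformed integer in column '", col, "' of ", path,
         " at data line(s) ", paste(bad, collapse = ", "))
  }
  out
}

#' Write a gene interval table
#' @param genes data.frame as returned by [read_gene_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_table <- function(genes, path) {
  utils::write.table(genes, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a long-format phenotype/covariate table
#'
#' Tab-delimited with header; requires key columns `fid`, `iid`, `exam` (one
#' row per person per exam) plus any number of numeric phenotype/covariate
#' columns. "NA"/empty fields become missing.
#'
#' @param path Path (plain or gzipped).
#' @return data.frame keyed by (`fid`, `iid`, `exam`).
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("fid", "iid", "exam")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) stop("phenotype table missing column(s): ", paste(miss, collapse = ", "))
  df$exam <- .parse_integer(df$exam, path, "exam")
  for (col in setdiff(names(df), need)) {
    df[[col]] <- .parse_numeric(df[[col]], path, col)
  }
  if (anyDuplicated(df[need])) stop("duplicate (fid, iid, exam) keys in phenotype table")
  df
}

#' Write a phenotype table
#' @param pheno data.frame as returned by [read_phenotypes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.table(pheno, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  invisible(path)
}
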