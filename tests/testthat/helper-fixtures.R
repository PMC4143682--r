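# Shared fixture builders: everything is generated in code at test time.

# Write a small VCF from explicit GT strings (variants x samples matrix).
write_fixture_vcf <- function(gt, chrom, pos, samples, path = tempfile(fileext = ".vcf"),
                              id = ".", ref = "A", alt = "T") {
  n_var <- nrow(gt)
  id <- rep_len(id, n_var); ref <- rep_len(ref, n_var); alt <- rep_len(alt, n_var)
  header <- c("##fileformat=VCFv4.2",
              '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", samples), collapse = "\t"))
  body <- vapply(seq_len(n_var), function(i) {
    paste(c(chrom[i], pos[i], id[i], ref[i], alt[i], ".", "PASS", ".", "GT",
            gt[i, ]), collapse = "\t")
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# A trio pedigree_set (founder couple + one child).
trio_ped <- function() {
  pedigree_set(data.frame(
    fid = "f1", iid = c("dad", "mum", "kid"),
    father = c(NA, NA, "dad"), mother = c(NA, NA, "mum"),
    sex = c("male", "female", "unknown"), stringsAsFactors = FALSE))
}

# genotype_matrix from a plain dosage matrix (samples x markers).
make_geno <- function(dosage, samples = rownames(dosage)) {
  M <- ncol(dosage)
  af <- colMeans(dosage, na.rm = TRUE) / 2
  genotype_matrix(dosage,
                  data.frame(chrom = "1", pos = seq_len(M) * 100L,
                             vid = paste0("1-", seq_len(M) * 100L),
                             ref = "A", alt = "T",
                             maf = pmin(af, 1 - af), flipped = FALSE,
                             stringsAsFactors = FALSE),
                  samples)
}

make_trait <- function(iids, values, fid = "f1") {
  structure(data.frame(fid = fid, iid = iids, value = values,
                       stringsAsFactors = FALSE),
            class = c("trait_vector", "data.frame"), exam = NA)
}

# Exhaustive enumeration of the offspring dosage distribution given parental
# dosages: every parental genotype is an unordered allele pair; each meiosis
# picks one allele uniformly. Independent oracle for conditional_distribution.
enumerate_offspring <- function(father, mother) {
  alleles <- function(d) switch(as.character(d), "0" = c(0, 0),
                                "1" = c(0, 1), "2" = c(1, 1))
  fa <- alleles(father); mo <- alleles(mother)
  counts <- c(`0` = 0, `1` = 0, `2` = 0)
  for (i in 1:2) for (j in 1:2) {
    x <- fa[i] + mo[j]
    counts[x + 1] <- counts[x + 1] + 0.25
  }
  m <- sum((0:2) * counts)
  list(probs = counts, mean = m, var = sum((0:2)^2 * counts) - m^2)
}

# Family-score scenario used by several fbat tests: n trios, both parents
# heterozygous at every marker, explicit child dosages and child traits.
# Parent trait values are set to -T/2 so the supplied trait is centered and
# family_scores uses the child values verbatim.
het_trio_ped <- function(n) {
  pedigree_set(data.frame(
    fid = rep(paste0("f", seq_len(n)), each = 3),
    iid = paste0(rep(c("dad", "mum", "kid"), n), rep(seq_len(n), each = 3)),
    father = as.vector(rbind(NA, NA, paste0("dad", seq_len(n)))),
    mother = as.vector(rbind(NA, NA, paste0("mum", seq_len(n)))),
    sex = rep(c("male", "female", "unknown"), n),
    stringsAsFactors = FALSE))
}

het_trio_scores <- function(child_dosages, traits, n_markers = 1) {
  child_dosages <- matrix(child_dosages, ncol = n_markers)
  n <- nrow(child_dosages)
  ped <- het_trio_ped(n)
  dos <- matrix(1, 3 * n, n_markers)
  rownames(dos) <- ped$persons$iid
  dos[paste0("kid", seq_len(n)), ] <- child_dosages
  geno <- make_geno(dos)
  tv <- as.vector(rbind(-traits / 2, -traits / 2, traits))
  trait <- make_trait(ped$persons$iid, tv, fid = ped$persons$fid)
  family_scores(decompose_nuclear(ped), geno, trait)
}
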