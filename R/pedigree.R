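#' Construct and validate a pedigree set
#'
#' @param persons data.frame with columns `fid`, `iid`, `father`, `mother`
#'   (iid or NA), `sex` ("male"/"female"/"unknown"). (fid, iid) must be
#'   unique, parent references must resolve within the same fid, and the
#'   parent graph must be acyclic.
#' @return An object of class `pedigree_set`: list with `persons` (the
#'   validated frame plus a logical `founder` column and a global `pid` key
#'   "fid:iid") and `fids`.
#' @export
pedigree_set <- function(persons) {
  need <- c("fid", "iid", "father", "mother", "sex")
  miss <- setdiff(need, names(persons))
  if (length(miss) > 0) stop("persons table missing column(s): ", paste(miss, collapse = ", "))
  p <- persons[need]
  p$fid <- as.character(p$fid); p$iid <- as.character(p$iid)
  p$father <- as.character(p$father); p$mother <- as.character(p$mother)
  key <- paste(p$fid, p$iid, sep = ":")
  if (anyDuplicated(key)) stop("(fid, iid) pairs must be unique")
  if (any(!is.na(p$father) & p$father == p$iid) ||
      any(!is.na(p$mother) & p$mother == p$iid)) {
    stop("pedigree structure error: individual listed as its own parent")
  }
  fkey <- ifelse(is.na(p$father), NA, paste(p$fid, p$father, sep = ":"))
  mkey <- ifelse(is.na(p$mother), NA, paste(p$fid, p$mother, sep = ":"))
  dangling <- c(stats::na.omit(fkey), stats::na.omit(mkey))
  dangling <- setdiff(dangling, key)
  if (length(dangling) > 0) {
    stop("pedigree structure error: parent id(s) not present: ",
         paste(dangling, collapse = ", "))
  }
  half <- xor(is.na(p$father), is.na(p$mother))
  if (any(half)) stop("persons must have either both parents or neither")
  p$founder <- is.na(p$father) & is.na(p$mother)
  p$pid <- key
  depth <- .generation_depth(key, fkey, mkey)  # errors on cycles
  p$depth <- depth
  rownames(p) <- NULL
  structure(list(persons = p, fids = unique(p$fid)), class = "pedigree_set")
}

# Longest ancestor-chain depth per person; detects cycles.
.generation_depth <- function(key, fkey, mkey) {
  n <- length(key)
  fi <- match(fkey, key); mi <- match(mkey, key)
  depth <- ifelse(is.na(fi) & is.na(mi), 0L, NA_integer_)
  for (iter in seq_len(n + 1)) {
    todo <- which(is.na(depth))
    if (length(todo) == 0) return(depth)
    pf <- depth[fi[todo]]; pm <- depth[mi[todo]]
    ready <- !is.na(pf) & !is.na(pm)
    if (!any(ready)) stop("pedigree structure error: cycle detected")
    depth[todo[ready]] <- pmax(pf[ready], pm[ready]) + 1L
  }
  stop("pedigree structure error: cycle detected")
}

#' @method print pedigree_set
#' @export
print.pedigree_set <- function(x, ...) {
  cat("pedigree_set:", nrow(x$persons), "persons in", length(x$fids),
      "pedigree(s);", sum(x$persons$founder), "founders\n")
  invisible(x)
}

#' Decompose pedigrees into nuclear families
#'
#' Every nonfounder appears as offspring in exactly one nuclear family (the
#' one defined by its parent pair); an individual may additionally appear as
#' a parent in another family. This is the decomposition under which
#' family-based tests treat nuclear families within a pedigree as
#' independent scoring units.
#'
#' @param ped A `pedigree_set`.
#' @return List of `nuclear_family` objects: list(fid, father, mother,
#'   offspring) with iids.
#' @export
decompose_nuclear <- function(ped) {
  p <- ped$persons
  kids <- p[!p$founder, , drop = FALSE]
  if (nrow(kids) == 0) return(list())
  grp <- paste(kids$fid, kids$father, kids$mother, sep = "\r")
  split_idx <- split(seq_len(nrow(kids)), grp)
  fams <- lapply(split_idx, function(ix) {
    structure(list(
      fid = kids$fid[ix[1]],
      father = kids$father[ix[1]],
      mother = kids$mother[ix[1]],
      offspring = kids$iid[ix]
    ), class = "nuclear_family")
  })
  # deterministic order: by fid then father/mother id
  ord <- order(vapply(fams, `[[`, "", "fid"),
               vapply(fams, `[[`, "", "father"),
               vapply(fams, `[[`, "", "mother"))
  unname(fams[ord])
}

#' Check offspring genotypes for Mendelian consistency
#'
#' A child dosage is impossible when it lies outside the range of dosages
#' reachable from the parental pair (each parent transmits 0 or 1 copies of
#' the counted allele according to its own dosage). Markers where either
#' parent is ungenotyped are not checked.
#'
#' @param family A `nuclear_family`.
#' @param geno A `genotype_matrix` containing the family members.
#' @return data.frame of violations with columns `iid`, `vid`, `child`,
#'   `father`, `mother` (zero rows when consistent).
#' @export
mendel_check <- function(family, geno) {
  d <- geno$dosage
  have <- function(i) i %in% rownames(d)
  if (!have(family$father) || !have(family$mother)) {
    return(data.frame(iid = character(0), vid = character(0), child = numeric(0),
                      father = numeric(0), mother = numeric(0)))
  }
  df <- d[family$father, ]
  dm <- d[family$mother, ]
  lo <- .transmit_min(df) + .transmit_min(dm)
  hi <- .transmit_max(df) + .transmit_max(dm)
  out <- list()
  for (kid in intersect(family$offspring, rownames(d))) {
    x <- d[kid, ]
    bad <- which(!is.na(x) & !is.na(lo) & (x < lo | x > hi))
    if (length(bad) > 0) {
      out[[kid]] <- data.frame(iid = kid, vid = colnames(d)[bad],
                               child = x[bad], father = df[bad], mother = dm[bad],
                               stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) {
    return(data.frame(iid = character(0), vid = character(0), child = numeric(0),
                      father = numeric(0), mother = numeric(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

.transmit_min <- function(d) ifelse(is.na(d), NA, ifelse(d == 2, 1, 0))
.transmit_max <- function(d) ifelse(is.na(d), NA, ifelse(d == 0, 0, 1))

#' Kinship matrix of a pedigree set
#'
#' Recursive kinship coefficients: founders are mutually unrelated and
#' non-inbred persons have self-kinship 1/2. Persons from different
#' pedigrees have kinship 0 (the matrix is block diagonal).
#'
#' @param ped A `pedigree_set`.
#' @return Symmetric matrix of kinship coefficients, dimnames = iid within
#'   "fid:iid" keys.
#' @export
kinship <- function(ped) {
  p <- ped$persons
  n <- nrow(p)
  ord <- order(p$depth)
  key <- p$pid[ord]
  fi <- match(ifelse(is.na(p$father[ord]), NA,
                     paste(p$fid[ord], p$father[ord], sep = ":")), key)
  mi <- match(ifelse(is.na(p$mother[ord]), NA,
                     paste(p$fid[ord], p$mother[ord], sep = ":")), key)
  phi <- matrix(0, n, n, dimnames = list(key, key))
  for (i in seq_len(n)) {
    if (is.na(fi[i])) {
      phi[i, i] <- 0.5
    } else {
      phi[i, i] <- 0.5 * (1 + phi[fi[i], mi[i]])
      js <- seq_len(i - 1L)
      v <- 0.5 * (phi[fi[i], js] + phi[mi[i], js])
      phi[i, js] <- v
      phi[js, i] <- v
    }
  }
  # return in the original person order
  back <- match(p$pid, key)
  phi[back, back, drop = FALSE]
}
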