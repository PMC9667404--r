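# Haploid genotype matrices: polarized 0/1/NA calls over short unlinked loci.

#' Construct a haploid genotype matrix
#'
#' The central data container: one haploid call per sample per site, coded
#' `0` (ancestral), `1` (derived) or `NA` (missing). Sites carry a locus
#' identifier, a 1-based position within the locus, and the ancestral and
#' derived alleles inferred from an outgroup-aligned reference.
#'
#' @param calls integer matrix, samples in rows, sites in columns, values in
#'   `{0, 1, NA}`.
#' @param sites data.frame with columns `locus_id`, `position`,
#'   `ancestral_allele`, `derived_allele`; one row per column of `calls`.
#' @param samples character vector of sample identifiers (row names).
#' @return an object of class `haplo_matrix`.
#' @export
haplo_matrix <- function(calls, sites, samples = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(samples)) stop("sample identifiers are required")
  samples <- as.character(samples)
  if (nrow(calls) != length(samples)) stop("calls rows must match samples")
  required <- c("locus_id", "position", "ancestral_allele", "derived_allele")
  if (!all(required %in% names(sites))) {
    stop("sites must have columns: ", paste(required, collapse = ", "))
  }
  sites <- as.data.frame(sites)[required]
  sites$locus_id <- as.character(sites$locus_id)
  sites$position <- as.integer(sites$position)
  if (ncol(calls) != nrow(sites)) stop("calls columns must match sites rows")
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% c(0L, 1L))) {
    stop("calls must be 0, 1 or NA")
  }
  # positions strictly increasing within each locus
  if (nrow(sites) > 1L) {
    same <- sites$locus_id[-1L] == sites$locus_id[-nrow(sites)]
    if (any(same & diff(sites$position) <= 0L)) {
      stop("positions within a locus must be strictly increasing")
    }
  }
  dimnames(calls) <- list(samples, NULL)
  structure(list(calls = calls, sites = sites, samples = samples),
            class = "haplo_matrix")
}

#' @export
print.haplo_matrix <- function(x, ...) {
  cat(sprintf("haplo_matrix: %d samples x %d sites (%d loci), %.1f%% missing\n",
              n_samples(x), n_sites(x), length(unique(x$sites$locus_id)),
              100 * mean(is.na(x$calls))))
  invisible(x)
}

#' Number of samples / sites in a haploid matrix
#' @param m a `haplo_matrix`.
#' @return integer scalar.
#' @export
n_samples <- function(m) length(m$samples)

#' @rdname n_samples
#' @export
n_sites <- function(m) nrow(m$sites)

#' Subset a haploid matrix by samples or by site index
#'
#' Order of retained samples/sites follows the matrix, not the request.
#'
#' @param m a `haplo_matrix`.
#' @param samples character vector of sample ids to keep.
#' @param idx integer or logical index over sites.
#' @return a `haplo_matrix`.
#' @export
subset_samples <- function(m, samples) {
  keep <- m$samples %in% samples
  if (!any(keep)) stop("no matching samples")
  haplo_matrix(m$calls[keep, , drop = FALSE], m$sites, m$samples[keep])
}

#' @rdname subset_samples
#' @export
subset_sites <- function(m, idx) {
  haplo_matrix(m$calls[, idx, drop = FALSE],
               m$sites[idx, , drop = FALSE], m$samples)
}

#' Read a haploid SNP matrix
#'
#' Two on-disk dialects are supported.
#'
#' `tabular`: tab-separated, header row
#' `locus_id  position  ancestral_allele  derived_allele  <sample ids...>`,
#' then one row per site with calls in `{0, 1, .}` (`.` = missing).
#'
#' `vcf`: a VCF with haploid GT fields (`0`, `1` or `.`; any diploid
#' genotype is an error). The ancestral allele is taken from the `AA` INFO
#' tag when present, else the REF allele. Sites whose ancestral allele
#' matches neither REF nor ALT, and multi-allelic sites, are dropped with a
#' message; calls are recoded so 0 = ancestral. The locus identifier is the
#' CHROM field (one RAD locus per contig/chromosome entry).
#'
#' @param path file path.
#' @param format `"tabular"` or `"vcf"`.
#' @return a `haplo_matrix`; attribute `n_dropped` counts sites discarded
#'   during polarization.
#' @export
read_matrix <- function(path, format = c("tabular", "vcf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "tabular") read_matrix_tabular(path) else read_matrix_vcf(path)
}

read_matrix_tabular <- function(path) {
  tab <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                    colClasses = "character", comment.char = "#")
  fixed <- c("locus_id", "position", "ancestral_allele", "derived_allele")
  if (!all(fixed %in% names(tab))) {
    stop("malformed tabular matrix (header line 1): expected columns ",
         paste(fixed, collapse = ", "))
  }
  samples <- setdiff(names(tab), fixed)
  if (!length(samples)) stop("malformed tabular matrix: no sample columns")
  callchar <- as.matrix(tab[samples])
  ok <- matrix(callchar %in% c("0", "1", "."), nrow(callchar))
  if (!all(ok)) {
    bad <- which(!ok, arr.ind = TRUE)
    stop(sprintf("parse error at data line %d: call '%s' is not 0/1/.",
                 bad[1L, "row"], callchar[bad[1L, "row"], bad[1L, "col"]]))
  }
  callchar[callchar == "."] <- NA_character_
  calls <- t(matrix(as.integer(callchar), nrow(callchar), ncol(callchar)))
  m <- haplo_matrix(calls, tab[fixed], samples)
  attr(m, "n_dropped") <- 0L
  m
}

read_matrix_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (any(grepl("[/|]", gt), na.rm = TRUE)) {
    stop("format error: diploid genotype encountered; haploid calls required")
  }
  info_aa <- sub(".*(?:^|;)AA=([^;]*).*", "\\1", fix$INFO)
  has_aa <- grepl("(^|;)AA=", fix$INFO)
  anc <- toupper(ifelse(has_aa, info_aa, fix$REF))
  multi <- grepl(",", fix$ALT)
  unpol <- !(anc == toupper(fix$REF) | anc == toupper(fix$ALT))
  keep <- !multi & !unpol & !is.na(fix$ALT) & fix$ALT != "."
  n_dropped <- sum(!keep)
  if (n_dropped) {
    message(sprintf(
      "read_matrix: dropped %d site(s) (%d multi-allelic, %d without a usable ancestral state)",
      n_dropped, sum(multi), sum(unpol & !multi)))
  }
  fix <- fix[keep, , drop = FALSE]
  gt <- gt[keep, , drop = FALSE]
  anc <- anc[keep]
  flip <- anc == toupper(fix$ALT)  # ALT is ancestral: recode so 0 = ancestral
  num <- matrix(NA_integer_, nrow(gt), ncol(gt))
  num[gt == "0"] <- 0L
  num[gt == "1"] <- 1L
  num[flip, ] <- 1L - num[flip, , drop = FALSE]
  der <- ifelse(flip, toupper(fix$REF), toupper(fix$ALT))
  sites <- data.frame(locus_id = fix$CHROM,
                      position = as.integer(fix$POS),
                      ancestral_allele = anc,
                      derived_allele = der,
                      stringsAsFactors = FALSE)
  ord <- order(sites$locus_id, sites$position)
  m <- haplo_matrix(t(num)[, ord, drop = FALSE], sites[ord, ], colnames(gt))
  attr(m, "n_dropped") <- n_dropped
  m
}

#' Write a haploid matrix in the tabular dialect
#'
#' @param m a `haplo_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  callchar <- t(m$calls)
  callchar[] <- as.character(callchar)
  callchar[is.na(callchar)] <- "."
  out <- cbind(m$sites, as.data.frame(callchar, stringsAsFactors = FALSE))
  names(out) <- c(names(m$sites), m$samples)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a sample-to-population map
#'
#' Two-column tab-separated file (`sample`, `population`), no header.
#' The population order of the returned map is the order of first
#' appearance in the file.
#'
#' @param path file path.
#' @return a data.frame with columns `sample` and `population`, class
#'   `pop_map`; `levels(factor())` order is preserved via the
#'   `populations` attribute.
#' @export
read_popmap <- function(path) {
  tab <- read.table(path, header = FALSE, sep = "\t",
                    colClasses = "character", col.names = c("sample", "population"))
  pop_map(setNames(tab$population, tab$sample))
}

#' @rdname read_popmap
#' @param pmap a `pop_map`.
#' @export
write_popmap <- function(pmap, path) {
  write.table(data.frame(pmap$sample, pmap$population), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a population map
#'
#' @param assignments named character vector: names are sample ids, values
#'   are population labels.
#' @return a `pop_map` data.frame with attribute `populations` (ordered
#'   labels, first appearance order).
#' @export
pop_map <- function(assignments) {
  if (is.null(names(assignments)) || anyDuplicated(names(assignments))) {
    stop("assignments must be uniquely named by sample")
  }
  out <- data.frame(sample = names(assignments),
                    population = unname(as.character(assignments)),
                    stringsAsFactors = FALSE)
  structure(out, populations = unique(out$population),
            class = c("pop_map", "data.frame"))
}

#' Samples belonging to one population
#' @param pmap a `pop_map`.
#' @param pop population label.
#' @return character vector of sample ids.
#' @export
pop_samples <- function(pmap, pop) {
  if (!pop %in% pmap$population) stop("unknown population: ", pop)
  pmap$sample[pmap$population == pop]
}

#' Per-locus sample presence filter
#'
#' A locus is "present" in a sample if the sample has at least one
#' non-missing call at that locus; loci present in fewer than
#' `min_fraction` of samples are discarded (the standard RAD-seq
#' missing-data filter; the default reproduces an 80% threshold).
#'
#' @param m a `haplo_matrix`.
#' @param min_fraction minimum fraction of samples, in `(0, 1]`. A value of
#'   0 is treated as "any presence".
#' @return the filtered `haplo_matrix`; attribute `n_loci_dropped` records
#'   how many loci were removed.
#' @export
filter_locus_presence <- function(m, min_fraction = 0.8) {
  if (n_sites(m) == 0L) stop("empty matrix")
  if (min_fraction < 0 || min_fraction > 1) stop("min_fraction must be in (0, 1]")
  locus <- factor(m$sites$locus_id, levels = unique(m$sites$locus_id))
  called <- !is.na(m$calls)  # samples x sites
  # per (sample, locus): any called site
  pres <- vapply(split(seq_len(n_sites(m)), locus), function(ix) {
    sum(rowSums(called[, ix, drop = FALSE]) > 0L)
  }, integer(1))
  frac <- pres / n_samples(m)
  keep_locus <- if (min_fraction == 0) frac > 0 else frac >= min_fraction
  keep <- locus %in% levels(locus)[keep_locus]
  out <- subset_sites(m, keep)
  attr(out, "n_loci_dropped") <- sum(!keep_locus)
  out
}

#' Thin a matrix to one SNP per locus
#'
#' Selects one site per locus uniformly at random; the same seed always
#' yields the same selection. Used to build quasi-independent site sets for
#' likelihood evaluation and for block-resampling statistics.
#'
#' @param m a `haplo_matrix`.
#' @param seed integer seed.
#' @return a `haplo_matrix` with exactly one site per locus.
#' @export
one_snp_per_locus <- function(m, seed) {
  locus <- factor(m$sites$locus_id, levels = unique(m$sites$locus_id))
  idx <- split(seq_len(n_sites(m)), locus)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(as.integer(seed))
  pick <- vapply(idx, function(ix) if (length(ix) == 1L) ix else ix[sample.int(length(ix), 1L)],
                 integer(1))
  subset_sites(m, sort(pick))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
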