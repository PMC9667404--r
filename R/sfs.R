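# Unfolded joint site-frequency spectra with hypergeometric projection.

#' Construct a joint SFS object
#'
#' A d-dimensional table over derived-allele counts `0..n_k` per population
#' axis. Observed spectra hold (possibly fractional) site counts; expected
#' spectra hold proportions over polymorphic cells.
#'
#' @param counts numeric array with `dim = sample_sizes + 1`.
#' @param pop_labels character vector, one per axis.
#' @param sample_sizes integer haploid projection size per axis.
#' @param is_expected logical; `TRUE` for expected-proportion spectra.
#' @return an object of class `joint_sfs`.
#' @export
joint_sfs <- function(counts, pop_labels, sample_sizes, is_expected = FALSE) {
  counts <- as.array(counts)
  sample_sizes <- as.integer(sample_sizes)
  if (length(pop_labels) != length(sample_sizes)) {
    stop("pop_labels and sample_sizes must have equal length")
  }
  if (!identical(dim(counts), sample_sizes + 1L)) {
    dim(counts) <- sample_sizes + 1L
  }
  if (any(counts < 0)) stop("SFS entries must be non-negative")
  structure(list(counts = counts, pop_labels = as.character(pop_labels),
                 sample_sizes = sample_sizes, is_expected = isTRUE(is_expected)),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat(sprintf("joint_sfs (%s): %s; total mass %.4g (%.4g polymorphic)\n",
              if (x$is_expected) "expected proportions" else "observed counts",
              paste0(x$pop_labels, "=", x$sample_sizes, collapse = ", "),
              sum(x$counts), sum(x$counts[sfs_polymorphic_mask(x)])))
  invisible(x)
}

#' Logical mask over the polymorphic cells of a joint SFS
#'
#' Excludes the two monomorphic corners: all-ancestral (index 0 on every
#' axis) and all-derived (index `n_k` on every axis).
#'
#' @param j a `joint_sfs`.
#' @return logical array shaped like `j$counts`.
#' @export
sfs_polymorphic_mask <- function(j) {
  mask <- array(TRUE, dim = dim(j$counts))
  mask[1L] <- FALSE
  mask[length(mask)] <- FALSE
  mask
}

#' Hypergeometric projection of one site
#'
#' Distribution of the derived-allele count in a draw of `n_proj` alleles
#' taken without replacement from the `n_obs` non-missing alleles observed
#' at a site, `d_obs` of which are derived. This is how spectra are
#' projected down to a common sample size in the presence of missing data.
#'
#' @param n_obs non-missing allele count at the site.
#' @param d_obs derived-allele count among them.
#' @param n_proj projection size.
#' @return numeric vector of probabilities over derived counts `0..n_proj`;
#'   sums to one.
#' @export
project_site <- function(n_obs, d_obs, n_proj) {
  if (d_obs < 0 || d_obs > n_obs) stop("d_obs must lie in [0, n_obs]")
  if (n_proj > n_obs) stop("site not projectable: n_proj > n_obs")
  dhyper(0:n_proj, m = d_obs, n = n_obs - d_obs, k = n_proj)
}

#' Build an unfolded joint SFS from a genotype matrix
#'
#' Every usable site (each population has at least `projections[k]`
#' non-missing calls) contributes its product-of-hypergeometrics mass to
#' the table (`method = "expected"`, the default, deterministic) or one
#' random draw of `projections[k]` alleles per population
#' (`method = "sampled"`). Sites failing the projection precondition are
#' skipped and counted.
#'
#' @param m a `haplo_matrix`, polarized (0 = ancestral).
#' @param pmap a `pop_map` covering the samples of `m`.
#' @param projections named integer vector: haploid projection size per
#'   population; names select which populations form the SFS axes.
#' @param mode `"all_snps"` or `"one_per_locus"`.
#' @param seed integer; required for `mode = "one_per_locus"` and
#'   `method = "sampled"`.
#' @param method `"expected"` (fractional masses) or `"sampled"` (one
#'   random subsample of individuals per site).
#' @return a `joint_sfs` with attributes `n_sites_used` and `n_skipped`.
#' @export
build_joint_sfs <- function(m, pmap, projections,
                            mode = c("all_snps", "one_per_locus"),
                            seed = NULL,
                            method = c("expected", "sampled")) {
  mode <- match.arg(mode)
  method <- match.arg(method)
  pops <- names(projections)
  if (is.null(pops)) stop("projections must be named by population")
  missing_pop <- setdiff(pops, unique(pmap$population))
  if (length(missing_pop)) stop("population absent from map: ", missing_pop[1L])
  if (mode == "one_per_locus") {
    if (is.null(seed)) stop("mode 'one_per_locus' needs a seed")
    m <- one_snp_per_locus(m, derive_seed(seed, "one_per_locus"))
  }
  sample_sets <- lapply(pops, function(p) {
    s <- intersect(m$samples, pop_samples(pmap, p))
    if (!length(s)) stop("population absent from matrix: ", p)
    s
  })
  if (any(vapply(sample_sets, length, 1L) < projections)) {
    stop("projections exceed per-population sample counts")
  }
  d <- length(pops)
  dims <- as.integer(projections) + 1L
  counts <- array(0, dim = dims)
  # per-pop derived and called counts for every site
  dmat <- vapply(sample_sets, function(s) {
    colSums(m$calls[s, , drop = FALSE] == 1L, na.rm = TRUE)
  }, numeric(n_sites(m)))
  nmat <- vapply(sample_sets, function(s) {
    colSums(!is.na(m$calls[s, , drop = FALSE]))
  }, numeric(n_sites(m)))
  dmat <- matrix(dmat, ncol = d)
  nmat <- matrix(nmat, ncol = d)
  usable <- rowSums(nmat >= rep(as.integer(projections), each = nrow(nmat))) == d
  n_skipped <- sum(!usable)
  strides <- cumprod(c(1L, dims[-d]))
  if (method == "sampled") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    if (is.null(seed)) stop("method 'sampled' needs a seed")
    set.seed(derive_seed(seed, "sfs_sampled"))
  }
  for (s in which(usable)) {
    if (method == "expected") {
      mass <- 1
      for (k in seq_len(d)) {
        mass <- outer(mass, project_site(nmat[s, k], dmat[s, k], projections[[k]]))
      }
      counts <- counts + as.vector(mass)
    } else {
      cellidx <- 1L
      for (k in seq_len(d)) {
        alleles <- c(rep(1L, dmat[s, k]), rep(0L, nmat[s, k] - dmat[s, k]))
        draw <- sum(alleles[sample.int(length(alleles), projections[[k]])])
        cellidx <- cellidx + draw * strides[k]
      }
      counts[cellidx] <- counts[cellidx] + 1
    }
  }
  out <- joint_sfs(counts, pops, as.integer(projections), is_expected = FALSE)
  attr(out, "n_sites_used") <- sum(usable)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Marginal SFS of one population axis
#'
#' Sums the joint table over all other axes; total mass is preserved.
#'
#' @param j a `joint_sfs`.
#' @param pop population label of the axis to keep.
#' @return a one-dimensional `joint_sfs`.
#' @export
marginal_sfs <- function(j, pop) {
  k <- match(pop, j$pop_labels)
  if (is.na(k)) stop("unknown population label: ", pop)
  v <- apply(j$counts, k, sum)
  joint_sfs(array(v, dim = length(v)), pop, j$sample_sizes[k], j$is_expected)
}

#' Read / write the plain-text joint SFS format
#'
#' Header comments give the population labels, projection sizes, and the
#' expected/observed flag, then one whitespace-separated run of entries in
#' row-major order (last axis fastest), so small fixtures are
#' hand-checkable.
#'
#' @param j a `joint_sfs`.
#' @param path file path.
#' @param comments optional extra header comment lines (provenance).
#' @return `path` (write) or a `joint_sfs` (read).
#' @export
write_sfs <- function(j, path, comments = character()) {
  d <- length(j$sample_sizes)
  flat <- as.vector(aperm(j$counts, rev(seq_len(d))))  # row-major
  lines <- c(paste0("# ", comments),
             paste("#labels:", paste(j$pop_labels, collapse = " ")),
             paste("#sizes:", paste(j$sample_sizes, collapse = " ")),
             paste("#expected:", if (j$is_expected) "1" else "0"),
             paste(format(flat, digits = 17, trim = TRUE, scientific = FALSE),
                   collapse = " "))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sfs
#' @export
read_sfs <- function(path) {
  lines <- readLines(path)
  grab <- function(key) {
    ln <- grep(paste0("^#", key, ":"), lines, value = TRUE)
    if (!length(ln)) stop("malformed SFS file: missing #", key)
    strsplit(sub(paste0("^#", key, ":\\s*"), "", ln[1L]), "\\s+")[[1L]]
  }
  labels <- grab("labels")
  sizes <- as.integer(grab("sizes"))
  expected <- grab("expected") == "1"
  datalines <- lines[!grepl("^#", lines) & nzchar(lines)]
  flat <- as.numeric(strsplit(paste(datalines, collapse = " "), "\\s+")[[1L]])
  d <- length(sizes)
  arr <- array(flat, dim = rev(sizes + 1L))
  arr <- aperm(arr, rev(seq_len(d)))
  joint_sfs(arr, labels, sizes, expected)
}
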