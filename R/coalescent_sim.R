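# R-side interface to the structured-coalescent core: expected spectra,
# sampled spectra, genotype simulation, Monte-Carlo error.

run_core <- function(comp, n_sims, mode, seed, theta = 0, n_batches = 0L) {
  .coal_core(comp$ne0, comp$lin_deme, comp$lin_cell, comp$ncells,
             comp$events, comp$mig, as.integer(n_sims), as.integer(mode),
             theta, comp$locus_length, as.numeric(seed), as.integer(n_batches))
}

#' Expected joint SFS under a demographic model
#'
#' Simulates `n_sims` independent genealogies of the model's sample under
#' the structured coalescent and accumulates every branch's length into
#' the SFS cell indexed by its descendant counts per population. Under the
#' infinite-sites model the expected SFS over polymorphic cells is the
#' normalized branch-length table, independent of the mutation rate. The
#' result is deterministic given the seed.
#'
#' @param spec a `model_spec` (all parameters fixed, or `values` supplied).
#' @param n_sims number of genealogies.
#' @param seed integer seed.
#' @param values named numeric values for free parameters.
#' @param sample_sizes,sfs_pops optional overrides (see
#'   [compile_model()]).
#' @param n_batches batches retained for [mc_standard_error()].
#' @return an expected-proportion `joint_sfs` (polymorphic cells sum to
#'   one) with attributes `n_sims`, `mean_total_length`, and `batches`.
#' @export
simulate_expected_sfs <- function(spec, n_sims, seed, values = NULL,
                                  sample_sizes = NULL, sfs_pops = NULL,
                                  n_batches = 20L) {
  comp <- compile_model(spec, values, sample_sizes, sfs_pops)
  res <- run_core(comp, n_sims, 0L, seed, n_batches = min(n_batches, n_sims))
  arr <- array(res$sfs, dim = comp$dims)
  out <- joint_sfs(arr, comp$sfs_pops, comp$sample_sizes, is_expected = TRUE)
  mask <- sfs_polymorphic_mask(out)
  tot <- sum(out$counts[mask])
  out$counts[!mask] <- 0
  if (tot > 0) out$counts <- out$counts / tot
  attr(out, "n_sims") <- res$n_sims
  attr(out, "mean_total_length") <- res$mean_total_length
  # expected branch length (per locus) carrying polymorphic-cell mutations:
  # feeds the optional Poisson total-count likelihood term
  attr(out, "poly_length_per_locus") <- tot / res$n_sims
  attr(out, "mutation_rate") <- spec$mutation_rate
  attr(out, "locus_length") <- comp$locus_length
  if (!is.null(res$batches)) attr(out, "batches") <- res$batches
  out
}

#' Sampled (observed-style) joint SFS under a demographic model
#'
#' One genealogy per unlinked locus; mutations are dropped on branches as
#' a Poisson process with rate `mutation_rate * locus_length * branch
#' length` (infinite sites), and each mutation increments the SFS cell of
#' its branch. Integer counts, reproducible by seed.
#'
#' @inheritParams simulate_expected_sfs
#' @param n_loci number of unlinked loci.
#' @return an observed-count `joint_sfs` with attribute
#'   `mean_total_length`.
#' @export
sample_observed_sfs <- function(spec, n_loci, seed, values = NULL,
                                sample_sizes = NULL, sfs_pops = NULL) {
  comp <- compile_model(spec, values, sample_sizes, sfs_pops)
  theta <- comp$mutation_rate * comp$locus_length
  res <- run_core(comp, n_loci, 1L, seed, theta = theta)
  out <- joint_sfs(array(res$sfs, dim = comp$dims), comp$sfs_pops,
                   comp$sample_sizes, is_expected = FALSE)
  attr(out, "n_sims") <- res$n_sims
  attr(out, "n_loci") <- as.integer(n_loci)
  attr(out, "mean_total_length") <- res$mean_total_length
  out
}

#' Monte-Carlo standard error of an expected SFS
#'
#' Per-cell between-batch standard error of the expected proportions,
#' from the batch decomposition stored by [simulate_expected_sfs()].
#'
#' @param j an expected `joint_sfs` carrying a `batches` attribute.
#' @return numeric array of per-cell standard errors, shaped like the SFS.
#' @export
mc_standard_error <- function(j) {
  b <- attr(j, "batches")
  if (is.null(b)) stop("SFS carries no batch decomposition; rerun simulate_expected_sfs with n_batches > 1")
  mask <- as.vector(sfs_polymorphic_mask(j))
  tot <- rowSums(b[, mask, drop = FALSE])
  props <- b / tot
  props[, !mask] <- 0
  nb <- nrow(b)
  se <- apply(props, 2L, sd) / sqrt(nb)
  array(se, dim = dim(j$counts))
}

#' Simulate raw haploid genotypes under a demographic model
#'
#' One genealogy per locus with infinite-sites mutations at distinct
#' positions; returns the per-locus 0/1 haplotypes for every sampled
#' lineage, the substrate for the synthetic-data generator.
#'
#' @inheritParams sample_observed_sfs
#' @return list with `locus` (integer locus index per site), `position`
#'   (1-based within locus), `geno` (samples x sites 0/1 matrix),
#'   `pop_of_sample`, and `mean_total_length`.
#' @export
simulate_genotypes <- function(spec, n_loci, seed, values = NULL,
                               sample_sizes = NULL) {
  comp <- compile_model(spec, values, sample_sizes)
  theta <- comp$mutation_rate * comp$locus_length
  res <- run_core(comp, n_loci, 2L, seed, theta = theta)
  list(locus = res$locus, position = res$position,
       geno = t(res$geno),  # samples x sites
       pop_of_sample = comp$pop_of_sample,
       locus_length = comp$locus_length,
       n_loci = n_loci,
       mean_total_length = res$mean_total_length)
}
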