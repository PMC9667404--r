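# Synthetic RAD-like haploid SNP datasets with known demographic truth.

#' Describe a synthetic dataset with known truth
#'
#' Bundles a generating `model_spec` with the dataset-shape settings:
#' number of short unlinked loci, locus length, whole-locus dropout
#' probability (RAD-style allele dropout: a sample misses an entire locus
#' or none of it), and the seed. `(truth, seed)` regenerates the identical
#' dataset.
#'
#' @param spec generating `model_spec` (all parameters fixed); its
#'   `sample_sizes` define the sample layout.
#' @param seed integer seed.
#' @param n_loci number of loci.
#' @param locus_length locus length in bp (defaults to the spec's).
#' @param missingness per-sample per-locus dropout probability.
#' @return an object of class `synthetic_truth`.
#' @export
synthetic_truth <- function(spec, seed, n_loci = 1000L, locus_length = NULL,
                            missingness = 0.1) {
  stopifnot(n_loci >= 1L, missingness >= 0, missingness < 1)
  if (!is.null(locus_length)) spec$locus_length <- as.integer(locus_length)
  structure(list(spec = spec, seed = as.integer(seed),
                 n_loci = as.integer(n_loci),
                 locus_length = spec$locus_length,
                 missingness = missingness,
                 sample_layout = spec$sample_sizes),
            class = "synthetic_truth")
}

#' Paper-shaped generating model
#'
#' The default emulation preset: three focal populations (a large
#' recurvum-like species REC and two flexuosum-like populations ENA and
#' EUR) plus a deep-diverged outgroup OUT, under the secondary-contact
#' history that the three-population zoo calls "model 10": gene flow from
#' ENA to EUR, from ENA to REC, and from REC into the flexuosum ancestor
#' during a contact window that follows an isolation period. Effective
#' sizes and divergence times are set so that, at the standard moss
#' mutation rate of 2.8e-8 per site per generation, roughly one SNP per
#' 90-bp locus segregates — the density of a typical RAD assembly.
#'
#' @param sample_sizes named haploid sample counts (defaults mirror a
#'   60-sample study layout plus outgroup).
#' @return a `model_spec` including the outgroup deme.
#' @export
paper_shape_spec <- function(sample_sizes = c(REC = 16, ENA = 28, EUR = 16,
                                              OUT = 3)) {
  model_spec(
    populations = list(REC = "N_REC", ENA = "N_ENA", EUR = "N_EUR",
                       OUT = "N_OUT"),
    divergences = list(
      list(time = "T_FLEX", child = "EUR", parent = "ENA"),
      list(time = "T_SP", child = "ENA", parent = "REC"),
      list(time = "T_OUT", child = "OUT", parent = "REC")),
    size_changes = list(
      list(time = "T_FLEX", pop = "ENA", ne = "N_ANCFLEX"),
      list(time = "T_SP", pop = "REC", ne = "N_ANC")),
    migrations = list(
      list(source = "ENA", dest = "EUR", m = "m_ENA_EUR",
           t_start = 0, t_end = "T_FLEX"),
      list(source = "ENA", dest = "REC", m = "m_ENA_REC",
           t_start = 0, t_end = "T_FLEX"),
      list(source = "REC", dest = "ENA", m = "m_REC_ANC",
           t_start = "T_FLEX", t_end = "T_SC")),
    params = list(N_REC = 20000, N_ENA = 12000, N_EUR = 5000,
                  N_ANCFLEX = 3000, N_ANC = 15000, N_OUT = 15000,
                  T_FLEX = 15000, T_SP = 50000, T_OUT = 150000,
                  T_SC = list(frac = 0.5, from = "T_FLEX", to = "T_SP"),
                  m_ENA_EUR = 1e-3, m_ENA_REC = 1.1e-4, m_REC_ANC = 0.01),
    mutation_rate = 2.8e-8,
    sample_sizes = sample_sizes,
    locus_length = 90L,
    name = "paper_shape_truth")
}

#' Generate a synthetic haploid SNP dataset
#'
#' One coalescent genealogy per locus, Poisson infinite-sites mutations on
#' branches at distinct within-locus positions, whole-locus dropout per
#' sample at the configured missingness, exact polarization (the
#' simulator's ancestral state is state 0). Sites left without any
#' non-missing call after dropout are removed.
#'
#' @param truth a `synthetic_truth`.
#' @return list with `matrix` (a `haplo_matrix`), `popmap` (a `pop_map`)
#'   and `truth` (echoed; `truth$snp_locus_fraction` is filled with the
#'   fraction of loci carrying at least one SNP).
#' @export
generate_dataset <- function(truth) {
  stopifnot(inherits(truth, "synthetic_truth"))
  sim <- simulate_genotypes(truth$spec, truth$n_loci,
                            derive_seed(truth$seed, "genotypes"))
  pops <- sim$pop_of_sample
  samples <- paste0(pops, "_", unlist(lapply(table(factor(pops, unique(pops))),
                                             seq_len)))
  calls <- sim$geno
  rownames(calls) <- samples
  n_loci_with_snp <- length(unique(sim$locus))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(derive_seed(truth$seed, "dropout"))
  if (truth$missingness > 0 && length(sim$locus)) {
    drop <- matrix(runif(length(samples) * truth$n_loci) < truth$missingness,
                   nrow = length(samples))  # samples x loci
    calls[drop[, sim$locus, drop = FALSE]] <- NA_integer_
  }
  # allele letters per site, seeded
  nsite <- length(sim$locus)
  bases <- c("A", "C", "G", "T")
  anc <- bases[sample.int(4L, nsite, replace = TRUE)]
  der <- bases[(match(anc, bases) + sample.int(3L, nsite, replace = TRUE) - 1L) %% 4L + 1L]
  sites <- data.frame(locus_id = sprintf("L%05d", sim$locus),
                      position = sim$position,
                      ancestral_allele = anc,
                      derived_allele = der,
                      stringsAsFactors = FALSE)
  keep <- colSums(!is.na(calls)) > 0L
  m <- haplo_matrix(calls[, keep, drop = FALSE], sites[keep, , drop = FALSE],
                    samples)
  truth$snp_locus_fraction <- n_loci_with_snp / truth$n_loci
  list(matrix = m, popmap = pop_map(setNames(pops, samples)), truth = truth)
}

#' Write a synthetic dataset to disk
#'
#' Emits the tabular matrix, the population map, and a JSON truth record
#' (generating parameter values, seed, shape settings).
#'
#' @param ds result of [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(ds$matrix, file.path(dir, "matrix.tsv"))
  write_popmap(ds$popmap, file.path(dir, "popmap.tsv"))
  tr <- ds$truth
  rec <- list(seed = tr$seed, n_loci = tr$n_loci,
              locus_length = tr$locus_length,
              missingness = tr$missingness,
              sample_layout = as.list(tr$sample_layout),
              model = tr$spec$name,
              params = as.list(resolve_params(tr$spec)),
              snp_locus_fraction = tr$snp_locus_fraction)
  jsonlite::write_json(rec, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
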