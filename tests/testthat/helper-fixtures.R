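# Small in-code fixtures shared across tests.

`%||%` <- function(a, b) if (is.null(a)) b else a

# deterministic 6-sample, 2-locus matrix with known composition
tiny_matrix <- function() {
  calls <- rbind(
    s1 = c(0L, 0L, 1L, 0L, 1L),
    s2 = c(0L, 1L, 1L, 0L, NA),
    s3 = c(0L, 1L, 0L, NA, 1L),
    s4 = c(1L, 0L, 0L, 1L, 0L),
    s5 = c(1L, 0L, NA, 1L, 0L),
    s6 = c(1L, 1L, 0L, 1L, 0L))
  sites <- data.frame(locus_id = c("L1", "L1", "L1", "L2", "L2"),
                      position = c(3L, 10L, 55L, 2L, 71L),
                      ancestral_allele = c("A", "C", "G", "T", "A"),
                      derived_allele = c("T", "G", "A", "C", "G"))
  haplo_matrix(calls, sites)
}

tiny_popmap <- function() {
  pop_map(setNames(rep(c("X", "Y"), each = 3), paste0("s", 1:6)))
}

# random matrix with per-locus missingness at known rates
random_matrix <- function(n_samples = 10, n_loci = 40, snps_per_locus = 3,
                          locus_dropout = 0.3, seed = 99) {
  set.seed(seed)
  n_sites <- n_loci * snps_per_locus
  calls <- matrix(sample(0:1, n_samples * n_sites, replace = TRUE),
                  nrow = n_samples)
  drop <- matrix(runif(n_samples * n_loci) < locus_dropout, nrow = n_samples)
  locus <- rep(seq_len(n_loci), each = snps_per_locus)
  calls[drop[, locus]] <- NA_integer_
  sites <- data.frame(locus_id = sprintf("L%03d", locus),
                      position = rep(seq_len(snps_per_locus) * 7L, n_loci),
                      ancestral_allele = "A", derived_allele = "T")
  haplo_matrix(calls, sites, paste0("s", seq_len(n_samples)))
}

expect_no_violations <- function(spec, values = NULL) {
  expect_identical(validate_model(spec, values), character(0))
}
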