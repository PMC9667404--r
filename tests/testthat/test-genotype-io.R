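test_that("tabular matrix round-trips calls and site metadata exactly", {
  m <- tiny_matrix()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_matrix(m, path)
  m2 <- read_matrix(path, "tabular")
  expect_identical(m2$calls, m$calls)
  expect_identical(m2$sites, m$sites)
  expect_identical(m2$samples, m$samples)
})

test_that("constructor enforces the matrix invariants", {
  m <- tiny_matrix()
  expect_error(haplo_matrix(m$calls + 1L, m$sites, m$samples), "0, 1 or NA")
  bad_sites <- m$sites
  bad_sites$position[2] <- 1L  # not increasing within L1
  expect_error(haplo_matrix(m$calls, bad_sites, m$samples),
               "strictly increasing")
  expect_error(haplo_matrix(m$calls[, 1:3], m$sites, m$samples), "match")
})

test_that("malformed tabular input is reported with its location", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tposition\tancestral_allele\tderived_allele\ts1",
               "L1\t1\tA\tT\t2"), path)
  expect_error(read_matrix(path, "tabular"), "line 1")
  writeLines(c("locus\tpos\ts1", "L1\t1\t0"), path)
  expect_error(read_matrix(path, "tabular"), "malformed")
})

write_test_vcf <- function(path, gts, alt = NULL, info = NULL) {
  n <- ncol(gts)
  alt <- alt %||% rep("T", nrow(gts))
  info <- info %||% rep(".", nrow(gts))
  header <- c("##fileformat=VCFv4.2",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", paste0("s", seq_len(n))), collapse = "\t"))
  rows <- vapply(seq_len(nrow(gts)), function(i) {
    paste(c(sprintf("L%03d", i), "5", ".", "A", alt[i], ".", "PASS",
            info[i], "GT", gts[i, ]), collapse = "\t")
  }, "")
  writeLines(c(header, rows), path)
}

test_that("haploid VCF parsing polarizes on the AA tag and drops unusable sites", {
  path <- withr::local_tempfile(fileext = ".vcf")
  gts <- rbind(c("0", "1", "1"),   # AA=REF: calls kept as-is
               c("0", "1", "."),   # AA=ALT: calls flipped
               c("0", "1", "0"),   # AA matches neither: dropped
               c("0", "0", "1"))   # multi-allelic: dropped
  write_test_vcf(path, gts,
                 alt = c("T", "T", "T", "T,G"),
                 info = c("AA=A", "AA=T", "AA=C", "AA=A"))
  expect_message(m <- read_matrix(path, "vcf"), "dropped 2")
  expect_identical(n_sites(m), 2L)
  expect_identical(attr(m, "n_dropped"), 2L)
  expect_identical(unname(m$calls[, m$sites$locus_id == "L001"]), c(0L, 1L, 1L))
  # flipped site: ancestral is the ALT base, so 0 <-> 1 and missing stays
  expect_identical(unname(m$calls[, m$sites$locus_id == "L002"]), c(1L, 0L, NA))
  expect_identical(m$sites$ancestral_allele[m$sites$locus_id == "L002"], "T")
  expect_identical(m$sites$derived_allele[m$sites$locus_id == "L002"], "A")
})

test_that("diploid genotypes in a VCF are a format error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, rbind(c("0/1", "1", "0")))
  expect_error(suppressWarnings(read_matrix(path, "vcf")), "diploid")
})

test_that("population map round-trips and validates", {
  pm <- tiny_popmap()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_popmap(pm, path)
  pm2 <- read_popmap(path)
  expect_identical(pm2$sample, pm$sample)
  expect_identical(pm2$population, pm$population)
  expect_identical(attr(pm2, "populations"), c("X", "Y"))
  expect_identical(pop_samples(pm, "Y"), c("s4", "s5", "s6"))
  expect_error(pop_samples(pm, "Z"), "unknown population")
  expect_error(pop_map(c(a = "X", a = "Y")), "uniquely named")
})

test_that("locus presence filter keeps exactly the loci above threshold", {
  # 10 samples; locus A called in 8, locus B in 7
  calls <- matrix(0L, 10, 2)
  calls[9:10, 1] <- NA_integer_
  calls[8:10, 2] <- NA_integer_
  calls[1, ] <- 1L
  m <- haplo_matrix(calls, data.frame(locus_id = c("A", "B"), position = c(1L, 1L),
                                      ancestral_allele = "A", derived_allele = "T"),
                    paste0("s", 1:10))
  kept <- filter_locus_presence(m, 0.8)
  expect_identical(unique(kept$sites$locus_id), "A")
  expect_identical(attr(kept, "n_loci_dropped"), 1L)
  # boundary: min_fraction = 0 keeps every locus with any call
  expect_identical(unique(filter_locus_presence(m, 0)$sites$locus_id), c("A", "B"))
  expect_error(filter_locus_presence(subset_sites(m, integer(0))), "empty")
})

test_that("locus presence filter matches an exhaustive per-locus recount", {
  m <- random_matrix(n_samples = 12, n_loci = 60, locus_dropout = 0.35, seed = 5)
  for (thr in c(0.5, 0.75, 0.9)) {
    kept <- filter_locus_presence(m, thr)
    # brute force: loop every locus, count samples with any non-missing call
    expected_loci <- character()
    for (loc in unique(m$sites$locus_id)) {
      sub <- m$calls[, m$sites$locus_id == loc, drop = FALSE]
      pres <- sum(apply(!is.na(sub), 1, any))
      if (pres / n_samples(m) >= thr) expected_loci <- c(expected_loci, loc)
    }
    expect_identical(unique(kept$sites$locus_id), expected_loci)
  }
})

test_that("one SNP per locus is seed-reproducible and uniform", {
  m <- random_matrix(n_samples = 6, n_loci = 50, snps_per_locus = 3,
                     locus_dropout = 0, seed = 7)
  a <- one_snp_per_locus(m, seed = 11)
  b <- one_snp_per_locus(m, seed = 11)
  expect_identical(a$sites, b$sites)
  expect_identical(nrow(a$sites), 50L)
  expect_true(all(table(a$sites$locus_id) == 1L))
  # a locus with a single SNP always keeps that SNP
  single <- random_matrix(n_samples = 4, n_loci = 10, snps_per_locus = 1,
                          locus_dropout = 0, seed = 2)
  expect_identical(one_snp_per_locus(single, 3)$sites, single$sites)
  # uniformity: across many seeds each of the 3 positions of a locus is
  # picked about 1/3 of the time
  picks <- vapply(1:1500, function(s) {
    one_snp_per_locus(m, s)$sites$position[1]
  }, numeric(1))
  freqs <- table(picks) / length(picks)
  expect_equal(length(freqs), 3L)
  expect_true(all(abs(freqs - 1 / 3) < 0.05))
  expect_false(identical(one_snp_per_locus(m, 1)$sites,
                         one_snp_per_locus(m, 2)$sites))
})

test_that("locus filtering commutes with sample subsetting when no samples are removed", {
  m <- random_matrix(seed = 13)
  all_samples <- m$samples
  a <- filter_locus_presence(subset_samples(m, all_samples), 0.7)
  b <- subset_samples(filter_locus_presence(m, 0.7), all_samples)
  expect_identical(a$calls, b$calls)
  expect_identical(a$sites, b$sites)
})
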