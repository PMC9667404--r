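test_that("hypergeometric projection matches exhaustive subset enumeration", {
  # trivial anchors
  expect_equal(project_site(4, 0, 2), c(1, 0, 0))
  expect_equal(project_site(2, 1, 2), c(0, 1, 0))
  # enumeration oracle: all C(n_obs, n_proj) unordered draws
  enum <- function(n_obs, d_obs, n_proj) {
    alleles <- c(rep(1, d_obs), rep(0, n_obs - d_obs))
    draws <- utils::combn(n_obs, n_proj)
    tab <- tabulate(colSums(matrix(alleles[draws], nrow = n_proj)) + 1L,
                    nbins = n_proj + 1L)
    tab / ncol(draws)
  }
  for (case in list(c(4, 2, 2), c(6, 3, 4), c(5, 1, 3), c(7, 6, 2))) {
    expect_equal(project_site(case[1], case[2], case[3]),
                 enum(case[1], case[2], case[3]),
                 tolerance = 1e-12,
                 label = paste(case, collapse = ","))
  }
  expect_error(project_site(4, 5, 2), "d_obs")
  expect_error(project_site(4, 2, 5), "not projectable")
})

test_that("projection conserves mass for random configurations", {
  set.seed(42)
  for (i in 1:50) {
    n_obs <- sample(2:20, 1)
    d_obs <- sample(0:n_obs, 1)
    n_proj <- sample(1:n_obs, 1)
    expect_equal(sum(project_site(n_obs, d_obs, n_proj)), 1)
  }
})

test_that("joint SFS of a fully-called matrix at full projection is a direct tally", {
  m <- random_matrix(n_samples = 8, n_loci = 30, locus_dropout = 0, seed = 21)
  pm <- pop_map(setNames(rep(c("X", "Y"), each = 4), m$samples))
  j <- build_joint_sfs(m, pm, c(X = 4, Y = 4))
  # brute force: per-site derived counts per population
  tally <- array(0, dim = c(5, 5))
  for (s in seq_len(n_sites(m))) {
    dx <- sum(m$calls[1:4, s] == 1L)
    dy <- sum(m$calls[5:8, s] == 1L)
    tally[dx + 1, dy + 1] <- tally[dx + 1, dy + 1] + 1
  }
  expect_equal(j$counts, tally, ignore_attr = TRUE)
  expect_identical(attr(j, "n_skipped"), 0L)
})

test_that("fixed-difference site puts unit mass in its corner cell", {
  calls <- rbind(a = 1L, b = 1L, c = 0L, d = 0L)
  m <- haplo_matrix(calls, data.frame(locus_id = "L1", position = 1L,
                                      ancestral_allele = "A",
                                      derived_allele = "T"),
                    c("a", "b", "c", "d"))
  pm <- pop_map(c(a = "P1", b = "P1", c = "P2", d = "P2"))
  j <- build_joint_sfs(m, pm, c(P1 = 1, P2 = 1))
  expect_equal(j$counts[2, 1], 1)  # derived in P1, ancestral in P2
  expect_equal(sum(j$counts), 1)
})

test_that("sites below the projection threshold are skipped and counted", {
  m <- tiny_matrix()  # s2 missing at site 5, s3 at site 4, s5 at site 3
  pm <- tiny_popmap()
  j <- build_joint_sfs(m, pm, c(X = 3, Y = 3))
  expect_identical(attr(j, "n_skipped"), 3L)
  expect_identical(attr(j, "n_sites_used"), 2L)
  # per usable site the projected mass is exactly one
  expect_equal(sum(j$counts), 2)
  expect_error(build_joint_sfs(m, pm, c(X = 3, Z = 2)), "absent")
  expect_error(build_joint_sfs(m, pm, c(X = 4, Y = 3)), "exceed")
})

test_that("fractional projection masses average the per-site hypergeometrics", {
  m <- tiny_matrix()
  pm <- tiny_popmap()
  j <- build_joint_sfs(m, pm, c(X = 2, Y = 2))
  # independent accumulation with explicit loops
  ref <- array(0, dim = c(3, 3))
  for (s in seq_len(n_sites(m))) {
    cx <- m$calls[1:3, s]; cy <- m$calls[4:6, s]
    nx <- sum(!is.na(cx)); ny <- sum(!is.na(cy))
    if (nx < 2 || ny < 2) next
    px <- project_site(nx, sum(cx == 1L, na.rm = TRUE), 2)
    py <- project_site(ny, sum(cy == 1L, na.rm = TRUE), 2)
    ref <- ref + outer(px, py)
  }
  expect_equal(j$counts, ref, ignore_attr = TRUE)
})

test_that("sampled-mode projection has the expected mean and is seeded", {
  m <- random_matrix(n_samples = 10, n_loci = 80, snps_per_locus = 1,
                     locus_dropout = 0.2, seed = 3)
  pm <- pop_map(setNames(rep(c("X", "Y"), each = 5), m$samples))
  s1 <- build_joint_sfs(m, pm, c(X = 3, Y = 3), method = "sampled", seed = 8)
  s2 <- build_joint_sfs(m, pm, c(X = 3, Y = 3), method = "sampled", seed = 8)
  expect_identical(s1$counts, s2$counts)
  # averaging many sampled draws approaches the expectation projection
  e <- build_joint_sfs(m, pm, c(X = 3, Y = 3))
  acc <- 0
  for (s in 1:300) {
    acc <- acc + build_joint_sfs(m, pm, c(X = 3, Y = 3),
                                 method = "sampled", seed = s)$counts
  }
  expect_equal(acc / 300, e$counts, tolerance = 0.12)
})

test_that("one-per-locus spectra carry no more mass than all-SNP spectra", {
  m <- random_matrix(n_samples = 8, n_loci = 40, snps_per_locus = 3,
                     locus_dropout = 0.2, seed = 17)
  pm <- pop_map(setNames(rep(c("X", "Y"), each = 4), m$samples))
  ja <- build_joint_sfs(m, pm, c(X = 3, Y = 3), mode = "all_snps")
  jo <- build_joint_sfs(m, pm, c(X = 3, Y = 3), mode = "one_per_locus", seed = 4)
  expect_true(sum(jo$counts) <= sum(ja$counts))
})

test_that("marginal spectra equal explicit axis sums and keep total mass", {
  set.seed(31)
  counts <- array(runif(3 * 4 * 5), dim = c(3, 4, 5))
  j <- joint_sfs(counts, c("A", "B", "C"), c(2, 3, 4))
  mB <- marginal_sfs(j, "B")
  ref <- apply(counts, 2, sum)
  expect_equal(as.vector(mB$counts), ref)
  expect_equal(sum(mB$counts), sum(j$counts))
  # d = 1 input returns itself; zero table gives zero vector
  j1 <- joint_sfs(array(1:4, 4), "A", 3)
  expect_equal(marginal_sfs(j1, "A")$counts, j1$counts)
  jz <- joint_sfs(array(0, dim = c(3, 3)), c("A", "B"), c(2, 2))
  expect_equal(as.vector(marginal_sfs(jz, "A")$counts), c(0, 0, 0))
  expect_error(marginal_sfs(j, "nope"), "unknown")
})

test_that("the plain-text SFS format round-trips and is row-major", {
  counts <- array(1:12, dim = c(3, 4))
  j <- joint_sfs(counts, c("A", "B"), c(2, 3))
  path <- withr::local_tempfile(fileext = ".txt")
  write_sfs(j, path, comments = "fixture")
  j2 <- read_sfs(path)
  expect_equal(j2$counts, j$counts, ignore_attr = TRUE)
  expect_identical(j2$pop_labels, j$pop_labels)
  expect_identical(j2$sample_sizes, j$sample_sizes)
  expect_false(j2$is_expected)
  # row-major: last axis fastest, so the first row of the array comes first
  data_line <- readLines(path)
  data_line <- data_line[!grepl("^#", data_line)]
  flat <- as.numeric(strsplit(data_line, " ")[[1]])
  expect_equal(flat[1:4], counts[1, ])
})
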