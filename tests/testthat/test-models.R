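test_that("the model zoo contains every named family with the right structure", {
  zoo <- model_zoo(sample_sizes = c(REC = 4, ENA = 4, EUR = 4))
  expect_length(zoo$no_migration$migrations, 0L)
  expect_length(zoo$full_migration$migrations, 8L)
  expect_length(zoo$current_pops_only$migrations, 6L)
  expect_length(zoo$model10_secondary$migrations, 3L)
  drop1 <- zoo[grepl("^drop1_", names(zoo))]
  expect_length(drop1, 8L)
  expect_true(all(vapply(drop1, function(s) length(s$migrations), 1L) == 7L))
  # every model validates at its midpoint parameters
  for (nm in names(zoo)) expect_no_violations(zoo[[nm]])
})

test_that("the free-parameter count is a pure function of the spec", {
  zoo <- model_zoo()
  # strict isolation: 5 sizes + species split time + nested split fraction
  expect_identical(n_free_params(zoo$no_migration), 7L)
  expect_identical(n_free_params(zoo$full_migration), 7L + 8L)
  expect_identical(n_free_params(zoo$model10), 7L + 3L)
  # timing variants add one free contact/stop fraction
  expect_identical(n_free_params(zoo$model10_secondary), 7L + 3L + 1L)
  expect_identical(n_free_params(zoo$model10_early), 7L + 3L + 1L)
  # fixing a parameter removes it from k
  fixed <- make_model(c("ENA>EUR"), params = list(N_REC = 5000))
  expect_identical(n_free_params(fixed), 7L + 1L - 1L)
  expect_error(make_model("EUR>XYZ"), "unknown gene-flow event")
})

test_that("the validator flags migration outside a population's existence", {
  # EUR <-> REC migration beyond the flexuosum split: EUR no longer exists
  bad <- make_model("EUR>REC")
  bad$migrations[[1]]$t_end <- "T_SP"  # extends past T_FLEX
  v <- validate_model(bad)
  expect_true(any(grepl("existence of 'EUR'", v)))
  good <- make_model("EUR>REC")
  expect_no_violations(good)
  # secondary-contact window sits strictly inside the ancestral epoch
  sc <- make_model("REC>ANC", timing = "secondary_contact")
  vals <- midpoint_params(sc)
  resolved <- resolve_params(sc, vals)
  expect_gt(resolved[["T_ANC"]], resolved[["T_FLEX"]])
  expect_lt(resolved[["T_ANC"]], resolved[["T_SP"]])
  expect_no_violations(sc)
})

test_that("fuzzed windows agree with an independent interval checker", {
  set.seed(64)
  for (i in 1:40) {
    t_flex <- runif(1, 100, 5000)
    t_sp <- t_flex + runif(1, 100, 5000)
    w <- sort(runif(2, 0, t_sp * 1.3))
    spec <- make_model("ENA>EUR",
                       params = list(T_SP = t_sp,
                                     rT_FLEX = t_flex / t_sp,
                                     m_ENA_EUR = 0.001))
    spec$migrations[[1]]$t_start <- w[1]
    spec$migrations[[1]]$t_end <- w[2]
    v <- validate_model(spec)
    # both ENA and EUR exist on [0, t_flex]; the window must fit inside
    ok <- w[2] <= t_flex + 1e-6 && w[1] < w[2]
    expect_identical(length(v) == 0L, ok, label = paste("fuzz case", i))
  }
})

test_that("forward-time migration maps to the documented backward lineage movement", {
  # one-way forward flow A -> B: backward in time, lineages sampled in B
  # must jump to A (rate m) before they can coalesce, so B accumulates
  # long external branches (excess private singletons) relative to A
  base <- list(populations = list(A = "NA_", B = "NB"),
               divergences = list(list(time = 1e7, child = "B", parent = "A")),
               params = list(NA_ = 1000, NB = 1000, m = 1e-4),
               sample_sizes = c(A = 2, B = 2), name = "oneway")
  fwd_ab <- do.call(model_spec, c(base, list(
    migrations = list(list(source = "A", dest = "B", m = "m",
                           t_start = 0, t_end = 1e7)))))
  fwd_ba <- do.call(model_spec, c(base, list(
    migrations = list(list(source = "B", dest = "A", m = "m",
                           t_start = 0, t_end = 1e7)))))
  e_ab <- simulate_expected_sfs(fwd_ab, 2e4, seed = 3)
  e_ba <- simulate_expected_sfs(fwd_ba, 2e4, seed = 3)
  singleton <- function(e, pop) marginal_sfs(e, pop)$counts[2]
  expect_gt(singleton(e_ab, "B"), 2 * singleton(e_ab, "A"))
  expect_gt(singleton(e_ba, "A"), 2 * singleton(e_ba, "B"))
})

test_that("model YAML round-trips to an equivalent simulation", {
  spec <- make_model(c("ENA>EUR", "REC>ANC"), timing = "secondary_contact",
                     params = list(N_REC = 8000, N_ENA = 4000, N_EUR = 1500,
                                   N_ANCFLEX = 1000, N_ANC = 6000,
                                   T_SP = 12000, rT_FLEX = 0.25,
                                   f_ANC = 0.5, m_ENA_EUR = 1e-3,
                                   m_REC_ANC = 0.01),
                     sample_sizes = c(REC = 3, ENA = 3, EUR = 3))
  path <- withr::local_tempfile(fileext = ".yaml")
  write_model_yaml(spec, path)
  spec2 <- read_model_yaml(path)
  expect_equal(resolve_params(spec2), resolve_params(spec))
  e1 <- simulate_expected_sfs(spec, 2000, seed = 5)
  e2 <- simulate_expected_sfs(spec2, 2000, seed = 5)
  expect_equal(e1$counts, e2$counts)
})

test_that("two-population and island builders assemble the advertised events", {
  im <- im_spec(1000, 500, 3000, m12 = 1e-4, sample_sizes = c(P1 = 4, P2 = 4))
  expect_length(im$migrations, 1L)
  expect_identical(im$migrations[[1]]$source, "P1")
  expect_identical(im$migrations[[1]]$dest, "P2")
  expect_no_violations(im)
  isl <- island_model_spec(1000, 4.5, n_demes = 3, n_per_deme = 4)
  expect_length(isl$migrations, 6L)
  expect_no_violations(isl)
  # finite-deme correction: the per-lineage rate for d demes is
  # (Nem / Ne) (d - 1) / d
  expect_equal(resolve_params(isl)[["MIG"]], 4.5 / 1000 * 2 / 3)
})
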