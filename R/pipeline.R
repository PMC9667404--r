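# Pipeline orchestration: stats -> trios -> SFS -> fit -> rank ->
# bootstrap from one configuration, with per-stage seeds and a
# machine-readable manifest.

#' Assemble a pipeline configuration
#'
#' Either pass a YAML file path or the fields directly. Required fields:
#' `seed`, plus either `input$matrix`/`input$popmap` (file paths) or
#' `input$synthetic = TRUE` with a generating preset. Optional stages are
#' controlled by the presence of their blocks: `stats`
#' (`total_sites`, `region_subsets` for the jackknife/ANOVA comparison),
#' `trios` (list of `list(trio=, outgroup=)`), `sfs`
#' (`projections`), `fit` (`models`, `n_runs`, `n_sims`, `n_cycles`,
#' `projections`), `bootstrap` (`n_reps`, `n_runs_per_rep`).
#'
#' @param path YAML config path, or `NULL` when fields are given.
#' @param ... fields overriding/instead of the file contents.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(path = NULL, ...) {
  cfg <- if (!is.null(path)) yaml::read_yaml(path) else list()
  cfg <- modifyList(cfg, list(...))
  if (is.null(cfg$seed)) stop("pipeline config requires a seed")
  structure(cfg, class = "pipeline_config")
}

#' Per-stage seed
#'
#' Stage seeds are derived as `derive_seed(master, stage)`, so adding a
#' stage never perturbs earlier ones.
#'
#' @param cfg a `pipeline_config` (or integer master seed).
#' @param stage stage label.
#' @return integer seed.
#' @export
stage_seed <- function(cfg, stage) {
  master <- if (is.list(cfg)) cfg$seed else cfg
  derive_seed(master, stage)
}

#' Run the full analysis pipeline
#'
#' Stages, in order: load-or-simulate input; diversity/differentiation
#' tables; jackknife + ANOVA group comparison; trio ABBA/BABA table;
#' joint-SFS construction (all SNPs and one SNP per locus); model fitting;
#' AIC ranking; parametric bootstrap of the best model. Each stage writes
#' a tidy TSV into `out_dir` and the run ends with a JSON manifest
#' (package version, seeds, input hashes, per-stage outputs). Stages not
#' configured are skipped; every stochastic stage consumes only its
#' derived stage seed, so a rerun with the same config reproduces every
#' output byte for byte.
#'
#' @param cfg a `pipeline_config` (or path to a YAML config).
#' @param out_dir output directory.
#' @return list of in-memory stage results, invisibly; files in
#'   `out_dir`.
#' @export
run_pipeline <- function(cfg, out_dir) {
  if (is.character(cfg)) cfg <- pipeline_config(cfg)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(package = "mireflow",
                   version = as.character(utils::packageVersion("mireflow")),
                   seed = cfg$seed, stages = list())
  results <- list()
  tsv <- function(df, name) {
    p <- file.path(out_dir, name)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    p
  }
  fail <- function(stage, e) {
    stop(sprintf("[stage %s] %s", stage, conditionMessage(e)), call. = FALSE)
  }

  # ---- input -------------------------------------------------------------
  withCallingHandlers({
    if (isTRUE(cfg$input$synthetic)) {
      spec <- if (!is.null(cfg$input$model_yaml)) {
        read_model_yaml(cfg$input$model_yaml)
      } else paper_shape_spec()
      truth <- synthetic_truth(spec, stage_seed(cfg, "simulate-data"),
                               n_loci = cfg$input$n_loci %||% 1000L,
                               missingness = cfg$input$missingness %||% 0.1)
      ds <- generate_dataset(truth)
      write_dataset(ds, file.path(out_dir, "synthetic-data"))
      m <- ds$matrix; pmap <- ds$popmap
    } else {
      if (!file.exists(cfg$input$matrix)) stop("input matrix not found")
      m <- read_matrix(cfg$input$matrix, cfg$input$format %||% "tabular")
      pmap <- read_popmap(cfg$input$popmap)
    }
    if (!is.null(cfg$input$min_locus_presence)) {
      m <- filter_locus_presence(m, cfg$input$min_locus_presence)
    }
    results$matrix <- m; results$popmap <- pmap
    manifest$stages$input <- list(n_samples = n_samples(m), n_sites = n_sites(m))
  }, error = function(e) fail("input", e))

  # ---- stats -------------------------------------------------------------
  if (!is.null(cfg$stats)) withCallingHandlers({
    ts <- cfg$stats$total_sites
    div <- diversity_summary(m, pmap, total_sites = ts)
    results$diversity <- div
    f1 <- tsv(div$within, "diversity_within.tsv")
    f2 <- if (!is.null(div$between)) tsv(div$between, "diversity_between.tsv")
    jk_files <- NULL
    if (!is.null(cfg$stats$region_subsets)) {
      jks <- lapply(cfg$stats$region_subsets, function(ss) {
        jackknife(function(mm, smp) {
          as.numeric(nucleotide_diversity(mm, smp, total_sites = ts))
        }, m, unlist(ss))
      })
      cmp <- compare_groups(jks)
      results$group_comparison <- cmp
      jk_tab <- data.frame(group = names(jks),
                           pi = vapply(jks, `[[`, 1, "point"),
                           jackknife_sd = vapply(jks, `[[`, 1, "sd"))
      jk_files <- c(tsv(jk_tab, "group_pi_jackknife.tsv"),
                    tsv(cbind(cmp$pairwise,
                              anova_F = cmp$anova$F, anova_p = cmp$anova$p),
                        "group_comparison.tsv"))
    }
    manifest$stages$stats <- list(outputs = c(f1, f2, jk_files))
  }, error = function(e) fail("stats", e))

  # ---- trios -------------------------------------------------------------
  if (!is.null(cfg$trios)) withCallingHandlers({
    tab <- do.call(rbind, lapply(cfg$trios, function(tr) {
      dtrios(m, pmap, unlist(tr$trio), tr$outgroup %||% NA,
             n_blocks = tr$n_blocks %||% 20L,
             orient = isTRUE(tr$orient))
    }))
    results$trios <- tab
    manifest$stages$trios <- list(outputs = tsv(tab, "trio_statistics.tsv"),
                                  bonferroni_alpha = 0.05 / nrow(tab))
  }, error = function(e) fail("trios", e))

  # ---- sfs ---------------------------------------------------------------
  if (!is.null(cfg$sfs) || !is.null(cfg$fit)) withCallingHandlers({
    proj <- unlist((cfg$sfs %||% cfg$fit)$projections)
    sseed <- stage_seed(cfg, "sfs")
    obs_all <- build_joint_sfs(m, pmap, proj, mode = "all_snps")
    obs_1pl <- build_joint_sfs(m, pmap, proj, mode = "one_per_locus",
                               seed = sseed)
    results$sfs_all <- obs_all; results$sfs_one_per_locus <- obs_1pl
    p1 <- file.path(out_dir, "sfs_all_snps.txt")
    p2 <- file.path(out_dir, "sfs_one_per_locus.txt")
    write_sfs(obs_all, p1, comments = sprintf("seed %d", sseed))
    write_sfs(obs_1pl, p2, comments = sprintf("seed %d", sseed))
    manifest$stages$sfs <- list(outputs = c(p1, p2),
                                n_sites_used = attr(obs_all, "n_sites_used"),
                                n_skipped = attr(obs_all, "n_skipped"))
  }, error = function(e) fail("sfs", e))

  # ---- fit / rank --------------------------------------------------------
  if (!is.null(cfg$fit)) withCallingHandlers({
    zoo <- model_zoo(sample_sizes = setNames(results$sfs_all$sample_sizes,
                                             results$sfs_all$pop_labels),
                     mutation_rate = cfg$fit$mutation_rate %||% 2.8e-8)
    models <- zoo[cfg$fit$models %||% names(zoo)]
    fits <- lapply(models, function(spec) {
      f <- fit_model(results$sfs_all, spec,
                     n_runs = cfg$fit$n_runs %||% 10L,
                     n_sims = cfg$fit$n_sims %||% 5000L,
                     n_cycles = cfg$fit$n_cycles %||% 10L,
                     seed = stage_seed(cfg, paste0("fit_", spec$name)),
                     n_loci = length(unique(m$sites$locus_id)))
      ev <- evaluate_model(f, spec, results$sfs_one_per_locus,
                           n_sims_eval = cfg$fit$n_sims_eval %||% 1e5,
                           seed = stage_seed(cfg, paste0("eval_", spec$name)))
      f$log10_CL_eval <- ev$log10_CL
      f$aic <- ev$aic
      f
    })
    results$fits <- fits
    ranking <- rank_models(fits)
    results$ranking <- ranking
    manifest$stages$fit <- list(outputs = tsv(ranking, "model_ranking.tsv"),
                                best = ranking$model[1L])
  }, error = function(e) fail("fit", e))

  # ---- bootstrap ---------------------------------------------------------
  if (!is.null(cfg$bootstrap) && !is.null(results$ranking)) withCallingHandlers({
    best_name <- results$ranking$model[1L]
    spec <- model_zoo(sample_sizes = setNames(results$sfs_all$sample_sizes,
                                              results$sfs_all$pop_labels))[[best_name]]
    bt <- parametric_bootstrap(
      results$fits[[best_name]], spec,
      n_loci = cfg$bootstrap$n_loci %||% length(unique(m$sites$locus_id)),
      n_reps = cfg$bootstrap$n_reps %||% 100L,
      n_runs_per_rep = cfg$bootstrap$n_runs_per_rep %||% 10L,
      n_sims = cfg$bootstrap$n_sims %||% 5000L,
      n_cycles = cfg$bootstrap$n_cycles %||% 10L,
      seed = stage_seed(cfg, "bootstrap"))
    results$bootstrap <- bt
    ci_tab <- data.frame(parameter = colnames(bt$ci),
                         estimate = results$fits[[best_name]]$estimates[colnames(bt$ci)],
                         lower = bt$ci["lower", ], upper = bt$ci["upper", ])
    manifest$stages$bootstrap <- list(outputs = tsv(ci_tab, "bootstrap_ci.tsv"),
                                      n_reps = bt$n_reps,
                                      n_dropped = bt$n_dropped)
  }, error = function(e) fail("bootstrap", e))

  manifest$input_hashes <- if (!isTRUE(cfg$input$synthetic)) {
    as.list(tools::md5sum(c(cfg$input$matrix, cfg$input$popmap)))
  } else list(synthetic_seed = stage_seed(cfg, "simulate-data"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(results)
}
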