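# Composite-likelihood fitting of demographic models to observed joint
# SFS: multinomial composite likelihood over polymorphic cells, cycle-based
# conditional maximization against simulated expected spectra, AIC
# ranking, parametric bootstrap.

#' Multinomial composite log10-likelihood of an observed SFS
#'
#' `sum over polymorphic cells of obs_i * log10(max(exp_i, floor))`, with
#' the floor (default `1 / (10 * n_sims)`) standing in for cells the
#' finite simulation left empty. Monomorphic corners are excluded: the
#' observed SFS tabulates SNPs only and the expected SFS is normalized
#' over polymorphic cells.
#'
#' Because a SNP-only SFS is normalized over polymorphic cells, the
#' multinomial part constrains only parameter ratios (a single-population
#' spectrum, for instance, has an Ne-free shape). Supplying `n_loci` adds
#' a Poisson term on the total polymorphic count, with mean
#' `mu * locus_length * n_loci * E[polymorphic branch length]` taken from
#' the expected SFS's simulation, which restores the absolute scale.
#'
#' @param obs observed `joint_sfs` (counts; fractional masses allowed).
#' @param expected expected `joint_sfs` (proportions).
#' @param floor minimum cell probability; default `1/(10 * n_sims)` using
#'   the expected SFS's simulation count.
#' @param n_loci number of unlinked loci behind `obs`; `NULL` (default)
#'   for the scale-free multinomial likelihood alone.
#' @return log10 composite likelihood (<= the saturated value).
#' @export
composite_log10_likelihood <- function(obs, expected, floor = NULL,
                                       n_loci = NULL) {
  if (!identical(dim(obs$counts), dim(expected$counts))) {
    stop("observed and expected SFS shapes differ")
  }
  if (is.null(floor)) {
    ns <- attr(expected, "n_sims")
    floor <- if (is.null(ns)) 1e-12 else 1 / (10 * ns)
  }
  mask <- sfs_polymorphic_mask(obs)
  o <- obs$counts[mask]
  e <- pmax(expected$counts[mask], floor)
  cl <- sum(o * log10(e))
  if (!is.null(n_loci)) {
    lam <- attr(expected, "mutation_rate") * attr(expected, "locus_length") *
      attr(expected, "poly_length_per_locus") * n_loci
    if (is.null(lam) || !is.finite(lam)) {
      stop("expected SFS carries no branch-length information for the total-count term")
    }
    s <- sum(o)
    cl <- cl + s * log10(max(lam, .Machine$double.xmin)) -
      (lam + lgamma(s + 1)) / log(10)
  }
  cl
}

#' Saturated-model composite log10-likelihood
#'
#' The maximum attainable composite likelihood for an observed SFS: the
#' multinomial likelihood at cell probabilities equal to the observed
#' proportions.
#'
#' @param obs observed `joint_sfs`.
#' @param poisson_total include the saturated Poisson total-count term
#'   (the value at rate parameter equal to the observed total), matching
#'   [composite_log10_likelihood()] with `n_loci` supplied.
#' @return log10 likelihood of the saturated model.
#' @export
saturated_log10_likelihood <- function(obs, poisson_total = FALSE) {
  o <- obs$counts[sfs_polymorphic_mask(obs)]
  s <- sum(o)
  o <- o[o > 0]
  cl <- sum(o * log10(o / s))
  if (poisson_total && s > 0) {
    cl <- cl + s * log10(s) - (s + lgamma(s + 1)) / log(10)
  }
  cl
}

#' AIC from a log10 composite likelihood
#'
#' `AIC = 2k - 2 ln(10) log10 CL` (the natural-log convention applied to a
#' log10 likelihood).
#'
#' @param log10_cl log10 composite likelihood.
#' @param k number of free parameters.
#' @return numeric AIC.
#' @export
aic_from_log10 <- function(log10_cl, k) 2 * k - 2 * log(10) * log10_cl

golden_max <- function(f, lo, hi, n_evals = 6L) {
  # golden-section maximization with a fixed evaluation budget
  phi <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  best_x <- if (f1 >= f2) x1 else x2
  best_f <- max(f1, f2)
  for (i in seq_len(max(0L, n_evals - 2L))) {
    if (f1 >= f2) {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - phi * (b - a); f1 <- f(x1)
      if (f1 > best_f) { best_f <- f1; best_x <- x1 }
    } else {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + phi * (b - a); f2 <- f(x2)
      if (f2 > best_f) { best_f <- f2; best_x <- x2 }
    }
  }
  list(x = best_x, f = best_f)
}

#' Fit a demographic model to an observed SFS
#'
#' Multi-start composite-likelihood search. Each run draws log-uniform
#' initial values inside the search ranges, then performs `n_cycles`
#' conditional-maximization cycles: one bracketed golden-section search
#' per free parameter on the log10 scale, holding the others fixed, each
#' objective evaluation being the composite likelihood against a freshly
#' simulated expected SFS of `n_sims` genealogies. Within a cycle all
#' evaluations reuse one simulation substream (common random numbers), so
#' the 1-D objective is a deterministic function of the parameter and
#' bracketing is not defeated by Monte-Carlo noise. The best run (final
#' composite likelihood, re-evaluated with a common seed across runs) is
#' returned. Deterministic given `seed`.
#'
#' @param obs observed `joint_sfs` (same axes/projections the model's
#'   `sample_sizes` produce).
#' @param spec a `model_spec` with at least one free parameter.
#' @param n_runs independent starts.
#' @param n_sims genealogies per expected-SFS evaluation.
#' @param n_cycles conditional-maximization cycles per run.
#' @param seed integer seed.
#' @param n_evals objective evaluations per 1-D search.
#' @param n_loci unlinked loci behind `obs`, enabling the Poisson
#'   total-count likelihood term (see
#'   [composite_log10_likelihood()]); defaults to the `n_loci` attribute
#'   that [sample_observed_sfs()] records. Pass `NULL` explicitly for a
#'   scale-free fit.
#' @return a `fit_result`: `model_name`, `estimates`, `log10_CL`,
#'   `max_possible_log10_CL`, `aic`, `k`, `run_meta`.
#' @export
fit_model <- function(obs, spec, n_runs = 10L, n_sims = 5000L,
                      n_cycles = 10L, seed = 1L, n_evals = 6L,
                      n_loci = attr(obs, "n_loci")) {
  fp <- free_params(spec)
  if (!length(fp)) stop("model has no free parameters")
  ranges <- lapply(fp, function(nm) spec$params[[nm]])
  names(ranges) <- fp
  degenerate <- vapply(ranges, function(r) r[1L] == r[2L], logical(1))
  sat <- saturated_log10_likelihood(obs, poisson_total = !is.null(n_loci))
  eval_cl <- function(values, sim_seed) {
    e <- simulate_expected_sfs(spec, n_sims, sim_seed, values = values,
                               sample_sizes = obs_sizes(obs, spec),
                               n_batches = 1L)
    composite_log10_likelihood(obs, e, n_loci = n_loci)
  }
  final_seed <- derive_seed(seed, "final_eval")
  best <- NULL
  for (run in seq_len(n_runs)) {
    rs <- derive_seed(seed, paste0("run", run))
    old <- .Random.seed_save()
    set.seed(rs)
    cur <- setNames(vapply(ranges, function(r) {
      if (r[1L] == r[2L]) r[1L] else exp(runif(1, log(r[1L]), log(r[2L])))
    }, 1), fp)
    .Random.seed_restore(old)
    for (cyc in seq_len(n_cycles)) {
      cseed <- derive_seed(seed, paste0("run", run, "_cycle", cyc))
      shrink <- 0.6^(cyc - 1)  # refine the bracket around the current value
      for (nm in fp[!degenerate]) {
        r <- log10(ranges[[nm]])
        half <- (r[2L] - r[1L]) / 2 * shrink
        ctr <- min(max(log10(cur[[nm]]), r[1L] + half), r[2L] - half)
        obj <- function(lx) {
          v <- cur; v[nm] <- 10^lx
          eval_cl(v, cseed)
        }
        g <- golden_max(obj, max(r[1L], ctr - half), min(r[2L], ctr + half),
                        n_evals)
        cur[nm] <- 10^g$x
      }
    }
    cl <- eval_cl(cur, final_seed)
    if (is.null(best) || cl > best$log10_CL) {
      best <- list(estimates = cur, log10_CL = cl, run = run)
    }
  }
  k <- length(fp)
  structure(list(model_name = spec$name,
                 estimates = best$estimates,
                 log10_CL = best$log10_CL,
                 max_possible_log10_CL = sat,
                 aic = aic_from_log10(best$log10_CL, k),
                 k = k,
                 run_meta = list(n_runs = n_runs, n_sims = n_sims,
                                 n_cycles = n_cycles, seed = seed,
                                 best_run = best$run)),
            class = "fit_result")
}

obs_sizes <- function(obs, spec) {
  setNames(obs$sample_sizes, obs$pop_labels)
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("fit_result '%s': log10 CL %.3f (saturated %.3f), AIC %.2f, k = %d\n",
              x$model_name, x$log10_CL, x$max_possible_log10_CL, x$aic, x$k))
  est <- format(signif(x$estimates, 4), trim = TRUE)
  cat(paste0("  ", names(x$estimates), " = ", est, collapse = "\n"), "\n")
  invisible(x)
}

#' High-precision evaluation of fitted parameters
#'
#' Second step of the two-step scheme: one expected SFS at the fixed
#' estimates from a large simulation, scored against the
#' one-SNP-per-locus observed SFS, and converted to AIC.
#'
#' @param fit a `fit_result` (or named estimates vector with `spec`).
#' @param spec the `model_spec` that was fitted.
#' @param obs_one_per_locus observed `joint_sfs` built with
#'   `mode = "one_per_locus"`.
#' @param n_sims_eval genealogies for the evaluation SFS.
#' @param seed integer seed.
#' @param n_loci optional locus count enabling the total-count term (off
#'   by default: a one-SNP-per-locus spectrum is thinned, so its total is
#'   not Poisson and ranking rests on the multinomial shape).
#' @return list `log10_CL`, `aic`, `k`.
#' @export
evaluate_model <- function(fit, spec, obs_one_per_locus, n_sims_eval = 1e5,
                           seed = 1L, n_loci = NULL) {
  est <- if (inherits(fit, "fit_result")) fit$estimates else fit
  k <- if (inherits(fit, "fit_result")) fit$k else n_free_params(spec)
  e <- simulate_expected_sfs(spec, n_sims_eval, derive_seed(seed, "evaluate"),
                             values = est,
                             sample_sizes = obs_sizes(obs_one_per_locus, spec),
                             n_batches = 1L)
  cl <- composite_log10_likelihood(obs_one_per_locus, e, n_loci = n_loci)
  list(log10_CL = cl, aic = aic_from_log10(cl, k), k = k)
}

#' Rank fitted models by AIC
#'
#' @param fits list of `fit_result`s (or of lists with `model_name`,
#'   `aic`, `log10_CL`, `k`).
#' @return data.frame ordered by ascending AIC with a `delta_aic` column;
#'   ties break by fewer parameters, then name.
#' @export
rank_models <- function(fits) {
  if (!length(fits)) stop("no fit results")
  tab <- do.call(rbind, lapply(fits, function(f) {
    data.frame(model = f$model_name, k = f$k, log10_CL = f$log10_CL,
               aic = f$aic, stringsAsFactors = FALSE)
  }))
  tab <- tab[order(tab$aic, tab$k, tab$model), , drop = FALSE]
  tab$delta_aic <- tab$aic - tab$aic[1L]
  rownames(tab) <- NULL
  tab
}

#' Parametric bootstrap of a fitted model
#'
#' Re-simulates `n_reps` observed spectra at the fitted parameters (same
#' locus count and mutation rate as the analysis), refits each with
#' `n_runs_per_rep` starts, keeps the best run per replicate, and forms
#' per-parameter percentile confidence intervals.
#'
#' @param fit a `fit_result` for `spec`.
#' @param spec the fitted `model_spec`.
#' @param n_loci unlinked loci per simulated dataset.
#' @param n_reps bootstrap replicates.
#' @param n_runs_per_rep starts per replicate refit.
#' @param n_sims,n_cycles,n_evals refit settings (see [fit_model()]).
#' @param seed integer seed.
#' @param level confidence level for the percentile interval.
#' @return a `bootstrap_result`: `replicate_estimates` (matrix reps x
#'   parameters), `ci` (2 x parameters), `n_dropped`.
#' @export
parametric_bootstrap <- function(fit, spec, n_loci, n_reps = 100L,
                                 n_runs_per_rep = 10L, n_sims = 5000L,
                                 n_cycles = 10L, n_evals = 6L, seed = 1L,
                                 level = 0.95) {
  fp <- free_params(spec)
  est <- matrix(NA_real_, n_reps, length(fp), dimnames = list(NULL, fp))
  dropped <- 0L
  sizes <- setNames(spec$sample_sizes, names(spec$sample_sizes))
  for (rep in seq_len(n_reps)) {
    rseed <- derive_seed(seed, paste0("bootrep", rep))
    sim <- sample_observed_sfs(spec, n_loci, rseed, values = fit$estimates)
    f <- tryCatch(fit_model(sim, spec, n_runs = n_runs_per_rep,
                            n_sims = n_sims, n_cycles = n_cycles,
                            seed = derive_seed(seed, paste0("bootfit", rep)),
                            n_evals = n_evals),
                  error = function(e) NULL)
    if (is.null(f)) {
      dropped <- dropped + 1L
      warning("bootstrap replicate ", rep, " failed and was dropped")
    } else {
      est[rep, ] <- f$estimates[fp]
    }
  }
  keep <- stats::complete.cases(est)
  alpha <- (1 - level) / 2
  ci <- apply(est[keep, , drop = FALSE], 2L, quantile,
              probs = c(alpha, 1 - alpha), names = FALSE)
  rownames(ci) <- c("lower", "upper")
  structure(list(replicate_estimates = est[keep, , drop = FALSE],
                 ci = ci, n_dropped = dropped,
                 n_reps = sum(keep)),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("bootstrap_result: %d replicates (%d dropped)\n",
              x$n_reps, x$n_dropped))
  print(signif(x$ci, 4))
  invisible(x)
}
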