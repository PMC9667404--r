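# Diversity and differentiation statistics with jackknife uncertainty.
#
# All pairwise statistics use pairwise-complete sites: a site enters the
# comparison of a sample pair only if both members are called there. When
# the total alignment length (including invariant sites) is known, per-site
# normalization assumes the sites absent from the SNP matrix are invariant
# and comparable in every pair.

pair_diff_counts <- function(callsA, callsB = NULL) {
  # returns list(diffs, comp): cross matrices of pairwise difference and
  # pairwise comparable-site counts over variant sites
  G1a <- (callsA == 1L); G0a <- (callsA == 0L)
  G1a[is.na(G1a)] <- FALSE; G0a[is.na(G0a)] <- FALSE
  Ma <- !is.na(callsA)
  if (is.null(callsB)) { G1b <- G1a; G0b <- G0a; Mb <- Ma }
  else {
    G1b <- (callsB == 1L); G0b <- (callsB == 0L)
    G1b[is.na(G1b)] <- FALSE; G0b[is.na(G0b)] <- FALSE
    Mb <- !is.na(callsB)
  }
  storage.mode(G1a) <- "double"; storage.mode(G0a) <- "double"
  storage.mode(G1b) <- "double"; storage.mode(G0b) <- "double"
  storage.mode(Ma) <- "double"; storage.mode(Mb) <- "double"
  list(diffs = tcrossprod(G1a, G0b) + tcrossprod(G0a, G1b),
       comp = tcrossprod(Ma, Mb))
}

pairwise_pi <- function(calls, total_sites = NULL) {
  # mean over unordered pairs of diffs / comparable sites
  pc <- pair_diff_counts(calls)
  n <- nrow(calls)
  ut <- upper.tri(pc$diffs)
  diffs <- pc$diffs[ut]
  comp <- pc$comp[ut]
  if (!is.null(total_sites)) comp <- comp + (total_sites - ncol(calls))
  if (any(comp == 0)) stop("a sample pair shares no comparable sites")
  mean(diffs / comp)
}

#' Nucleotide diversity
#'
#' Average per-site pairwise difference between samples: for every
#' unordered pair, the number of differing calls divided by the number of
#' sites comparable in that pair, averaged over pairs. With `total_sites`
#' supplied (alignment length including invariant sites) the estimate is
#' per alignment site; otherwise it is per variant site and flagged as
#' such.
#'
#' @param m a `haplo_matrix`.
#' @param samples optional subset of sample ids (default: all).
#' @param total_sites optional total alignment length including invariant
#'   sites.
#' @return numeric scalar; attribute `per_variant_site` is `TRUE` when
#'   `total_sites` was not supplied.
#' @export
nucleotide_diversity <- function(m, samples = NULL, total_sites = NULL) {
  calls <- m$calls
  if (!is.null(samples)) calls <- calls[m$samples %in% samples, , drop = FALSE]
  if (nrow(calls) < 2L) stop("nucleotide diversity needs at least 2 samples")
  out <- pairwise_pi(calls, total_sites)
  attr(out, "per_variant_site") <- is.null(total_sites)
  out
}

#' Average pairwise divergence between two groups (Dxy)
#'
#' Mean over all between-group sample pairs of per-site differences, with
#' the same pairwise-complete normalization as [nucleotide_diversity()].
#'
#' @inheritParams nucleotide_diversity
#' @param groupA,groupB character vectors of sample ids.
#' @return numeric scalar.
#' @export
dxy <- function(m, groupA, groupB, total_sites = NULL) {
  a <- m$calls[m$samples %in% groupA, , drop = FALSE]
  b <- m$calls[m$samples %in% groupB, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) stop("both groups must be non-empty")
  pc <- pair_diff_counts(a, b)
  comp <- pc$comp
  if (!is.null(total_sites)) comp <- comp + (total_sites - n_sites(m))
  if (any(comp == 0)) stop("a sample pair shares no comparable sites")
  out <- mean(pc$diffs / comp)
  attr(out, "per_variant_site") <- is.null(total_sites)
  out
}

#' Hudson-style fixation index
#'
#' `Fst = 1 - mean(pi_A, pi_B) / Dxy(A, B)`, where the within-group term is
#' the unweighted mean of the two group diversities. Reported unclipped:
#' values at or below zero indicate undifferentiated groups. Returns `NA`
#' with a warning when the between-group divergence is zero.
#'
#' @inheritParams dxy
#' @return numeric scalar (or flagged `NA`).
#' @export
fst <- function(m, groupA, groupB, total_sites = NULL) {
  if (sum(m$samples %in% groupA) < 2L || sum(m$samples %in% groupB) < 2L) {
    stop("fst needs at least 2 samples per group")
  }
  pw <- mean(c(as.numeric(nucleotide_diversity(m, groupA, total_sites)),
               as.numeric(nucleotide_diversity(m, groupB, total_sites))))
  pb <- as.numeric(dxy(m, groupA, groupB, total_sites))
  if (pb == 0) {
    warning("between-group divergence is zero; Fst undefined")
    return(NA_real_)
  }
  1 - pw / pb
}

#' Joint site classification for two groups
#'
#' Each site where both groups have at least one call is assigned exactly
#' one class: `monomorphic` (one and the same allele in both),
#' `fixed_difference` (each group fixed, for different alleles),
#' `shared_polymorphic` (both groups polymorphic) or `private_polymorphic`
#' (exactly one group polymorphic).
#'
#' @inheritParams dxy
#' @return named integer vector of class counts plus `n_sites_used`.
#' @export
site_classes <- function(m, groupA, groupB) {
  if (length(intersect(groupA, groupB))) stop("groups must be disjoint")
  a <- m$calls[m$samples %in% groupA, , drop = FALSE]
  b <- m$calls[m$samples %in% groupB, , drop = FALSE]
  derA <- colSums(a == 1L, na.rm = TRUE); nA <- colSums(!is.na(a))
  derB <- colSums(b == 1L, na.rm = TRUE); nB <- colSums(!is.na(b))
  use <- nA > 0L & nB > 0L
  polyA <- derA > 0L & derA < nA
  polyB <- derB > 0L & derB < nB
  fixA <- ifelse(derA == 0L, 0L, ifelse(derA == nA, 1L, NA_integer_))
  fixB <- ifelse(derB == 0L, 0L, ifelse(derB == nB, 1L, NA_integer_))
  shared <- use & polyA & polyB
  privat <- use & xor(polyA, polyB)
  fixdif <- use & !polyA & !polyB & fixA != fixB
  mono <- use & !polyA & !polyB & fixA == fixB
  c(monomorphic = sum(mono), fixed_difference = sum(fixdif),
    shared_polymorphic = sum(shared), private_polymorphic = sum(privat),
    n_sites_used = sum(use))
}

#' Diversity and differentiation summary table
#'
#' Per-population nucleotide diversity plus, for every population pair,
#' Hudson's Fst, Dxy and joint site-class counts. Mirrors the layout of a
#' within/between population summary table.
#'
#' @param m a `haplo_matrix`.
#' @param pmap a `pop_map`.
#' @param total_sites optional alignment length including invariant sites.
#' @return list with data.frames `within` and `between`.
#' @export
diversity_summary <- function(m, pmap, total_sites = NULL) {
  pops <- intersect(attr(pmap, "populations"), unique(pmap$population))
  pops <- pops[vapply(pops, function(p) sum(m$samples %in% pop_samples(pmap, p)) >= 2,
                      logical(1))]
  within <- data.frame(
    population = pops,
    n = vapply(pops, function(p) sum(m$samples %in% pop_samples(pmap, p)), 1L),
    pi = vapply(pops, function(p)
      as.numeric(nucleotide_diversity(m, pop_samples(pmap, p), total_sites)), 1),
    row.names = NULL)
  if (length(pops) < 2L) return(list(within = within, between = NULL))
  prs <- utils::combn(pops, 2L)
  between <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
    ga <- pop_samples(pmap, prs[1L, i]); gb <- pop_samples(pmap, prs[2L, i])
    cls <- site_classes(m, ga, gb)
    data.frame(pop1 = prs[1L, i], pop2 = prs[2L, i],
               fst = fst(m, ga, gb, total_sites),
               dxy = as.numeric(dxy(m, ga, gb, total_sites)),
               shared_polymorphic = cls[["shared_polymorphic"]],
               fixed_difference = cls[["fixed_difference"]],
               monomorphic = cls[["monomorphic"]],
               private_polymorphic = cls[["private_polymorphic"]])
  }))
  list(within = within, between = between)
}

#' Delete-one jackknife over samples
#'
#' Recomputes an estimator with each sample left out in turn and returns
#' the point estimate, the leave-one-out pseudovalue estimates and the
#' standard delete-one jackknife standard deviation
#' `sqrt(((n - 1) / n) * sum((theta_i - theta_bar)^2))`.
#'
#' @param stat function of `(m, samples)` returning a numeric scalar.
#' @param m a `haplo_matrix`.
#' @param samples character vector of sample ids (>= 3).
#' @return list with `point`, `pseudovalues`, `sd`, class
#'   `jackknife_estimate`.
#' @export
jackknife <- function(stat, m, samples) {
  samples <- intersect(m$samples, samples)
  n <- length(samples)
  if (n < 3L) stop("jackknife needs at least 3 samples")
  point <- stat(m, samples)
  pseudo <- vapply(seq_len(n), function(i) {
    out <- tryCatch(stat(m, samples[-i]), error = function(e) {
      stop("estimator failed on subsample without '", samples[i], "': ",
           conditionMessage(e))
    })
    as.numeric(out)
  }, numeric(1))
  structure(list(point = as.numeric(point), pseudovalues = pseudo,
                 sd = sqrt((n - 1) / n * sum((pseudo - mean(pseudo))^2))),
            class = "jackknife_estimate")
}

#' @export
print.jackknife_estimate <- function(x, ...) {
  cat(sprintf("jackknife: point %.6g, sd %.3g (n = %d)\n",
              x$point, x$sd, length(x$pseudovalues)))
  invisible(x)
}

#' Compare group estimates by ANOVA and Bonferroni t-tests
#'
#' One-way ANOVA over the per-group leave-one-out estimates, followed by
#' all pairwise two-sample Welch t-tests with Bonferroni adjustment
#' (`p_adj = min(1, p * n_comparisons)`).
#'
#' @param estimates named list: one numeric vector of pseudovalues (or a
#'   `jackknife_estimate`) per group.
#' @return list with `anova` (`F`, `p`) and `pairwise` data.frame
#'   (`group1`, `group2`, `t`, `p`, `p_adj`).
#' @export
compare_groups <- function(estimates) {
  vals <- lapply(estimates, function(e) {
    if (inherits(e, "jackknife_estimate")) e$pseudovalues else as.numeric(e)
  })
  if (length(vals) < 2L || any(vapply(vals, length, 1L) < 2L)) {
    stop("need >= 2 groups with >= 2 values each")
  }
  df <- data.frame(value = unlist(vals, use.names = FALSE),
                   group = factor(rep(names(vals), vapply(vals, length, 1L))))
  if (all(vapply(vals, function(v) var(v) == 0, logical(1)))) {
    warning("zero within-group variance in every group; ANOVA undefined")
    aov_out <- list(F = NA_real_, p = NA_real_)
  } else {
    fit <- anova(aov(value ~ group, data = df))
    aov_out <- list(F = fit$`F value`[1L], p = fit$`Pr(>F)`[1L])
  }
  prs <- utils::combn(names(vals), 2L)
  ncmp <- ncol(prs)
  pairwise <- do.call(rbind, lapply(seq_len(ncmp), function(i) {
    tt <- tryCatch(stats::t.test(vals[[prs[1L, i]]], vals[[prs[2L, i]]]),
                   error = function(e) NULL)  # zero-variance pair: flagged NA
    data.frame(group1 = prs[1L, i], group2 = prs[2L, i],
               t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
               p = if (is.null(tt)) NA_real_ else tt$p.value,
               p_adj = if (is.null(tt)) NA_real_ else min(1, tt$p.value * ncmp))
  }))
  list(anova = aov_out, pairwise = pairwise)
}

#' Island-model migrant number from an equilibrium fixation index
#'
#' Wright's island model for haploids: `Nem = (1/2) * (1/Fst - 1)` expected
#' migrants per generation at equilibrium. Strictly decreasing in `Fst`.
#'
#' @param fst fixation index in `(0, 1)`.
#' @return expected number of migrants per generation.
#' @export
wright_island_nem <- function(fst) {
  if (!is.numeric(fst) || any(fst <= 0) || any(fst >= 1)) {
    stop("fst must lie strictly between 0 and 1")
  }
  0.5 * (1 / fst - 1)
}

#' Migrants per generation from an effective size and a migration rate
#'
#' `Nem = Ne * m`: the expected number of individuals replaced by migrants
#' per generation.
#'
#' @param ne haploid effective population size.
#' @param m per-generation migration rate.
#' @return `ne * m`.
#' @export
migrants_per_generation <- function(ne, m) {
  stopifnot(ne > 0, m >= 0)
  ne * m
}
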