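# Frequency-based ABBA/BABA site-pattern statistics: Patterson's D, f4,
# f4-ratio, block-jackknife significance.

#' Per-site derived-allele frequencies for a set of populations
#'
#' @param m a `haplo_matrix` (polarized, 0 = ancestral).
#' @param pmap a `pop_map`.
#' @param pops character vector of population labels, in the order the
#'   columns of the result should take.
#' @return numeric matrix, sites x populations; `NA` where a population
#'   has no call at a site.
#' @export
derived_freqs <- function(m, pmap, pops) {
  out <- vapply(pops, function(p) {
    calls <- m$calls[m$samples %in% pop_samples(pmap, p), , drop = FALSE]
    if (!nrow(calls)) stop("population absent from matrix: ", p)
    colMeans(calls, na.rm = TRUE)
  }, numeric(n_sites(m)))
  matrix(out, ncol = length(pops), dimnames = list(NULL, pops))
}

#' Site-pattern sums for one (P1, P2, P3, outgroup) arrangement
#'
#' Population-frequency weighted counts of the concordant pattern (BBAA:
#' P1 and P2 share the derived allele) and the two discordant patterns
#' (ABBA, BABA), summed over sites:
#' `abba = sum (1-p1) p2 p3 (1-p4)`, `baba = sum p1 (1-p2) p3 (1-p4)`,
#' `bbaa = sum p1 p2 (1-p3) (1-p4)`.
#'
#' @param freqs numeric matrix, sites x 4, derived-allele frequencies for
#'   P1, P2, P3 and the outgroup. Sites with any `NA` are skipped.
#' @return named numeric vector `c(bbaa, abba, baba)`.
#' @export
site_pattern_sums <- function(freqs) {
  stopifnot(ncol(freqs) == 4L)
  f <- freqs[stats::complete.cases(freqs), , drop = FALSE]
  p1 <- f[, 1L]; p2 <- f[, 2L]; p3 <- f[, 3L]; p4 <- f[, 4L]
  c(bbaa = sum(p1 * p2 * (1 - p3) * (1 - p4)),
    abba = sum((1 - p1) * p2 * p3 * (1 - p4)),
    baba = sum(p1 * (1 - p2) * p3 * (1 - p4)))
}

#' Patterson's D statistic
#'
#' `D = (ABBA - BABA) / (ABBA + BABA)`; zero under incomplete lineage
#' sorting alone, non-zero under gene flow between P3 and one of P1/P2.
#'
#' @param abba,baba site-pattern sums.
#' @return numeric scalar in `[-1, 1]`; flagged `NA` when both sums are 0.
#' @export
d_statistic <- function(abba, baba) {
  if (abba + baba == 0) {
    warning("ABBA + BABA = 0; D undefined")
    return(NA_real_)
  }
  (abba - baba) / (abba + baba)
}

#' f4 and f4-ratio admixture-fraction estimate
#'
#' `f4(P1,P2;P3,O) = sum (p1 - p2)(p3 - p4)`. The ratio estimator divides
#' by the same quantity with P3 substituted for P2 (the
#' complete-introgression reference): `alpha = f4(P1,P2;P3,O) /
#' f4(P1,P3;P3,O)`. Because no subpopulation split of P3 is available this
#' is an f-homozygosity style approximation; the result carries a
#' `denominator` attribute for inspection.
#'
#' @inheritParams site_pattern_sums
#' @return estimated admixed genome fraction; flagged `NA` when the
#'   denominator is ~0.
#' @export
f4_ratio <- function(freqs) {
  stopifnot(ncol(freqs) == 4L)
  f <- freqs[stats::complete.cases(freqs), , drop = FALSE]
  p1 <- f[, 1L]; p2 <- f[, 2L]; p3 <- f[, 3L]; p4 <- f[, 4L]
  num <- sum((p1 - p2) * (p3 - p4))
  den <- sum((p1 - p3) * (p3 - p4))
  if (abs(den) < .Machine$double.eps^0.5) {
    warning("f4-ratio denominator ~ 0; estimate undefined")
    return(NA_real_)
  }
  structure(num / den, denominator = den)
}

#' Block-jackknife significance of Patterson's D
#'
#' Sites are cut into `n_blocks` contiguous equal-size blocks in input
#' order; D is recomputed with each block deleted, the delete-m jackknife
#' standard error is formed, and `Z = D / SE` is referred to a standard
#' normal (two-tailed).
#'
#' @inheritParams site_pattern_sums
#' @param n_blocks number of blocks (>= 2).
#' @return list `d`, `se`, `z`, `p`, `n_blocks`; `z`/`p` flagged `NA` when
#'   the jackknife SE is zero.
#' @export
block_jackknife_d <- function(freqs, n_blocks = 20L) {
  f <- freqs[stats::complete.cases(freqs), , drop = FALSE]
  ns <- nrow(f)
  if (n_blocks < 2L) stop("need >= 2 blocks")
  if (ns < n_blocks) stop("fewer usable sites than blocks")
  block <- ceiling(seq_len(ns) / (ns / n_blocks))
  block[block > n_blocks] <- n_blocks
  per_abba <- (1 - f[, 1L]) * f[, 2L] * f[, 3L] * (1 - f[, 4L])
  per_baba <- f[, 1L] * (1 - f[, 2L]) * f[, 3L] * (1 - f[, 4L])
  A <- sum(per_abba); B <- sum(per_baba)
  d <- d_statistic(A, B)
  ab_blk <- vapply(split(per_abba, block), sum, 1)
  ba_blk <- vapply(split(per_baba, block), sum, 1)
  d_del <- (A - ab_blk - (B - ba_blk)) / (A - ab_blk + B - ba_blk)
  d_del <- d_del[is.finite(d_del)]  # blocks holding all pattern mass
  nb <- length(d_del)
  if (is.na(d) || nb < 2L) {
    warning("too few informative blocks; Z undefined")
    return(list(d = d, se = NA_real_, z = NA_real_, p = NA_real_,
                n_blocks = nb))
  }
  se <- sqrt((nb - 1) / nb * sum((d_del - mean(d_del))^2))
  if (se == 0) {
    warning("block-jackknife SE is zero; Z undefined")
    return(list(d = d, se = 0, z = NA_real_, p = NA_real_, n_blocks = nb))
  }
  z <- d / se
  list(d = d, se = se, z = z, p = 2 * pnorm(-abs(z)), n_blocks = nb)
}

#' Orient a trio so the concordant pattern dominates and D >= 0
#'
#' Swaps P1 and P2 when the observed D is negative (D is antisymmetric
#' under that swap); reports whether BBAA is the maximal pattern sum, i.e.
#' whether the assumed species tree is supported. Fixed-trio analyses that
#' must reproduce a hypothesis-driven table can skip reorientation via
#' [dtrios()]'s `orient = FALSE`.
#'
#' @inheritParams site_pattern_sums
#' @param trio character vector of the three ingroup labels (P1, P2, P3);
#'   column order of `freqs` must be `c(trio, outgroup)`.
#' @return list `trio` (possibly with P1/P2 swapped), `freqs` (columns
#'   reordered to match), `swapped`, `bbaa_is_max`.
#' @export
orient_trio <- function(freqs, trio) {
  stopifnot(ncol(freqs) == 4L, length(trio) == 3L)
  sums <- site_pattern_sums(freqs)
  d <- d_statistic(sums[["abba"]], sums[["baba"]])
  swapped <- isTRUE(d < 0)
  if (swapped) {
    freqs <- freqs[, c(2L, 1L, 3L, 4L), drop = FALSE]
    trio <- trio[c(2L, 1L, 3L)]
    sums <- site_pattern_sums(freqs)
  }
  list(trio = trio, freqs = freqs, swapped = swapped,
       bbaa_is_max = sums[["bbaa"]] >= max(sums))
}

#' ABBA/BABA analysis of one trio plus outgroup
#'
#' Computes the pattern sums, Patterson's D, block-jackknife Z and p, and
#' the f4-ratio for one `(P1, P2, P3, outgroup)` arrangement.
#'
#' @param m a `haplo_matrix`.
#' @param pmap a `pop_map`.
#' @param trio character vector `(P1, P2, P3)` of ingroup labels.
#' @param outgroup outgroup population label, or `NA` to take the outgroup
#'   frequency as identically 0 (valid for polarized data; identical to
#'   using a monomorphic-ancestral outgroup population).
#' @param n_blocks jackknife blocks.
#' @param orient reorient P1/P2 per [orient_trio()] before testing?
#' @return one-row data.frame (class `trio_result`): trio labels, pattern
#'   sums, `d`, `z`, `p`, `f4_ratio`, `n_blocks`.
#' @export
dtrios <- function(m, pmap, trio, outgroup, n_blocks = 20L, orient = FALSE) {
  stopifnot(length(trio) == 3L)
  if (is.na(outgroup)) {
    freqs <- cbind(derived_freqs(m, pmap, trio), 0)
    colnames(freqs)[4L] <- "ancestral"
    outgroup <- "ancestral"
  } else {
    freqs <- derived_freqs(m, pmap, c(trio, outgroup))
  }
  if (orient) {
    o <- orient_trio(freqs, trio)
    freqs <- o$freqs
    trio <- o$trio
  }
  sums <- site_pattern_sums(freqs)
  bj <- block_jackknife_d(freqs, n_blocks)
  out <- data.frame(p1 = trio[1L], p2 = trio[2L], p3 = trio[3L],
                    outgroup = outgroup,
                    bbaa = sums[["bbaa"]], abba = sums[["abba"]],
                    baba = sums[["baba"]],
                    d = bj$d, z = bj$z, p = bj$p,
                    f4_ratio = as.numeric(f4_ratio(freqs)),
                    n_blocks = bj$n_blocks)
  class(out) <- c("trio_result", "data.frame")
  out
}
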