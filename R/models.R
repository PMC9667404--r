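# Declarative demographic models: populations with haploid effective
# sizes, divergence events, size changes, and time-windowed directional
# migration. Time is measured in generations before present; no calendar
# calibration is attempted (parameter values are relative).
#
# Parameter slots in a spec are either a number, the name of an entry in
# `params`, or a fraction rule `list(frac=, from=, to=)` resolving to
# `from + frac * (to - from)` (used to keep nested times inside their
# enclosing epoch by construction). `params` entries are: length-1 numeric
# (fixed), length-2 numeric (free, search range), or a fraction rule
# (derived).

#' Construct a demographic model specification
#'
#' @param populations named list/vector: population name -> present-day
#'   haploid effective size slot.
#' @param divergences list of `list(time=, child=, parent=)`: backward in
#'   time, lineages of `child` join `parent` at `time`.
#' @param size_changes list of `list(time=, pop=, ne=)`.
#' @param migrations list of `list(source=, dest=, m=, t_start=, t_end=)`;
#'   `source`/`dest` are forward-time direction (individuals move source ->
#'   dest), `m` is a per-lineage per-generation probability, the window is
#'   in generations before present with `t_start < t_end`.
#' @param params named list of parameter definitions (see Details).
#' @param mutation_rate per-site per-generation mutation rate.
#' @param sample_sizes named integer vector of haploid sample sizes.
#' @param locus_length locus length in bp.
#' @param name model name (used in fit tables).
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(populations, divergences = list(), size_changes = list(),
                       migrations = list(), params = list(),
                       mutation_rate = 2.8e-8, sample_sizes = NULL,
                       locus_length = 90L, name = "model") {
  if (!is.null(sample_sizes)) sample_sizes <- unlist(sample_sizes)
  spec <- structure(list(populations = as.list(populations),
                         divergences = divergences,
                         size_changes = size_changes,
                         migrations = migrations,
                         params = params,
                         mutation_rate = mutation_rate,
                         sample_sizes = sample_sizes,
                         locus_length = as.integer(locus_length),
                         name = name),
                    class = "model_spec")
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model_spec '%s': %d populations, %d divergences, %d migration events, k = %d free parameters\n",
              x$name, length(x$populations), length(x$divergences),
              length(x$migrations), n_free_params(x)))
  invisible(x)
}

#' Free parameters of a model
#'
#' A parameter is free when its definition is a length-2 numeric range.
#' The count `k` is what enters the AIC penalty.
#'
#' @param spec a `model_spec`.
#' @return character vector of names ([free_params()]) or integer count
#'   ([n_free_params()]).
#' @export
free_params <- function(spec) {
  names(spec$params)[vapply(spec$params,
                            function(p) is.numeric(p) && length(p) == 2L,
                            logical(1))]
}

#' @rdname free_params
#' @export
n_free_params <- function(spec) length(free_params(spec))

#' Resolve all parameters of a model to numbers
#'
#' Fixed parameters come from the spec; free parameters must be supplied
#' in `values`; derived (fraction-rule) parameters are resolved
#' iteratively.
#'
#' @param spec a `model_spec`.
#' @param values named numeric vector covering the free parameters.
#' @return named numeric vector of all parameter values.
#' @export
resolve_params <- function(spec, values = numeric()) {
  vals <- list()
  for (nm in names(values)) vals[[nm]] <- unname(values[[nm]])
  pending <- list()
  for (nm in names(spec$params)) {
    p <- spec$params[[nm]]
    if (is.numeric(p) && length(p) == 1L) {
      if (is.null(vals[[nm]])) vals[[nm]] <- p
    } else if (is.numeric(p) && length(p) == 2L) {
      if (is.null(vals[[nm]])) stop("no value supplied for free parameter '", nm, "'")
    } else if (is.list(p)) {
      pending[[nm]] <- p
    } else stop("bad parameter definition: ", nm)
  }
  for (pass in seq_len(length(pending) + 1L)) {
    if (!length(pending)) break
    done <- character()
    for (nm in names(pending)) {
      v <- try_resolve_slot(pending[[nm]], vals)
      if (!is.null(v)) { vals[[nm]] <- v; done <- c(done, nm) }
    }
    if (!length(done)) stop("circular derived parameters: ",
                            paste(names(pending), collapse = ", "))
    pending[done] <- NULL
  }
  unlist(vals)
}

try_resolve_slot <- function(x, vals) {
  if (is.numeric(x)) return(unname(x[1L]))
  if (is.character(x)) {
    v <- vals[[x]]
    return(if (is.null(v)) NULL else unname(v))
  }
  if (is.list(x)) {
    f <- try_resolve_slot(x$frac, vals)
    a <- try_resolve_slot(x$from, vals)
    b <- try_resolve_slot(x$to, vals)
    if (is.null(f) || is.null(a) || is.null(b)) return(NULL)
    return(a + f * (b - a))
  }
  stop("bad slot")
}

resolve_slot <- function(x, vals) {
  v <- try_resolve_slot(x, vals)
  if (is.null(v)) stop("unresolvable slot: ", deparse(x))
  v
}

#' Default values for a model's free parameters
#'
#' The geometric midpoint of each search range; handy for validation and
#' as a deterministic starting point.
#'
#' @param spec a `model_spec`.
#' @return named numeric vector.
#' @export
midpoint_params <- function(spec) {
  fp <- free_params(spec)
  setNames(vapply(fp, function(nm) {
    r <- spec$params[[nm]]
    exp(mean(log(pmax(r, 1e-300))))
  }, 1), fp)
}

#' Validate a demographic model
#'
#' Structural diagnostics, not exceptions: checks that divergences form a
#' single tree, that sizes, rates and times are in range, and that each
#' migration window lies inside the interval in which both of its
#' populations exist (a population exists from time 0 back to the
#' divergence that absorbs it).
#'
#' @param spec a `model_spec`.
#' @param values named numeric values for the free parameters (defaults to
#'   [midpoint_params()]).
#' @return character vector of violations; empty when valid.
#' @export
validate_model <- function(spec, values = NULL) {
  bad <- character()
  vals <- resolve_params(spec, values %||% midpoint_params(spec))
  pops <- names(spec$populations)
  ne <- vapply(spec$populations, resolve_slot, 1, vals = vals)
  if (any(ne <= 0)) bad <- c(bad, "all present-day Ne must be > 0")
  merge_time <- setNames(rep(Inf, length(pops)), pops)
  merged <- character()
  for (dv in spec$divergences) {
    tm <- resolve_slot(dv$time, vals)
    if (tm < 0) bad <- c(bad, "divergence time < 0")
    if (!dv$child %in% pops || !dv$parent %in% pops) {
      bad <- c(bad, sprintf("divergence references unknown population (%s -> %s)",
                            dv$child, dv$parent))
      next
    }
    if (dv$child %in% merged) {
      bad <- c(bad, sprintf("population '%s' diverges more than once", dv$child))
    }
    merged <- c(merged, dv$child)
    merge_time[dv$child] <- tm
  }
  if (length(spec$divergences) != length(pops) - 1L ||
      length(setdiff(pops, merged)) != 1L) {
    bad <- c(bad, "divergences must join all populations into a single tree")
  }
  for (sc in spec$size_changes) {
    if (resolve_slot(sc$ne, vals) <= 0) bad <- c(bad, "size change to Ne <= 0")
    if (resolve_slot(sc$time, vals) < 0) bad <- c(bad, "size change at time < 0")
  }
  eps <- 1e-6
  for (mg in spec$migrations) {
    m <- resolve_slot(mg$m, vals)
    if (m < 0 || m >= 1) bad <- c(bad, "migration rate must lie in [0, 1)")
    t0 <- resolve_slot(mg$t_start, vals)
    t1 <- resolve_slot(mg$t_end, vals)
    if (!(t0 < t1)) bad <- c(bad, sprintf("empty migration window [%g, %g]", t0, t1))
    for (p in c(mg$source, mg$dest)) {
      if (!p %in% pops) { bad <- c(bad, "migration references unknown population"); next }
      if (t1 > merge_time[p] + eps) {
        bad <- c(bad, sprintf(
          "migration window [%g, %g] extends beyond the existence of '%s' (merges at %g)",
          t0, t1, p, merge_time[p]))
      }
    }
  }
  bad
}

#' Compile a model to simulator arguments
#'
#' Translates the declarative spec into the flat deme/event/migration
#' arrays consumed by the coalescent core. Forward-time migration
#' `source -> dest` becomes backward-time lineage movement `dest ->
#' source`; the per-generation probability `m` becomes the continuous rate
#' `-log(1 - m)`, exact for one-generation pulse windows and equal to `m`
#' to first order otherwise.
#'
#' @param spec a `model_spec`.
#' @param values named numeric values for free parameters.
#' @param sample_sizes named vector overriding `spec$sample_sizes`.
#' @param sfs_pops populations forming SFS axes (default: all sampled).
#' @return list of arrays for the simulator core.
#' @keywords internal
compile_model <- function(spec, values = NULL, sample_sizes = NULL,
                          sfs_pops = NULL) {
  vals <- resolve_params(spec, values %||% midpoint_params(spec))
  pops <- names(spec$populations)
  idx <- setNames(seq_along(pops) - 1L, pops)
  ne0 <- vapply(spec$populations, resolve_slot, 1, vals = vals)
  ev <- matrix(0, 0, 5)
  for (dv in spec$divergences) {
    ev <- rbind(ev, c(resolve_slot(dv$time, vals), 0, idx[[dv$child]],
                      idx[[dv$parent]], 0))
  }
  for (sc in spec$size_changes) {
    ev <- rbind(ev, c(resolve_slot(sc$time, vals), 1, idx[[sc$pop]], 0,
                      resolve_slot(sc$ne, vals)))
  }
  if (nrow(ev)) ev <- ev[order(ev[, 1L], ev[, 2L]), , drop = FALSE]
  mg <- matrix(0, 0, 5)
  for (mi in spec$migrations) {
    m <- resolve_slot(mi$m, vals)
    if (m <= 0) next
    mg <- rbind(mg, c(idx[[mi$dest]], idx[[mi$source]], -log1p(-m),
                      resolve_slot(mi$t_start, vals),
                      resolve_slot(mi$t_end, vals)))
  }
  ss <- sample_sizes %||% spec$sample_sizes
  if (is.null(ss)) stop("sample sizes are required for simulation")
  ss <- ss[ss > 0]
  lin_deme <- rep(idx[names(ss)], times = ss)
  sfs_pops <- sfs_pops %||% names(ss)
  dims <- as.integer(ss[sfs_pops]) + 1L
  strides <- cumprod(c(1L, dims[-length(dims)]))
  stride_of <- setNames(rep(0L, length(ss)), names(ss))
  stride_of[sfs_pops] <- strides
  lin_cell <- rep(stride_of[names(ss)], times = ss)
  list(ne0 = unname(ne0), lin_deme = as.integer(unname(lin_deme)),
       lin_cell = as.integer(unname(lin_cell)),
       ncells = as.integer(prod(dims)), dims = dims,
       events = ev, mig = mg,
       sfs_pops = sfs_pops, sample_sizes = as.integer(ss[sfs_pops]),
       pop_of_sample = rep(names(ss), times = ss),
       mutation_rate = spec$mutation_rate,
       locus_length = spec$locus_length)
}

# ---------------------------------------------------------------------------
# The three-population model family: a focal species pair in which one
# species (REC) diverged first, after which the other (flexuosum-like)
# split into two allopatric populations (ENA, EUR). Deme "ENA" carries the
# flexuosum ancestor between the two divergences (size N_ANCFLEX) and deme
# "REC" carries the species ancestor (size N_ANC) beyond the species split.

#' The eight enumerable gene-flow events
#'
#' Six between the three current populations plus two between ancestral
#' populations (`ANC` denotes the ancestor of ENA and EUR, which exists
#' between the two divergence times). Direction is forward in time,
#' written `source>dest`.
#'
#' @return character vector of event ids.
#' @export
gene_flow_events <- function() {
  c("ENA>EUR", "EUR>ENA", "ENA>REC", "REC>ENA", "EUR>REC", "REC>EUR",
    "REC>ANC", "ANC>REC")
}

event_param <- function(ev) paste0("m_", sub(">", "_", ev, fixed = TRUE))

#' Build a three-population gene-flow model
#'
#' Assembles a `model_spec` for the fixed bifurcating history
#' `((ENA, EUR), REC)` with any subset of the eight gene-flow events of
#' [gene_flow_events()]. Ancestral events (`REC>ANC`, `ANC>REC`) can be
#' `"continuous"` over the whole ancestral epoch, `"early"` (a window
#' opening at the species divergence and closing at a free stop time) or
#' `"secondary_contact"` (a window opening at a free contact time after an
#' isolation period and closing at the next divergence).
#'
#' @param events character vector drawn from [gene_flow_events()].
#' @param timing timing mode for the ancestral events.
#' @param params named list overriding/fixing parameter definitions
#'   (numeric length 1 = fixed, length 2 = free range).
#' @param sample_sizes,mutation_rate,locus_length,name passed to
#'   [model_spec()].
#' @return a `model_spec`; its free-parameter count `k` is the AIC count.
#' @export
make_model <- function(events = character(),
                       timing = c("continuous", "early", "secondary_contact"),
                       params = list(), sample_sizes = NULL,
                       mutation_rate = 2.8e-8, locus_length = 90L,
                       name = NULL) {
  timing <- match.arg(timing)
  unknown <- setdiff(events, gene_flow_events())
  if (length(unknown)) stop("unknown gene-flow event: ", unknown[1L])
  defaults <- list(N_REC = c(100, 50000), N_ENA = c(100, 50000),
                   N_EUR = c(100, 50000), N_ANCFLEX = c(100, 50000),
                   N_ANC = c(100, 50000),
                   T_SP = c(500, 50000), rT_FLEX = c(0.05, 0.95),
                   T_FLEX = list(frac = "rT_FLEX", from = 0, to = "T_SP"))
  anc_events <- intersect(events, c("REC>ANC", "ANC>REC"))
  if (length(anc_events) && timing != "continuous") {
    defaults$f_ANC <- c(0.05, 0.95)
    defaults$T_ANC <- list(frac = "f_ANC", from = "T_FLEX", to = "T_SP")
  }
  for (ev in events) defaults[[event_param(ev)]] <- c(1e-6, 0.1)
  for (nm in names(params)) defaults[[nm]] <- params[[nm]]
  migs <- lapply(events, function(ev) {
    parts <- strsplit(ev, ">", fixed = TRUE)[[1L]]
    anc <- "ANC" %in% parts
    src <- if (parts[1L] == "ANC") "ENA" else parts[1L]
    dst <- if (parts[2L] == "ANC") "ENA" else parts[2L]
    if (anc) {
      win <- switch(timing,
                    continuous = list("T_FLEX", "T_SP"),
                    early = list("T_ANC", "T_SP"),
                    secondary_contact = list("T_FLEX", "T_ANC"))
    } else {
      win <- list(0, "T_FLEX")
    }
    list(source = src, dest = dst, m = event_param(ev),
         t_start = win[[1L]], t_end = win[[2L]])
  })
  if (is.null(name)) {
    name <- if (!length(events)) "no_migration"
            else paste0("gf_", paste(sub(">", "-", events), collapse = "_"),
                        if (timing != "continuous") paste0("_", timing) else "")
  }
  model_spec(
    populations = list(REC = "N_REC", ENA = "N_ENA", EUR = "N_EUR"),
    divergences = list(list(time = "T_FLEX", child = "EUR", parent = "ENA"),
                       list(time = "T_SP", child = "ENA", parent = "REC")),
    size_changes = list(list(time = "T_FLEX", pop = "ENA", ne = "N_ANCFLEX"),
                        list(time = "T_SP", pop = "REC", ne = "N_ANC")),
    migrations = migs,
    params = defaults,
    mutation_rate = mutation_rate,
    sample_sizes = sample_sizes,
    locus_length = locus_length,
    name = name)
}

#' The model zoo
#'
#' Every model family named in the analysis design: strict isolation, full
#' migration (all eight events), gene flow among current populations only,
#' the eight leave-one-out variants of the full model, and "model 10"
#' (three events: ENA to EUR, ENA to REC, REC to the flexuosum ancestor),
#' each ancestral-flow family also in early and secondary-contact timing
#' variants. Arbitrary further subsets come from [make_model()].
#'
#' @param ... passed to [make_model()] (e.g. `sample_sizes`, `params`).
#' @return named list of `model_spec`s.
#' @export
model_zoo <- function(...) {
  all8 <- gene_flow_events()
  model10_events <- c("ENA>EUR", "ENA>REC", "REC>ANC")
  zoo <- list(
    no_migration = make_model(character(), name = "no_migration", ...),
    full_migration = make_model(all8, name = "full_migration", ...),
    full_migration_early = make_model(all8, timing = "early",
                                      name = "full_migration_early", ...),
    full_migration_secondary = make_model(all8, timing = "secondary_contact",
                                          name = "full_migration_secondary", ...),
    current_pops_only = make_model(setdiff(all8, c("REC>ANC", "ANC>REC")),
                                   name = "current_pops_only", ...),
    model10 = make_model(model10_events, name = "model10", ...),
    model10_early = make_model(model10_events, timing = "early",
                               name = "model10_early", ...),
    model10_secondary = make_model(model10_events, timing = "secondary_contact",
                                   name = "model10_secondary", ...))
  for (ev in all8) {
    nm <- paste0("drop1_", sub(">", "-", ev, fixed = TRUE))
    zoo[[nm]] <- make_model(setdiff(all8, ev), name = nm, ...)
  }
  zoo
}

#' Two-population isolation-with-migration model
#'
#' Convenience builder for tests and calibration experiments: two
#' populations `P1`, `P2` splitting from an ancestor at `t_div`, with
#' optional directional gene flow over `[0, t_div]`.
#'
#' @param ne1,ne2,ne_anc haploid effective sizes (numeric, or length-2
#'   range to leave free).
#' @param t_div divergence time in generations.
#' @param m12 forward-time rate P1 -> P2; `m21` the reverse.
#' @param sample_sizes named vector (`P1`, `P2`).
#' @param mutation_rate,locus_length see [model_spec()].
#' @return a `model_spec`.
#' @export
im_spec <- function(ne1, ne2, t_div, m12 = 0, m21 = 0, ne_anc = NULL,
                    sample_sizes = c(P1 = 8, P2 = 8),
                    mutation_rate = 2.8e-8, locus_length = 90L) {
  params <- list(N1 = ne1, N2 = ne2, T = t_div,
                 NA_ = ne_anc %||% ne1, m12 = m12, m21 = m21)
  migs <- list()
  if (!identical(m12, 0)) {
    migs <- c(migs, list(list(source = "P1", dest = "P2", m = "m12",
                              t_start = 0, t_end = "T")))
  }
  if (!identical(m21, 0)) {
    migs <- c(migs, list(list(source = "P2", dest = "P1", m = "m21",
                              t_start = 0, t_end = "T")))
  }
  model_spec(populations = list(P1 = "N1", P2 = "N2"),
             divergences = list(list(time = "T", child = "P2", parent = "P1")),
             size_changes = list(list(time = "T", pop = "P1", ne = "NA_")),
             migrations = migs, params = params,
             mutation_rate = mutation_rate, sample_sizes = sample_sizes,
             locus_length = locus_length, name = "im_2pop")
}

#' Symmetric n-island model at a target migrant number
#'
#' Builds a symmetric island model whose equilibrium fixation index
#' matches Wright's haploid prediction `Fst = 1 / (2 Nem + 1)`. The
#' infinite-island formula overstates differentiation for a finite number
#' of demes `d`, where the exact coalescent result is
#' `Fst = 1 / (1 + 2 d N m / (d - 1))`; the per-lineage simulation rate is
#' therefore `m = (Nem / Ne) * (d - 1) / d`, which makes a finite-deme
#' simulation sit at the Fst the infinite-island formula predicts for the
#' given `Nem`.
#'
#' @param ne haploid deme size.
#' @param nem target migrants per generation (island-model sense).
#' @param n_demes number of demes (>= 2).
#' @param n_per_deme haploid sample size per deme.
#' @param t_merge time at which demes merge into one ancestral population
#'   (set far beyond `ne` so the migration equilibrium dominates).
#' @param mutation_rate,locus_length see [model_spec()].
#' @return a `model_spec` with demes `D1..Dd`.
#' @export
island_model_spec <- function(ne, nem, n_demes = 2L, n_per_deme = 10L,
                              t_merge = 200 * ne, mutation_rate = 2.8e-8,
                              locus_length = 90L) {
  stopifnot(n_demes >= 2L)
  m <- (nem / ne) * (n_demes - 1) / n_demes
  demes <- paste0("D", seq_len(n_demes))
  params <- list(NE = ne, TM = t_merge, MIG = m)
  migs <- list()
  for (a in demes) for (b in demes) {
    if (a != b) migs <- c(migs, list(list(source = a, dest = b, m = "MIG",
                                          t_start = 0, t_end = "TM")))
  }
  model_spec(populations = setNames(rep(list("NE"), n_demes), demes),
             divergences = lapply(demes[-1L], function(d)
               list(time = "TM", child = d, parent = demes[1L])),
             migrations = migs, params = params,
             mutation_rate = mutation_rate,
             sample_sizes = setNames(rep(n_per_deme, n_demes), demes),
             locus_length = locus_length, name = "island_model")
}

# ---------------------------------------------------------------------------
# YAML round-trip

#' Read / write a model specification as YAML
#'
#' The on-disk schema mirrors the `model_spec` fields; parameter ranges
#' are two-element sequences, fraction rules are maps with keys
#' `frac`/`from`/`to`.
#'
#' @param spec a `model_spec`.
#' @param path file path.
#' @return `path` (write) or a `model_spec` (read).
#' @export
write_model_yaml <- function(spec, path) {
  raw <- unclass(spec)
  if (!is.null(raw$sample_sizes)) raw$sample_sizes <- as.list(raw$sample_sizes)
  yaml::write_yaml(raw, path)
  invisible(path)
}

#' @rdname write_model_yaml
#' @export
read_model_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(model_spec, raw[c("populations", "divergences", "size_changes",
                            "migrations", "params", "mutation_rate",
                            "sample_sizes", "locus_length", "name")])
}
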