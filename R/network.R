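#' @importFrom stats runif rnorm sd quantile
#' @importFrom utils write.table
NULL

# Run code under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Projection specification
#'
#' One row of the connectivity table: a named projection between two
#' populations with polarity, synaptic weight, wiring pattern, synaptic decay
#' constant and axonal delay.
#'
#' @param name Projection label (e.g. `"TRN->SP"`).
#' @param source,target Population names.
#' @param polarity `"exc"` or `"inh"`.
#' @param g_s Synaptic weight (mS).
#' @param pattern One of `"one_to_one"`, `"one_to_many"`, `"eight_to_one"`,
#'   `"one_to_eight"`, `"all_to_all"`.
#' @param p Connection probability, required for `one_to_many`.
#' @param tau_s Synaptic decay constant (ms), or `NA` for instantaneous
#'   pulse coupling (the cortico-cortical rows).
#' @param delay Axonal delay (ms, integer), or `NA` meaning zero-delay.
#' @return List of class `projection_spec`.
#' @export
projection_spec <- function(name, source, target, polarity, g_s, pattern,
                            p = NA_real_, tau_s = NA_real_, delay = NA_real_) {
  polarity <- match.arg(polarity, c("exc", "inh"))
  pattern <- match.arg(pattern, c("one_to_one", "one_to_many", "eight_to_one",
                                  "one_to_eight", "all_to_all"))
  if (pattern == "one_to_many" && (is.na(p) || p <= 0 || p > 1))
    stop("projection ", name, ": one_to_many requires p in (0, 1]")
  if (!is.na(tau_s) && tau_s <= 0) stop("projection ", name, ": tau_s <= 0")
  structure(list(name = name, source = source, target = target,
                 polarity = polarity, g_s = g_s, pattern = pattern, p = p,
                 tau_s = tau_s, delay = delay),
            class = "projection_spec")
}

#' Default connectivity table of the thalamo-cortical module
#'
#' All 13 projections: Poisson peripheral input lines onto SP and NSP, the
#' intrathalamic loops (SP-TRN one-to-one, divergent TRN-NSP coupling),
#' the topographic cortico-thalamic (8-to-1) and thalamo-cortical (1-to-8 and
#' divergent NSP) pathways, and the instantaneous all-to-all cortico-cortical
#' synapses. `E` denotes the excitatory and `I` the inhibitory cortical
#' subpopulation; `INPUT_SP`/`INPUT_NSP` are the peripheral Poisson sources.
#'
#' @return A list of [projection_spec()] objects.
#' @export
default_projection_table <- function() {
  list(
    projection_spec("Input-SP->SP", "INPUT_SP", "SP", "exc", 0.005,
                    "one_to_one", tau_s = 10, delay = 0),
    projection_spec("Input-NSP->NSP", "INPUT_NSP", "NSP", "exc", 0.005,
                    "one_to_one", tau_s = 10, delay = 0),
    projection_spec("SP->TRN", "SP", "TRN", "exc", 0.018,
                    "one_to_one", tau_s = 10, delay = 3),
    projection_spec("TRN->SP", "TRN", "SP", "inh", 0.35,
                    "one_to_one", tau_s = 75, delay = 3),
    projection_spec("TRN->NSP", "TRN", "NSP", "inh", 0.18,
                    "one_to_many", p = 0.15, tau_s = 75, delay = 3),
    projection_spec("NSP->TRN", "NSP", "TRN", "exc", 0.015,
                    "one_to_many", p = 0.15, tau_s = 10, delay = 3),
    projection_spec("E->TRN", "E", "TRN", "exc", 0.02,
                    "eight_to_one", tau_s = 7, delay = 7),
    projection_spec("E->SP", "E", "SP", "exc", 0.007,
                    "eight_to_one", tau_s = 7, delay = 7),
    projection_spec("E->NSP", "E", "NSP", "exc", 0.02,
                    "eight_to_one", tau_s = 7, delay = 7),
    projection_spec("SP->E", "SP", "E", "exc", 0.002,
                    "one_to_eight", tau_s = 7, delay = 7),
    projection_spec("NSP->E", "NSP", "E", "exc", 0.8,
                    "one_to_many", p = 0.03, tau_s = 7, delay = 7),
    projection_spec("E->E/I", "E", "CRX", "exc", 0.3, "all_to_all"),
    projection_spec("I->I/E", "I", "CRX", "inh", 1, "all_to_all")
  )
}

#' Default population sizes
#' @return Named integer vector: SP, NSP, TRN (100 each), CRX (800 E + 200 I).
#' @export
default_population_sizes <- function() {
  c(SP = 100L, NSP = 100L, TRN = 100L, CRX = 1000L,
    E = 800L, I = 200L, INPUT_SP = 100L, INPUT_NSP = 100L)
}

#' Realize one projection as an edge set
#'
#' Deterministic given `seed`. Patterns: `one_to_one` wires i to i (equal
#' sizes required); `one_to_many` draws each (i, j) pair independently with
#' probability `p`; `eight_to_one` wires the contiguous source block
#' `(8k+1)..(8k+8)` onto target `k+1` (topographic, so a contiguous cortical
#' lesion deafferents a contiguous thalamic zone); `one_to_eight` is its
#' transpose; `all_to_all` is complete, minus self-edges when source and
#' target index the same cells.
#'
#' @param spec A [projection_spec()].
#' @param n_source,n_target Population sizes.
#' @param seed RNG seed for the probabilistic pattern (`NULL` uses the
#'   current RNG state).
#' @param exclude_self For `all_to_all`, drop i -> i edges.
#' @return data.frame with 1-based columns `src`, `tgt` and column `weight`
#'   (signed: negative for inhibitory projections).
#' @export
build_projection <- function(spec, n_source, n_target, seed = NULL,
                             exclude_self = identical(spec$source, spec$target)) {
  w <- if (spec$polarity == "inh") -spec$g_s else spec$g_s
  edges <- switch(spec$pattern,
    one_to_one = {
      if (n_source != n_target)
        stop("projection ", spec$name, ": one_to_one requires equal sizes (",
             n_source, " vs ", n_target, ")")
      data.frame(src = seq_len(n_source), tgt = seq_len(n_target))
    },
    one_to_many = with_seed(seed, {
      keep <- runif(n_source * n_target) < spec$p
      idx <- which(keep) - 1L
      data.frame(src = idx %% n_source + 1L, tgt = idx %/% n_source + 1L)
    }),
    eight_to_one = {
      if (n_source != 8L * n_target)
        stop("projection ", spec$name, ": eight_to_one requires source = 8 x target")
      data.frame(src = seq_len(n_source), tgt = rep(seq_len(n_target), each = 8L))
    },
    one_to_eight = {
      if (n_target != 8L * n_source)
        stop("projection ", spec$name, ": one_to_eight requires target = 8 x source")
      data.frame(src = rep(seq_len(n_source), each = 8L), tgt = seq_len(n_target))
    },
    all_to_all = {
      e <- expand.grid(src = seq_len(n_source), tgt = seq_len(n_target))
      if (exclude_self) e <- e[e$src != e$tgt, ]
      e
    })
  edges$weight <- w
  rownames(edges) <- NULL
  edges
}

#' Build the full network topology
#'
#' Realizes every projection of the connectivity table. The two
#' cortico-cortical all-to-all rows are materialized as one dense weight
#' matrix (targets x sources over the 1000 cortical cells, zero diagonal:
#' no self-connections): instantaneous pulse synapses whose per-edge
#' strength is, by default, drawn uniformly from `[0, g_s]` for excitatory
#' and `[-g_s, 0]` for inhibitory sources, following the reference cortical
#' network this sheet is modeled on. With `cc_weights = "fixed"` every edge
#' instead carries exactly `g_s` (this makes the recurrent excitation
#' overpower inhibition, collapsing the sheet into pathological
#' whole-population volleys; see the methods vignette).
#'
#' @param projections Projection table, default [default_projection_table()].
#' @param sizes Named population sizes, default [default_population_sizes()].
#' @param seed RNG seed for the probabilistic patterns.
#' @param cc_weights `"uniform"` (per-edge uniform random scaling, default)
#'   or `"fixed"` (the printed value on every edge).
#' @return List of class `network_topology`: `sizes`, `projections` (each
#'   spec plus `edges` data.frame, or `w_matrix` for the cortico-cortical
#'   rows), `w_cc` (combined 1000 x 1000 pulse-weight matrix), `seed`,
#'   `lesion_mask` (all-`FALSE` logical over cortical cells).
#' @export
build_network <- function(projections = default_projection_table(),
                          sizes = default_population_sizes(), seed = 1L,
                          cc_weights = c("uniform", "fixed")) {
  cc_weights <- match.arg(cc_weights)
  need <- c("Input-SP->SP", "Input-NSP->NSP", "SP->TRN", "TRN->SP", "TRN->NSP",
            "NSP->TRN", "E->TRN", "E->SP", "E->NSP", "SP->E", "NSP->E",
            "E->E/I", "I->I/E")
  have <- vapply(projections, `[[`, "", "name")
  if (length(miss <- setdiff(need, have)))
    stop("missing projection row(s): ", paste(miss, collapse = ", "))
  n_crx <- sizes[["CRX"]]; n_exc <- sizes[["E"]]
  w_cc <- matrix(0, n_crx, n_crx)
  realized <- with_seed(seed, lapply(projections, function(sp) {
    sp <- unclass(sp)
    if (sp$pattern == "all_to_all") {
      src_idx <- if (sp$source == "I") n_exc + seq_len(sizes[["I"]])
                 else seq_len(sizes[["E"]])
      sgn <- if (sp$polarity == "inh") -1 else 1
      w <- if (cc_weights == "uniform")
        matrix(runif(n_crx * length(src_idx), 0, sp$g_s), n_crx)
      else matrix(sp$g_s, n_crx, length(src_idx))
      w_cc[, src_idx] <<- sgn * w
      sp$edges <- NULL
      sp$implicit <- TRUE
    } else {
      sp$edges <- build_projection(structure(sp, class = "projection_spec"),
                                   sizes[[sp$source]], sizes[[sp$target]],
                                   seed = NULL)
      sp$implicit <- FALSE
    }
    sp
  }))
  diag(w_cc) <- 0
  names(realized) <- have
  structure(list(sizes = sizes, projections = realized, w_cc = w_cc,
                 seed = seed, lesion_mask = logical(n_crx)),
            class = "network_topology")
}

#' Poisson peripheral drive
#'
#' Independent Bernoulli(P) spike trains, one line per target neuron, one
#' draw per 1 ms step. The specific nucleus is driven at P = 0.5 and the
#' non-specific nucleus at P = 0.35, keeping both in a physiological firing
#' range with peripheral dominance for SP.
#'
#' @param P Per-step spike probability in `[0, 1]`.
#' @param n_neurons Number of independent lines.
#' @param n_steps Number of 1 ms steps (> 0).
#' @param seed RNG seed (`NULL` uses the current RNG state).
#' @return Integer 0/1 matrix, `n_neurons` x `n_steps`.
#' @export
poisson_drive <- function(P, n_neurons, n_steps, seed = NULL) {
  stopifnot(P >= 0, P <= 1, n_steps > 0)
  with_seed(seed, {
    m <- matrix((runif(n_neurons * n_steps) < P) + 0L,
                nrow = n_neurons, ncol = n_steps)
    m
  })
}

#' Serialize a topology to a tabular edge list
#'
#' Writes one row per realized edge: projection name, source population,
#' source index, target population, target index, weight, delay. Implicit
#' all-to-all projections are written as a single summary row with index 0.
#'
#' @param topology A [build_network()] result.
#' @param path Output file (tab-separated).
#' @return `path`, invisibly.
#' @export
write_topology <- function(topology, path) {
  rows <- lapply(topology$projections, function(sp) {
    if (isTRUE(sp$implicit)) {
      data.frame(projection = sp$name, source = sp$source, src = 0L,
                 target = sp$target, tgt = 0L,
                 weight = if (sp$polarity == "inh") -sp$g_s else sp$g_s,
                 delay = ifelse(is.na(sp$delay), 0, sp$delay))
    } else {
      data.frame(projection = sp$name, source = sp$source, src = sp$edges$src,
                 target = sp$target, tgt = sp$edges$tgt,
                 weight = sp$edges$weight,
                 delay = ifelse(is.na(sp$delay), 0, sp$delay))
    }
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
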