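#' A tandem repeat array (one homolog)
#'
#' Unit-level representation of a tandem array: an ordered vector of unit
#' types with orientations, flanked (or not) by MGEs at both outer
#' boundaries. A zero-unit array is the epsps-null state left behind by an
#' unequal crossover.
#'
#' @param units Character vector of unit types in order (may be empty).
#' @param orientation Orientations, recycled (default `"forward"`).
#' @param flanked MGE present at both outer boundaries (precondition for
#'   MGE-mediated misalignment).
#' @return A `RepeatArray`.
#' @export
repeat_array <- function(units = "full", orientation = "forward",
                         flanked = TRUE) {
  units <- as.character(units)
  if (length(units) == 1L && is.na(units[1])) units <- character(0)
  structure(list(units = units,
                 orientation = rep_len(orientation, length(units)),
                 flanked = isTRUE(flanked)),
            class = "RepeatArray")
}

#' @export
print.RepeatArray <- function(x, ...) {
  if (n_units(x) == 0) cat("<RepeatArray> epsps_null\n")
  else cat("<RepeatArray>", paste(x$units, collapse = " | "), "\n")
  invisible(x)
}

#' Number of units in an array
#' @param array A `RepeatArray`.
#' @return Integer unit count.
#' @export
n_units <- function(array) length(array$units)

is_null_array <- function(array) n_units(array) == 0L

#' Unequal crossing over between two arrays
#'
#' The arrays misalign at homologous MGE boundaries, shifted by `offset`
#' units, and recombine after unit `breakpoint`. The products carry
#' `n_a + offset` and `n_b - offset` units; total unit count is conserved
#' exactly. `offset = 0` is an equal crossover (both arrays returned with
#' exchanged tails of equal size). With single-unit arrays and `offset = 1`
#' this is the initiating event: one duplicated gamete and one epsps-null
#' gamete.
#'
#' @param a,b `RepeatArray`s (must be MGE-flanked so boundaries can
#'   misalign, unless `require_flanked = FALSE`).
#' @param offset Misalignment in units (`0 <= offset`, and
#'   `breakpoint + offset <= n_b`).
#' @param breakpoint Crossover position: after unit `breakpoint` of `a`
#'   (`0 <= breakpoint <= n_a`).
#' @param require_flanked Enforce the MGE-boundary precondition.
#' @return List with `expanded` (n_a + offset units) and `contracted`
#'   (n_b - offset units).
#' @export
unequal_crossover <- function(a, b, offset, breakpoint,
                              require_flanked = TRUE) {
  stopifnot(inherits(a, "RepeatArray"), inherits(b, "RepeatArray"))
  if (require_flanked && !(a$flanked && b$flanked))
    stop("unequal crossover requires MGE-flanked arrays")
  na <- n_units(a)
  nb <- n_units(b)
  offset <- as.integer(offset)
  breakpoint <- as.integer(breakpoint)
  if (offset < 0 || breakpoint < 0 || breakpoint > na ||
      breakpoint + offset > nb)
    stop("invalid offset/breakpoint: would produce a negative unit count")
  expanded <- repeat_array(
    c(b$units[seq_len(breakpoint + offset)], a$units[seq_len(na - breakpoint) + breakpoint]),
    c(b$orientation[seq_len(breakpoint + offset)],
      a$orientation[seq_len(na - breakpoint) + breakpoint]),
    a$flanked)
  rest_b <- if (breakpoint + offset < nb) (breakpoint + offset + 1L):nb else integer(0)
  contracted <- repeat_array(
    c(a$units[seq_len(breakpoint)], b$units[rest_b]),
    c(a$orientation[seq_len(breakpoint)], b$orientation[rest_b]),
    b$flanked)
  list(expanded = expanded, contracted = contracted)
}

#' Microhomology-mediated truncation of a full unit
#'
#' A double-stranded break at an MGE boundary repaired through a short
#' microhomology within the repeat converts a full-length unit into the
#' truncated type; the unit count never changes.
#'
#' @param array A `RepeatArray`.
#' @param unit_index Index of the unit to truncate; must be a full-type
#'   unit.
#' @return The modified `RepeatArray`.
#' @export
microhomology_truncation <- function(array, unit_index) {
  n <- n_units(array)
  unit_index <- as.integer(unit_index)
  if (unit_index < 1L || unit_index > n) stop("unit_index out of range")
  if (array$units[unit_index] != "full")
    stop("truncation requires a full-type unit at the given index")
  array$units[unit_index] <- "truncated"
  array
}

#' Configuration for the array-evolution simulator
#'
#' The mechanism (MGE-mediated misalignment, unequal crossover,
#' microhomology truncation) is fixed; the rates are free parameters with
#' deliberately modest defaults: crossover 0.01 per meiosis, truncation
#' 0.001 per meiosis, misalignment offset geometric with p = 0.7 (so mostly
#' one-unit slips).
#'
#' @param population_size Diploid population size (>= 2), held constant.
#' @param generations Number of generations to simulate.
#' @param crossover_rate Per-meiosis probability of an unequal crossover.
#' @param truncation_rate Per-meiosis probability of a truncation event.
#' @param offset_geom_p Geometric parameter for the misalignment offset
#'   (offset = 1 + Geom(p), clipped to what the arrays allow).
#' @param selection `NULL` for flat fitness, or a function mapping diploid
#'   total unit count to relative fitness.
#' @param seed Integer seed; identical config + seed gives an identical
#'   trajectory.
#' @return An `EvolutionConfig` list.
#' @export
evolution_config <- function(population_size = 50L, generations = 50L,
                             crossover_rate = 0.01, truncation_rate = 0.001,
                             offset_geom_p = 0.7, selection = NULL,
                             seed = 1L) {
  stopifnot(population_size >= 2, generations >= 0,
            crossover_rate >= 0, crossover_rate <= 1,
            truncation_rate >= 0, truncation_rate <= 1,
            offset_geom_p > 0, offset_geom_p <= 1)
  if (!is.null(selection)) stopifnot(is.function(selection))
  structure(list(population_size = as.integer(population_size),
                 generations = as.integer(generations),
                 crossover_rate = crossover_rate,
                 truncation_rate = truncation_rate,
                 offset_geom_p = offset_geom_p,
                 selection = selection, seed = as.integer(seed)),
            class = "EvolutionConfig")
}

#' Step fitness in copy number
#'
#' Herbicide-selection stand-in: individuals at or above `threshold` total
#' units have fitness `high`, others `low`.
#'
#' @param threshold Diploid total unit count for full fitness.
#' @param low,high Relative fitnesses.
#' @return A fitness function for [evolution_config()].
#' @export
step_selection <- function(threshold = 3L, low = 0.2, high = 1) {
  force(threshold); force(low); force(high)
  function(total_units) ifelse(total_units >= threshold, high, low)
}

# One meiosis: returns a gamete (unit-type character vector).
meiosis <- function(homolog_a, homolog_b, cfg) {
  ga <- homolog_a
  gb <- homolog_b
  if (runif(1) < cfg$crossover_rate) {
    na <- length(ga)
    nb <- length(gb)
    offset <- 1L + rgeom(1, cfg$offset_geom_p)
    offset <- min(offset, nb)
    if (offset >= 1L && nb - offset >= 0L && min(na, nb - offset) >= 0L) {
      bp_max <- min(na, nb - offset)
      if (bp_max >= 0L) {
        bp <- sample.int(bp_max + 1L, 1L) - 1L
        expanded <- c(gb[seq_len(bp + offset)], ga[seq_len(na - bp) + bp])
        contracted <- c(ga[seq_len(bp)],
                        if (bp + offset < nb) gb[(bp + offset + 1L):nb] else character(0))
        if (runif(1) < 0.5) {
          ga <- expanded; gb <- contracted
        } else {
          ga <- contracted; gb <- expanded
        }
      }
    }
  }
  gam <- if (runif(1) < 0.5) ga else gb
  if (runif(1) < cfg$truncation_rate) {
    full_idx <- which(gam == "full")
    if (length(full_idx) > 0)
      gam[full_idx[sample.int(length(full_idx), 1L)]] <- "truncated"
  }
  gam
}

#' Simulate tandem-array evolution in a population
#'
#' Wright--Fisher-style simulation of the unequal-crossover model: every
#' individual starts with a single MGE-flanked full unit on each homolog;
#' each generation, offspring are formed from fitness-weighted parents via
#' meiosis with unequal crossover at `crossover_rate` (geometric offset) and
#' microhomology truncation at `truncation_rate`; zygotes null on both
#' homologs are inviable (the epsps-null/epsps-null genotype is lethal) and
#' are redrawn. The per-generation distribution of diploid total unit count
#' is recorded.
#'
#' @param config An `EvolutionConfig`.
#' @return List with `trajectory` (data.frame `generation`, `mean_copies`,
#'   `var_copies`, `min_copies`, `max_copies`), `final_population` (list of
#'   `list(a, b)` unit-type vectors), `extinct` (logical), `config`.
#' @export
simulate_generations <- function(config) {
  stopifnot(inherits(config, "EvolutionConfig"))
  with_seed(config$seed, {
    N <- config$population_size
    fit_fun <- if (is.null(config$selection)) function(x) rep(1, length(x)) else config$selection
    pop <- replicate(N, list(a = "full", b = "full"), simplify = FALSE)
    totals <- vapply(pop, function(ind) length(ind$a) + length(ind$b), numeric(1))
    traj <- list(data.frame(generation = 0L, mean_copies = mean(totals),
                            var_copies = var(totals), min_copies = min(totals),
                            max_copies = max(totals)))
    extinct <- FALSE
    for (gen in seq_len(config$generations)) {
      w <- fit_fun(totals)
      if (all(w <= 0)) { extinct <- TRUE; break }
      newpop <- vector("list", N)
      for (i in seq_len(N)) {
        viable <- FALSE
        for (attempt in 1:1000) {
          parents <- sample.int(N, 2L, replace = TRUE, prob = w)
          g1 <- meiosis(pop[[parents[1]]]$a, pop[[parents[1]]]$b, config)
          g2 <- meiosis(pop[[parents[2]]]$a, pop[[parents[2]]]$b, config)
          if (length(g1) + length(g2) > 0) { viable <- TRUE; break }
        }
        if (!viable) { extinct <- TRUE; break }
        newpop[[i]] <- list(a = g1, b = g2)
      }
      if (extinct) break
      pop <- newpop
      totals <- vapply(pop, function(ind) length(ind$a) + length(ind$b), numeric(1))
      traj[[length(traj) + 1L]] <- data.frame(
        generation = gen, mean_copies = mean(totals), var_copies = var(totals),
        min_copies = min(totals), max_copies = max(totals))
    }
    list(trajectory = do.call(rbind, traj), final_population = pop,
         extinct = extinct, config = config)
  })
}
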