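# Seeded synthetic count-table generation with known ground truth, so the
# metrics pipeline can be exercised end-to-end without any measured data.

#' Specification for synthetic count-table generation
#'
#' Fixes the ground truth of a synthetic experiment: for every cell class,
#' the probability that a cell ends up in each section, the total number
#' of cells per class per disk, the number of replicate disks, and the
#' random seed. Counts are later drawn class-wise from a multinomial over
#' sections, so per-class totals are exact by construction.
#'
#' @param probabilities named list, one element per cell class; each a
#'   named numeric vector of per-section probabilities summing to 1.
#' @param totals named numeric vector of per-class totals (> 0); names
#'   must match `probabilities`.
#' @param n_disks number of replicate disks (>= 1).
#' @param seed integer seed governing the whole table; per-disk streams
#'   are derived by a fixed increment of 1000.
#' @return an object of class `generation_spec`.
#' @examples
#' generation_spec(list(WBC = c(E = 0.95, C = 0.01, A = 0.04)),
#'                 totals = c(WBC = 10000), n_disks = 3, seed = 1)
#' @export
generation_spec <- function(probabilities, totals, n_disks = 1, seed = 1) {
  stopifnot(is.list(probabilities), length(probabilities) >= 1L)
  if (is.null(names(probabilities)) || any(names(probabilities) == ""))
    stop("probabilities must be a named list (one element per cell class)",
         call. = FALSE)
  for (cl in names(probabilities)) {
    p <- probabilities[[cl]]
    if (is.null(names(p)) || any(names(p) == ""))
      stop("per-section probabilities for '", cl, "' must be named by section",
           call. = FALSE)
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
      stop("probabilities for '", cl,
           "' must be non-negative and sum to 1", call. = FALSE)
  }
  if (!setequal(names(totals), names(probabilities)))
    stop("totals must be named to match the probability classes",
         call. = FALSE)
  if (any(totals <= 0) || any(totals != round(totals)))
    stop("totals must be positive integers", call. = FALSE)
  if (n_disks < 1) stop("n_disks must be >= 1", call. = FALSE)
  structure(list(probabilities = probabilities,
                 totals = totals[names(probabilities)],
                 n_disks = as.integer(n_disks),
                 seed = as.integer(seed)),
            class = "generation_spec")
}

#' Draw a synthetic count table from a generation spec
#'
#' For each disk and cell class, draws the per-section counts from a
#' multinomial with the spec's probabilities and the class total. The
#' draw is reproducible: disk `i` uses seed `seed + 1000 * (i - 1)`.
#'
#' @param spec a [generation_spec()].
#' @return a [count_table()].
#' @examples
#' spec <- generation_spec(list(WBC = c(E = 1)), c(WBC = 1000))
#' generate_count_table(spec)
#' @export
generate_count_table <- function(spec) {
  stopifnot(inherits(spec, "generation_spec"))
  rows <- list()
  for (d in seq_len(spec$n_disks)) {
    set.seed(spec$seed + 1000L * (d - 1L))
    for (cl in names(spec$probabilities)) {
      p <- spec$probabilities[[cl]]
      counts <- as.vector(stats::rmultinom(1, size = spec$totals[[cl]],
                                           prob = p))
      rows[[length(rows) + 1L]] <-
        data.frame(disk = d, section = names(p), cell_class = cl,
                   count = counts, stringsAsFactors = FALSE)
    }
  }
  count_table(do.call(rbind, rows))
}

#' Generation spec from a model-predicted partition
#'
#' Closes the loop from physics to measurement: converts the partition
#' predicted by [predict_partitions()] into a near-deterministic
#' probability spec, with mass `1 - epsilon` on each species' predicted
#' section and `epsilon` spread uniformly over the remaining sections
#' (carry-over and counting noise). Sampling a table from the result and
#' running [partition_metrics()] on it recovers the predicted target
#' section as the retention maximum.
#'
#' @param lane a [lane_design()].
#' @param panel list of [cell_species()].
#' @param protocol a [spin_protocol()].
#' @param totals named per-class totals (names = species names); a single
#'   unnamed number is recycled to all species.
#' @param n_disks number of replicate disks.
#' @param seed integer seed.
#' @param epsilon off-target probability mass in `[0, 1)`, default 0.02.
#' @return a [generation_spec()].
#' @export
generate_prediction_fixture <- function(lane, panel, protocol,
                                        totals = 10000, n_disks = 3,
                                        seed = 1, epsilon = 0.02) {
  if (epsilon < 0 || epsilon >= 1)
    stop("epsilon must lie in [0, 1)", call. = FALSE)
  parts <- predict_partitions(panel, lane, protocol)
  sections <- vapply(lane$sections, `[[`, character(1), "label")
  probs <- lapply(seq_len(nrow(parts)), function(i) {
    p <- stats::setNames(rep(0, length(sections)), sections)
    tgt <- parts$section[i]
    if (length(sections) == 1L) {
      p[tgt] <- 1
    } else {
      p[] <- epsilon / (length(sections) - 1L)
      p[tgt] <- 1 - epsilon
    }
    p
  })
  names(probs) <- parts$species
  if (is.null(names(totals)))
    totals <- stats::setNames(rep(totals, length.out = nrow(parts)),
                              parts$species)
  generation_spec(probs, totals, n_disks = n_disks, seed = seed)
}
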