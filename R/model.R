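# Central modelling object: one lane + fluid + protocol + cell panel,
# with the classic method surface (print / summary / predict / plot /
# simulate) over the physics functions.

#' Assemble a disk separation model
#'
#' Bundles a lane design, the sample fluid, a spin protocol and a cell
#' panel into a single model object. The object's methods answer the
#' design questions the physics supports: `predict()` gives the end-of-run
#' partition of the panel (or full migration schedules), `summary()` adds
#' the per-valve burst thresholds, `plot()` draws the cumulative migration
#' timeline, and `simulate()` draws synthetic replicate count tables whose
#' ground truth is the predicted partition.
#'
#' @param lane a [lane_design()]; default: the reference lane loaded with
#'   the sample in section F.
#' @param fluid a [fluid_sample()].
#' @param protocol a [spin_protocol()].
#' @param panel list of [cell_species()].
#' @return an object of class `disk_model`.
#' @examples
#' m <- disk_model(panel = reference_cell_panel(rbc_agglutination = 3))
#' predict(m)
#' @export
disk_model <- function(lane = reference_lane(sample_fluid = fluid),
                       fluid = fluid_sample(),
                       protocol = spin_protocol(),
                       panel = reference_cell_panel()) {
  stopifnot(inherits(lane, "lane_design"), inherits(fluid, "fluid_sample"),
            inherits(protocol, "spin_protocol"), is.list(panel))
  structure(list(lane = lane, fluid = fluid, protocol = protocol,
                 panel = panel),
            class = "disk_model")
}

#' @export
print.disk_model <- function(x, ...) {
  cat("Disk separation model\n")
  cat(sprintf("  lane: %d sections, disk radius %g mm\n",
              length(x$lane$sections), x$lane$disk_radius))
  cat(sprintf("  protocol: %g RCF for %g s (+ramps)\n",
              x$protocol$plateau_rcf, x$protocol$plateau_duration))
  cat(sprintf("  panel: %s\n",
              paste(vapply(x$panel, `[[`, character(1), "name"),
                    collapse = ", ")))
  invisible(x)
}

#' Predict partitions or migration schedules from a disk model
#'
#' @param object a [disk_model()].
#' @param type `"partitions"` for the end-of-run [predict_partitions()]
#'   map, `"schedules"` for per-species [migration_schedule()] results.
#' @param ... unused.
#' @return a `partition_map`, or a named list of `migration_result`.
#' @export
predict.disk_model <- function(object, type = c("partitions", "schedules"),
                               ...) {
  type <- match.arg(type)
  if (type == "partitions")
    predict_partitions(object$panel, object$lane, object$protocol)
  else
    lapply(object$panel, migration_schedule, lane = object$lane,
           protocol = object$protocol)
}

#' @export
summary.disk_model <- function(object, ...) {
  structure(list(model = object,
                 burst = burst_table(object$lane, object$fluid),
                 partitions = predict(object, "partitions"),
                 ramp_correction_s = ramp_correction(object$protocol)),
            class = "summary.disk_model")
}

#' @export
print.summary.disk_model <- function(x, ...) {
  print(x$model)
  cat("\nCapillary valve burst thresholds:\n")
  print(x$burst, digits = 4, row.names = FALSE)
  cat(sprintf("\nRamp correction: %.1f s\n", x$ramp_correction_s))
  cat("\n")
  print(x$partitions)
  invisible(x)
}

#' Plot cumulative migration times of the panel
#'
#' A timeline of when each species clears successive section boundaries at
#' plateau speed (ramp correction included); species that never leave
#' their trapping interface are listed as non-migrating.
#'
#' @param x a [disk_model()].
#' @param ... further arguments passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.disk_model <- function(x, ...) {
  sched <- predict(x, "schedules")
  corr <- ramp_correction(x$protocol)
  labels <- vapply(x$lane$sections, `[[`, character(1), "label")
  nb <- length(labels)
  tmat <- sapply(sched, function(s) {
    tt <- rep(NA_real_, nb)
    if (nrow(s$boundary_arrivals))
      tt[seq_len(nrow(s$boundary_arrivals))] <-
        s$boundary_arrivals$cumulative_time_s + corr
    tt
  })
  movers <- colnames(tmat)[colSums(!is.na(tmat)) > 0]
  graphics::matplot(seq_len(nb), tmat, type = "b", pch = 19, lty = 1,
                    xaxt = "n", xlab = "boundary cleared (distal edge of)",
                    ylab = "cumulative time incl. ramps (s)",
                    main = "Predicted migration timeline", ...)
  graphics::axis(1, at = seq_len(nb), labels = labels[seq_len(nb)])
  graphics::legend("topleft", legend = colnames(tmat),
                   col = seq_len(ncol(tmat)), pch = 19, cex = 0.8)
  non <- setdiff(colnames(tmat), movers)
  if (length(non))
    graphics::mtext(paste("non-migrating:", paste(non, collapse = ", ")),
                    side = 3, cex = 0.8)
  invisible(x)
}

#' Simulate synthetic count tables from a disk model
#'
#' Draws replicate count tables whose ground-truth partition is the
#' model's own prediction: each species places mass `1 - epsilon` in its
#' predicted section and `epsilon` spread uniformly elsewhere (see
#' [generate_prediction_fixture()]).
#'
#' @param object a [disk_model()].
#' @param nsim number of replicate disks.
#' @param seed integer seed (required for reproducibility; default 1).
#' @param totals per-class cell totals (named, or one number for all).
#' @param epsilon off-target probability mass.
#' @param ... unused.
#' @return a [count_table()] with `nsim` disks.
#' @export
simulate.disk_model <- function(object, nsim = 3, seed = 1,
                                totals = 10000, epsilon = 0.02, ...) {
  spec <- generate_prediction_fixture(object$lane, object$panel,
                                      object$protocol, totals = totals,
                                      n_disks = nsim, seed = seed,
                                      epsilon = epsilon)
  generate_count_table(spec)
}
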