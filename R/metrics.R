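# Fraction count-table analysis: retention, exclusion and enrichment of
# cell classes across disk sections, with across-disk replicate summaries.

#' Construct a validated fraction count table
#'
#' A count table records, for each replicate disk, how many cells of each
#' class were recovered from each lane section. The sections present in
#' the table define the counting universe: if intermediate sections were
#' pooled or represented by one section during counting, the metrics use
#' exactly the sections given, matching how such tables are reported.
#'
#' @param x a data.frame with columns `disk`, `section`, `cell_class`,
#'   `count` (non-negative integers; `(disk, section, cell_class)` unique).
#' @return the validated data.frame with class `count_table`.
#' @examples
#' count_table(data.frame(disk = 1, section = c("E", "A"),
#'                        cell_class = "WBC", count = c(9515, 485)))
#' @export
count_table <- function(x) {
  stopifnot(is.data.frame(x))
  need <- c("disk", "section", "cell_class", "count")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols))
    stop("count table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  x <- as.data.frame(x)[need]
  if (!is.numeric(x$count))
    stop("counts must be numeric", call. = FALSE)
  bad <- which(x$count < 0 | x$count != round(x$count) | !is.finite(x$count))
  if (length(bad))
    stop("counts must be non-negative integers; offending row(s): ",
         paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
  key <- paste(x$disk, x$section, x$cell_class, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup))
    stop("duplicate (disk, section, cell_class) key at row(s): ",
         paste(utils::head(dup, 5), collapse = ", "), call. = FALSE)
  x$count <- as.integer(round(x$count))
  class(x) <- c("count_table", "data.frame")
  x
}

#' Per-disk separation metrics for one target section
#'
#' For each replicate disk, computes how well a target cell class is
#' concentrated in a chosen section:
#' \itemize{
#'   \item retention: percentage of the target class recovered in the
#'     target section, out of that class's total across all sections;
#'   \item exclusion: percentage of the contaminant class \emph{not} in
#'     the target section;
#'   \item enrichment fold: the target:contaminant ratio in the section
#'     divided by the overall target:contaminant ratio.
#' }
#' A disk with a zero total for a class has that metric undefined and
#' reported as `NA` (never as 0 or 100).
#'
#' @param table a [count_table()].
#' @param target_class cell class to be recovered (e.g. `"WBC"`).
#' @param contaminant_class cell class to be excluded (e.g. `"RBC"`).
#' @param target_section section label in which the target is collected.
#' @return a data.frame with one row per disk: `disk`, `retention_pct`,
#'   `exclusion_pct`, `enrichment_fold`. Percentages are full precision;
#'   round at presentation.
#' @examples
#' tab <- count_table(data.frame(
#'   disk = 1,
#'   section = rep(c("E", "C", "A"), 2),
#'   cell_class = rep(c("WBC", "RBC"), each = 3),
#'   count = c(9515, 100, 385, 2000, 8000, 990000)))
#' partition_metrics(tab, "WBC", "RBC", "E")  # 95.15% retained, 99.8% excluded
#' @export
partition_metrics <- function(table, target_class, contaminant_class,
                              target_section) {
  table <- count_table(table)
  if (!target_section %in% table$section)
    stop("target section '", target_section, "' not present in the table",
         call. = FALSE)
  for (cl in c(target_class, contaminant_class))
    if (!cl %in% table$cell_class)
      stop("cell class '", cl, "' not present in the table", call. = FALSE)
  disks <- unique(table$disk)
  rows <- lapply(disks, function(d) {
    sub <- table[table$disk == d, , drop = FALSE]
    tot_t <- sum(sub$count[sub$cell_class == target_class])
    tot_c <- sum(sub$count[sub$cell_class == contaminant_class])
    in_t <- sum(sub$count[sub$cell_class == target_class &
                            sub$section == target_section])
    in_c <- sum(sub$count[sub$cell_class == contaminant_class &
                            sub$section == target_section])
    retention <- if (tot_t > 0) 100 * in_t / tot_t else NA_real_
    exclusion <- if (tot_c > 0) 100 * (1 - in_c / tot_c) else NA_real_
    enrichment <- if (tot_t > 0 && tot_c > 0) {
      overall <- tot_t / tot_c
      if (in_c > 0) (in_t / in_c) / overall
      else if (in_t > 0) Inf else NA_real_
    } else NA_real_
    if (tot_t == 0 || tot_c == 0)
      warning("disk ", d, ": zero total for a class; metric reported as NA",
              call. = FALSE)
    data.frame(disk = d, retention_pct = retention,
               exclusion_pct = exclusion, enrichment_fold = enrichment)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Across-disk summary of separation metrics
#'
#' Computes per-disk metrics with [partition_metrics()] and summarises
#' each across replicate disks by the arithmetic mean and sample standard
#' deviation ("on average" figures in separation reports are across-disk
#' means). With a single disk the mean is reported and the dispersion is
#' `NA`.
#'
#' @inheritParams partition_metrics
#' @return a data.frame with one row per metric: `metric`, `mean`, `sd`,
#'   `n_disks`.
#' @examples
#' tab <- count_table(data.frame(
#'   disk = rep(1:3, each = 2), section = rep(c("E", "A"), 3),
#'   cell_class = "WBC", count = c(94, 6, 95, 5, 9645, 355)))
#' summarize_disks(tab, "WBC", "WBC", "E")
#' @export
summarize_disks <- function(table, target_class, contaminant_class,
                            target_section) {
  per_disk <- partition_metrics(table, target_class, contaminant_class,
                                target_section)
  metrics <- c("retention_pct", "exclusion_pct", "enrichment_fold")
  n <- nrow(per_disk)
  out <- data.frame(
    metric = metrics,
    mean = vapply(metrics, function(m) mean(per_disk[[m]]), numeric(1)),
    sd = if (n >= 2L)
      vapply(metrics, function(m) stats::sd(per_disk[[m]]), numeric(1))
    else rep(NA_real_, length(metrics)),
    n_disks = n,
    row.names = NULL, stringsAsFactors = FALSE
  )
  out
}
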