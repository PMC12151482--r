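#' Write a result table as TSV
#'
#' Plain tab-separated output with a header row; used by the experiment
#' runner and the command-line interface.
#'
#' @param x A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a lineage trajectory as TSV
#'
#' Columns `time`, `concentration`, `event_flag`; reproducible given the
#' generating configuration and seed.
#'
#' @param trajectory A trajectory tibble from [simulate_lineage_feedback()]
#'   or [simulate_lineage_partitioning()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_tsv <- function(trajectory, path) {
  stopifnot(all(c("time", "x", "event") %in% names(trajectory)))
  out <- data.frame(time = trajectory$time,
                    concentration = trajectory$x,
                    event_flag = trajectory$event)
  write_tsv_table(out, path)
}

#' Write colony snapshots as TSV
#'
#' One row per cell: `colony_id`, `cell_id`, `parent_id`, `birth_time`,
#' `concentration` (plus `alive`).
#'
#' @param snapshots A `colony_snapshot` or list of them.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_snapshot_tsv <- function(snapshots, path) {
  if (inherits(snapshots, "colony_snapshot")) snapshots <- list(snapshots)
  out <- purrr::map_dfr(snapshots, function(s) {
    data.frame(colony_id = s$colony_id,
               cell_id = s$cells$cell,
               parent_id = s$cells$parent,
               birth_time = s$cells$birth_time,
               concentration = s$cells$x,
               alive = s$cells$alive)
  })
  write_tsv_table(out, path)
}
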