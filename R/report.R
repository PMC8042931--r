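# Sweep reporting: TSV tables, a JSON summary and per-condition bar panels
# (persistence count vs. beneficial probability).

#' Write sweep tables and persistence panels
#'
#' Emits `runs.tsv` (one row per run), `aggregates.tsv` (persistence counts
#' by bp level and by condition), `summary.json`, and one bar panel per
#' condition showing the number of replicates that persisted at each
#' beneficial-probability level. Panels are PNG where a PNG device is
#' available, PDF otherwise.
#'
#' @param result a `te_sweep_result`.
#' @param output_dir directory to write into (created if needed).
#' @return character vector of written paths, invisibly.
#' @export
render_report <- function(result, output_dir) {
  stopifnot(inherits(result, "te_sweep_result"))
  if (!dir.exists(output_dir) &&
      !dir.create(output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", output_dir)

  paths <- character(0)
  runs_path <- file.path(output_dir, "runs.tsv")
  utils::write.table(result$runs, runs_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths <- c(paths, runs_path)

  pt <- result$persistence
  agg_path <- file.path(output_dir, "aggregates.tsv")
  by_bp <- cbind(group = "bp", level = pt$by_bp$bp,
                 pt$by_bp[c("n_runs", "n_persist")])
  by_cond <- cbind(group = "condition", level = pt$by_condition$condition,
                   pt$by_condition[c("n_runs", "n_persist")])
  utils::write.table(rbind(by_bp, by_cond), agg_path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  paths <- c(paths, agg_path)

  sum_path <- file.path(output_dir, "summary.json")
  jsonlite::write_json(
    list(n_runs = nrow(result$runs), total_persist = pt$total_persist,
         by_bp = pt$by_bp, by_condition = pt$by_condition),
    sum_path, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, sum_path)

  if (nrow(result$runs) > 0) {
    ext <- if (isTRUE(capabilities("png")[["png"]])) "png" else "pdf"
    for (cc in unique(result$runs$condition)) {
      sub <- result$runs[result$runs$condition == cc, ]
      counts <- tapply(sub$outcome == "PERSIST", sub$bp, sum)
      df <- data.frame(bp = as.numeric(names(counts)),
                       n_persist = as.vector(counts))
      max_reps <- max(tapply(sub$outcome, sub$bp, length))
      p <- ggplot2::ggplot(df, ggplot2::aes(x = factor(bp), y = n_persist)) +
        ggplot2::geom_col(fill = "darkgreen") +
        ggplot2::scale_y_continuous(limits = c(0, max_reps),
                                    breaks = 0:max_reps) +
        ggplot2::labs(title = cc, x = "Probability of beneficial insertion",
                      y = "Runs with TE persistence") +
        ggplot2::theme_minimal()
      panel_path <- file.path(output_dir, paste0("panel_", cc, ".", ext))
      ggplot2::ggsave(panel_path, p, width = 4, height = 3, dpi = 150)
      paths <- c(paths, panel_path)
    }
  }
  invisible(paths)
}
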