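#' Figures for scans, curves and weight reports
#'
#' Plot builders for the standard analyses: the per-size
#' transfer-entropy vs importance scatter grid, the per-size mean
#' curves, the pooled weight histograms and rank curves, and the
#' single-weight importance heatmap.
#'
#' @param paired A [te_importance_scan()] table with importance.
#' @return A ggplot object.
#' @export
plot_te_importance_grid <- function(paired) {
  stopifnot("importance" %in% names(paired))
  ggplot2::ggplot(paired,
                  ggplot2::aes(x = .data$importance,
                               y = .data$te_bits)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.7) +
    ggplot2::facet_wrap(~set_size, nrow = 3) +
    ggplot2::labs(x = "importance I (mean fitness loss)",
                  y = "TE (bits)",
                  title = "Set transfer entropy vs weight-group importance")
}

#' @rdname plot_te_importance_grid
#' @param curves A [set_size_curves()] table.
#' @export
plot_set_size_curves <- function(curves) {
  long <- rbind(
    data.frame(method = curves$method, set_size = curves$set_size,
               quantity = "mean TE (bits)", value = curves$mean_te,
               se = curves$se_te),
    data.frame(method = curves$method, set_size = curves$set_size,
               quantity = "mean TE per node (bits)",
               value = curves$mean_te_per_node,
               se = curves$se_te_per_node)
  )
  if ("mean_importance" %in% names(curves)) {
    long <- rbind(long, data.frame(
      method = curves$method, set_size = curves$set_size,
      quantity = "mean importance",
      value = curves$mean_importance, se = curves$se_importance
    ))
  }
  ggplot2::ggplot(long, ggplot2::aes(x = .data$set_size,
                                     y = .data$value,
                                     colour = .data$method)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - .data$se,
                   ymax = .data$value + .data$se,
                   fill = .data$method),
      alpha = 0.25, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "source-set size |S|", y = NULL,
                  title = "Robustness and information flow by set size")
}

#' @rdname plot_te_importance_grid
#' @param report A [weight_distribution_report()].
#' @export
plot_weight_distributions <- function(report) {
  stopifnot(inherits(report, "weight_report"))
  ggplot2::ggplot(report$weights,
                  ggplot2::aes(x = .data$weight,
                               colour = .data$method)) +
    ggplot2::geom_freqpoly(bins = 60) +
    ggplot2::labs(x = "recurrent weight", y = "count",
                  title = "Pooled recurrent-weight distributions")
}

#' @rdname plot_te_importance_grid
#' @export
plot_weight_rank_curves <- function(report) {
  stopifnot(inherits(report, "weight_report"))
  ggplot2::ggplot(report$rank_curves,
                  ggplot2::aes(x = .data$rank, y = .data$weight,
                               colour = .data$method,
                               group = interaction(.data$method,
                                                   .data$network_id))) +
    ggplot2::geom_line(alpha = 0.5, linewidth = 0.3) +
    ggplot2::labs(x = "rank", y = "weight",
                  title = "Rank-sorted recurrent weights per network")
}

#' @rdname plot_te_importance_grid
#' @param imat An [importance_matrix()].
#' @export
plot_importance_heatmap <- function(imat) {
  d <- expand.grid(target = seq_len(nrow(imat)) - 1L,
                   source = seq_len(ncol(imat)) - 1L)
  d$I <- as.vector(imat)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$source, y = .data$target,
                                  fill = .data$I)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "source node j", y = "target node i",
                  title = "Single-weight importance of M")
}

#' @rdname plot_te_importance_grid
#' @param run A `training_run` with snapshots (see `snapshot_every`).
#' @export
plot_weight_trajectories <- function(run) {
  if (length(run$snapshots) == 0) {
    stop("plot_weight_trajectories: run has no snapshots; ",
         "train with snapshot_every > 0")
  }
  d <- do.call(rbind, lapply(seq_along(run$snapshots), function(k) {
    data.frame(snapshot = k, weight_id = seq_len(N_HID * N_HID),
               value = as.vector(run$snapshots[[k]]))
  }))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$snapshot, y = .data$value,
                                  group = .data$weight_id)) +
    ggplot2::geom_line(alpha = 0.2, linewidth = 0.2) +
    ggplot2::labs(x = "snapshot", y = "recurrent weight",
                  title = paste0("Recurrent-weight trajectories (",
                                 run$method, ")"))
}

#' Render a full analysis report to a directory
#'
#' Writes the figures for the paired scan, the per-size curves and the
#' weight comparison, every numeric table backing them as
#' tab-delimited text, and a JSON-like manifest (seeds, configs,
#' package version, MD5 hashes of the emitted tables) from which the
#' report can be regenerated.
#'
#' @param outdir Output directory (created if missing).
#' @param paired A [te_importance_scan()] table with importance.
#' @param weight_report A [weight_distribution_report()].
#' @param seed The master seed the scans were run with (recorded in
#'   the manifest).
#' @param device `"pdf"` (default) or `"png"`.
#' @return Invisibly, the manifest as a named list.
#' @export
build_report <- function(outdir, paired, weight_report, seed = NA,
                         device = c("pdf", "png")) {
  device <- match.arg(device)
  if (is.null(paired) || nrow(paired) == 0) {
    stop("build_report: empty paired scan; nothing to report")
  }
  stopifnot(inherits(weight_report, "weight_report"))
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  curves <- set_size_curves(paired)
  correl <- correlation_by_size(paired)

  tables <- list(
    paired_scan = paired, set_size_curves = curves,
    correlation_by_size = correl,
    pooled_weights = weight_report$weights,
    rank_curves = weight_report$rank_curves
  )
  table_paths <- character(0)
  for (nm in names(tables)) {
    p <- file.path(outdir, paste0(nm, ".tsv"))
    write.table(tables[[nm]], p, sep = "\t", row.names = FALSE,
                quote = FALSE)
    table_paths[nm] <- p
  }

  figures <- list(
    te_vs_importance = plot_te_importance_grid(paired),
    set_size_curves = plot_set_size_curves(curves),
    weight_distributions = plot_weight_distributions(weight_report),
    weight_rank_curves = plot_weight_rank_curves(weight_report)
  )
  open_dev <- function(path) {
    if (device == "pdf") {
      grDevices::pdf(path, width = 8, height = 6)
    } else {
      grDevices::png(path, width = 1200, height = 900, res = 150)
    }
  }
  fig_paths <- character(0)
  for (nm in names(figures)) {
    p <- file.path(outdir, paste0(nm, ".", device))
    open_dev(p)
    print(figures[[nm]])
    grDevices::dev.off()
    fig_paths[nm] <- p
  }

  manifest <- list(
    package = "rnnflow",
    version = as.character(utils::packageVersion("rnnflow")),
    r_version = R.version.string,
    seed = seed,
    methods = unique(paired$method),
    n_rows_paired = nrow(paired),
    ks_statistic = weight_report$ks_statistic,
    ks_p_value = weight_report$ks_p_value,
    table_md5 = as.list(tools::md5sum(unname(table_paths)))
  )
  manifest_lines <- vapply(names(manifest), function(k) {
    v <- manifest[[k]]
    if (is.list(v)) v <- paste(names(v), unlist(v), sep = "=",
                               collapse = " ")
    paste0(k, ": ", paste(v, collapse = " "))
  }, character(1))
  writeLines(manifest_lines, file.path(outdir, "manifest.txt"))
  invisible(manifest)
}
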