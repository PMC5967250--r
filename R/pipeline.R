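# End-to-end orchestration: manifests -> records -> profiles -> comparison
# report, plus the standard plot types.

#' Run configuration for the profiling pipeline
#'
#' @param manifest_a,manifest_b Paths to dataset manifests (set A is the
#'   reference set; `manifest_b` may be `NULL` for a single-set run).
#' @param block_table_path Optional path to a block-table file; the
#'   shipped default is used when `NULL`.
#' @param angle_bin,length_bin Bin widths (degrees / Angstrom).
#' @param min_prominence Peak threshold fraction.
#' @param out_dir Output directory (created if needed).
#' @param policy_xray,policy_em Selection policies applied to structures
#'   according to their manifest `method` (`synthetic` entries use the EM
#'   policy, i.e. all chains). The defaults mirror standard practice:
#'   first chain for crystallographic sets, all chains for EM sets.
#' @return Object of class `run_config`.
#' @export
run_config <- function(manifest_a, manifest_b = NULL,
                       block_table_path = NULL,
                       angle_bin = 5, length_bin = 0.05,
                       min_prominence = 0.05,
                       out_dir = "blocklen-out",
                       policy_xray = selection_policy("first"),
                       policy_em = selection_policy("all")) {
  stopifnot(angle_bin > 0, length_bin > 0)
  structure(list(manifest_a = manifest_a, manifest_b = manifest_b,
                 block_table_path = block_table_path,
                 angle_bin = angle_bin, length_bin = length_bin,
                 min_prominence = min_prominence, out_dir = out_dir,
                 policy_xray = policy_xray, policy_em = policy_em),
            class = "run_config")
}

# records for every structure of one manifest; unreadable files are
# skipped and logged
.records_for_manifest <- function(manifest, config, block_table) {
  log <- list()
  recs <- list()
  for (i in seq_len(nrow(manifest))) {
    entry <- manifest[i, ]
    policy <- if (entry$method == "xray") config$policy_xray else config$policy_em
    res <- tryCatch({
      models <- read_ensemble(entry$path)
      per_model <- lapply(models, function(ps) {
        extract_records(apply_selection(ps, policy), block_table,
                        source = entry$id)
      })
      do.call(rbind, per_model)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      log[[length(log) + 1L]] <- data.frame(
        id = entry$id, status = "skipped", n_records = 0L,
        detail = conditionMessage(res))
    } else {
      log[[length(log) + 1L]] <- data.frame(
        id = entry$id, status = "processed", n_records = nrow(res),
        detail = "")
      recs[[length(recs) + 1L]] <- res
    }
  }
  if (length(recs) == 0L) {
    stop("no structure in the manifest could be read")
  }
  out <- do.call(rbind, recs)
  class(out) <- c("conformation_records", "data.frame")
  attr(out, "run_log") <- do.call(rbind, log)
  out
}

#' Run the full profiling pipeline
#'
#' Reads every structure of the manifest(s), applies the per-method
#' selection policy, extracts conformation records, and writes per-residue
#' npdf tables, (phi, dBlock) histogram tables and -- when two manifests
#' are given -- a comparison report. All outputs are deterministic given
#' the configuration and inputs.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list (`bundle`) with `records_a`, `records_b`
#'   (or `NULL`), `comparisons` (list per residue type), `log` (per
#'   structure processing status) and `out_dir`.
#' @export
run_profile <- function(config) {
  stopifnot(inherits(config, "run_config"))
  block_table <- if (is.null(config$block_table_path)) {
    default_block_table()
  } else {
    read_block_table(config$block_table_path)
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  man_a <- read_manifest(config$manifest_a)
  records_a <- .records_for_manifest(man_a, config, block_table)
  log <- cbind(set = "A", attr(records_a, "run_log"))
  records_b <- NULL
  if (!is.null(config$manifest_b)) {
    man_b <- read_manifest(config$manifest_b)
    records_b <- .records_for_manifest(man_b, config, block_table)
    log <- rbind(log, cbind(set = "B", attr(records_b, "run_log")))
  }
  write_records(records_a, file.path(config$out_dir, "records_A.tsv"))
  if (!is.null(records_b)) {
    write_records(records_b, file.path(config$out_dir, "records_B.tsv"))
  }
  utils::write.table(log, file.path(config$out_dir, "run_log.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  comparisons <- list()
  types <- sort(intersect(unique(records_a$res_type), names(block_table)))
  for (rt in types) {
    sub_a <- records_a[records_a$res_type == rt, , drop = FALSE]
    h2 <- tryCatch(build_hist2d(sub_a, x = "phi", y = "dblock",
                                x_width = config$angle_bin,
                                y_width = config$length_bin),
                   error = function(e) NULL)
    if (!is.null(h2)) {
      write_profile_table(h2, file.path(config$out_dir,
                                        sprintf("hist2d_%s_A.tsv", rt)))
    }
    if (!is.null(records_b) && rt %in% records_b$res_type) {
      cmp <- compare_sets(records_a, records_b, rt,
                          min_prominence = config$min_prominence)
      comparisons[[rt]] <- cmp
      fdb <- cmp$features$dblock
      if (!identical(fdb, "not comparable")) {
        write_profile_table(fdb$npdf_a,
                            file.path(config$out_dir,
                                      sprintf("npdf_dblock_%s_A.tsv", rt)))
        write_profile_table(fdb$npdf_b,
                            file.path(config$out_dir,
                                      sprintf("npdf_dblock_%s_B.tsv", rt)))
      }
    }
  }
  if (length(comparisons)) {
    report <- do.call(rbind, lapply(names(comparisons), function(rt) {
      ex <- comparisons[[rt]]$features$dblock
      if (identical(ex, "not comparable") || nrow(ex$exceedance) == 0L) {
        return(NULL)
      }
      cbind(res_type = rt, ex$exceedance)
    }))
    if (is.null(report)) {
      report <- data.frame(res_type = character(), lo = numeric(),
                           hi = numeric(), mass_a = numeric(),
                           mass_b = numeric())
    }
    utils::write.table(report,
                       file.path(config$out_dir, "exceedance_report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(list(records_a = records_a, records_b = records_b,
                 comparisons = comparisons, log = log,
                 out_dir = config$out_dir))
}

#' Plot an npdf overlay for one residue type and feature
#'
#' Two curves on the reference scale: the reference set peaks at 1.
#'
#' @param comparison A `set_comparison` from [compare_sets()].
#' @param feature Feature to plot.
#' @param labels Length-2 labels for sets A and B.
#' @return A ggplot object.
#' @export
plot_npdf <- function(comparison, feature = "dblock",
                      labels = c("set A", "set B")) {
  fc <- comparison$features[[feature]]
  if (is.null(fc) || identical(fc, "not comparable")) {
    stop("feature not comparable for ", comparison$res_type)
  }
  df <- rbind(
    data.frame(mid = fc$npdf_a$mids, npdf = fc$npdf_a$values, set = labels[1L]),
    data.frame(mid = fc$npdf_b$mids, npdf = fc$npdf_b$values, set = labels[2L]))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mid, y = .data$npdf,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = feature, y = "npdf",
                  title = paste0(comparison$res_type, ": ", feature)) +
    ggplot2::theme_minimal()
}

#' Ramachandran plot colored by chi1
#'
#' (phi, psi) scatter in the 0-360 convention, with chi1 as color code.
#'
#' @param records A `conformation_records` data frame.
#' @param res_type Optional residue type filter.
#' @return A ggplot object.
#' @export
plot_ramachandran <- function(records, res_type = NULL) {
  if (!is.null(res_type)) {
    records <- records[records$res_type == res_type, , drop = FALSE]
  }
  records <- records[!is.na(records$phi) & !is.na(records$psi), , drop = FALSE]
  ggplot2::ggplot(records, ggplot2::aes(x = .data$phi, y = .data$psi,
                                        colour = .data$chi1)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::scale_x_continuous(limits = c(0, 360), breaks = seq(0, 360, 60)) +
    ggplot2::scale_y_continuous(limits = c(0, 360), breaks = seq(0, 360, 60)) +
    ggplot2::scale_colour_viridis_c(limits = c(0, 360)) +
    ggplot2::labs(x = "phi (deg)", y = "psi (deg)", colour = "chi1") +
    ggplot2::theme_minimal()
}

#' Heat map of a peak-normalized 2D histogram
#'
#' Cells colored by population ratio, with the modal cell at the top of
#' the scale.
#'
#' @param hist A `hist2d`.
#' @return A ggplot object.
#' @export
plot_hist2d <- function(hist) {
  grid <- expand.grid(x = hist$xmids, y = hist$ymids)
  grid$ratio <- as.vector(hist$ratio)
  ggplot2::ggplot(grid[grid$ratio > 0, , drop = FALSE],
                  ggplot2::aes(x = .data$x, y = .data$y,
                               fill = .data$ratio)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1), option = "turbo") +
    ggplot2::labs(x = hist$xfeature, y = hist$yfeature,
                  fill = "ratio") +
    ggplot2::theme_minimal()
}

#' 3D scatter of (phi, psi, chi1) colored by chi1
#'
#' @param records A `conformation_records` data frame.
#' @param res_type Optional residue type filter.
#' @return A lattice `cloud` plot object.
#' @export
plot_scatter3d <- function(records, res_type = NULL) {
  if (!is.null(res_type)) {
    records <- records[records$res_type == res_type, , drop = FALSE]
  }
  records <- records[stats::complete.cases(records[, c("phi", "psi", "chi1")]), ,
                     drop = FALSE]
  cols <- grDevices::hcl.colors(12, "viridis")[
    pmin(12L, floor(records$chi1 / 30) + 1L)]
  lattice::cloud(chi1 ~ phi * psi, data = records, col = cols, pch = 16,
                 cex = 0.4, xlab = "phi", ylab = "psi", zlab = "chi1")
}

#' Render the standard plot set of a pipeline run
#'
#' One image per residue type and requested kind, written under
#' `<out_dir>/plots`. Plotting failures (e.g. a type with too few
#' records) are logged and skipped; numbers, not figures, are the
#' pipeline's contract.
#'
#' @param bundle The list returned by [run_profile()].
#' @param kinds Subset of `"npdf"`, `"ramachandran_chi1"`, `"hist2d"`,
#'   `"scatter3d"`.
#' @param width,height Device size in inches.
#' @return Character vector of written file paths, invisibly.
#' @export
plot_outputs <- function(bundle,
                         kinds = c("npdf", "ramachandran_chi1", "hist2d",
                                   "scatter3d"),
                         width = 6, height = 5) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  plot_dir <- file.path(bundle$out_dir, "plots")
  dir.create(plot_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character()
  emit <- function(file, expr) {
    ok <- tryCatch({
      grDevices::png(file, width = width, height = height, units = "in",
                     res = 150)
      on.exit(grDevices::dev.off(), add = TRUE)
      print(expr)
      TRUE
    }, error = function(e) {
      message("plot skipped (", basename(file), "): ", conditionMessage(e))
      FALSE
    })
    if (ok) written <<- c(written, file)
  }
  types <- sort(unique(bundle$records_a$res_type))
  for (rt in types) {
    sub_a <- bundle$records_a[bundle$records_a$res_type == rt, , drop = FALSE]
    if ("ramachandran_chi1" %in% kinds) {
      emit(file.path(plot_dir, sprintf("rama_%s.png", rt)),
           plot_ramachandran(sub_a))
    }
    if ("scatter3d" %in% kinds) {
      emit(file.path(plot_dir, sprintf("scatter3d_%s.png", rt)),
           plot_scatter3d(sub_a))
    }
    if ("hist2d" %in% kinds) {
      h2 <- tryCatch(build_hist2d(sub_a), error = function(e) NULL)
      if (!is.null(h2)) {
        emit(file.path(plot_dir, sprintf("hist2d_%s.png", rt)),
             plot_hist2d(h2))
      }
    }
    if ("npdf" %in% kinds && rt %in% names(bundle$comparisons)) {
      cmp <- bundle$comparisons[[rt]]
      if (!identical(cmp$features$dblock, "not comparable")) {
        emit(file.path(plot_dir, sprintf("npdf_dblock_%s.png", rt)),
             plot_npdf(cmp, "dblock"))
      }
    }
  }
  invisible(written)
}
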