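# Correlation matrix and figure-style exports.

#' Pairwise correlation matrix of a feature table
#'
#' Pearson (default) or Spearman correlations over the numeric columns,
#' pairwise-complete; constant columns are flagged as undefined (NA row and
#' column) rather than reported as zero. The diagonal is exactly 1 for
#' non-constant columns and the matrix equals its transpose bit-for-bit.
#'
#' @param table data.frame (non-numeric columns are dropped).
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return matrix of class \code{correlation_matrix}; attribute
#'   \code{constant_cols} names the undefined columns.
#' @export
correlation_matrix <- function(table, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  num <- table[vapply(table, is.numeric, TRUE)]
  if (ncol(num) < 2) stop("need at least 2 numeric columns")
  if (nrow(num) < 3) stop("need at least 3 rows")
  const <- vapply(num, function(x) stats::sd(x, na.rm = TRUE) == 0, TRUE)
  if (all(const)) stop("all columns are constant: correlations undefined")
  r <- suppressWarnings(stats::cor(as.matrix(num), method = method,
                                   use = "pairwise.complete.obs"))
  r[const, ] <- NA_real_; r[, const] <- NA_real_
  diag(r)[!const] <- 1
  r[lower.tri(r)] <- t(r)[lower.tri(r)]  # enforce bit-exact symmetry
  structure(r, constant_cols = names(num)[const],
            class = c("correlation_matrix", "matrix", "array"))
}

#' @export
print.correlation_matrix <- function(x, digits = 2, ...) {
  cat("<correlation_matrix> ", nrow(x), " variables\n", sep = "")
  print(round(unclass(x), digits))
  cc <- attr(x, "constant_cols")
  if (length(cc)) cat("constant (undefined):", paste(cc, collapse = ", "), "\n")
  invisible(x)
}

#' Export run figures
#'
#' Writes deterministic-named PNG figures: one index heatmap per supplied
#' heatmap table, one box plot per plot-statistics group, and one
#' predicted-vs-truth scatter per model report. With empty inputs no files
#' are written and a notice is given.
#'
#' @param heatmaps named list of data.frames from [vi_heatmap()] (name =
#'   index name); may be empty.
#' @param vi_stats list of \code{plot_vi_stats}; may be empty.
#' @param reports list of \code{model_report}s; may be empty.
#' @param outdir output directory (created if missing).
#' @return character vector of written file paths (possibly empty).
#' @export
export_figures <- function(heatmaps = list(), vi_stats = list(),
                           reports = list(), outdir) {
  if (!dir.exists(outdir)) {
    ok <- dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(outdir)) stop("cannot create output directory: ", outdir)
  }
  files <- character(0)
  for (nm in names(heatmaps)) {
    f <- file.path(outdir, sprintf("heatmap_%s.png", nm))
    grDevices::png(f, width = 640, height = 480)
    hm <- heatmaps[[nm]]
    graphics::barplot(hm$mean, names.arg = hm$plot_id,
                      main = paste(nm, "per-plot mean"), xlab = "plot",
                      ylab = nm, col = "darkgreen", border = NA)
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (length(vi_stats)) {
    byidx <- split(vi_stats, vapply(vi_stats, `[[`, "", "index_name"))
    for (nm in names(byidx)) {
      st <- Filter(function(s) !s$empty, byidx[[nm]])
      if (!length(st)) next
      f <- file.path(outdir, sprintf("boxplot_%s.png", nm))
      grDevices::png(f, width = 800, height = 480)
      graphics::plot(NULL, xlim = c(0.5, length(st) + 0.5),
                     ylim = range(c(vapply(st, `[[`, 0, "whisker_lo"),
                                    vapply(st, `[[`, 0, "whisker_hi"),
                                    unlist(lapply(st, `[[`, "outliers")))),
                     xlab = "plot", ylab = nm, main = paste(nm, "by plot"))
      for (i in seq_along(st)) {
        s <- st[[i]]
        graphics::rect(i - 0.3, s$q1, i + 0.3, s$q3, col = "lightgreen")
        graphics::segments(i - 0.3, s$median, i + 0.3, s$median, lwd = 2)
        graphics::segments(i, s$whisker_lo, i, s$q1)
        graphics::segments(i, s$q3, i, s$whisker_hi)
        if (length(s$outliers))
          graphics::points(rep(i, length(s$outliers)), s$outliers,
                           col = "red", pch = 4)
      }
      grDevices::dev.off()
      files <- c(files, f)
    }
  }
  for (r in reports) {
    f <- file.path(outdir, sprintf("scatter_%s_%s_%s.png",
                                   r$kind, r$fs_id, r$trait))
    grDevices::png(f, width = 560, height = 560)
    graphics::plot(r$truth, r$predictions, xlab = "ground truth",
                   ylab = "predicted", col = "orange", pch = 16,
                   main = sprintf("%s / %s / %s (R2 = %.3f)", r$kind, r$fs_id,
                                  r$trait, r$R2))
    graphics::abline(0, 1, col = "blue")
    grDevices::dev.off()
    files <- c(files, f)
  }
  if (!length(files)) message("export_figures: nothing to export")
  files
}
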