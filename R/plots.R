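# Base-graphics plot exports: optimization convergence and detection
# curves. Written as PNGs by the CLI; usable interactively as well.

#' Plot a Bayesian-optimization convergence trace
#'
#' Per-evaluation loss and the best-so-far envelope, with overexploitation
#' retries marked.
#'
#' @param trace trace data.frame from [bayes_optimize()].
#' @param path optional PNG path; if given the plot is written there.
#' @return `path` (or NULL), invisibly.
#' @export
plot_bo_trace <- function(trace, path = NULL) {
  if (!is.null(path)) grDevices::png(path, width = 640, height = 480)
  plot(trace$iter, trace$loss, pch = 19, col = "grey40",
       xlab = "evaluation", ylab = "loss", log = if (all(trace$loss > 0)) "y" else "",
       main = "parameter search")
  lines(trace$iter, trace$best, col = "red", lwd = 2)
  if (any(trace$overexploit))
    points(trace$iter[trace$overexploit], trace$loss[trace$overexploit],
           pch = 1, cex = 2, col = "blue")
  legend("topright", legend = c("evaluation", "best so far"),
         pch = c(19, NA), lty = c(NA, 1), col = c("grey40", "red"), bty = "n")
  if (!is.null(path)) grDevices::dev.off()
  invisible(path)
}

#' Plot PR and ROC curves for both response statistics
#'
#' @param curves_vmean,curves_vmax outputs of [pr_roc_curves()].
#' @param path optional PNG path.
#' @return `path` (or NULL), invisibly.
#' @export
plot_detection_curves <- function(curves_vmean, curves_vmax, path = NULL) {
  if (!is.null(path)) grDevices::png(path, width = 960, height = 480)
  op <- par(mfrow = c(1, 2))
  on.exit({ par(op); if (!is.null(path)) grDevices::dev.off() }, add = TRUE)
  plot(curves_vmean$pr$recall, curves_vmean$pr$precision, type = "s", col = "red",
       xlim = c(0, 1), ylim = c(0, 1), xlab = "recall", ylab = "precision",
       main = "PR")
  lines(curves_vmax$pr$recall, curves_vmax$pr$precision, type = "s", col = "blue")
  legend("bottomleft", c("V_mean", "V_max"), col = c("red", "blue"), lty = 1, bty = "n")
  plot(curves_vmean$roc$fpr, curves_vmean$roc$recall, type = "s", col = "red",
       xlim = c(0, 1), ylim = c(0, 1), xlab = "false positive rate",
       ylab = "sensitivity", main = "ROC")
  lines(curves_vmax$roc$fpr, curves_vmax$roc$recall, type = "s", col = "blue")
  abline(0, 1, lty = 3)
  legend("bottomright", c("V_mean", "V_max"), col = c("red", "blue"), lty = 1, bty = "n")
  invisible(path)
}
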