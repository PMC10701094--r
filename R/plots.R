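# Plotting of analysis results: bar charts for the categorical analyses
# and the per-nucleotide miRNA binding profile. Base graphics, Bang Wong
# palette, deterministic category order (the result-table order).

.plot_device <- function(path, width, height) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = grDevices::png(path, width = width, height = height, units = "in",
                         res = 150),
    svg = grDevices::svg(path, width = width, height = height),
    .stop_hyb("config", sprintf("unsupported plot format '.%s' (png or svg)", ext)))
}

.top_k <- function(df, k) {
  if (nrow(df) <= k) return(df)
  out <- df[seq_len(k), , drop = FALSE]
  extra <- df[1, , drop = FALSE]
  extra[[1]] <- "other"
  extra$count <- sum(df$count[-seq_len(k)])
  rbind(out, extra)
}

.bar_chart <- function(df, path, main, xlab, ylab, top_k) {
  df <- .top_k(df, top_k)
  .plot_device(path, 7, 5)
  on.exit(grDevices::dev.off())
  graphics::par(mar = c(9, 4.5, 3, 1))
  graphics::barplot(df$count, names.arg = df[[1]], las = 2,
                    col = wong_palette(nrow(df)), border = NA,
                    main = main, ylab = ylab, cex.names = 0.8)
  invisible(path)
}

#' Plot analysis results
#'
#' Renders one analysis result as an image file: bar charts of the type,
#' miRNA-placement, energy-histogram, or per-miRNA target tables, or the
#' per-nucleotide binding profile (fraction of hybrids whose miRNA
#' position is predicted bound to the target, by miRNA position 5' to
#' 3'). Colors come from the Bang Wong palette assigned by rank; category
#' order is the deterministic result-table order, so output is identical
#' for identical input.
#'
#' @param results A [finalize_analysis()] result.
#' @param which One of `"type"`, `"mirna"`, `"target"`, `"energy"`,
#'   `"fold_profile"`.
#' @param path Output image path; `.png` or `.svg`.
#' @param top_k For categorical plots, the number of leading categories
#'   shown; the remainder is grouped as `"other"`.
#' @param mirna For `which = "target"`, the miRNA reference whose targets
#'   are plotted (default: the miRNA with the highest total).
#' @param weighted For `which = "fold_profile"`, plot the count-weighted
#'   fraction (`TRUE`) or the per-record fraction (`FALSE`).
#' @return Invisibly, `path`, or `NULL` when the requested result is
#'   empty (a warning is emitted and no file is written).
#' @export
plot_analysis <- function(results,
                          which = c("type", "mirna", "target", "energy",
                                    "fold_profile"),
                          path, top_k = 10L, mirna = NULL, weighted = FALSE) {
  stopifnot(inherits(results, "hyb_analysis_results"))
  which <- match.arg(which)
  empty <- function(msg) { warning(msg); invisible(NULL) }
  if (which == "type") {
    df <- results$type$pairs
    if (is.null(df) || nrow(df) == 0L)
      return(empty("plot_analysis: type results are empty; no plot written"))
    .bar_chart(df, path, "Hybrid segment-type pairs", "", "count", top_k)
  } else if (which == "mirna") {
    df <- results$mirna$placement
    if (is.null(df) || nrow(df) == 0L)
      return(empty("plot_analysis: mirna results are empty; no plot written"))
    .bar_chart(df, path, "miRNA placement within hybrids", "", "count", top_k)
  } else if (which == "target") {
    tab <- results$target
    if (is.null(tab) || nrow(tab$summary) == 0L)
      return(empty("plot_analysis: target results are empty; no plot written"))
    if (is.null(mirna)) mirna <- tab$summary$mirna[1]
    df <- tab$counts[tab$counts$mirna == mirna, c("target", "count")]
    if (nrow(df) == 0L)
      return(empty(sprintf("plot_analysis: no targets recorded for '%s'", mirna)))
    .bar_chart(df, path, sprintf("Targets of %s", mirna), "", "count", top_k)
  } else if (which == "energy") {
    h <- results$energy
    if (is.null(h) || nrow(h$histogram) == 0L)
      return(empty("plot_analysis: energy results are empty; no plot written"))
    .plot_device(path, 7, 5)
    on.exit(grDevices::dev.off())
    graphics::barplot(h$histogram$count,
                      names.arg = sprintf("%g", h$histogram$bin_lo),
                      col = wong_palette(2)[2], border = NA, las = 2,
                      main = "Hybrid energy distribution",
                      xlab = "energy bin lower edge (kcal/mol)", ylab = "count")
  } else {
    pr <- results$fold$profile
    if (is.null(pr) || nrow(pr) == 0L)
      return(empty("plot_analysis: fold profile is empty; no plot written"))
    frac <- if (weighted) pr$frac_weighted else pr$frac_record
    .plot_device(path, 7, 5)
    on.exit(grDevices::dev.off())
    graphics::barplot(frac, names.arg = pr$position,
                      col = wong_palette(3)[3], border = NA, ylim = c(0, 1),
                      main = "Predicted miRNA binding by position",
                      xlab = "miRNA position (5' to 3')",
                      ylab = "fraction of hybrids bound")
  }
  invisible(path)
}
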