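# Publication-style figures with base graphics. Each function draws on the
# current device; the pipeline report stage wraps them in png().

shade_pulse <- function(protocol, col = grDevices::adjustcolor("grey60", 0.35)) {
  usr <- graphics::par("usr")
  graphics::rect(pulse_onset(protocol), usr[3], pulse_offset(protocol),
                 usr[4], col = col, border = NA)
}

#' Mean +/- SEM dR/R0 trace per group
#'
#' Solid line: framewise group mean; shading: SEM. The grey band marks the
#' pulse.
#'
#' @param rts_by_group Named list: group -> list of `ratio_trace`.
#' @param main Plot title.
#' @return Invisibly, the list of per-group summaries.
#' @export
plot_mean_sem <- function(rts_by_group, main = "Calcium response (% dR/R0)") {
  summaries <- lapply(rts_by_group, cohort_mean_sem)
  protocol <- rts_by_group[[1]][[1]]$protocol
  ylim <- range(unlist(lapply(summaries, function(s)
    c(s$mean_pct - s$sem_pct, s$mean_pct + s$sem_pct))))
  cols <- grDevices::hcl.colors(max(2, length(summaries)), "Dark 2")
  graphics::plot(NA, xlim = range(summaries[[1]]$t_s), ylim = ylim,
                 xlab = "Time (s)", ylab = "% dR/R0", main = main)
  shade_pulse(protocol)
  for (i in seq_along(summaries)) {
    s <- summaries[[i]]
    graphics::polygon(c(s$t_s, rev(s$t_s)),
                      c(s$mean_pct - s$sem_pct, rev(s$mean_pct + s$sem_pct)),
                      col = grDevices::adjustcolor(cols[i], 0.3), border = NA)
    graphics::lines(s$t_s, s$mean_pct, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = names(summaries), col = cols,
                   lwd = 2, bty = "n")
  invisible(summaries)
}

#' Heatmap of per-animal dR/R0 traces ordered by hierarchical clustering
#'
#' @param rts List of `ratio_trace`.
#' @param ord Row order, e.g. from [order_for_heatmap()]; `NULL` computes
#'   it.
#' @param main Plot title.
#' @return Invisibly, the row order used.
#' @export
plot_response_heatmap <- function(rts, ord = NULL,
                                  main = "Individual responses") {
  if (is.null(ord)) ord <- order_for_heatmap(rts)
  m <- do.call(rbind, lapply(rts, `[[`, "dr_pct"))[ord, , drop = FALSE]
  t_s <- rts[[1]]$t_s
  lim <- max(abs(m))
  graphics::image(t_s, seq_len(nrow(m)), t(m),
                  col = grDevices::hcl.colors(101, "Blue-Red 3"),
                  zlim = c(-lim, lim), xlab = "Time (s)", ylab = "Animal",
                  main = main)
  graphics::abline(v = pulse_window(rts[[1]]$protocol), lty = 2)
  invisible(ord)
}

#' Violin-style per-animal peak amplitude plot
#'
#' Boxplot with overlaid per-animal points (each point one animal), as in
#' peak-quantification panels.
#'
#' @param calls Calls data frame from [classify_cohort()].
#' @param metric `"max_pct"` or `"min_pct"`.
#' @param main Plot title.
#' @export
plot_peak_violin <- function(calls, metric = "max_pct",
                             main = "Peak response amplitude") {
  f <- stats::reformulate("group", metric)
  graphics::boxplot(f, data = calls, outline = FALSE, main = main,
                    ylab = sprintf("%s (%% dR/R0)", metric), border = "grey40")
  graphics::stripchart(f, data = calls, vertical = TRUE, method = "jitter",
                       add = TRUE, pch = 19,
                       col = grDevices::adjustcolor("steelblue", 0.7))
}

#' Mean +/- SEM instantaneous-speed traces
#'
#' One line per (group, condition); shading is SEM and the grey band marks
#' the pulse clock times.
#'
#' @param speed_summary `speed_summary` data frame from
#'   [behavior_cohort_table()].
#' @param protocol The behavior `stimulus_protocol` (for the pulse band).
#' @param main Plot title.
#' @export
plot_speed_traces <- function(speed_summary, protocol,
                              main = "Instantaneous speed") {
  key <- paste(speed_summary$group, speed_summary$condition)
  ks <- unique(key)
  cols <- grDevices::hcl.colors(max(2, length(ks)), "Dark 2")
  ylim <- c(0, max(speed_summary$mean_mm_s + speed_summary$sem_mm_s))
  graphics::plot(NA, xlim = range(speed_summary$t_s), ylim = ylim,
                 xlab = "Time (s)", ylab = "Speed (mm/s)", main = main)
  shade_pulse(protocol, grDevices::adjustcolor("khaki", 0.5))
  for (i in seq_along(ks)) {
    s <- speed_summary[key == ks[i], ]
    graphics::polygon(c(s$t_s, rev(s$t_s)),
                      c(s$mean_mm_s - s$sem_mm_s,
                        rev(s$mean_mm_s + s$sem_mm_s)),
                      col = grDevices::adjustcolor(cols[i], 0.25),
                      border = NA)
    graphics::lines(s$t_s, s$mean_mm_s, col = cols[i], lwd = 2)
  }
  graphics::legend("topright", legend = ks, col = cols, lwd = 2, bty = "n")
}

#' Chemotaxis-index dot plot by group
#'
#' @param ci Data frame with columns `group` and `index`.
#' @param main Plot title.
#' @export
plot_chemotaxis <- function(ci, main = "Chemotaxis index") {
  graphics::stripchart(index ~ group, data = ci, vertical = TRUE,
                       method = "jitter", pch = 19, ylim = c(-1, 1),
                       col = grDevices::adjustcolor("darkorange", 0.8),
                       ylab = "Chemotaxis index", main = main)
  graphics::abline(h = 0, lty = 2)
  means <- tapply(ci$index, ci$group, mean)
  graphics::points(seq_along(means), means, pch = "-", cex = 3)
}
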