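#' Fit an empirical null from air-control recordings
#'
#' Computes the chosen per-animal response statistic over the response
#' window for each air-control ratio trace and summarizes its spread: the
#' null SD (sample SD, n-1 denominator) against which stimulus responses
#' are classified. The default statistic is the per-animal signed extremum
#' of dR/R0 (the value of largest magnitude), matching a classification
#' rule on the absolute value of the response.
#'
#' @param air_traces List of `ratio_trace` from air-control recordings
#'   (at least 2), with identical protocol timing.
#' @param response_window Half-open `(start_s, end_s)`; default as in
#'   [peak_amplitudes()].
#' @param statistic `"extremum"`, `"max"`, or `"min"`.
#' @return A `null_model` with `sd`, `statistic_name`, `n_controls`,
#'   `window`, and the per-animal `values`. A zero SD (all controls
#'   identical) triggers a degenerate-null warning.
#' @export
fit_air_null <- function(air_traces, response_window = NULL,
                         statistic = c("extremum", "max", "min")) {
  statistic <- match.arg(statistic)
  if (!is.list(air_traces) || length(air_traces) < 2)
    abort_invalid("at least 2 air-control traces are required")
  if (!all(vapply(air_traces, inherits, logical(1), "ratio_trace")))
    abort_invalid("`air_traces` must be a list of ratio_trace objects")
  p0 <- air_traces[[1]]$protocol
  for (rt in air_traces[-1])
    if (!same_timing(rt$protocol, p0))
      abort_invalid("all air-control traces must share the same protocol timing")
  if (is.null(response_window)) response_window <- default_response_window(p0)
  check_window(response_window, "response_window")
  values <- vapply(air_traces, function(rt) {
    switch(statistic,
           extremum = extremum_stat(rt, response_window),
           max = peak_amplitudes(rt, response_window)[["max_pct"]],
           min = peak_amplitudes(rt, response_window)[["min_pct"]])
  }, numeric(1))
  s <- stats::sd(values)
  if (s == 0)
    warning("degenerate null: all air-control statistics identical (sd = 0)",
            call. = FALSE)
  structure(
    list(statistic_name = statistic, sd = s, n_controls = length(values),
         window = response_window, values = values),
    class = "null_model"
  )
}

#' @export
print.null_model <- function(x, ...) {
  cat(sprintf("Air-control null: sd(%s) = %.3f%% from %d controls over [%g, %g) s\n",
              x$statistic_name, x$sd, x$n_controls, x$window[1], x$window[2]))
  invisible(x)
}

#' Classify a response as excitatory, inhibitory, or silent
#'
#' A response is excitatory if its maximum dR/R0 exceeds `k` null SDs and is
#' at least as large as the magnitude of its minimum; inhibitory if the
#' magnitude of its minimum exceeds `k` null SDs and dominates the maximum;
#' silent otherwise. Magnitude ties above threshold classify excitatory
#' (probability zero under continuous noise). With `k = 3` this is the
#' 3-SD-of-air-control rule.
#'
#' @param peaks Named numeric with `max_pct` and `min_pct` (as returned by
#'   [peak_amplitudes()]).
#' @param null A `null_model`.
#' @param k Threshold multiplier (default 3).
#' @return `"excitatory"`, `"inhibitory"`, or `"silent"`.
#' @export
categorize_response <- function(peaks, null, k = 3) {
  stopifnot(inherits(null, "null_model"))
  check_number(k, "k", strict_min = 0)
  mx <- peaks[["max_pct"]]
  mn <- peaks[["min_pct"]]
  if (!is.finite(mx) || !is.finite(mn) || mx < mn)
    abort_invalid("`peaks` must supply finite max_pct >= min_pct")
  if (null$sd == 0)
    warning("degenerate null (sd = 0): every nonzero response classifies as non-silent",
            call. = FALSE)
  thr <- k * null$sd
  if (mx > thr && mx >= abs(mn)) "excitatory"
  else if (abs(mn) > thr && abs(mn) > mx) "inhibitory"
  else "silent"
}

#' Classify a cohort of recordings against an air-control null
#'
#' Converts every trace to dR/R0, measures peak amplitudes over the
#' response window, fits the air-control null, and classifies each animal.
#'
#' @param traces List of `calcium_trace` (stimulus recordings).
#' @param air_traces List of `calcium_trace` air controls (>= 2).
#' @param baseline_window,response_window Windows as elsewhere; `NULL` for
#'   defaults.
#' @param k Threshold multiplier (default 3).
#' @param statistic Null statistic, see [fit_air_null()].
#' @return A `response_classification`: `calls` (data frame of animal_id,
#'   group, neuron, max_pct, min_pct, class), `table` (group x class counts
#'   with percentages), and the fitted `null`.
#' @export
classify_cohort <- function(traces, air_traces, baseline_window = NULL,
                            response_window = NULL, k = 3,
                            statistic = "extremum") {
  if (!is.list(traces) || length(traces) == 0)
    abort_invalid("`traces` must be a non-empty list of calcium_trace objects")
  rts <- lapply(traces, compute_ratio_trace, baseline_window = baseline_window)
  air_rts <- lapply(air_traces, compute_ratio_trace,
                    baseline_window = baseline_window)
  if (is.null(response_window))
    response_window <- default_response_window(rts[[1]]$protocol)
  null <- fit_air_null(air_rts, response_window, statistic = statistic)
  calls <- do.call(rbind, lapply(rts, function(rt) {
    pk <- peak_amplitudes(rt, response_window)
    data.frame(animal_id = rt$animal_id, group = rt$group,
               neuron = rt$neuron, max_pct = pk[["max_pct"]],
               min_pct = pk[["min_pct"]],
               class = categorize_response(pk, null, k),
               stringsAsFactors = FALSE)
  }))
  classes <- c("excitatory", "inhibitory", "silent")
  counts <- table(factor(calls$group), factor(calls$class, levels = classes))
  tab <- as.data.frame(counts, stringsAsFactors = FALSE)
  names(tab) <- c("group", "class", "n")
  totals <- stats::ave(tab$n, tab$group, FUN = sum)
  tab$pct <- 100 * tab$n / totals
  structure(
    list(calls = calls, table = tab, null = null, k = k,
         response_window = response_window),
    class = "response_classification"
  )
}

#' @export
print.response_classification <- function(x, ...) {
  cat(sprintf("Response classification (k = %g, null sd = %.3f%%, %d controls)\n",
              x$k, x$null$sd, x$null$n_controls))
  tb <- x$table
  tb$pct <- sprintf("%.1f%%", tb$pct)
  print(tb, row.names = FALSE)
  invisible(x)
}

#' Framewise mean and SEM across a cohort of ratio traces
#'
#' @param rts List of at least 2 `ratio_trace` on an identical frame grid.
#' @return A data frame with `t_s`, `mean_pct`, `sem_pct` (sample SD /
#'   sqrt(n), n-1 convention).
#' @export
cohort_mean_sem <- function(rts) {
  if (!is.list(rts) || length(rts) < 2)
    abort_invalid("at least 2 ratio traces are required")
  t0 <- rts[[1]]$t_s
  for (rt in rts[-1])
    if (length(rt$t_s) != length(t0) || any(abs(rt$t_s - t0) > 1e-9))
      abort_invalid("all traces must share an identical frame grid")
  m <- do.call(rbind, lapply(rts, `[[`, "dr_pct"))
  data.frame(
    t_s = t0,
    mean_pct = colMeans(m),
    sem_pct = apply(m, 2, stats::sd) / sqrt(nrow(m))
  )
}

# Canonical leaf order of an hclust tree: at every internal node the child
# whose smallest label ranks first comes first. Labels (animal ids) make the
# ordering invariant to the order traces are supplied in; index rank is the
# final tie-break for duplicate labels.
canonical_leaf_order <- function(merge, labels) {
  key <- order(order(labels, seq_along(labels)))  # rank of each leaf's label
  node_leaves <- function(k) {
    if (k < 0) return(-k)
    a <- node_leaves(merge[k, 1])
    b <- node_leaves(merge[k, 2])
    if (min(key[a]) <= min(key[b])) c(a, b) else c(b, a)
  }
  node_leaves(nrow(merge))
}

#' Order animals for a response heatmap by hierarchical clustering
#'
#' Agglomeratively clusters the per-animal dR/R0 vectors and returns the
#' dendrogram leaf order, canonicalized so that at every merge the subtree
#' containing the smallest animal index leads. The ordering is therefore
#' deterministic and does not depend on the order the traces are supplied
#' in (up to exact distance ties).
#'
#' @param rts List of at least 2 `ratio_trace` on a common frame grid.
#' @param metric Distance metric passed to [stats::dist()] (default
#'   `"euclidean"`).
#' @param linkage Agglomeration method passed to [stats::hclust()] (default
#'   `"average"`).
#' @return Integer permutation of `seq_along(rts)`.
#' @export
order_for_heatmap <- function(rts, metric = "euclidean", linkage = "average") {
  if (!is.list(rts) || length(rts) < 2)
    abort_invalid("at least 2 traces are required")
  m <- do.call(rbind, lapply(rts, `[[`, "dr_pct"))
  if (any(!is.finite(m)))
    abort_data("traces contain non-finite dR/R0 values")
  if (nrow(m) == 2) return(c(1L, 2L))
  labels <- vapply(rts, `[[`, character(1), "animal_id")
  hc <- stats::hclust(stats::dist(m, method = metric), method = linkage)
  canonical_leaf_order(hc$merge, labels)
}
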