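# Configuration-driven orchestration: simulate (or load) -> calcium ->
# behavior -> stats -> report, with a JSON manifest recording seeds,
# parameter defaults, file checksums, and collected warnings.

protocol_from_config <- function(pc, default_rate) {
  make_protocol(pc$pre_s, pc$pulse_s, pc$post_s,
                pc$frame_rate %||% default_rate,
                pulse_label = pc$pulse_label %||% "CO2",
                pulse_composition = pc$pulse_composition %||% NULL)
}

air_version <- function(protocol) {
  seg <- protocol$segments
  make_protocol(seg$start_s[2], seg$end_s[2] - seg$start_s[2],
                seg$end_s[3] - seg$end_s[2], protocol$frame_rate,
                pulse_label = "air")
}

#' Validate a pipeline run configuration
#'
#' Structural checks only: every diagnostic names the offending key. An
#' empty result means the config is runnable.
#'
#' @param config Configuration list (see [read_run_config()] and the
#'   shipped demo config).
#' @return Character vector of diagnostics (empty if valid).
#' @export
validate_config <- function(config) {
  diags <- character()
  note <- function(...) diags <<- c(diags, sprintf(...))
  check_protocol <- function(pc, key) {
    if (is.null(pc)) { note("%s: missing", key); return(invisible()) }
    for (f in c("pre_s", "pulse_s", "post_s")) {
      v <- pc[[f]]
      if (is.null(v) || !is.numeric(v) || v <= 0)
        note("%s.%s: must be a positive duration", key, f)
    }
    if (!is.null(pc$frame_rate) && pc$frame_rate <= 0)
      note("%s.frame_rate: must be positive", key)
  }
  if (!is.null(config$calcium)) {
    check_protocol(config$calcium$protocol, "calcium.protocol")
    has_groups <- !is.null(config$calcium$groups)
    has_input <- !is.null(config$calcium$input)
    if (has_groups == has_input)
      note("calcium: exactly one of `groups` (generator) or `input` (file paths) is required")
    if (has_groups) {
      for (g in names(config$calcium$groups)) {
        gc <- config$calcium$groups[[g]]
        if (is.null(gc$n_animals) || gc$n_animals < 1)
          note("calcium.groups.%s.n_animals: must be a positive count", g)
        if (!is.null(gc$class_mix) &&
            (length(gc$class_mix) != 3 ||
             abs(sum(unlist(gc$class_mix)) - 1) > 1e-6))
          note("calcium.groups.%s.class_mix: must be 3 probabilities summing to 1", g)
      }
      if (is.null(config$calcium$air_controls$n_animals) ||
          config$calcium$air_controls$n_animals < 2)
        note("calcium.air_controls.n_animals: at least 2 air controls are required")
    }
  }
  if (!is.null(config$behavior)) {
    check_protocol(config$behavior$protocol, "behavior.protocol")
    has_groups <- !is.null(config$behavior$groups)
    has_input <- !is.null(config$behavior$input)
    if (has_groups == has_input)
      note("behavior: exactly one of `groups` (generator) or `input` (file paths) is required")
    if (has_groups) {
      for (g in names(config$behavior$groups)) {
        gc <- config$behavior$groups[[g]]
        if (is.null(gc$preset) && is.null(gc$params))
          note("behavior.groups.%s: needs a `preset` or `params` block", g)
        if (!is.null(gc$preset) &&
            !gc$preset %in% c("dauer_like", "adult_like"))
          note("behavior.groups.%s.preset: unknown preset \"%s\"", g, gc$preset)
        if (is.null(gc$n_animals) || gc$n_animals < 1)
          note("behavior.groups.%s.n_animals: must be a positive count", g)
      }
    }
  }
  if (!is.null(config$chemotaxis)) {
    for (g in names(config$chemotaxis$groups)) {
      gc <- config$chemotaxis$groups[[g]]
      if (is.null(gc$p_test) || gc$p_test < 0 || gc$p_test > 1)
        note("chemotaxis.groups.%s.p_test: must be in [0, 1]", g)
      if (is.null(gc$n_worms) || gc$n_worms < 1)
        note("chemotaxis.groups.%s.n_worms: must be a positive count", g)
    }
  }
  known_tests <- c("welch_t", "mann_whitney", "kruskal_dunn",
                   "anova_dunnett", "anova2_sidak", "fisher_excitatory",
                   "fisher_inhibitory")
  for (i in seq_along(config$stats$plan)) {
    pl <- config$stats$plan[[i]]
    if (is.null(pl$test) || !pl$test %in% known_tests)
      note("stats.plan[%d].test: unknown test \"%s\"", i,
           pl$test %||% "<missing>")
    if (is.null(pl$stream) ||
        !pl$stream %in% c("calcium", "behavior", "chemotaxis"))
      note("stats.plan[%d].stream: must be calcium, behavior, or chemotaxis", i)
  }
  diags
}

stream_seed <- function(root, stream, idx = 0) {
  base <- match(stream, c("calcium", "behavior", "chemotaxis", "air"))
  child_seed(root, base * 10000 + idx)
}

#' Run the full analysis pipeline from a configuration
#'
#' Executes, in order, the selected stages:
#' `simulate` (or load input files) -> `calcium` -> `behavior` -> `stats`
#' -> `report`. All tabular outputs are CSV under `out_dir`; figures are
#' PNG; a JSON manifest with the config hash, seed, package version, file
#' checksums, and collected warnings is written last. Identical config and
#' seed reproduce bit-identical CSV outputs, and each stage reads only the
#' prior stage's on-disk outputs, so stages can be rerun in isolation.
#'
#' @param config Configuration list, or a path to a YAML/JSON config file.
#' @param seed Root seed (overrides `config$seed`; default 1).
#' @param out_dir Output directory (overrides `config$out_dir`).
#' @param stages Subset of
#'   `c("simulate", "calcium", "behavior", "stats", "report")`.
#' @return The run manifest, invisibly.
#' @export
run_pipeline <- function(config, seed = NULL, out_dir = NULL,
                         stages = c("simulate", "calcium", "behavior",
                                    "stats", "report")) {
  if (is.character(config)) config <- read_run_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  diags <- validate_config(config)
  if (length(diags) > 0)
    abort_invalid(paste0("invalid config:\n  ", paste(diags, collapse = "\n  ")))
  seed <- seed %||% config$seed %||% 1
  out_dir <- out_dir %||% config$out_dir %||%
    abort_invalid("out_dir: not set in config or call")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data_dir <- file.path(out_dir, "data")
  dir.create(data_dir, showWarnings = FALSE)
  warnings_log <- character()
  run_stage <- function(expr) {
    withCallingHandlers(expr, warning = function(w) {
      warnings_log <<- c(warnings_log, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  }

  cal_protocol <- if (!is.null(config$calcium))
    protocol_from_config(config$calcium$protocol, default_rate = 2)
  beh_protocol <- if (!is.null(config$behavior))
    protocol_from_config(config$behavior$protocol, default_rate = 5)

  if ("simulate" %in% stages) run_stage({
    if (!is.null(config$calcium$groups)) {
      traces <- list(); truth <- list()
      gi <- 0
      for (g in names(config$calcium$groups)) {
        gi <- gi + 1
        gc <- config$calcium$groups[[g]]
        mix <- unlist(gc$class_mix %||% c(0.6, 0.1, 0.3))
        sim <- simulate_calcium_cohort(
          cal_protocol, class_mix = mix,
          amplitude_dist = gc$amplitude %||% list(kind = "uniform", min = 20, max = 35),
          n = gc$n_animals, seed = stream_seed(seed, "calcium", gi),
          noise_sd = gc$noise_sd %||% 0.01,
          neuron = config$calcium$neuron %||% "AIB", group = g,
          post_offset = isTRUE(gc$post_offset)
        )
        traces <- c(traces, sim$traces)
        truth[[g]] <- sim$truth
      }
      air <- simulate_calcium_cohort(
        air_version(cal_protocol),
        class_mix = c(0, 0, 1), n = config$calcium$air_controls$n_animals,
        seed = stream_seed(seed, "air", 1),
        noise_sd = config$calcium$air_controls$noise_sd %||% 0.01,
        neuron = config$calcium$neuron %||% "AIB", group = "air_control"
      )
      write_traces_csv(traces, file.path(data_dir, "calcium_traces.csv"))
      write_traces_csv(air$traces, file.path(data_dir, "calcium_air_controls.csv"))
      utils::write.csv(do.call(rbind, truth),
                       file.path(data_dir, "calcium_truth.csv"),
                       row.names = FALSE)
    }
    if (!is.null(config$behavior$groups)) {
      trajs <- list()
      gi <- 0
      for (g in names(config$behavior$groups)) {
        gc <- config$behavior$groups[[g]]
        params <- if (!is.null(gc$preset))
          locomotion_preset(gc$preset, frame_rate = beh_protocol$frame_rate)
        else do.call(locomotion_params, gc$params)
        for (cond in (gc$conditions %||% list("CO2", "air"))) {
          gi <- gi + 1
          proto <- if (cond == "air") air_version(beh_protocol) else beh_protocol
          sim <- simulate_trajectory_cohort(
            proto, params, n = gc$n_animals,
            seed = stream_seed(seed, "behavior", gi), group = g,
            id_prefix = paste(g, cond, sep = "_")
          )
          trajs <- c(trajs, sim$trajectories)
          st <- do.call(rbind, lapply(seq_along(sim$states), function(i) {
            tt <- sim$trajectories[[i]]$t_s
            data.frame(animal_id = sim$trajectories[[i]]$animal_id,
                       t_s = tt[-length(tt)],
                       state = as.character(sim$states[[i]]),
                       stringsAsFactors = FALSE)
          }))
          truth_path <- file.path(data_dir, "behavior_truth.csv")
          utils::write.csv(st, sub("\\.csv$",
                                   sprintf("_%s_%s.csv", g, cond), truth_path),
                           row.names = FALSE)
        }
      }
      # air-protocol trajectories carry their own protocol; store condition in id
      co2 <- Filter(function(tr) !is_air_control(tr$protocol), trajs)
      air <- Filter(function(tr) is_air_control(tr$protocol), trajs)
      write_trajectories_csv(co2, file.path(data_dir, "trajectories_co2.csv"))
      if (length(air) > 0)
        write_trajectories_csv(air, file.path(data_dir, "trajectories_air.csv"))
    }
    if (!is.null(config$chemotaxis)) {
      rows <- list()
      gi <- 0
      for (g in names(config$chemotaxis$groups)) {
        gc <- config$chemotaxis$groups[[g]]
        for (p in seq_len(gc$n_plates %||% 1)) {
          gi <- gi + 1
          cts <- simulate_chemotaxis_assay(
            gc$p_test, gc$n_worms,
            seed = stream_seed(seed, "chemotaxis", gi),
            plate_id = sprintf("%s_plate%02d", g, p)
          )
          rows[[gi]] <- data.frame(plate_id = cts$plate_id, group = g,
                                   n_test = cts$n_test,
                                   n_control = cts$n_control,
                                   stringsAsFactors = FALSE)
        }
      }
      utils::write.csv(do.call(rbind, rows),
                       file.path(data_dir, "chemotaxis_counts.csv"),
                       row.names = FALSE)
    }
  })

  if ("calcium" %in% stages && !is.null(config$calcium)) run_stage({
    paths <- if (!is.null(config$calcium$input)) config$calcium$input else
      list(traces = file.path(data_dir, "calcium_traces.csv"),
           air = file.path(data_dir, "calcium_air_controls.csv"))
    traces <- read_traces_csv(paths$traces, cal_protocol)
    air <- read_traces_csv(paths$air, air_version(cal_protocol))
    an <- config$calcium$analysis %||% list()
    cls <- classify_cohort(
      traces, air,
      baseline_window = unlist(an$baseline_window) %||% NULL,
      response_window = unlist(an$response_window) %||% NULL,
      k = an$k_sd %||% 3
    )
    utils::write.csv(cls$calls, file.path(out_dir, "calcium_calls.csv"),
                     row.names = FALSE)
    utils::write.csv(cls$table, file.path(out_dir, "calcium_class_table.csv"),
                     row.names = FALSE)
    rts <- lapply(traces, compute_ratio_trace,
                  baseline_window = unlist(an$baseline_window) %||% NULL)
    groups <- vapply(rts, `[[`, character(1), "group")
    ords <- lapply(split(seq_along(rts), groups), function(ix) {
      if (length(ix) < 2) return(ix)
      ix[order_for_heatmap(rts[ix],
                           metric = an$clustering$metric %||% "euclidean",
                           linkage = an$clustering$linkage %||% "average")]
    })
    jsonlite::write_json(
      lapply(ords, function(ix) vapply(rts[ix], `[[`, character(1), "animal_id")),
      file.path(out_dir, "calcium_heatmap_order.json")
    )
  })

  if ("behavior" %in% stages && !is.null(config$behavior)) run_stage({
    paths <- if (!is.null(config$behavior$input)) config$behavior$input else
      list(co2 = file.path(data_dir, "trajectories_co2.csv"),
           air = file.path(data_dir, "trajectories_air.csv"))
    trajs <- read_trajectories_csv(paths$co2, beh_protocol)
    if (!is.null(paths$air) && file.exists(paths$air))
      trajs <- c(trajs, read_trajectories_csv(paths$air,
                                              air_version(beh_protocol)))
    an <- config$behavior$analysis %||% list()
    bt <- behavior_cohort_table(
      trajs, smooth_s = an$smooth_s %||% 1,
      pause_speed_mm_s = an$pause_speed_mm_s %||% 0.02,
      min_bout_s = an$min_bout_s %||% 0.6,
      reversal_angle_deg = an$reversal_angle_deg %||% 120
    )
    utils::write.csv(bt$per_animal, file.path(out_dir, "behavior_metrics.csv"),
                     row.names = FALSE)
    utils::write.csv(bt$speed_summary,
                     file.path(out_dir, "behavior_speed_summary.csv"),
                     row.names = FALSE)
  })

  if ("stats" %in% stages && !is.null(config$stats$plan)) run_stage({
    rows <- list()
    calls <- beh <- chem <- NULL
    f_calls <- file.path(out_dir, "calcium_calls.csv")
    f_beh <- file.path(out_dir, "behavior_metrics.csv")
    f_chem <- file.path(data_dir, "chemotaxis_counts.csv")
    if (file.exists(f_calls)) calls <- utils::read.csv(f_calls)
    if (file.exists(f_beh)) beh <- utils::read.csv(f_beh)
    if (file.exists(f_chem)) chem <- utils::read.csv(f_chem)
    for (pl in config$stats$plan) {
      res <- run_plan_entry(pl, calls, beh, chem)
      rows[[length(rows) + 1]] <- res
    }
    utils::write.csv(do.call(rbind, rows),
                     file.path(out_dir, "stats_results.csv"),
                     row.names = FALSE)
  })

  if ("report" %in% stages) run_stage({
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    fig <- function(name, expr, width = 900, height = 600) {
      grDevices::png(file.path(fig_dir, name), width = width, height = height,
                     res = 110)
      on.exit(grDevices::dev.off())
      force(expr)
    }
    f_traces <- file.path(data_dir, "calcium_traces.csv")
    if (!is.null(config$calcium) && file.exists(f_traces)) {
      traces <- read_traces_csv(f_traces, cal_protocol)
      an <- config$calcium$analysis %||% list()
      rts <- lapply(traces, compute_ratio_trace,
                    baseline_window = unlist(an$baseline_window) %||% NULL)
      groups <- vapply(rts, `[[`, character(1), "group")
      by_group <- split(rts, groups)
      fig("calcium_mean_sem.png", plot_mean_sem(by_group))
      fig("calcium_heatmap.png", plot_response_heatmap(rts))
      calls <- utils::read.csv(file.path(out_dir, "calcium_calls.csv"))
      fig("calcium_peaks.png", plot_peak_violin(calls))
    }
    f_speed <- file.path(out_dir, "behavior_speed_summary.csv")
    if (file.exists(f_speed)) {
      fig("behavior_speed.png",
          plot_speed_traces(utils::read.csv(f_speed), beh_protocol))
    }
    f_chem <- file.path(data_dir, "chemotaxis_counts.csv")
    if (file.exists(f_chem)) {
      chem <- utils::read.csv(f_chem)
      chem$index <- mapply(chemotaxis_index, chem$n_test, chem$n_control)
      fig("chemotaxis_index.png", plot_chemotaxis(chem))
    }
  })

  manifest <- build_manifest(config, seed, out_dir, warnings_log)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

run_plan_entry <- function(pl, calls, beh, chem) {
  row <- function(contrast, statistic, p, p_adj = NA_real_, n = NA) {
    data.frame(name = pl$name %||% pl$test, stream = pl$stream,
               metric = pl$metric %||% "", test = pl$test,
               contrast = contrast, statistic = statistic, p = p,
               p_adj = p_adj, n = paste(n, collapse = "/"),
               stringsAsFactors = FALSE)
  }
  expand <- function(res, contrast) {
    main <- row(contrast, res$statistic, res$p_value, n = res$n)
    if (is.null(res$comparisons)) return(main)
    rbind(main, do.call(rbind, lapply(seq_len(nrow(res$comparisons)),
      function(i) {
        cmp <- res$comparisons[i, ]
        row(cmp$pair, cmp$statistic, cmp$p_raw, cmp$p_adj, n = res$n)
      })))
  }
  if (pl$stream == "calcium") {
    if (is.null(calls)) abort_invalid("stats plan needs the calcium stage outputs")
    gsel <- unlist(pl$groups) %||% unique(calls$group)
    d <- calls[calls$group %in% gsel, ]
    if (pl$test %in% c("fisher_excitatory", "fisher_inhibitory")) {
      cls <- sub("fisher_", "", pl$test)
      tab <- t(vapply(gsel[1:2], function(g) {
        x <- d$class[d$group == g]
        c(sum(x == cls), sum(x != cls))
      }, numeric(2)))
      res <- compare_categorical(tab)
      return(expand(res, paste(gsel[1:2], collapse = " vs ")))
    }
    vals <- split(d[[pl$metric]], d$group)[gsel]
    if (pl$test %in% c("welch_t", "mann_whitney")) {
      res <- compare_two(vals[[1]], vals[[2]], pl$test)
      return(expand(res, paste(gsel[1:2], collapse = " vs ")))
    }
    res <- compare_multi(d[[pl$metric]], d$group, pl$test,
                         ref = pl$ref %||% NULL)
    return(expand(res, "omnibus"))
  }
  if (pl$stream == "behavior") {
    if (is.null(beh)) abort_invalid("stats plan needs the behavior stage outputs")
    if (pl$test == "anova2_sidak") {
      res <- compare_multi(beh[[pl$metric]], method = "anova2_sidak",
                           design = data.frame(group = beh$group,
                                               condition = beh$condition))
      return(expand(res, "group x condition"))
    }
    gsel <- unlist(pl$groups) %||% unique(beh$group)
    d <- beh[beh$group %in% gsel & beh$condition == (pl$condition %||% "CO2"), ]
    vals <- split(d[[pl$metric]], d$group)[gsel]
    if (pl$test %in% c("welch_t", "mann_whitney")) {
      res <- compare_two(vals[[1]], vals[[2]], pl$test)
      return(expand(res, paste(gsel[1:2], collapse = " vs ")))
    }
    res <- compare_multi(d[[pl$metric]], d$group, pl$test,
                         ref = pl$ref %||% NULL)
    return(expand(res, "omnibus"))
  }
  # chemotaxis
  if (is.null(chem)) abort_invalid("stats plan needs the chemotaxis counts")
  chem$index <- mapply(chemotaxis_index, chem$n_test, chem$n_control)
  if (pl$test %in% c("welch_t", "mann_whitney")) {
    gsel <- unlist(pl$groups) %||% unique(chem$group)
    vals <- split(chem$index, chem$group)[gsel]
    res <- compare_two(vals[[1]], vals[[2]], pl$test)
    return(expand(res, paste(gsel[1:2], collapse = " vs ")))
  }
  res <- compare_multi(chem$index, chem$group, pl$test, ref = pl$ref %||% NULL)
  expand(res, "omnibus")
}

build_manifest <- function(config, seed, out_dir, warnings_log) {
  cfg_json <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  tmp <- tempfile()
  writeLines(as.character(cfg_json), tmp)
  cfg_hash <- unname(tools::md5sum(tmp))
  unlink(tmp)
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[!grepl("manifest\\.json$", files)]
  inventory <- data.frame(
    path = sub(paste0("^", out_dir, "/?"), "", files),
    md5 = unname(tools::md5sum(files)),
    stringsAsFactors = FALSE
  )
  list(
    config_hash = cfg_hash,
    seed = seed,
    package_version = as.character(utils::packageVersion("nemoresponse")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    warnings = warnings_log,
    files = inventory
  )
}
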