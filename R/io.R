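# Tidy CSV interchange. Traces: animal_id, neuron, group, t_s, donor,
# acceptor. Trajectories: animal_id, group, t_s, x_mm, y_mm. The protocol
# travels in the run config, not the CSV.

#' Write / read calcium traces as tidy CSV
#'
#' One row per (animal, frame), columns `animal_id, neuron, group, t_s,
#' donor, acceptor`. Reading requires the stimulus protocol the recordings
#' were made under.
#'
#' @param traces List of `calcium_trace`.
#' @param path CSV file path.
#' @return `write_traces_csv()` the path, invisibly; `read_traces_csv()` a
#'   list of `calcium_trace`.
#' @export
write_traces_csv <- function(traces, path) {
  df <- do.call(rbind, lapply(traces, function(tr) {
    data.frame(animal_id = tr$animal_id, neuron = tr$neuron,
               group = tr$group, t_s = tr$t_s, donor = tr$donor,
               acceptor = tr$acceptor, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param protocol The `stimulus_protocol` of the recordings.
#' @export
read_traces_csv <- function(path, protocol) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "neuron", "group", "t_s", "donor", "acceptor")
  if (!all(need %in% names(df)))
    abort_data(sprintf("trace CSV must have columns: %s",
                       paste(need, collapse = ", ")))
  lapply(split(df, factor(df$animal_id, levels = unique(df$animal_id))),
         function(d) {
           d <- d[order(d$t_s), ]
           new_calcium_trace(d$animal_id[1], d$neuron[1], d$group[1],
                             d$t_s, d$donor, d$acceptor, protocol)
         })
}

#' Write / read centroid trajectories as tidy CSV
#'
#' One row per (animal, frame), columns `animal_id, group, t_s, x_mm,
#' y_mm`.
#'
#' @param trajectories List of `trajectory`.
#' @param path CSV file path.
#' @return `write_trajectories_csv()` the path, invisibly;
#'   `read_trajectories_csv()` a list of `trajectory`.
#' @export
write_trajectories_csv <- function(trajectories, path) {
  df <- do.call(rbind, lapply(trajectories, function(tr) {
    data.frame(animal_id = tr$animal_id, group = tr$group, t_s = tr$t_s,
               x_mm = tr$x_mm, y_mm = tr$y_mm, stringsAsFactors = FALSE)
  }))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories_csv
#' @param protocol The `stimulus_protocol` of the recordings.
#' @export
read_trajectories_csv <- function(path, protocol) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("animal_id", "group", "t_s", "x_mm", "y_mm")
  if (!all(need %in% names(df)))
    abort_data(sprintf("trajectory CSV must have columns: %s",
                       paste(need, collapse = ", ")))
  lapply(split(df, factor(df$animal_id, levels = unique(df$animal_id))),
         function(d) {
           d <- d[order(d$t_s), ]
           new_trajectory(d$animal_id[1], d$group[1], d$t_s, d$x_mm,
                          d$y_mm, protocol)
         })
}

#' Read a pipeline run configuration (YAML or JSON)
#'
#' @param path Config file; `.json` is parsed with jsonlite, anything else
#'   with yaml.
#' @return The configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path))
    abort_invalid(sprintf("config file not found: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else
    yaml::read_yaml(path)
}
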