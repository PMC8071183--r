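#' Write a trace to CSV with a JSON sidecar
#'
#' Stores the samples as a two-column CSV (`time_s`, `current_uA`) and the
#' provenance -- seed, protocol steps, cascade parameters, ligand and sample
#' rate -- in `<path>.json` next to it.
#'
#' @param trace A `girk_trace`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  readr::write_csv(
    tibble(time_s = trace$time, current_uA = trace$current), path
  )
  params <- attr(trace, "params")
  protocol <- attr(trace, "protocol")
  ligand <- attr(trace, "ligand")
  sidecar <- list(
    seed = attr(trace, "seed"),
    sample_rate = if (!is.null(params)) params$sample_rate else NULL,
    baseline_subtracted = isTRUE(attr(trace, "baseline_subtracted")),
    params = if (!is.null(params)) unclass(params) else NULL,
    ligand = if (!is.null(ligand)) as.list(ligand) else NULL,
    protocol = if (!is.null(protocol)) protocol_to_list(protocol) else NULL
  )
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Read a trace written by [write_trace()]
#'
#' @param path CSV path; the `<path>.json` sidecar is read when present.
#' @return A `girk_trace`.
#' @export
read_trace <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  out <- tibble(time = df$time_s, current = df$current_uA)
  sidecar_path <- paste0(path, ".json")
  protocol <- NULL
  params <- NULL
  ligand <- NULL
  seed <- NULL
  baseline_subtracted <- FALSE
  if (file.exists(sidecar_path)) {
    side <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    if (!is.null(side$protocol)) protocol <- as_perfusion_protocol(side$protocol)
    if (!is.null(side$params)) params <- do.call(cascade_params, side$params)
    if (!is.null(side$ligand)) ligand <- do.call(ligand_kinetics, side$ligand[
      intersect(names(side$ligand), c("name", "k_on", "k_off", "efficacy"))
    ])
    seed <- side$seed
    baseline_subtracted <- isTRUE(side$baseline_subtracted)
  }
  new_girk_trace(out, protocol = protocol, params = params, ligand = ligand,
                 seed = seed, baseline_subtracted = baseline_subtracted)
}

#' @rdname read_protocol
#' @param protocol A `perfusion_protocol`.
#' @export
protocol_to_list <- function(protocol) {
  list(
    steps = purrr::transpose(as.list(as_tibble(
      protocol[c("t_start", "t_end", "ligand", "concentration", "role")]
    ))),
    total_duration = attr(protocol, "total_duration"),
    baseline_window = attr(protocol, "baseline_window")
  )
}

#' @rdname read_protocol
#' @param x A list (parsed YAML/JSON) with `steps`, `total_duration` and
#'   optionally `baseline_window`.
#' @export
as_perfusion_protocol <- function(x) {
  steps <- x$steps
  if (is.data.frame(steps)) {
    steps <- as_tibble(steps)
  } else {
    steps <- dplyr::bind_rows(purrr::map(steps, as_tibble))
  }
  if (!"role" %in% names(steps)) steps$role <- "agonist"
  new_perfusion_protocol(
    steps,
    total_duration = x$total_duration %||% max(steps$t_end),
    baseline_window = unlist(x$baseline_window) %||% c(0, min(steps$t_start))
  )
}

#' Read or write perfusion protocols as YAML/JSON
#'
#' Protocols serialize to a list with `steps` (each with `t_start`, `t_end`,
#' `ligand`, `concentration`, `role`), `total_duration` and
#' `baseline_window`; files ending in `.json` use JSON, anything else YAML.
#'
#' @param path File path.
#' @return [read_protocol()] returns a `perfusion_protocol`;
#'   [write_protocol()] returns `path` invisibly.
#' @export
read_protocol <- function(path) {
  x <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_perfusion_protocol(x)
}

#' @rdname read_protocol
#' @export
write_protocol <- function(protocol, path) {
  x <- protocol_to_list(protocol)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' Serialize fit results to JSON records
#'
#' @param x An `exp_fit`, `sigmoid_fit`, `linear_range_fit` or
#'   `correlation_result` (or a list of them).
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(x, path) {
  to_rec <- function(f) {
    if (inherits(f, c("exp_fit", "sigmoid_fit", "linear_range_fit",
                      "correlation_result"))) {
      c(list(type = class(f)[1]), unclass(f))
    } else {
      f
    }
  }
  recs <- if (inherits(x, c("exp_fit", "sigmoid_fit", "linear_range_fit",
                            "correlation_result"))) {
    to_rec(x)
  } else {
    purrr::map(x, to_rec)
  }
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
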