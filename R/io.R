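#' Write / read an orientation layout as delimited text
#'
#' Columns: `population`, `neuron`, `x`, `y`, `theta_deg`.
#'
#' @param layout An `orientation_layout`.
#' @param path Output file (TSV).
#' @return `path` invisibly; `read_layout()` returns the layout tibble.
#' @export
write_layout <- function(layout, path) {
  readr::write_tsv(as_tibble(layout), path)
  invisible(path)
}

#' @rdname write_layout
#' @param m Patch size recorded on the restored object.
#' @export
read_layout <- function(path, m = 1) {
  tb <- readr::read_tsv(path, show_col_types = FALSE)
  n_e <- sum(tb$population == "E"); n_i <- sum(tb$population == "I")
  structure(as_tibble(tb), m = m, n_e = n_e, n_i = n_i,
            layout_mode = "restored",
            class = c("orientation_layout", "layer_geometry", class(tibble())))
}

#' Write / read a connectivity graph as a delimited edge list
#'
#' The edge list (`post_pop`, `post`, `pre_pop`, `pre`, `w`) is written as
#' TSV, preceded by a commented YAML header carrying the sampling metadata
#' (population sizes, `k`, `sigma`, reconnection modulations, seed), so a
#' graph file is self-describing and can be reloaded with its geometry.
#'
#' @param graph A `connectivity_graph`.
#' @param path Output file.
#' @return `path` invisibly; `read_graph()` returns the graph (geometry
#'   rebuilt from the header).
#' @export
write_graph <- function(graph, path) {
  hdr <- list(
    n_e = attr(graph, "n_e"), n_i = attr(graph, "n_i"),
    m = attr(graph, "m"), k = attr(graph, "k"), sigma = attr(graph, "sigma"),
    k_max = attr(graph, "k_max"),
    eps_ce = attr(graph, "eps_ce"), eps_ci = attr(graph, "eps_ci"),
    seed = attr(graph, "seed") %||% NA_integer_,
    n_clamped = attr(graph, "n_clamped")
  )
  lines <- paste0("# ", strsplit(yaml::as.yaml(hdr), "\n")[[1]])
  writeLines(lines, path)
  readr::write_tsv(as_tibble(graph), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_graph
#' @export
read_graph <- function(path) {
  all_lines <- readLines(path)
  hdr_lines <- grep("^# ", all_lines, value = TRUE)
  hdr <- yaml::yaml.load(paste(sub("^# ", "", hdr_lines), collapse = "\n"))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  geom <- build_geometry(hdr$n_e, hdr$n_i, hdr$m)
  structure(as_tibble(tb),
            geometry = geom, m = hdr$m, k = hdr$k, sigma = hdr$sigma,
            k_max = hdr$k_max, n_e = hdr$n_e, n_i = hdr$n_i,
            n_clamped = hdr$n_clamped, eps_ce = hdr$eps_ce,
            eps_ci = hdr$eps_ci, seed = hdr$seed,
            class = c("connectivity_graph", class(tibble())))
}

#' Write / read spike rasters as delimited text
#'
#' Columns: `angle_deg`, `population`, `neuron`, `time_ms`, `transient`.
#'
#' @param spikes A `spike_data` tibble.
#' @param path Output file (TSV).
#' @return `path` invisibly; `read_spikes()` returns the spike tibble.
#' @export
write_spikes <- function(spikes, path) {
  hdr <- list(n_e = attr(spikes, "n_e"), n_i = attr(spikes, "n_i"),
              t_total = attr(spikes, "t_total"),
              t_transient = attr(spikes, "t_transient"),
              config_digest = attr(spikes, "config_digest") %||% NA_character_)
  lines <- paste0("# ", strsplit(yaml::as.yaml(hdr), "\n")[[1]])
  writeLines(lines, path)
  readr::write_tsv(as_tibble(spikes), path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  all_lines <- readLines(path)
  hdr_lines <- grep("^# ", all_lines, value = TRUE)
  hdr <- yaml::yaml.load(paste(sub("^# ", "", hdr_lines), collapse = "\n"))
  tb <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  structure(as_tibble(tb),
            n_e = hdr$n_e, n_i = hdr$n_i, t_total = hdr$t_total,
            t_transient = hdr$t_transient,
            angles = sort(unique(tb$angle_deg)),
            config_digest = hdr$config_digest,
            class = c("spike_data", class(tibble())))
}
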