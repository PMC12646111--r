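#' Read / write dam-connectivity networks as JSON
#'
#' The on-disk format is an object with `nodes` (records `id`, `type`) and
#' `edges` (records `from`, `to`, oriented downstream to upstream), the
#' input format of [to_tree()].  Round-trips are lossless.
#'
#' @param path File path.
#' @param nodes,edges Data frames as accepted by [to_tree()].
#' @return `read_network()` returns `list(nodes, edges)`.
#' @export
read_network <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$nodes) || is.null(x$edges)) {
    abort(sprintf("%s: network JSON needs 'nodes' and 'edges'", path),
          "resghg_schema_error")
  }
  nodes <- as.data.frame(x$nodes, stringsAsFactors = FALSE)
  edges <- as.data.frame(x$edges, stringsAsFactors = FALSE)
  check_columns(nodes, c("id", "type"), "node")
  check_columns(edges, c("from", "to"), "edge")
  list(nodes = nodes, edges = edges)
}

#' @rdname read_network
#' @export
write_network <- function(nodes, edges, path) {
  jsonlite::write_json(list(nodes = nodes, edges = edges), path,
                       dataframe = "rows", auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Emit a machine-readable run report
#'
#' Collects the per-reservoir gross and net emissions under both methods,
#' the emission-factor comparison table and the frontier summary into one
#' JSON document.
#'
#' @param emissions Per-reservoir emission table (see [fleet_emissions()]).
#' @param ef_comparison Data frame comparing emission-factor tables.
#' @param frontier_summary A [frontier_report()] data frame (optional).
#' @param path Output file path.
#' @param meta Named list of run metadata (seed, config echo).
#' @return `path`, invisibly.
#' @export
emit_report <- function(emissions, ef_comparison = NULL,
                        frontier_summary = NULL, path, meta = list()) {
  payload <- list(meta = meta,
                  totals = list(
                    net_model_mass = sum(emissions$net_model_mass),
                    net_ef_mass = sum(emissions$net_ef_mass)),
                  reservoirs = emissions,
                  ef_comparison = ef_comparison,
                  frontier = frontier_summary)
  jsonlite::write_json(payload, path, dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' Render an emission-factor comparison table
#'
#' A table shaped like the published comparison: one row per climate zone,
#' one column block per pathway with the global factor and each fitted
#' variant as `"ef (margin)"` strings; absent cells become dashes.
#'
#' @param tables Named list of [ef_table()]s; the first is the reference.
#' @return A data frame of formatted strings.
#' @export
ef_comparison_table <- function(tables) {
  zones <- climate_zones()
  out <- data.frame(zone = zones, stringsAsFactors = FALSE)
  for (p in emission_pathways()) {
    for (nm in names(tables)) {
      tab <- tables[[nm]]
      col <- vapply(zones, function(z) {
        i <- which(tab$zone == z & tab$pathway == p)
        if (!length(i)) return("-")
        if (!is.na(tab$margin[i])) {
          sprintf("%.0f(%.0f)", tab$flux[i], tab$margin[i])
        } else {
          sprintf("%.2f", tab$flux[i])
        }
      }, character(1))
      out[[paste(p, nm, sep = ".")]] <- col
    }
  }
  out
}

#' Read a run-configuration file
#'
#' YAML run configuration: seeds, paths, emission-factor selection, net
#' conversion parameters, planner settings.  Unknown keys are preserved.
#'
#' @param path YAML file path.
#' @return A named list.
#' @export
read_run_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    abort("the 'yaml' package is required to read run configurations",
          "resghg_bad_argument")
  }
  yaml::read_yaml(path)
}
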