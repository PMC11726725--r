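# Configuration loading, packaged fixture parameter sets, and CSV output
# with a JSON metadata header.

# valid flat keys per fixture family
.param_keys <- list(
  ode = c("dt", "k1", "k2", "k3", "k4", "cX", "cY", "cA"),
  replication = c("A0", "cX", "cY", "kRR", "dR", "k1", "k2", "k3", "k4", "dt"),
  mas = c("sizeX", "sizeY", "init_R", "init_P", "agent_size", "Nmax", "d",
          "aR", "aP", "lP", "D", "Dprime", "delta", "dt", "K_repl",
          "k1", "k2", "k3", "k4", "n_inhibitors", "n_anti_inhibitors",
          "target_mode")
)

.fixture_family <- c(table1 = "ode", table2 = "replication", table3 = "mas")

#' Path to a packaged parameter fixture
#' @param name fixture name (\code{"table1"}, \code{"table2"},
#'   \code{"table3"}).
#' @return Path to the installed YAML file.
#' @export
fixture_path <- function(name) {
  if (!name %in% names(.fixture_family))
    stop("unknown fixture '", name, "'; known fixtures: ",
         paste(names(.fixture_family), collapse = ", "))
  system.file("extdata", paste0(name, ".yaml"), package = "ribostat",
              mustWork = TRUE)
}

#' Load a scenario configuration
#'
#' Reads a flat YAML parameter mapping, either one of the packaged fixtures
#' (\code{"table1"}: deterministic binding network, \code{"table2"}:
#' self-replication scenario, \code{"table3"}: multi-agent scenario) by name,
#' or any YAML file by path.  Keys are validated against the known parameter
#' names of the scenario family; an unknown key is an error that lists the
#' valid keys.  Overrides are applied after loading and validated the same
#' way, and the effective parameter set (after overrides) is what the config
#' carries.
#'
#' @param source fixture name or path to a YAML file.
#' @param scenario scenario family, one of \code{"ode"},
#'   \code{"replication"}, \code{"mas"}; inferred automatically for the
#'   packaged fixtures.
#' @param overrides named list of parameter overrides.
#' @param seed optional integer seed carried with the config.
#' @param out optional output path carried with the config.
#' @return An object of class \code{scenario_config}: list with
#'   \code{scenario}, \code{params} (named list), \code{seed}, \code{out},
#'   \code{source}.
#' @examples
#' cfg <- load_config("table1")
#' cfg$params$cY # 24.45
#' @export
load_config <- function(source, scenario = NULL, overrides = list(),
                        seed = NULL, out = NULL) {
  if (source %in% names(.fixture_family)) {
    path <- fixture_path(source)
    if (is.null(scenario)) scenario <- .fixture_family[[source]]
  } else {
    path <- source
    if (!file.exists(path)) stop("no such fixture or file: ", source)
    if (is.null(scenario))
      stop("scenario must be given explicitly for a non-fixture file ",
           "(one of: ", paste(names(.param_keys), collapse = ", "), ")")
  }
  scenario <- match.arg(scenario, names(.param_keys))
  params <- yaml::read_yaml(path)
  valid <- .param_keys[[scenario]]
  check_keys <- function(keys, where) {
    bad <- setdiff(keys, valid)
    if (length(bad))
      stop("unknown ", where, " key(s) for scenario '", scenario, "': ",
           paste(bad, collapse = ", "), "; valid keys: ",
           paste(valid, collapse = ", "))
  }
  check_keys(names(params), "config")
  if (length(overrides)) {
    check_keys(names(overrides), "override")
    params <- modifyList(params, overrides)
  }
  structure(list(scenario = scenario, params = params,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 out = out, source = source),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("scenario config (", x$scenario, ") from ", x$source, ":\n", sep = "")
  for (k in names(x$params)) cat(" ", k, "=", format(x$params[[k]]), "\n")
  invisible(x)
}

#' Rate constants / totals from a configuration
#'
#' Convenience accessors turning a flat \code{\link{load_config}} parameter
#' mapping into the package's domain objects.
#'
#' @param config a \code{scenario_config} with keys \code{k1..k4} (for
#'   rates) or \code{cA}/\code{A0}, \code{cX}, \code{cY} (for totals).
#' @return A \code{\link{rate_constants}} or \code{\link{totals}} object.
#' @export
config_rates <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params
  rate_constants(p$k1, p$k2, p$k3, p$k4)
}

#' @rdname config_rates
#' @export
config_totals <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  p <- config$params
  cA <- if (!is.null(p$cA)) p$cA else p$A0
  totals(cA = cA, cX = p$cX, cY = if (is.null(p$cY)) 0 else p$cY)
}

#' @rdname config_rates
#' @export
config_mas_params <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  if (config$scenario != "mas")
    stop("config is not a multi-agent scenario")
  do.call(mas_params, config$params)
}

#' Write a time series with a JSON metadata header
#'
#' Writes any tabular run output (an ODE trajectory or a multi-agent census)
#' as plain CSV preceded by a single comment line \code{# \{...\}} holding
#' JSON metadata (parameters, seed, package version, and anything passed in
#' \code{metadata}).  \code{\link{read_trajectory}} round-trips it.
#'
#' @param x a data frame (e.g. a \code{mixture_trajectory} or
#'   \code{mas_series}).
#' @param path output file path.
#' @param metadata named list merged into the header; the seed attribute of
#'   \code{x}, if any, is always included.
#' @return \code{path}, invisibly.
#' @export
write_trajectory <- function(x, path, metadata = list()) {
  stopifnot(is.data.frame(x))
  meta <- c(list(seed = attr(x, "seed"),
                 package = "ribostat",
                 version = as.character(utils::packageVersion("ribostat"))),
            metadata)
  meta <- meta[!vapply(meta, is.null, logical(1))]
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# ", jsonlite::toJSON(meta, auto_unbox = TRUE)), con)
  write.csv(as.data.frame(x), con, row.names = FALSE)
  invisible(path)
}

#' Read a time series written by \code{\link{write_trajectory}}
#'
#' @param path file path.
#' @return The data frame, with the parsed header in attribute
#'   \code{metadata}.  An empty (header-only) file reads back as a
#'   zero-row data frame.
#' @export
read_trajectory <- function(path) {
  lines <- readLines(path)
  meta <- list()
  skip <- 0L
  if (length(lines) && startsWith(lines[1], "# ")) {
    meta <- jsonlite::fromJSON(sub("^# ", "", lines[1]))
    skip <- 1L
  }
  df <- read.csv(path, skip = skip)
  attr(df, "metadata") <- meta
  df
}
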