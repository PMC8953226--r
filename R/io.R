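## Delimited-text I/O with unit-suffix column validation, config
## handling and report rendering.
##
## Dialect: comma-separated, UTF-8, "." decimal, header row with
## ISO-style column names carrying unit suffixes (_s, _umol_L, _g_L,
## _ml_min, _umol_gDMB, ...).

#' Read and validate a time-series file
#'
#' Checks that the expected columns (with their unit suffixes) are
#' present and that the time column is strictly increasing.
#'
#' @param path CSV file path.
#' @param columns required column names; the first is treated as the
#'   time column.
#' @param monotone_time require strictly increasing time.
#' @return validated data frame.
#' @export
read_timeseries <- function(path,
                            columns = c("time_s", "glucose_umol_L"),
                            monotone_time = TRUE) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop("file ", basename(path), " lacks required column(s): ",
         paste(missing, collapse = ", "),
         " (column names carry unit suffixes, e.g. time_s)")
  tcol <- df[[columns[1]]]
  if (monotone_time && any(diff(tcol) <= 0))
    stop("time column '", columns[1], "' in ", basename(path),
         " is not strictly increasing")
  df
}

#' Default pipeline configuration
#'
#' Nested sections mirroring the experimental operating point; every
#' value can be overridden from a YAML file via
#' [read_pipeline_config()].
#'
#' @return nested named list with sections `reactor`, `feed`,
#'   `kinetics`, `gas`, `sensors`, `metabolome`, `synth`.
#' @export
pipeline_config <- function() {
  list(
    reactor = list(working_volume = 1.7, feed_glucose = 22.5,
                   base_feed_rate = 2.83, gas_flow_in = 0.8),
    feed = list(mode = "intermittent", cycle_period = 9,
                off_duration = 2, on_rate = 3.64),
    kinetics = list(q_max = 12.36, K_M = 1000, yield_xs = 0.494,
                    maintenance_q = 0, overflow_threshold = 207,
                    starvation_threshold = 53),
    gas = list(inlet_o2 = 0.2095, inlet_co2 = 0.0004,
               molar_volume = 22.414),
    sensors = list(o2 = list(delay = 180, time_constant = 120),
                   co2 = list(delay = 180, time_constant = 120),
                   smoothing_window = 3),
    metabolome = list(include = NULL,
                      axp_factors = list(ATP = 2.71, ADP = 1.88,
                                         AMP = 1.21),
                      mds_k = 2),
    synth = list(replicates = 3, seed = 1,
                 noise = list(gas = 0.002, metabolite = 0.05,
                              feed = 0.005, biomass = 0.01))
  )
}

merge_config <- function(base, override, path = character()) {
  for (key in names(override)) {
    if (!key %in% names(base))
      stop("unknown config key: ",
           paste(c(path, key), collapse = "$"))
    if (is.list(base[[key]]) && is.list(override[[key]])) {
      base[[key]] <- merge_config(base[[key]], override[[key]],
                                  c(path, key))
    } else {
      base[[key]] <- override[[key]]
    }
  }
  base
}

#' Read a pipeline configuration file
#'
#' YAML file with any subset of the [pipeline_config()] sections;
#' unknown keys are rejected, missing ones keep their defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return resolved configuration list.
#' @export
read_pipeline_config <- function(path = NULL) {
  cfg <- pipeline_config()
  if (is.null(path)) return(cfg)
  if (!file.exists(path)) stop("config file not found: ", path)
  merge_config(cfg, yaml::read_yaml(path))
}

#' Write report tables as CSV plus a human-readable rendering
#'
#' Each table is written to `<name>.csv`; a combined plain-text
#' `report.txt` renders the tables with aligned columns. p-values
#' above 0.05 are rendered as "n.s." in change columns upstream
#' (see [welch_compare()]).
#'
#' @param tables named list of data frames.
#' @param dir output directory (created if missing).
#' @return character vector of files written, invisibly.
#' @export
write_report <- function(tables, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- character(0)
  txt <- character(0)
  for (nm in names(tables)) {
    f <- file.path(dir, paste0(nm, ".csv"))
    utils::write.csv(tables[[nm]], f, row.names = FALSE)
    files <- c(files, f)
    txt <- c(txt, paste0("== ", nm, " =="),
             utils::capture.output(print(tables[[nm]],
                                         row.names = FALSE)), "")
  }
  rep_file <- file.path(dir, "report.txt")
  writeLines(txt, rep_file)
  invisible(c(files, rep_file))
}
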