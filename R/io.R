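# Readers/writers: CSV datasets with JSON sidecar metadata, DCF key-value
# parameter configs, trajectory CSVs, JSON fit manifests/results.  All
# numeric output is full double precision ("%.17g") so round trips are exact
# to 1e-12 and writes are atomic (tempfile + rename).

fmt_num <- function(x) sprintf("%.17g", x)

atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("atomic write failed for ", path)
  invisible(path)
}

#' Read and write clamp datasets as CSV with a JSON sidecar
#'
#' The CSV has columns `x`, `y`, `weight` (full double precision); protocol
#' tag, units and provenance travel in `<path>.json`.
#'
#' @param ds a [clamp_dataset()].
#' @param path CSV file path.
#' @return `write_clamp_dataset` returns `path` invisibly;
#'   `read_clamp_dataset` returns a [clamp_dataset()].
#' @export
write_clamp_dataset <- function(ds, path) {
  stopifnot(inherits(ds, "clamp_dataset"))
  atomic_write(path, function(tmp) {
    df <- data.frame(x = fmt_num(ds$x), y = fmt_num(ds$y),
                     weight = fmt_num(ds$weight))
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  })
  meta <- list(protocol = ds$protocol, x_units = ds$x_units,
               y_units = ds$y_units, provenance = ds$provenance)
  atomic_write(paste0(path, ".json"), function(tmp)
    jsonlite::write_json(meta, tmp, auto_unbox = TRUE, pretty = TRUE))
  invisible(path)
}

#' @rdname write_clamp_dataset
#' @export
read_clamp_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("x", "y")
  if (!all(need %in% names(df)))
    stop("malformed dataset CSV (need columns x, y): ", path)
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path))
    jsonlite::read_json(meta_path, simplifyVector = TRUE)
  else list(protocol = "availability", x_units = "", y_units = "",
            provenance = "")
  clamp_dataset(as.numeric(df$x), as.numeric(df$y),
                weight = if ("weight" %in% names(df))
                  as.numeric(df$weight) else NULL,
                protocol = meta$protocol, x_units = meta$x_units,
                y_units = meta$y_units, provenance = meta$provenance)
}

#' Read and write model parameters as a flat key-value config
#'
#' Debian-control-format (`key: value`) files carrying the documented keys
#' `c1_alpha_m`, `c2_alpha_m`, ..., `c1_beta_h`, `c2_beta_h` plus optional
#' `k_on`, `k_off`, `drug_conc_uM`, `g_max`, `E_Na_mV`.  Concentration is
#' micromolar at this boundary and converted to molar internally.
#'
#' @param gating a [gating_params()] object.
#' @param path file path.
#' @param drug optional [drug_params()].
#' @param channel optional [channel_params()].
#' @return `write_params_config` returns `path` invisibly;
#'   `read_params_config` returns
#'   `list(gating, drug, channel)` (missing sections are `NULL`).
#' @export
write_params_config <- function(gating, path, drug = NULL, channel = NULL) {
  validate_gating_params(gating)
  kv <- as.list(stats::setNames(fmt_num(unclass(gating)),
                                names(unclass(gating))))
  if (!is.null(drug)) {
    kv$k_on <- fmt_num(drug$k_on)
    kv$k_off <- fmt_num(drug$k_off)
    kv$drug_conc_uM <- fmt_num(drug$conc * 1e6)
  }
  if (!is.null(channel)) {
    kv$g_max <- fmt_num(channel$g_max)
    kv$E_Na_mV <- fmt_num(channel$E_Na)
  }
  atomic_write(path, function(tmp)
    write.dcf(as.data.frame(kv, check.names = FALSE), tmp))
  invisible(path)
}

#' @rdname write_params_config
#' @export
read_params_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  m <- read.dcf(path)
  kv <- stats::setNames(as.list(m[1, ]), colnames(m))
  num <- function(k) if (is.null(kv[[k]])) NULL else as.numeric(kv[[k]])
  need <- gating_param_names()
  if (!all(need %in% names(kv)))
    stop("config missing gating keys: ",
         paste(setdiff(need, names(kv)), collapse = ", "))
  gating <- do.call(gating_params, stats::setNames(lapply(need, num), need))
  drug <- NULL
  if (!is.null(kv$k_on)) {
    conc_uM <- if (is.null(kv$drug_conc_uM)) 0 else num("drug_conc_uM")
    if (conc_uM < 0)
      stop("invalid drug concentration (", conc_uM,
           " uM): must be >= 0 (units: micromolar)")
    drug <- drug_params(num("k_on"), num("k_off"), uM(conc_uM))
  }
  channel <- NULL
  if (!is.null(kv$g_max))
    channel <- channel_params(num("g_max"),
                              if (is.null(kv$E_Na_mV)) 70 else num("E_Na_mV"))
  list(gating = gating, drug = drug, channel = channel)
}

#' Write a simulated trajectory as CSV
#'
#' Columns `t_ms`, `V_mV`, `m`, `h`, `b`, `f_open`, `I_Na` at full double
#' precision.
#'
#' @param traj a trajectory from [simulate_gating()].
#' @param path file path.
#' @export
write_trajectory <- function(traj, path) {
  cols <- c("t_ms", "V_mV", "m", "h", "b", "f_open", "I_Na")
  stopifnot(all(cols %in% names(traj)))
  atomic_write(path, function(tmp) {
    df <- as.data.frame(lapply(traj[cols], fmt_num))
    utils::write.csv(df, tmp, row.names = FALSE, quote = FALSE)
  })
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  if (!file.exists(path)) stop("trajectory file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as.data.frame(lapply(df, as.numeric))
}

#' Read and write fit manifests
#'
#' A manifest is a JSON array of entries `{file, tag, weight}` pointing at
#' dataset CSVs, consumed by the `fit` CLI subcommand.
#'
#' @param entries data frame with columns `file`, `tag`, `weight`.
#' @param path file path.
#' @export
write_manifest <- function(entries, path) {
  stopifnot(all(c("file", "tag", "weight") %in% names(entries)))
  atomic_write(path, function(tmp)
    jsonlite::write_json(entries, tmp, pretty = TRUE, digits = NA))
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  stopifnot(all(c("file", "tag", "weight") %in% names(m)))
  m
}
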