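# Plain-text formats: tab-separated sweep tables with `# key = value`
# metadata headers, YAML channel configs with explicit unit tags, TSV
# results tables and a JSON run manifest.  No binary acquisition formats.

.SWEEP_COLUMNS <- c("time_s", "voltage_mV", "current_pA", "temperature_C")

#' Write a sweep record to a tab-separated table
#'
#' Format: leading `# key = value` metadata lines (channel, seed, leak_nS,
#' protocol, one `segment` line per protocol segment), then a header row
#' `time_s voltage_mV current_pA temperature_C` and the samples.  Series
#' are written with 15 significant digits so a write/read round trip
#' preserves them to better than 1e-9 relative.
#'
#' @param record A `sweep_record`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_sweep_table <- function(record, path) {
  stopifnot(inherits(record, "sweep_record"))
  m <- record$meta
  hdr <- c(sprintf("# channel = %s", m$channel %||% "unknown"),
           sprintf("# seed = %s", format(m$seed %||% NA)),
           sprintf("# leak_nS = %s", format(m$leak_nS %||% 0, digits = 15)),
           sprintf("# protocol = %s", m$protocol %||% "unknown"))
  seg <- m$segments
  if (!is.null(seg)) {
    hdr <- c(hdr, vapply(seq_len(nrow(seg)), function(k) {
      sprintf("# segment = %s:%s:%s:%s:%s:%s",
              seg$label[k], seg$kind[k],
              format(seg$v_start[k], digits = 15),
              format(seg$v_end[k], digits = 15),
              format(seg$t_start_s[k], digits = 15),
              format(seg$t_end_s[k], digits = 15))
    }, character(1)))
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  writeLines(paste(.SWEEP_COLUMNS, collapse = "\t"), con)
  d <- record$data
  body <- do.call(paste, c(lapply(.SWEEP_COLUMNS, function(cl) {
    formatC(d[[cl]], digits = 15, format = "g")
  }), sep = "\t"))
  writeLines(body, con)
  invisible(path)
}

parse_error <- function(path, line, msg) {
  stop(sprintf("%s:%d: %s", path, line, msg), call. = FALSE)
}

#' Read a sweep table
#'
#' Parses the dialect written by [write_sweep_table()].  Missing columns,
#' non-monotone time and malformed metadata raise errors naming the
#' offending line.
#'
#' @param path File path.
#' @return A `sweep_record`.
#' @export
read_sweep_table <- function(path) {
  lines <- readLines(path)
  is_meta <- startsWith(lines, "#")
  n_meta <- match(FALSE, is_meta, nomatch = length(lines) + 1L) - 1L
  meta <- list(segments = NULL)
  seg_rows <- list()
  for (i in seq_len(n_meta)) {
    m <- regmatches(lines[i], regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", lines[i]))[[1]]
    if (length(m) != 3) parse_error(path, i, "malformed metadata line")
    key <- m[2]; val <- trimws(m[3])
    if (key == "segment") {
      f <- strsplit(val, ":", fixed = TRUE)[[1]]
      if (length(f) != 6) parse_error(path, i, "segment metadata needs 6 fields")
      seg_rows[[length(seg_rows) + 1L]] <- data.frame(
        kind = f[2], v_start = as.numeric(f[3]), v_end = as.numeric(f[4]),
        duration_ms = (as.numeric(f[6]) - as.numeric(f[5])) * 1000,
        label = if (f[1] == "NA") NA_character_ else f[1],
        t_start_s = as.numeric(f[5]), t_end_s = as.numeric(f[6]))
    } else if (key %in% c("seed", "leak_nS")) {
      meta[[key]] <- as.numeric(val)
    } else {
      meta[[key]] <- val
    }
  }
  if (length(seg_rows) > 0) meta$segments <- do.call(rbind, seg_rows)
  if (n_meta + 1L > length(lines)) parse_error(path, n_meta + 1L, "missing header row")
  header <- strsplit(lines[n_meta + 1L], "\t", fixed = TRUE)[[1]]
  missing <- setdiff(.SWEEP_COLUMNS, header)
  if (length(missing) > 0) {
    parse_error(path, n_meta + 1L,
                sprintf("missing column(s): %s", paste(missing, collapse = ", ")))
  }
  d <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                         check.names = FALSE)
  d <- d[, .SWEEP_COLUMNS]
  for (cl in .SWEEP_COLUMNS) {
    if (!is.numeric(d[[cl]])) parse_error(path, n_meta + 2L,
                                          sprintf("column %s is not numeric", cl))
  }
  bad <- which(diff(d$time_s) <= 0)
  if (length(bad) > 0) {
    parse_error(path, n_meta + 2L + bad[1], "time is not strictly increasing")
  }
  new_sweep_record(d, meta)
}

#' Write a sweep family plus an index table
#'
#' @param records List of `sweep_record`s.
#' @param dir Output directory (created if absent).
#' @param stem File-name stem; files are `<stem>_001.tsv`, ... plus
#'   `<stem>_index.tsv`.
#' @return Path of the index file, invisibly.
#' @export
write_sweep_family <- function(records, dir, stem = "sweep") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(seq_along(records), function(i) {
    p <- file.path(dir, sprintf("%s_%03d.tsv", stem, i))
    write_sweep_table(records[[i]], p)
    p
  }, character(1))
  idx <- data.frame(
    file = basename(paths),
    protocol = vapply(records, function(r) r$meta$protocol %||% "unknown", character(1)),
    seed = vapply(records, function(r) as.numeric(r$meta$seed %||% NA), numeric(1)))
  ipath <- file.path(dir, sprintf("%s_index.tsv", stem))
  utils::write.table(idx, ipath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(ipath)
}

# ---- channel configuration -------------------------------------------------

.ENERGY_UNITS <- c("J/mol" = 1, "kJ/mol" = 1000, "kcal/mol" = 4184)
.ENTROPY_UNITS <- c("J/(mol.K)" = 1, "kJ/(mol.K)" = 1000, "kcal/(mol.K)" = 4184)

.config_keys <- list(
  top = c("channel_name", "units", "J", "L", "D", "csi"),
  units = c("energy", "entropy"),
  trans = c("dH", "dS", "z"),
  csi = c("v_half", "q"))

check_keys <- function(x, allowed, where, path) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0) {
    stop(sprintf("%s: unknown key(s) in %s: %s", path, where,
                 paste(extra, collapse = ", ")), call. = FALSE)
  }
}

need_key <- function(x, key, where, path) {
  if (is.null(x[[key]])) {
    stop(sprintf("%s: missing required key '%s' in %s", path, key, where),
         call. = FALSE)
  }
  x[[key]]
}

#' Load and validate a channel parameter configuration
#'
#' YAML schema: `channel_name`; a `units` block tagging the energy and
#' entropy units (`J/mol`, `kJ/mol` or `kcal/mol`, and the matching
#' per-Kelvin forms); a pore transition `L {dH, dS, z}`; optionally a
#' voltage-sensor transition `J {dH, dS, z}` with coupling factor `D`; and
#' optionally a `csi {v_half, q}` availability curve (mV, e0).  All values
#' are normalized to SI internally.  Unknown keys, missing required keys
#' and bad unit tags are rejected.  Without a `J` block the configuration
#' describes a two-state channel and a `thermo_transition` is returned.
#'
#' @param path Path to a YAML config file.
#' @return An `allosteric_params` or `thermo_transition` with attributes
#'   `channel_name` and `csi`.
#' @export
load_channel_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path), call. = FALSE)
  cfg <- yaml::read_yaml(path)
  check_keys(cfg, .config_keys$top, "top level", path)
  name <- need_key(cfg, "channel_name", "top level", path)
  units <- need_key(cfg, "units", "top level", path)
  check_keys(units, .config_keys$units, "units", path)
  e_tag <- need_key(units, "energy", "units", path)
  s_tag <- need_key(units, "entropy", "units", path)
  if (!e_tag %in% names(.ENERGY_UNITS)) {
    stop(sprintf("%s: bad energy unit tag '%s'", path, e_tag), call. = FALSE)
  }
  if (!s_tag %in% names(.ENTROPY_UNITS)) {
    stop(sprintf("%s: bad entropy unit tag '%s'", path, s_tag), call. = FALSE)
  }
  as_trans <- function(block, where) {
    check_keys(block, .config_keys$trans, where, path)
    thermo_transition(
      dH = need_key(block, "dH", where, path) * .ENERGY_UNITS[[e_tag]],
      dS = need_key(block, "dS", where, path) * .ENTROPY_UNITS[[s_tag]],
      z = need_key(block, "z", where, path))
  }
  L <- as_trans(need_key(cfg, "L", "top level", path), "L")
  model <- if (is.null(cfg$J)) {
    if (!is.null(cfg$D)) {
      stop(sprintf("%s: D given without a J block", path), call. = FALSE)
    }
    L
  } else {
    D <- need_key(cfg, "D", "top level", path)
    if (!is.numeric(D) || D < 0) {
      stop(sprintf("%s: coupling factor D must be >= 0", path), call. = FALSE)
    }
    allosteric_params(J = as_trans(cfg$J, "J"), L = L, D = D)
  }
  attr(model, "channel_name") <- name
  if (!is.null(cfg$csi)) {
    check_keys(cfg$csi, .config_keys$csi, "csi", path)
    attr(model, "csi") <- list(v_half = need_key(cfg$csi, "v_half", "csi", path),
                               q = need_key(cfg$csi, "q", "csi", path))
  }
  model
}

#' Write a results table (TSV with units in the header)
#'
#' @param df data.frame whose column names carry units (e.g. `v_half_mV`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a machine-readable run manifest
#'
#' Records what produced a set of outputs: parameters, seeds, the files
#' written and the package version.
#'
#' @param path Output JSON path.
#' @param inputs Named list of input parameters.
#' @param seeds Integer vector of seeds used.
#' @param outputs Character vector of output file paths.
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, inputs = list(), seeds = integer(),
                               outputs = character()) {
  manifest <- list(
    package = "thermogate",
    version = as.character(utils::packageVersion("thermogate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seeds = seeds, inputs = inputs, outputs = outputs)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a run manifest
#' @param path JSON path written by [write_run_manifest()].
#' @return Named list.
#' @export
read_run_manifest <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
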