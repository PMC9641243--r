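#' Read an event table (CSV dialect or FCS)
#'
#' The CSV event dialect is a header row of channel roles followed by one
#' event per row, with `time` in seconds. FCS 3.0/3.1 files are read
#' directly (list-mode, float32/float64 data); the `$TIMESTEP` keyword is
#' honoured when present, otherwise the time channel is assumed to already
#' be in seconds.
#'
#' @param path file to read; format chosen by extension (`.fcs` vs
#'   anything else = CSV).
#' @param channel_map optional named character vector mapping panel roles
#'   to the names used in the file, e.g.
#'   `c(Fluo4 = "FITC-A", CD19 = "PE-A")`; matched case-insensitively.
#' @return a `data.table` with a `time` column and one column per channel;
#'   unknown extra channels are preserved.
#' @export
read_event_table <- function(path, channel_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  tab <- if (ext == "fcs") read_fcs(path) else {
    out <- tryCatch(data.table::fread(path),
                    error = function(e) stop("unparseable event file: ", path,
                                             " (", conditionMessage(e), ")"))
    out
  }
  if (!is.null(channel_map)) {
    for (role in names(channel_map)) {
      hit <- match(tolower(channel_map[[role]]), tolower(names(tab)))
      if (!is.na(hit)) data.table::setnames(tab, hit, role)
    }
  }
  # accept a case-insensitive 'Time' column from instruments
  ti <- match("time", tolower(names(tab)))
  if (!is.na(ti)) data.table::setnames(tab, ti, "time")
  miss <- setdiff(required_channels(), names(tab))
  if (length(miss))
    stop("required channel(s) missing after channel-map resolution: ",
         paste(miss, collapse = ", "))
  tab
}

#' Write an event table in the CSV dialect
#'
#' @param events event table (data.frame).
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
write_event_table <- function(events, path) {
  data.table::fwrite(as.data.frame(events), path)
  invisible(path)
}

# ---- minimal FCS 3.0/3.1 support ------------------------------------------
# List-mode, $DATATYPE F or D, all parameters same bit width, byte order
# little ("1,2,3,4") or big ("4,3,2,1"). Enough for kinetic acquisitions
# exported per subset; not a general-purpose FCS implementation.

#' Write events as a minimal FCS 3.0 file
#'
#' Float32 list-mode data. Non-numeric columns (e.g. the generator's
#' ground-truth labels) are dropped with a warning since FCS carries only
#' numeric parameters. The time channel is stored in ticks of `timestep`
#' seconds and `$TIMESTEP` is written accordingly.
#'
#' @param events event table with a `time` column.
#' @param path destination path.
#' @param timestep seconds per time-channel tick (default 1).
#' @return `path`, invisibly.
#' @export
write_fcs <- function(events, path, timestep = 1) {
  events <- as.data.frame(events)
  for (j in seq_along(events))
    if (is.logical(events[[j]])) events[[j]] <- as.numeric(events[[j]])
  num <- vapply(events, is.numeric, logical(1))
  if (!all(num)) {
    warning("dropping non-numeric column(s) for FCS: ",
            paste(names(events)[!num], collapse = ", "))
    events <- events[num]
  }
  stopifnot("time" %in% names(events))
  events$time <- events$time / timestep
  mat <- as.matrix(events)
  n <- nrow(mat); p <- ncol(mat)
  kw <- c("$DATATYPE", "F", "$MODE", "L", "$BYTEORD", "1,2,3,4",
          "$TOT", format(n, scientific = FALSE),
          "$PAR", format(p, scientific = FALSE),
          "$TIMESTEP", format(timestep),
          "$BEGINANALYSIS", "0", "$ENDANALYSIS", "0",
          "$BEGINSTEXT", "0", "$ENDSTEXT", "0")
  for (j in seq_len(p)) {
    kw <- c(kw,
            sprintf("$P%dN", j), colnames(mat)[j],
            sprintf("$P%dB", j), "32",
            sprintf("$P%dE", j), "0,0",
            sprintf("$P%dR", j), format(ceiling(max(mat[, j], 1)),
                                        scientific = FALSE))
  }
  # two passes: BEGINDATA/ENDDATA are padded to fixed width so the TEXT
  # segment length does not depend on the offsets themselves
  build_text <- function(b, e) {
    paste0("/", paste(c(kw, "$BEGINDATA", sprintf("%12d", b),
                        "$ENDDATA", sprintf("%12d", e)),
                      collapse = "/"), "/")
  }
  probe <- build_text(0, 0)
  text_start <- 58L
  text_end <- text_start + nchar(probe, type = "bytes") - 1L
  data_start <- text_end + 1L
  data_end <- data_start + 4L * n * p - 1L
  txt <- build_text(data_start, data_end)
  header <- sprintf("FCS3.0    %8d%8d%8d%8d%8d%8d",
                    text_start, text_end,
                    data_start, data_end, 0L, 0L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  writeChar(txt, con, eos = NULL)
  writeBin(as.vector(t(mat)), con, size = 4, endian = "little")
  invisible(path)
}

#' Read a minimal FCS 3.0/3.1 file
#'
#' @param path FCS file.
#' @return `data.table` of events; the channel named `time`/`Time` is
#'   rescaled to seconds via `$TIMESTEP` when present.
#' @export
read_fcs <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (length(raw) < 58) stop("unparseable FCS file (truncated header): ", path)
  version <- rawToChar(raw[1:6])
  if (!version %in% c("FCS3.0", "FCS3.1"))
    stop("unsupported FCS version: ", version)
  off <- function(a, b) as.integer(trimws(rawToChar(raw[a:b])))
  text_start <- off(11, 18); text_end <- off(19, 26)
  txt <- rawToChar(raw[(text_start + 1):(text_end + 1)])
  delim <- substr(txt, 1, 1)
  parts <- strsplit(substring(txt, 2), delim, fixed = TRUE)[[1]]
  if (length(parts) %% 2 == 1) parts <- parts[-length(parts)]
  keys <- trimws(parts[seq(1, length(parts), 2)])
  vals <- parts[seq(2, length(parts), 2)]
  kv <- stats::setNames(vals, toupper(keys))
  n <- as.integer(kv[["$TOT"]]); p <- as.integer(kv[["$PAR"]])
  dtype <- toupper(kv[["$DATATYPE"]] %||% "F")
  if (!dtype %in% c("F", "D"))
    stop("unsupported $DATATYPE: ", dtype, " (only F/D)")
  size <- if (dtype == "F") 4L else 8L
  byteord <- kv[["$BYTEORD"]] %||% "1,2,3,4"
  endian <- if (byteord == "4,3,2,1") "big" else "little"
  data_start <- off(27, 34); data_end <- off(35, 42)
  if (data_start == 0) {
    data_start <- as.integer(kv[["$BEGINDATA"]])
    data_end <- as.integer(kv[["$ENDDATA"]])
  }
  vec <- readBin(raw[(data_start + 1):(data_end + 1)], "numeric",
                 n = n * p, size = size, endian = endian)
  mat <- matrix(vec, nrow = n, ncol = p, byrow = TRUE)
  nm <- vapply(seq_len(p),
               function(j) kv[[sprintf("$P%dN", j)]] %||% sprintf("P%d", j),
               character(1))
  colnames(mat) <- nm
  out <- data.table::as.data.table(mat)
  ts <- suppressWarnings(as.numeric(kv[["$TIMESTEP"]] %||% "1"))
  ti <- match("time", tolower(nm))
  if (!is.na(ti) && is.finite(ts) && ts != 1)
    out[[ti]] <- out[[ti]] * ts
  out
}

# ---- compensation ----------------------------------------------------------

#' Construct and validate a spillover matrix
#'
#' @param m square numeric matrix with channel names on both dimensions,
#'   unit diagonal; entry `m[i, j]` is the fraction of channel `i`'s signal
#'   spilling into channel `j`.
#' @return the validated matrix with class `spillover_matrix`.
#' @export
spillover_matrix <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("spillover matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop("spillover matrix needs identical row and column channel labels")
  if (any(abs(diag(m) - 1) > 1e-12))
    stop("spillover matrix diagonal entries must equal 1")
  det_ok <- tryCatch({ solve(m); TRUE }, error = function(e) FALSE)
  if (!det_ok) stop("spillover matrix is not invertible")
  structure(m, class = c("spillover_matrix", class(m)))
}

#' Apply spillover compensation to an event table
#'
#' Standard matrix compensation: observed intensities are multiplied by the
#' inverse of the spillover matrix, channel-wise over the matrix's
#' channels. The time column and channels outside the matrix are untouched.
#'
#' @param events event table.
#' @param m a [spillover_matrix()] (or plain matrix, validated on the fly)
#'   whose channels are all present in `events`.
#' @param validate enforce the spillover-matrix invariants (unit diagonal,
#'   invertibility). Set `FALSE` only to apply an already-inverted matrix,
#'   e.g. to undo a previous compensation.
#' @return compensated copy of `events`.
#' @export
apply_compensation <- function(events, m, validate = TRUE) {
  if (validate) {
    if (!inherits(m, "spillover_matrix")) m <- spillover_matrix(m)
  } else m <- as.matrix(m)
  chans <- rownames(m)
  miss <- setdiff(chans, names(events))
  if (length(miss))
    stop("spillover channels absent from events: ", paste(miss, collapse = ", "))
  out <- data.table::as.data.table(events)
  comp <- as.matrix(out[, chans, with = FALSE]) %*% solve(unclass(m))
  for (j in seq_along(chans)) data.table::set(out, j = chans[j],
                                              value = comp[, j])
  out
}

# ---- manifest and run configuration ---------------------------------------

#' Read a cohort manifest
#'
#' @param path CSV with at least `sample_id`, `group`, `subject_id`,
#'   `path`; extra columns are preserved. Relative sample paths are
#'   resolved against the manifest's directory.
#' @return `data.table` of the manifest.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- data.table::fread(path)
  miss <- setdiff(c("sample_id", "group", "subject_id", "path"), names(man))
  if (length(miss))
    stop("manifest missing column(s): ", paste(miss, collapse = ", "))
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  man
}

#' Default pipeline configuration
#'
#' All tunables of the analysis with their defaults: 5-s bins with at least
#' 5 events each, stimulation at 120 s, AUC window ending at 1020 s, FMO
#' quantile 0.995, loading-gate threshold 10 intensity units, statistics at
#' alpha 0.05 with Grubbs screening at alpha 0.01.
#'
#' @return nested list of configuration values.
#' @export
default_run_config <- function() {
  list(
    manifest = NULL,
    out_dir = NULL,
    channel_map = NULL,
    compensation = NULL,            # path to a spillover CSV, or NULL
    gating = list(
      fmo_quantile = 0.995,
      thresholds = NULL,            # named list; NULL = derive from FMO files
      fmo_files = NULL,
      loading_threshold = 10),
    kinetics = list(
      bin_width = 5, min_per_bin = 5,
      stim_time = 120, t_end = 1020,
      split_cd25 = FALSE),
    stats = list(
      alpha = 0.05, grubbs_alpha = 0.01,
      grubbs = TRUE,
      paired = NULL,                # c(pre=..., post=...)
      parameters = NULL),           # NULL = all derived parameters
    seed = 1L)
}

# recursive defaults merge: user values win
merge_config <- function(user, defaults) {
  for (k in names(defaults)) {
    if (is.null(user[[k]])) user[k] <- defaults[k]
    else if (is.list(defaults[[k]]) && is.list(user[[k]]))
      user[[k]] <- merge_config(user[[k]], defaults[[k]])
  }
  user
}

#' Read a YAML run configuration
#'
#' Unspecified keys fall back to [default_run_config()]. Relative manifest
#' and FMO paths are resolved against the config file's directory.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path)
  cfg <- merge_config(yaml::read_yaml(path), default_run_config())
  root <- dirname(path)
  fix <- function(p) if (!is.null(p) && !grepl("^(/|[A-Za-z]:)", p))
    file.path(root, p) else p
  cfg$manifest <- fix(cfg$manifest)
  cfg$compensation <- fix(cfg$compensation)
  if (!is.null(cfg$gating$fmo_files))
    cfg$gating$fmo_files <- lapply(cfg$gating$fmo_files, fix)
  cfg
}
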