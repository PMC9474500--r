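# Plain-text dataset and model-document IO: one CSV trace file per molecule
# with a '#'-prefixed header, a JSON manifest, and JSON model/config
# documents shared between the simulator, the inference engine and the
# evaluator (a single in-house dialect).

TRACE_FORMAT_VERSION <- "fretkin-trace-1"
CONFIG_FORMAT_VERSION <- "fretkin-config-1"

#' Write an smFRET dataset to trace files and a manifest
#'
#' One CSV file per trace (columns `time_s, donor, acceptor,
#' acceptor_direct, fret`, values at 12 significant digits, `#` header lines
#' carrying the trace id and sampling rate), a JSON manifest listing the
#' files with provenance (seed, config hash), and -- for simulated data -- a
#' ground-truth sidecar with the generating model, per-trace state paths and
#' variation factors.
#'
#' @param dataset a `fret_dataset`.
#' @param directory output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_traces <- function(dataset, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  files <- character(length(dataset$traces))
  for (i in seq_along(dataset$traces)) {
    tr <- dataset$traces[[i]]
    files[i] <- paste0(tr$trace_id, ".csv")
    path <- file.path(directory, files[i])
    con <- file(path, "w")
    writeLines(c(
      paste0("# format: ", TRACE_FORMAT_VERSION),
      paste0("# trace_id: ", tr$trace_id),
      paste0("# sampling_rate_hz: ", format(tr$sampling_rate, digits = 12)),
      "time_s,donor,acceptor,acceptor_direct,fret"), con)
    m <- cbind(tr$time_s, tr$donor, tr$acceptor, tr$acceptor_direct, tr$fret)
    writeLines(apply(m, 1L, function(r)
      paste(format(r, digits = 12, trim = TRUE, scientific = FALSE),
            collapse = ",")), con)
    close(con)
  }
  cfg_tmp <- tempfile(fileext = ".json")
  writeLines(config_to_json(dataset$config), cfg_tmp)
  manifest <- list(
    format_version = TRACE_FORMAT_VERSION,
    sampling_rate_hz = dataset$config$sampling_rate,
    channels = c("donor", "acceptor", "acceptor_direct"),
    traces = files,
    provenance = list(seed = dataset$config$seed,
                      config_hash = unname(tools::md5sum(cfg_tmp)),
                      generator = paste0("fretkin ",
                                         as.character(utils::packageVersion("fretkin")))))
  unlink(cfg_tmp)
  manifest_path <- file.path(directory, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  if (!is.null(dataset$model))
    write_model_config(dataset$model, dataset$config,
                       file.path(directory, "ground_truth.json"))
  invisible(manifest_path)
}

#' Read an smFRET dataset from a manifest
#'
#' Parses every trace file listed in the manifest, validating the header,
#' the column layout and the time column, and recomputes the FRET
#' efficiency from the intensity channels (the file's `fret` column is
#' informational, not trusted).
#'
#' @param manifest path to a `manifest.json` (or to the directory holding
#'   it).
#' @return A `fret_dataset` (without ground truth unless a
#'   `ground_truth.json` sidecar is present).
#' @export
read_traces <- function(manifest) {
  if (dir.exists(manifest)) manifest <- file.path(manifest, "manifest.json")
  if (!file.exists(manifest)) stop("manifest not found: ", manifest, call. = FALSE)
  man <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  dir <- dirname(manifest)
  if (!identical(man$format_version, TRACE_FORMAT_VERSION))
    stop("unsupported trace format version: ", man$format_version, call. = FALSE)
  missing <- man$traces[!file.exists(file.path(dir, man$traces))]
  if (length(missing))
    stop("manifest references missing file(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  traces <- lapply(man$traces, function(f) read_one_trace(file.path(dir, f)))
  rates <- vapply(traces, `[[`, numeric(1), "sampling_rate")
  if (length(unique(signif(rates, 10))) > 1L)
    stop("inconsistent sampling rates across trace files", call. = FALSE)
  gt_path <- file.path(dir, "ground_truth.json")
  model <- NULL; config <- NULL
  if (file.exists(gt_path)) {
    gt <- read_model_config(gt_path)
    model <- gt$model; config <- gt$config
  }
  if (is.null(config))
    config <- simulation_config(
      sampling_rate = rates[1L], bleach_rate = 1e-3,
      min_length = 1, max_length = 1e6, n_traces = length(traces),
      emission_means = matrix(1, 1, 3), emission_cov = diag(3))
  structure(list(traces = traces, model = model, config = config,
                 ground_truth = NULL),
            class = "fret_dataset")
}

read_one_trace <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines)
  header <- lines[hdr]
  get_field <- function(key) {
    ln <- grep(paste0("^# ", key, ":"), header, value = TRUE)
    if (!length(ln)) stop("malformed header in ", path, ": missing '", key, "'",
                          call. = FALSE)
    trimws(sub(paste0("^# ", key, ":"), "", ln[1L]))
  }
  trace_id <- get_field("trace_id")
  sampling_rate <- as.numeric(get_field("sampling_rate_hz"))
  body <- lines[-hdr]
  if (!length(body) || body[1L] != "time_s,donor,acceptor,acceptor_direct,fret")
    stop("malformed column header in ", path, call. = FALSE)
  if (length(body) == 1L) {
    df <- data.frame(time_s = numeric(0), donor = numeric(0),
                     acceptor = numeric(0), acceptor_direct = numeric(0),
                     fret = numeric(0))
  } else {
    parts <- strsplit(body[-1L], ",", fixed = TRUE)
    bad <- which(lengths(parts) != 5L)
    if (length(bad))
      stop("inconsistent column count in ", path, " at data line ", bad[1L],
           call. = FALSE)
    m <- matrix(suppressWarnings(as.numeric(unlist(parts))), ncol = 5L,
                byrow = TRUE)
    if (anyNA(m[, 1L]) || any(m[, 1L] < 0))
      stop("invalid time value in ", path, " at data line ",
           which(is.na(m[, 1L]) | m[, 1L] < 0)[1L], call. = FALSE)
    df <- data.frame(time_s = m[, 1L], donor = m[, 2L], acceptor = m[, 3L],
                     acceptor_direct = m[, 4L], fret = m[, 5L])
  }
  structure(
    list(time_s = df$time_s, donor = df$donor, acceptor = df$acceptor,
         acceptor_direct = df$acceptor_direct,
         fret = compute_fret(df$donor, df$acceptor),
         gt_occupancy = NULL, trace_id = trace_id,
         sampling_rate = sampling_rate),
    class = "fret_trace")
}

config_to_json <- function(config, model = NULL) {
  doc <- list(format_version = CONFIG_FORMAT_VERSION)
  if (!is.null(model))
    doc$model <- list(n_states = model$n_states,
                      rates = as.numeric(t(model$rates)),  # row-major
                      fret = model$fret,
                      state_labels = model$state_labels)
  if (!is.null(config)) {
    cfg <- unclass(config)
    cfg$emission_means <- as.numeric(t(cfg$emission_means))
    cfg$emission_cov <- lapply(cfg$emission_cov, function(S) as.numeric(t(S)))
    doc$simulation <- cfg
  }
  jsonlite::toJSON(doc, auto_unbox = TRUE, pretty = TRUE, digits = I(12))
}

#' Write a kinetic model (and optional simulation config) to JSON
#'
#' The single model-document dialect used for ground-truth sidecars,
#' inferred-model exports and simulator configuration; rate matrices and
#' emission parameters are stored row-major at 12 significant digits so a
#' read/write round trip is stable.
#'
#' @param model a `kinetic_model` (or `NULL`).
#' @param config a `simulation_config` (or `NULL`).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_model_config <- function(model, config, path) {
  writeLines(config_to_json(config, model), path)
  invisible(path)
}

#' Read a kinetic model and simulation config from JSON
#'
#' @param path a model/config document written by [write_model_config()].
#' @return List with `model` (validated `kinetic_model` or `NULL`) and
#'   `config` (`simulation_config` or `NULL`). Unknown keys are preserved
#'   in an `extras` element with a warning.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format_version, CONFIG_FORMAT_VERSION))
    stop("unsupported config format version: ", doc$format_version,
         call. = FALSE)
  known <- c("format_version", "model", "simulation", "inference")
  extras <- doc[setdiff(names(doc), known)]
  if (length(extras))
    warning("unknown config keys preserved: ",
            paste(names(extras), collapse = ", "))
  model <- NULL
  if (!is.null(doc$model)) {
    n <- doc$model$n_states
    rates <- matrix(doc$model$rates, n, n, byrow = TRUE)
    model <- kinetic_model(rates, fret = doc$model$fret,
                           state_labels = doc$model$state_labels)
  }
  config <- NULL
  if (!is.null(doc$simulation)) {
    s <- doc$simulation
    n_st <- length(s$emission_means) / 3L
    if (!is.null(s$max_length) && !is.null(s$min_length) &&
        s$max_length < s$min_length)
      stop("schema error: max_length < min_length", call. = FALSE)
    config <- simulation_config(
      sampling_rate = s$sampling_rate, bleach_rate = s$bleach_rate,
      min_length = s$min_length, max_length = s$max_length,
      n_traces = s$n_traces,
      emission_means = matrix(unlist(s$emission_means), n_st, 3L, byrow = TRUE),
      emission_cov = if (is.matrix(s$emission_cov)) {
        lapply(seq_len(nrow(s$emission_cov)), function(i)
          matrix(s$emission_cov[i, ], 3L, 3L, byrow = TRUE))
      } else {
        lapply(s$emission_cov, function(v)
          matrix(unlist(v), 3L, 3L, byrow = TRUE))
      },
      mean_jitter_scale = s$mean_jitter_scale,
      brightness_base = s$brightness_base,
      enable_mean_jitter = isTRUE(s$enable_mean_jitter),
      enable_brightness = isTRUE(s$enable_brightness),
      enable_blinking = isTRUE(s$enable_blinking),
      blink_rates = lapply(s$blink_rates, unlist),
      donor_dark_baseline = s$donor_dark_baseline %||% 0,
      seed = s$seed)
  }
  out <- list(model = model, config = config)
  if (!is.null(doc$inference)) out$inference <- doc$inference
  if (length(extras)) out$extras <- extras
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Export an inferred model in the model-document dialect
#'
#' Writes the inferred rate matrix, FRET parameters, likelihood and
#' convergence metadata so an inferred model can be compared directly with
#' a ground-truth config by the evaluator.
#'
#' @param model an `inferred_model`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_inferred_model <- function(model, path) {
  km <- as_kinetic_model(model)
  doc <- list(
    format_version = CONFIG_FORMAT_VERSION,
    model = list(n_states = km$n_states,
                 rates = as.numeric(t(km$rates)),
                 fret = km$fret, state_labels = km$state_labels),
    inference = list(fret_sds = model$fret_sds,
                     transition_matrix = as.numeric(t(model$A)),
                     loglik = model$loglik, bic = model$bic,
                     n_frames = model$n_frames,
                     frame_period_s = model$frame_period,
                     rate_method = model$rate_method,
                     iterations = model$iterations,
                     converged = model$converged))
  if (!is.null(model$ci95))
    doc$inference$ci95 <- list(level = model$ci95$level,
                               low = as.numeric(t(model$ci95$low)),
                               high = as.numeric(t(model$ci95$high)))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = I(12))
  invisible(path)
}
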