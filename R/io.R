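#' Write a voltage trace as TSV
#'
#' Columns \code{time_ms}, \code{V_mV}, \code{I_pA}; voltage rounded to
#' 1e-4 mV and current to 1e-3 pA, so a write/read round trip is lossless
#' at that precision.
#'
#' @param trace a \code{voltage_trace}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = (seq_along(trace$V) - 1) * trace$dt,
                   V_mV = round(trace$V, 4),
                   I_pA = round(trace$I_in, 3))
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a voltage trace from TSV
#'
#' @param path TSV file with header \code{time_ms  V_mV  I_pA} and a
#'   uniform time grid
#' @return a \code{voltage_trace}
#' @export
read_trace <- function(path) {
  if (file.size(path) == 0) stop("empty trace file: ", path)
  df <- utils::read.table(path, header = TRUE, sep = "\t")
  need <- c("time_ms", "V_mV", "I_pA")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("trace file missing column(s): ", paste(miss, collapse = ", "))
  if (nrow(df) < 2) stop("trace file has fewer than 2 samples")
  dts <- diff(df$time_ms)
  bad <- which(abs(dts - dts[1]) > 1e-9 * max(1, abs(dts[1])))
  if (length(bad))
    stop("non-uniform time grid at row ", bad[1] + 1)
  voltage_trace(dts[1], df$V_mV, df$I_pA, source = "synthetic-recording")
}

#' Write spike times (one per line)
#'
#' @param spikes a \code{spike_train}
#' @param path output path
#' @return \code{path}, invisibly
#' @export
write_spikes <- function(spikes, path) {
  writeLines(format(as.numeric(spikes), trim = TRUE), path)
  invisible(path)
}

#' Read spike times
#'
#' @param path file with one spike time (ms) per line
#' @param duration trace duration (ms); defaults to the last spike time
#' @return a \code{spike_train}
#' @export
read_spikes <- function(path, duration = NULL) {
  x <- as.numeric(readLines(path))
  x <- x[!is.na(x)]
  spike_train(x, duration = if (is.null(duration))
    (if (length(x)) max(x) else 0) else duration)
}

#' Run a named pipeline stage from a configuration list
#'
#' A small reproducible-run driver: executes one named stage with explicit
#' parameters and seed, writes its outputs, and returns a structured log.
#' Stages: \code{"simulate"} (params + protocol -> trace and spikes files)
#' and \code{"fit_dyniv"} (noise + pulse traces -> params JSON).
#'
#' @param config list with \code{stage}, \code{seed}, \code{out} (output
#'   directory), and stage-specific fields: for \code{simulate}:
#'   \code{params_file}, \code{protocol} (a list of
#'   \code{\link{build_protocol}} arguments); for \code{fit_dyniv}:
#'   \code{noise_trace}, \code{pulse_trace} (paths)
#' @return list with \code{outputs} (paths) and \code{log} (parameters,
#'   seed, runtime, warnings)
#' @export
run_stage <- function(config) {
  stopifnot(is.list(config), !is.null(config$stage), !is.null(config$out))
  t0 <- Sys.time()
  if (!dir.exists(config$out)) dir.create(config$out, recursive = TRUE)
  warns <- character(0)
  outputs <- withCallingHandlers({
    if (identical(config$stage, "simulate")) {
      if (!is.null(config$seed)) set.seed(config$seed)
      params <- read_params_json(config$params_file)
      wf <- do.call(build_protocol, config$protocol)
      res <- integrate_aeif(params, wf)
      tp <- file.path(config$out, "trace.tsv")
      sp <- file.path(config$out, "spikes.txt")
      write_trace(res$trace, tp)
      write_spikes(res$spikes, sp)
      c(trace = tp, spikes = sp)
    } else if (identical(config$stage, "fit_dyniv")) {
      noise <- read_trace(config$noise_trace)
      pulse <- if (!is.null(config$pulse_trace))
        read_trace(config$pulse_trace) else NULL
      fit <- fit_full(noise, pulse)
      pp <- file.path(config$out, "params.json")
      write_params_json(fit$params, pp)
      c(params = pp)
    } else stop("unknown stage: ", config$stage)
  }, warning = function(w) {
    warns <<- c(warns, conditionMessage(w))
    invokeRestart("muffleWarning")
  })
  list(outputs = outputs,
       log = list(stage = config$stage, seed = config$seed,
                  runtime_s = as.numeric(difftime(Sys.time(), t0,
                                                  units = "secs")),
                  warnings = warns))
}
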