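RESULT_FORMAT_VERSION <- "1"

#' Write / read a simulation result
#'
#' A `tc_simulation` is stored as two plain-text files: `<base>.csv` with
#' the time grid and every trace, and `<base>.json` with the metadata needed
#' to re-run the simulation bit-exactly (protocol, seed, integration
#' settings, gate state, format version and trace dimensions). `read_result`
#' validates the version and the dimensions, so a truncated trace file is
#' reported as an error rather than read silently.
#'
#' @param res a `tc_simulation` from [run_protocol()].
#' @param base path prefix (without extension).
#' @return `write_result` returns `base` invisibly; `read_result` returns a
#'   `tc_simulation`.
#' @export
write_result <- function(res, base) {
  stopifnot(inherits(res, "tc_simulation"))
  df <- data.frame(time = res$time, res$traces, check.names = FALSE)
  utils::write.csv(df, paste0(base, ".csv"), row.names = FALSE)
  meta <- list(version = RESULT_FORMAT_VERSION,
               proto = unclass(res$proto), seed = res$seed, fs = res$fs,
               dt = res$dt, kappa = res$kappa,
               clamp_drive = res$clamp_drive,
               gate = res$gate, n = nrow(res$traces),
               columns = colnames(res$traces))
  jsonlite::write_json(meta, paste0(base, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(base)
}

#' @rdname write_result
#' @export
read_result <- function(base) {
  csv <- paste0(base, ".csv"); js <- paste0(base, ".json")
  if (!file.exists(csv) || !file.exists(js))
    stop("result files not found at prefix: ", base, call. = FALSE)
  meta <- jsonlite::read_json(js, simplifyVector = TRUE)
  if (!identical(as.character(meta$version), RESULT_FORMAT_VERSION))
    stop("result format version mismatch: ", meta$version, call. = FALSE)
  df <- utils::read.csv(csv, check.names = FALSE)
  if (nrow(df) != meta$n || !identical(colnames(df)[-1], meta$columns))
    stop("corrupt or truncated result file: ", csv, call. = FALSE)
  tr <- as.matrix(df[, -1, drop = FALSE])
  proto <- stim_protocol(meta$proto$frequency, meta$proto$onset,
                         meta$proto$duration,
                         coupling = as.list(meta$proto$coupling),
                         gabab_enabled = meta$proto$gabab_enabled)
  structure(list(time = df$time, traces = tr, proto = proto,
                 seed = meta$seed, fs = meta$fs, dt = meta$dt,
                 kappa = meta$kappa,
                 clamp_drive = meta$clamp_drive,
                 gate = meta$gate),
            class = "tc_simulation")
}
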