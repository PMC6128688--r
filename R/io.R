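#' @include AllClasses.R
NULL

.sweepsetSchema <- "mechanopatch-sweepset-1"

#' Write a sweep set to the JSON container
#'
#' Serializes a [SweepSet-class] to a hierarchical JSON container: set-level
#' metadata, then one record per sweep holding the `current_pA` samples and
#' the attributes `fs_hz`, `v_hold_mv`, `stim_onset_ms`, `stim_duration_ms`,
#' `stim_amplitude`, `stim_kind` plus free-form annotations. Samples are
#' written at full floating precision so a write/read round trip is
#' lossless. Times are implicit (sampling rate + index); the delimited-text
#' dialect ([writeSweepCSV()]) carries explicit time for interoperability.
#'
#' The current sign convention (inward negative) is fixed at this boundary.
#'
#' @param set a [SweepSet-class].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [readSweepSet()], [writeSweepCSV()]
#' @export
writeSweepSet <- function(set, path) {
  validObject(set)
  obj <- list(
    schema = .sweepsetSchema,
    sign_convention = "inward negative (pA)",
    metadata = set@metadata,
    sweeps = lapply(set@sweeps, function(sw) {
      list(
        id = sw@id,
        fs_hz = sw@fsHz,
        v_hold_mv = sw@vHoldMV,
        stim_onset_ms = sw@stimOnsetMs,
        stim_duration_ms = sw@stimDurationMs,
        stim_amplitude = sw@stimAmplitude,
        stim_kind = sw@stimKind,
        annotations = sw@annotations,
        current_pA = sw@currentPA
      )
    })
  )
  # I(17) = 17 *significant* digits: doubles round-trip bit-exactly
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE, na = "null", null = "null")
  writeLines(json, path)
  invisible(path)
}

#' Read a sweep set from the JSON container
#'
#' @param path path to a file written by [writeSweepSet()].
#' @return A [SweepSet-class].
#' @export
readSweepSet <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  if (is.null(obj$schema) || obj$schema != .sweepsetSchema) {
    stop("not a ", .sweepsetSchema, " container (missing/unknown schema field)")
  }
  need <- c(
    "id", "fs_hz", "v_hold_mv", "stim_onset_ms", "stim_duration_ms",
    "stim_amplitude", "stim_kind", "current_pA"
  )
  sw <- lapply(obj$sweeps, function(rec) {
    miss <- setdiff(need, names(rec))
    if (length(miss)) {
      stop("malformed container: sweep record missing field(s) ", paste(miss, collapse = ", "))
    }
    toNum <- function(x) if (is.null(x)) NA_real_ else as.numeric(x)
    newSweep(
      currentPA = as.numeric(unlist(rec$current_pA)),
      fsHz = as.numeric(rec$fs_hz), vHoldMV = toNum(rec$v_hold_mv),
      stimOnsetMs = toNum(rec$stim_onset_ms),
      stimDurationMs = toNum(rec$stim_duration_ms),
      stimAmplitude = toNum(rec$stim_amplitude),
      stimKind = rec$stim_kind, id = rec$id,
      annotations = if (is.null(rec$annotations)) list() else rec$annotations
    )
  })
  newSweepSet(sw, metadata = if (is.null(obj$metadata)) list() else obj$metadata)
}

#' Write / read a single sweep as delimited text
#'
#' Text fallback for single sweeps: a CSV with columns `time_s`,
#' `current_pA` and `stimulus` (the stimulus waveform value at each sample).
#' On reading, the sampling rate is inferred from the time column and the
#' stimulus metadata from the stimulus column.
#'
#' @param sweep a [Sweep-class].
#' @param path CSV path.
#' @return `writeSweepCSV`: `path` invisibly; `readSweepCSV`: a
#'   [Sweep-class].
#' @export
writeSweepCSV <- function(sweep, path) {
  t_s <- sweepTimesMs(sweep) / 1000
  stim <- if (!is.na(sweep@stimOnsetMs) && !is.na(sweep@stimAmplitude)) {
    p <- stimulusProtocol(
      kind = if (sweep@stimKind == "pressure") "pressure" else "poke",
      onsetMs = sweep@stimOnsetMs, durationMs = sweep@stimDurationMs,
      amplitude = sweep@stimAmplitude
    )
    stimulusWaveform(p, sweepTimesMs(sweep))
  } else {
    rep(0, length(t_s))
  }
  utils::write.csv(
    data.frame(time_s = t_s, current_pA = sweep@currentPA, stimulus = stim),
    path,
    row.names = FALSE
  )
  invisible(path)
}

#' @rdname writeSweepCSV
#' @export
readSweepCSV <- function(path) {
  d <- utils::read.csv(path)
  need <- c("time_s", "current_pA", "stimulus")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("text sweep missing column(s): ", paste(miss, collapse = ", "))
  dt <- stats::median(diff(d$time_s))
  if (!is.finite(dt) || dt <= 0) stop("cannot infer sampling rate from time column")
  fs <- 1 / dt
  on <- which(d$stimulus != 0)
  stimOn <- if (length(on)) d$time_s[on[1]] * 1000 else NA_real_
  stimDur <- if (length(on)) (d$time_s[on[length(on)]] - d$time_s[on[1]]) * 1000 + dt * 1000 else NA_real_
  amp <- if (length(on)) max(abs(d$stimulus)) * sign(d$stimulus[on[1]]) else NA_real_
  newSweep(d$current_pA,
    fsHz = fs, stimOnsetMs = stimOn, stimDurationMs = stimDur,
    stimAmplitude = amp, stimKind = if (length(on)) "poke" else "none",
    id = sub("\\.[^.]*$", "", basename(path)),
    annotations = list(source = "csv")
  )
}
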