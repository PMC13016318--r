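# ---- flat binary array container -------------------------------------
# Continuous data and epoch arrays are stored as little-endian float32
# with a JSON header sidecar (<path>.json) holding dimensions and
# attributes. Write-then-read is bit-exact at float32 precision and a
# second write reproduces the file byte for byte.

writeArrayContainer <- function(x, path, attrs = list()) {
  dims <- dim(x)
  if (is.null(dims)) dims <- length(x)
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  header <- c(list(dims = as.integer(dims), dtype = "float32",
                   byteOrder = "little"), attrs)
  jsonlite::write_json(header, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

readArrayContainer <- function(path) {
  header <- jsonlite::read_json(paste0(path, ".json"),
                                simplifyVector = TRUE)
  n <- prod(header$dims)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
  if (length(header$dims) > 1) dim(x) <- header$dims
  list(data = x, header = header)
}

#' Write / read a continuous recording container
#'
#' Stores the channels x samples voltage matrix as little-endian float32
#' (`<path>.bin`) with a JSON header (`<path>.json`) carrying `sfreq`,
#' `ch_names` and exclusion flags.
#'
#' @param rec a [ContinuousRecording-class].
#' @param path file path without extension.
#' @return `writeRecording` the path, invisibly; `readRecording` a
#'   [ContinuousRecording-class].
#' @export
writeRecording <- function(rec, path) {
  writeArrayContainer(rec@data, path,
                      list(sfreq = rec@sfreq, ch_names = rec@chNames,
                           excluded = rec@excluded))
}

#' @rdname writeRecording
#' @export
readRecording <- function(path) {
  r <- readArrayContainer(path)
  ContinuousRecording(r$data, r$header$sfreq, r$header$ch_names,
                      as.logical(r$header$excluded))
}

#' Write / read baseline-normalized epochs
#'
#' The trials x electrodes x time BGA array goes to the float32
#' container; trial covariates and the electrode table go to TSV
#' sidecars (`<path>_trials.tsv`, `<path>_electrodes.tsv`).
#'
#' @param ep an [EnvelopeEpochs-class].
#' @param path file path without extension.
#' @return `writeEpochs` the path, invisibly; `readEpochs` an
#'   [EnvelopeEpochs-class].
#' @export
writeEpochs <- function(ep, path) {
  writeArrayContainer(ep@bga, path,
                      list(times = ep@times, baseline = ep@baseline))
  writeTsv(ep@trials, paste0(path, "_trials.tsv"))
  writeTsv(ep@electrodes, paste0(path, "_electrodes.tsv"))
  invisible(path)
}

#' @rdname writeEpochs
#' @export
readEpochs <- function(path) {
  r <- readArrayContainer(path)
  EnvelopeEpochs(r$data, r$header$times,
                 readTsv(paste0(path, "_trials.tsv")),
                 readTsv(paste0(path, "_electrodes.tsv")),
                 r$header$baseline)
}

writeTsv <- function(d, path) {
  data.table::fwrite(d, path, sep = "\t", quote = FALSE)
  invisible(path)
}

readTsv <- function(path, required = NULL) {
  if (!file.exists(path)) stop("missing file: ", path)
  d <- as.data.frame(data.table::fread(path, sep = "\t"))
  if (!is.null(required)) {
    miss <- setdiff(required, names(d))
    if (length(miss))
      stop("schema violation in ", basename(path), ": missing column(s) ",
           paste(miss, collapse = ", "))
  }
  d
}

#' Tabular readers with schema validation
#'
#' TSV readers for the pipeline's interchange tables; a missing required
#' column raises an error naming it.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
readEvents <- function(path)
  readTsv(path, required = c("onset_s", "word", "class", "response",
                             "rt_s", "correct"))

#' @rdname readEvents
#' @export
readElectrodes <- function(path)
  readTsv(path, required = c("name", "patient", "x", "y", "z", "roi"))

#' @rdname readEvents
#' @export
readLexicon <- function(path)
  readTsv(path, required = c("word", "class", "concreteness_mean",
                             "concreteness_sd", "length", "zipf"))

#' Write a simulated cohort to disk
#'
#' Per patient: `sub-XX_ieeg.bin/.json` (continuous recording),
#' `sub-XX_events.tsv`, `sub-XX_electrodes.tsv`; plus the shared
#' `lexicon.tsv` and `ground_truth.json`.
#'
#' @param cohort result of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  writeTsv(cohort$lexicon, file.path(dir, "lexicon.tsv"))
  gt <- list()
  for (pid in names(cohort$patients)) {
    p <- cohort$patients[[pid]]
    writeRecording(p$recording, file.path(dir, paste0(pid, "_ieeg")))
    writeTsv(p$events, file.path(dir, paste0(pid, "_events.tsv")))
    writeTsv(p$electrodes, file.path(dir, paste0(pid, "_electrodes.tsv")))
    gt[[pid]] <- p$groundTruth
  }
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(dir)
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  lex <- readLexicon(file.path(dir, "lexicon.tsv"))
  ids <- sub("_ieeg\\.json$", "",
             basename(Sys.glob(file.path(dir, "*_ieeg.json"))))
  patients <- lapply(ids, function(pid) {
    list(recording = readRecording(file.path(dir, paste0(pid, "_ieeg"))),
         events = readEvents(file.path(dir, paste0(pid, "_events.tsv"))),
         electrodes = readElectrodes(
           file.path(dir, paste0(pid, "_electrodes.tsv"))))
  })
  names(patients) <- ids
  list(lexicon = lex, patients = patients)
}
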