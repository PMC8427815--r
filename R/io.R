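# Dataset directory layout (schema "fractaleeg-epochs/1"):
#   <dir>/metadata.json          rate, duration, montage, groups, tasks,
#                                trial/sample counts, provenance
#   <dir>/participant_<id>.bin   raw little-endian doubles of that
#                                participant's (trial, task, channel, sample)
#                                array in column-major order
# Binary doubles round-trip bit-exactly, which a text rendering would not.

DATASET_SCHEMA <- "fractaleeg-epochs/1"

#' Write an epochs dataset to a directory
#'
#' @param dataset an [EpochsDataset-class].
#' @param path directory to create (must not already contain a dataset
#'   unless `overwrite = TRUE`).
#' @param overwrite replace an existing directory.
#' @return `path`, invisibly.
#' @seealso [readDataset()]
#' @export
writeDataset <- function(dataset, path, overwrite = FALSE) {
  stopifnot(is(dataset, "EpochsDataset"))
  if (dir.exists(path) && length(dir(path)) && !overwrite)
    stop(sprintf("'%s' exists and is not empty; use overwrite = TRUE", path),
         call. = FALSE)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  d <- dataset@data
  dn <- dimnames(d)
  meta <- list(schema = DATASET_SCHEMA,
               samplingRate = dataset@samplingRate,
               participants = dn[[1]], trials = dn[[2]], tasks = dn[[3]],
               montage = list(labels = dataset@montage@labels,
                              x = unname(dataset@montage@positions[, 1]),
                              y = unname(dataset@montage@positions[, 2])),
               groupOf = as.list(dataset@groupOf[dn[[1]]]),
               nSamples = dim(d)[5],
               endianness = "little",
               provenance = dataset@provenance)
  jsonlite::write_json(meta, file.path(path, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  for (p in dn[[1]]) {
    con <- file(file.path(path, sprintf("participant_%s.bin", p)), "wb")
    writeBin(as.vector(d[p, , , , ]), con, size = 8L, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read an epochs dataset from a directory
#'
#' Reads the layout written by [writeDataset()]; the round trip reproduces
#' the dataset bit-exactly. Malformed metadata produces an error naming the
#' offending field.
#'
#' @param path dataset directory.
#' @return an [EpochsDataset-class].
#' @export
readDataset <- function(path) {
  mf <- file.path(path, "metadata.json")
  if (!file.exists(mf))
    stop(sprintf("no metadata.json under '%s'", path), call. = FALSE)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  for (field in c("schema", "samplingRate", "participants", "trials",
                  "tasks", "montage", "groupOf", "nSamples"))
    if (is.null(meta[[field]]))
      stop(sprintf("dataset metadata is missing field '%s'", field),
           call. = FALSE)
  if (!identical(meta$schema, DATASET_SCHEMA))
    stop(sprintf("unsupported dataset schema '%s' (field 'schema')",
                 meta$schema), call. = FALSE)
  m <- meta$montage
  if (is.null(m$labels) || is.null(m$x) || is.null(m$y))
    stop("dataset metadata field 'montage' must contain labels, x, y",
         call. = FALSE)
  montage <- ChannelMontage(m$labels, cbind(m$x, m$y))
  groupOf <- unlist(meta$groupOf)
  missing <- setdiff(meta$participants, names(groupOf))
  if (length(missing))
    stop(sprintf("dataset metadata field 'groupOf' lacks participant(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  nP <- length(meta$participants); nT <- length(meta$trials)
  nTask <- length(meta$tasks); nC <- length(m$labels); nS <- meta$nSamples
  data <- array(NA_real_, dim = c(nP, nT, nTask, nC, nS),
                dimnames = list(meta$participants, meta$trials, meta$tasks,
                                m$labels, NULL))
  per <- nT * nTask * nC * nS
  for (p in meta$participants) {
    f <- file.path(path, sprintf("participant_%s.bin", p))
    if (!file.exists(f))
      stop(sprintf("missing data file for participant '%s'", p),
           call. = FALSE)
    con <- file(f, "rb")
    v <- readBin(con, "double", n = per + 1L, size = 8L, endian = "little")
    close(con)
    if (length(v) != per)
      stop(sprintf("data file for participant '%s' has %d values, expected %d",
                   p, length(v), per), call. = FALSE)
    data[p, , , , ] <- v
  }
  prov <- meta$provenance
  if (is.null(prov) || !length(prov)) prov <- list(kind = "import")
  prov <- as.list(prov)
  new("EpochsDataset", data = data, samplingRate = as.numeric(meta$samplingRate),
      montage = montage, groupOf = groupOf, provenance = prov)
}

## ---------------------------------------------------------------------------
## EDF import
## ---------------------------------------------------------------------------

# Minimal reader for continuous European Data Format (EDF) files: the
# 256-byte ASCII header, the per-signal header block, and 16-bit
# little-endian samples rescaled to physical units.
readEdfRaw <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- rawToChar(readBin(con, "raw", 256L))
  fld <- function(from, len) trimws(substr(hdr, from, from + len - 1L))
  nHeader <- as.integer(fld(185, 8))
  nRecords <- as.integer(fld(237, 8))
  recDur <- as.numeric(fld(245, 8))
  ns <- as.integer(fld(253, 4))
  if (is.na(ns) || ns < 1L)
    stop("not a valid EDF file: bad signal count", call. = FALSE)
  sig <- rawToChar(readBin(con, "raw", 256L * ns))
  block <- function(offset, len)
    vapply(seq_len(ns), function(i)
      trimws(substr(sig, offset * ns + (i - 1L) * len + 1L,
                    offset * ns + i * len)), character(1))
  labels <- block(0L, 16L)
  physMin <- as.numeric(block(16L + 80L + 8L, 8L))
  physMax <- as.numeric(block(16L + 80L + 8L + 8L, 8L))
  digMin <- as.numeric(block(16L + 80L + 8L + 16L, 8L))
  digMax <- as.numeric(block(16L + 80L + 8L + 24L, 8L))
  spr <- as.integer(block(16L + 80L + 8L + 32L + 80L, 8L))
  # header may be padded; skip to the data section
  seek(con, nHeader)
  perRec <- sum(spr)
  raw <- readBin(con, "integer", n = perRec * nRecords, size = 2L,
                 endian = "little")
  signals <- vector("list", ns)
  for (i in seq_len(ns)) signals[[i]] <- numeric(spr[i] * nRecords)
  offs <- c(0L, cumsum(spr))
  for (r in seq_len(nRecords)) {
    base <- (r - 1L) * perRec
    for (i in seq_len(ns)) {
      seg <- raw[(base + offs[i] + 1L):(base + offs[i + 1L])]
      signals[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <- seg
    }
  }
  gain <- (physMax - physMin) / (digMax - digMin)
  for (i in seq_len(ns))
    signals[[i]] <- (signals[[i]] - digMin[i]) * gain[i] + physMin[i]
  names(signals) <- labels
  list(labels = labels, samplingRate = spr / recDur, signals = signals,
       nRecords = nRecords, recordDuration = recDur)
}

#' Import EDF recordings as an epochs dataset
#'
#' Reads one continuous EDF (European Data Format) file per participant,
#' optionally keeps a subset of channels, and chops each recording into
#' consecutive non-overlapping trials of `trialDuration` seconds under a
#' single task label. The sampling rate is taken from the EDF header and
#' must agree across files and selected channels.
#'
#' @param paths character vector of EDF file paths, one per participant.
#' @param groups character vector of group labels, one per file.
#' @param channels channels to keep (default: all channels of the first
#'   file).
#' @param trialDuration trial length in seconds.
#' @param task task label for the imported trials.
#' @param montage optional [ChannelMontage-class] supplying positions; by
#'   default channels are placed on an inner circle.
#' @return an [EpochsDataset-class].
#' @export
importEdf <- function(paths, groups, channels = NULL, trialDuration = 5,
                      task = "MI", montage = NULL) {
  stopifnot(length(paths) == length(groups), length(paths) >= 1L)
  recs <- lapply(paths, readEdfRaw)
  if (is.null(channels)) channels <- recs[[1]]$labels
  for (i in seq_along(recs)) {
    bad <- setdiff(channels, recs[[i]]$labels)
    if (length(bad))
      stop(sprintf("EDF file '%s' lacks channel(s): %s", paths[i],
                   paste(bad, collapse = ", ")), call. = FALSE)
  }
  rate <- unique(unlist(lapply(recs, function(r)
    r$samplingRate[match(channels, r$labels)])))
  if (length(rate) != 1L)
    stop("selected channels must share a single sampling rate", call. = FALSE)
  nS <- as.integer(round(rate * trialDuration))
  nTrial <- min(vapply(recs, function(r)
    length(r$signals[[match(channels[1], r$labels)]]) %/% nS, integer(1)))
  if (nTrial < 1L)
    stop("recordings are shorter than one trial", call. = FALSE)
  pid <- sprintf("p%02d", seq_along(paths))
  data <- array(NA_real_, dim = c(length(paths), nTrial, 1L,
                                  length(channels), nS),
                dimnames = list(pid, sprintf("t%02d", seq_len(nTrial)), task,
                                channels, NULL))
  for (i in seq_along(recs)) {
    for (ci in seq_along(channels)) {
      x <- recs[[i]]$signals[[match(channels[ci], recs[[i]]$labels)]]
      data[i, , 1L, ci, ] <- matrix(x[seq_len(nTrial * nS)], nTrial, nS,
                                    byrow = TRUE)
    }
  }
  if (is.null(montage)) montage <- ChannelMontage(channels)
  else montage <- subsetMontage(montage, channels)
  grp <- groups; names(grp) <- pid
  new("EpochsDataset", data = data, samplingRate = rate, montage = montage,
      groupOf = grp,
      provenance = list(kind = "edf-import", files = basename(paths),
                        trialDuration = trialDuration))
}

## ---------------------------------------------------------------------------
## Feature table CSV
## ---------------------------------------------------------------------------

FEATURE_COLUMNS <- c("group", "participant", "trial", "task", "channel",
                     "offset", "hfd")

#' Read or write a feature table as CSV
#'
#' The tidy feature table has the fixed column order `group, participant,
#' trial, task, channel, offset, hfd`.
#'
#' @param features a feature table ([extractFeatures()]).
#' @param path CSV file path.
#' @return `writeFeatureTable()` returns `path` invisibly;
#'   `readFeatureTable()` returns the feature table as a `data.frame`.
#' @export
writeFeatureTable <- function(features, path) {
  stopifnot(all(FEATURE_COLUMNS %in% names(features)))
  data.table::fwrite(features[, FEATURE_COLUMNS], path)
  invisible(path)
}

#' @rdname writeFeatureTable
#' @export
readFeatureTable <- function(path) {
  df <- as.data.frame(data.table::fread(path))
  missing <- setdiff(FEATURE_COLUMNS, names(df))
  if (length(missing))
    stop(sprintf("feature table lacks column(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  df[, FEATURE_COLUMNS]
}
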