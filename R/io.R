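## On-disk formats: streams as CSV + JSON sidecar, feature windows as a
## dense matrix file + JSON header, model checkpoints as JSON. All
## formats are plain text and round-trip losslessly (including missing
## masks), which the tests assert.

#' Write a stream as CSV plus JSON sidecar
#'
#' The CSV has header \code{t,<channel>,...} with missing samples as
#' empty fields; the sidecar (same path with extension
#' \code{.meta.json}) carries placements, units, nominal rate, labels,
#' intensity and interference provenance.
#'
#' @param stream a \linkS4class{SensorStream}
#' @param path CSV path (sidecar path derived from it)
#' @return \code{path}, invisibly
#' @export
writeStream <- function(stream, path) {
  sig <- signalMatrix(stream)
  mis <- missingMask(stream)
  df <- as.data.frame(t(sig))
  names(df) <- channelNames(stream)
  for (j in seq_along(df)) df[[j]][mis[j, ]] <- NA
  df <- cbind(t = streamTimes(stream), df)
  utils::write.csv(df, path, row.names = FALSE, na = "")
  md <- metadata(stream)
  side <- list(
    placement = placements(stream),
    unit = as.character(rowData(stream)$unit),
    nominal_rate = nominalRate(stream),
    label = sampleLabels(stream),
    intensity = colData(stream)$intensity,
    interference = md$interference,
    seed = md$seed)
  jsonlite::write_json(side[!vapply(side, is.null, TRUE)],
                       sub("\\.csv$", ".meta.json", path),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read a stream written by \code{\link{writeStream}}
#'
#' Malformed headers (no \code{t} column, no channels) and
#' locale-comma decimal fields are rejected with a line-numbered
#' diagnostic.
#'
#' @param path CSV path
#' @return a \linkS4class{SensorStream}
#' @export
readStream <- function(path) {
  lines <- readLines(path, n = -1L)
  .stopIfNot(length(lines) >= 2, "stream file has no data rows")
  hdr <- strsplit(gsub("\"", "", lines[1]), ",")[[1]]
  .stopIfNot(identical(hdr[1], "t"),
             "malformed header at line 1: first column must be 't'")
  .stopIfNot(length(hdr) >= 2,
             "malformed header at line 1: no channel columns")
  body <- lines[-1]
  commaDec <- grep("\"[0-9]+,[0-9]+\"", body)
  .stopIfNot(length(commaDec) == 0,
             "locale-comma decimal field at line ", commaDec[1] + 1,
             ": use '.' as the decimal separator")
  df <- utils::read.csv(path, na.strings = "")
  for (j in seq_along(df))
    .stopIfNot(is.numeric(df[[j]]),
               "non-numeric values in column '", names(df)[j],
               "' (first bad row: line ",
               which(is.na(suppressWarnings(
                 as.numeric(as.character(df[[j]])))) & !is.na(df[[j]]))[1]
               + 1, ")")
  side <- jsonlite::read_json(sub("\\.csv$", ".meta.json", path),
                              simplifyVector = TRUE)
  sig <- t(as.matrix(df[-1]))
  rownames(sig) <- hdr[-1]
  mis <- is.na(sig)
  sig2 <- sig; sig2[mis] <- NA_real_
  SensorStream(sig2, time = df$t, placement = side$placement,
               unit = side$unit, nominal_rate = side$nominal_rate,
               label = side$label, intensity = side$intensity,
               missing = mis,
               metadata = list(interference = side$interference,
                               seed = side$seed))
}

#' Write feature windows as a dense matrix file with a JSON header
#'
#' The matrix file stacks the N windows row-wise ((N*T) x D, CSV); the
#' JSON header records T, D, N, channel names, labels, subjects, start
#' times, rate and normalisation statistics.
#'
#' @param fw a \linkS4class{FeatureWindows}
#' @param path CSV path (header path derived)
#' @return \code{path}, invisibly
#' @export
writeFeatures <- function(fw, path) {
  d <- dim(fw@windows)
  ## rows ordered window-major: window 1 rows 1..T, window 2 ...
  flat <- matrix(0, d[1] * d[3], d[2])
  for (i in seq_len(d[3]))
    flat[(i - 1) * d[1] + seq_len(d[1]), ] <- fw@windows[, , i]
  utils::write.table(flat, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  hdr <- list(T = d[1], D = d[2], N = d[3],
              channels = fw@channels,
              labels = as.character(fw@labels),
              label_levels = levels(fw@labels),
              subject = fw@subject, start_time = fw@startTime,
              rate = fw@rate, norm_center = fw@normCenter,
              norm_scale = fw@normScale)
  jsonlite::write_json(hdr, sub("\\.csv$", ".meta.json", path),
                       auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read feature windows written by \code{\link{writeFeatures}}
#'
#' @param path CSV path
#' @return a \linkS4class{FeatureWindows}
#' @export
readFeatures <- function(path) {
  hdr <- jsonlite::read_json(sub("\\.csv$", ".meta.json", path),
                             simplifyVector = TRUE)
  flat <- as.matrix(utils::read.table(path, sep = ","))
  .stopIfNot(nrow(flat) == hdr$T * hdr$N && ncol(flat) == hdr$D,
             "matrix shape does not match the JSON header")
  arr <- array(0, dim = c(hdr$T, hdr$D, hdr$N))
  for (i in seq_len(hdr$N))
    arr[, , i] <- flat[(i - 1) * hdr$T + seq_len(hdr$T), ]
  new("FeatureWindows", windows = arr,
      labels = factor(hdr$labels, levels = hdr$label_levels),
      subject = hdr$subject, startTime = hdr$start_time,
      channels = hdr$channels, rate = hdr$rate,
      normCenter = as.numeric(hdr$norm_center),
      normScale = as.numeric(hdr$norm_scale))
}

#' Write a model checkpoint (JSON: config + flattened weights)
#'
#' @param model a \linkS4class{HarModel}
#' @param path JSON path
#' @return \code{path}, invisibly
#' @export
writeCheckpoint <- function(model, path) {
  p <- modelParams(model)
  shape <- list(embDims = vapply(p$emb, function(e) nrow(e$W), 0))
  jsonlite::write_json(list(
    config = modelConfig(model),
    classes = model@classes,
    trained = model@trained,
    nodes = graphNodes(model@graph),
    adjacency = adjacency(model@graph),
    emb_dims = shape$embDims,
    params = .flattenParams(p)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a model checkpoint
#'
#' @param path JSON path written by \code{\link{writeCheckpoint}}
#' @return a \linkS4class{HarModel}
#' @export
readCheckpoint <- function(path) {
  ck <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- ck$config
  graph <- skeletonGraph(ck$nodes, as.matrix(ck$adjacency))
  embDims <- as.list(as.numeric(ck$emb_dims))
  names(embDims) <- ck$nodes            # JSON arrays drop names
  template <- .initHarParams(cfg, embDims, length(ck$classes))
  p <- .unflattenParams(template, as.numeric(ck$params))
  new("HarModel", config = cfg, params = p, graph = graph,
      classes = ck$classes, trained = isTRUE(ck$trained),
      log = data.frame())
}

#' Write an evaluation report as JSON plus a confusion-matrix CSV
#'
#' @param report an \linkS4class{EvalReport}
#' @param path JSON path (confusion CSV path derived)
#' @return \code{path}, invisibly
#' @export
writeEvalReport <- function(report, path) {
  jsonlite::write_json(list(
    accuracy = overallAccuracy(report),
    per_class = perClassMetrics(report)),
    path, auto_unbox = TRUE, digits = NA)
  utils::write.csv(confusionMatrix(report),
                   sub("\\.json$", "_confusion.csv", path))
  invisible(path)
}
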