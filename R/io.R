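## Plain-text interchange for traces: trace CSV (time_s,o2_uM), events CSV
## (time_s,label), metadata JSON.

#' Read a respirometry trace from CSV files
#'
#' @param traceFile CSV with header `time_s,o2_uM`.
#' @param eventsFile CSV with header `time_s,label`.
#' @param metadata either a JSON file path or a list, providing
#'   `sample_id`, `group`, `replicate_id`, `chamber_volume_ml`, `amount`,
#'   `amount_units`.
#' @return a validated [RespirometryTrace-class].
#' @seealso [writeTrace()]
#' @export
parseTrace <- function(traceFile, eventsFile, metadata) {
  tr <- utils::read.csv(traceFile)
  if (!all(c("time_s", "o2_uM") %in% names(tr)))
    stop("trace file must have columns time_s, o2_uM")
  ev <- utils::read.csv(eventsFile,
                        colClasses = c(time_s = "numeric", label = "character"))
  if (!all(c("time_s", "label") %in% names(ev)))
    stop("events file must have columns time_s, label")
  bad <- which(!(ev$label %in% eventVocabulary()))
  if (length(bad))
    stop(sprintf("unknown event label '%s' at events row %d",
                 ev$label[bad[1L]], bad[1L]))
  if (anyDuplicated(tr$time_s))
    stop("duplicate time stamps in trace file")
  if (is.character(metadata)) metadata <- jsonlite::read_json(metadata)
  need <- c("sample_id", "group", "replicate_id", "chamber_volume_ml",
            "amount", "amount_units")
  miss <- setdiff(need, names(metadata))
  if (length(miss))
    stop("missing metadata field(s): ", paste(miss, collapse = ", "))
  RespirometryTrace(sampleId = metadata$sample_id, group = metadata$group,
                    replicateId = metadata$replicate_id,
                    time = tr$time_s, o2 = tr$o2_uM, events = ev,
                    chamberVolumeMl = metadata$chamber_volume_ml,
                    amount = metadata$amount,
                    amountUnits = metadata$amount_units)
}

#' Write a respirometry trace to CSV files
#'
#' Inverse of [parseTrace()]: `parseTrace(writeTrace(x))` round-trips.
#'
#' @param trace a [RespirometryTrace-class].
#' @param traceFile,eventsFile output CSV paths.
#' @param metadataFile optional JSON output path for the sample metadata.
#' @return invisibly, the metadata list.
#' @export
writeTrace <- function(trace, traceFile, eventsFile, metadataFile = NULL) {
  utils::write.csv(data.frame(time_s = trace@time, o2_uM = trace@o2),
                   traceFile, row.names = FALSE)
  utils::write.csv(trace@events, eventsFile, row.names = FALSE)
  md <- list(sample_id = trace@sampleId, group = trace@group,
             replicate_id = trace@replicateId,
             chamber_volume_ml = trace@chamberVolumeMl,
             amount = trace@amount, amount_units = trace@amountUnits)
  if (!is.null(metadataFile))
    jsonlite::write_json(md, metadataFile, auto_unbox = TRUE, digits = NA)
  invisible(md)
}
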