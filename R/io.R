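#' Read and write recordings as CSV + JSON sidecar
#'
#' A recording is stored as a plain CSV numeric matrix (channels in rows,
#' samples in columns, no header) together with a JSON sidecar
#' `<path>.json` holding `rate`, `channel_labels` and `bad_channels`
#' (1-based indices).
#'
#' @param path CSV file path; the sidecar lives at `paste0(path, ".json")`.
#' @return `read_recording()` returns an [recording()];
#'   `write_recording()` returns `path` invisibly.
#' @export
read_recording <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(path)) stop("no such file: ", path)
  if (!file.exists(sidecar)) stop("missing sidecar: ", sidecar)
  meta <- jsonlite::fromJSON(sidecar)
  x <- as.matrix(utils::read.csv(path, header = FALSE))
  recording(x, rate = meta$rate,
            channel_labels = meta$channel_labels,
            bad_channels = if (length(meta$bad_channels))
              as.integer(meta$bad_channels) else NULL)
}

#' @param rec an [recording()].
#' @rdname read_recording
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "icto_recording"))
  utils::write.table(rec$samples, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- list(rate = rec$rate, channel_labels = rec$channel_labels,
               bad_channels = which(rec$bad_channels))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read and write cohort manifests
#'
#' A cohort manifest is a JSON array of case records with fields `id`,
#' `network` (path to a CSV adjacency, relative to the manifest), `resected`
#' (1-based node indices), `outcome` (`"good"`/`"poor"`) and optionally
#' `planted` and `suggested_sets`.
#'
#' @param path manifest path.
#' @return `read_cohort()` returns a list of [patient_case()] objects.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  recs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  base <- dirname(path)
  lapply(recs, function(r) {
    net <- read_network(file.path(base, r$network), format = "csv-matrix")
    patient_case(
      id = r$id, network = net,
      resected = as.integer(unlist(r$resected)),
      outcome = r$outcome,
      suggested_sets = if (!is.null(r$suggested_sets))
        lapply(r$suggested_sets, function(s) as.integer(unlist(s))),
      planted = if (!is.null(r$planted)) as.integer(unlist(r$planted)))
  })
}

#' @param cases list of [patient_case()] objects.
#' @param dir output directory (created if needed); per-case network CSVs
#'   are written next to the manifest.
#' @rdname read_cohort
#' @export
write_cohort <- function(cases, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  recs <- lapply(cases, function(cs) {
    net_file <- sprintf("%s_network.csv", cs$id)
    write_network(cs$network, file.path(dir, net_file), format = "csv-matrix")
    out <- list(id = cs$id, network = net_file, resected = cs$resected,
                outcome = cs$outcome)
    if (!is.null(cs$planted)) out$planted <- cs$planted
    if (!is.null(cs$suggested_sets)) out$suggested_sets <- cs$suggested_sets
    out
  })
  manifest <- file.path(dir, "manifest.json")
  jsonlite::write_json(recs, manifest, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
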