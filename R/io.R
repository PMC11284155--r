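# Plain-text fixture I/O: recordings as CSV signal + JSON sidecar,
# segmented datasets as one CSV per clip plus a manifest, feature matrices
# and model specs as CSV/JSON.

#' Write / read a recording fixture
#'
#' The fixture format is a CSV of the signal (one row per channel) next to
#' a JSON sidecar holding the sampling rate, channel names and seizure
#' annotations -- a portable stand-in for EDF suited to version-controlled
#' test data.
#'
#' @param recording a `recording`.
#' @param path basename; writes `<path>.csv` and `<path>.json`.
#' @return `write_recording`: the path, invisibly. `read_recording`: the
#'   `recording`.
#' @export
write_recording <- function(recording, path) {
  utils::write.table(recording$signal, paste0(path, ".csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(
    fs = recording$fs, channel_names = recording$channel_names,
    start_time = recording$start_time,
    seizure_onsets = recording$seizure_onsets
  ), paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @param path basename used at write time.
#' @export
read_recording <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sig <- as.matrix(utils::read.table(paste0(path, ".csv"), sep = ","))
  dimnames(sig) <- NULL
  new_recording(sig, meta$fs, channel_names = meta$channel_names,
                seizure_onsets = as.numeric(meta$seizure_onsets %||% numeric(0)),
                start_time = meta$start_time %||% 0)
}

#' Write / read a segmented dataset
#'
#' One CSV per clip (rows = channels) plus `manifest.csv` (clip id, label,
#' seizure/block group) and `meta.json` (`fs`, `segment_duration`) --
#' mirroring the layout of competition-style segment distributions.
#'
#' @param dataset a `segmented_dataset`.
#' @param dir output directory (created if needed).
#' @return `write_segments`: `dir`, invisibly; `read_segments`: the
#'   `segmented_dataset`.
#' @export
write_segments <- function(dataset, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  man <- data.frame(
    clip = sprintf("clip_%04d.csv", seq_along(dataset$segments)),
    label = vapply(dataset$segments, `[[`, "", "label"),
    group_id = vapply(dataset$segments, `[[`, 0, "group_id")
  )
  for (i in seq_along(dataset$segments)) {
    utils::write.table(dataset$segments[[i]]$data,
                       file.path(dir, man$clip[i]),
                       sep = ",", row.names = FALSE, col.names = FALSE)
  }
  utils::write.csv(man, file.path(dir, "manifest.csv"), row.names = FALSE)
  jsonlite::write_json(list(fs = dataset$fs,
                            segment_duration = dataset$segment_duration),
                       file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' @rdname write_segments
#' @export
read_segments <- function(dir) {
  man <- utils::read.csv(file.path(dir, "manifest.csv"),
                         stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  segs <- lapply(seq_len(nrow(man)), function(i) {
    d <- as.matrix(utils::read.table(file.path(dir, man$clip[i]), sep = ","))
    dimnames(d) <- NULL
    list(data = d, label = man$label[i], group_id = man$group_id[i])
  })
  structure(list(segments = segs, fs = meta$fs,
                 segment_duration = meta$segment_duration),
            class = "segmented_dataset")
}

#' Write a feature matrix to CSV with a JSON registry manifest
#'
#' @param fm a `feature_matrix`.
#' @param path basename; writes `<path>.csv` (windows x features, header =
#'   channel-qualified names, window keys as leading columns) and
#'   `<path>.json` (the registry).
#' @return the path, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  out <- cbind(fm$keys, as.data.frame(fm$values))
  utils::write.csv(out, paste0(path, ".csv"), row.names = FALSE)
  jsonlite::write_json(fm$registry, paste0(path, ".json"), digits = NA)
  invisible(path)
}

#' Serialize a trained model to JSON
#'
#' @param model a `seizure_model`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_model <- function(model, path) {
  jsonlite::write_json(list(
    coefficients = as.list(model$coefficients),
    selected_names = model$selected_names,
    selected = model$selected,
    sop_star = model$sop_star, k_star = model$k_star,
    normalization = list(center = model$normalization$center,
                         scale = model$normalization$scale,
                         zero_variance = model$normalization$zero_variance),
    class_weights = model$class_weights
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
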