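# Plain-text session container: a directory holding the activity
# matrix, cell types, trial table and JSON metadata. Chosen over a
# binary array container so sessions remain diffable and portable.

#' Write a session to a directory container
#'
#' Writes `activity.csv` (neurons x frames), `cell_types.csv`,
#' `trials.csv`, `metadata.json` (frame rate), and, when present,
#' `ground_truth.csv`.
#'
#' @param x a [PPCExperiment-class].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
writeSession <- function(x, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.csv(activity(x), file.path(dir, "activity.csv"))
  write.csv(data.frame(neuron = rownames(x),
                       cell_type = as.character(cellTypes(x))),
            file.path(dir, "cell_types.csv"), row.names = FALSE)
  write.csv(as.data.frame(trials(x)), file.path(dir, "trials.csv"),
            row.names = FALSE)
  jsonlite::write_json(list(frame_rate = frameRate(x),
                            n_neurons = nrow(x), n_frames = ncol(x)),
                       file.path(dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA)
  gt <- groundTruth(x)
  if (!is.null(gt))
    write.csv(as.data.frame(gt), file.path(dir, "ground_truth.csv"),
              row.names = FALSE)
  invisible(dir)
}

#' Read a session from a directory container
#'
#' @param dir directory written by [writeSession()].
#' @return a [PPCExperiment-class].
#' @export
readSession <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "metadata.json"),
                              simplifyVector = TRUE)
  act <- as.matrix(read.csv(file.path(dir, "activity.csv"),
                            row.names = 1, check.names = FALSE))
  colnames(act) <- NULL
  ct <- read.csv(file.path(dir, "cell_types.csv"))
  tr <- read.csv(file.path(dir, "trials.csv"))
  md <- list()
  gtPath <- file.path(dir, "ground_truth.csv")
  if (file.exists(gtPath)) {
    gt <- read.csv(gtPath)
    gt$class <- factor(gt$class,
                       levels = c("Sound", "Photostim",
                                  "Sound&Photostim", "Unmodulated"))
    md$ground_truth <- as(gt, "DFrame")
  }
  PPCExperiment(act, ct$cell_type, tr, frameRate = meta$frame_rate,
                metadata = md)
}
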