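# Plain-text persistence: TSV matrices with JSON sidecars carrying the
# metadata (coordinates, rates, ground truth). One directory per record,
# mirroring the logical layout /lfp/{data,coords_mm,fs}, /calcium/{...}.

write_matrix_tsv <- function(m, path) {
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
}

read_matrix_tsv <- function(path) {
  as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
}

#' Write / read a grid LFP record
#'
#' @param lfp A [grid_lfp()].
#' @param dir Output directory (created).
#' @return `dir`, invisibly; `read_grid_lfp()` returns the record.
#' @export
write_grid_lfp <- function(lfp, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(lfp$data, file.path(dir, "lfp_data.tsv"))
  meta <- list(fs = lfp$fs, t0 = lfp$t0, coords_mm = lfp$coords)
  gt <- attr(lfp, "ground_truth")
  if (!is.null(gt)) meta$ground_truth <- gt
  jsonlite::write_json(meta, file.path(dir, "lfp_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_grid_lfp
#' @export
read_grid_lfp <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "lfp_meta.json"),
                              simplifyVector = TRUE)
  out <- grid_lfp(read_matrix_tsv(file.path(dir, "lfp_data.tsv")),
                  as.matrix(meta$coords_mm), meta$fs, meta$t0)
  if (!is.null(meta$ground_truth))
    attr(out, "ground_truth") <- meta$ground_truth
  out
}

#' Write a wave-event table as TSV
#'
#' @param waves Wave-event data.frame from [detect_waves()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_wave_table <- function(waves, path) {
  utils::write.table(waves, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write / read a calcium raster
#'
#' @param raster A [calcium_raster()].
#' @param dir Output directory.
#' @return `dir`, invisibly; the reader returns the record.
#' @export
write_calcium_raster <- function(raster, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(raster$dff, file.path(dir, "calcium_dff.tsv"))
  write_matrix_tsv(raster$deconv, file.path(dir, "calcium_deconv.tsv"))
  meta <- list(frame_rate = raster$frame_rate, centroids = raster$centroids)
  gt <- attr(raster, "ground_truth")
  if (!is.null(gt)) meta$ground_truth <- gt
  jsonlite::write_json(meta, file.path(dir, "calcium_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_calcium_raster
#' @export
read_calcium_raster <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "calcium_meta.json"),
                              simplifyVector = TRUE)
  out <- calcium_raster(read_matrix_tsv(file.path(dir, "calcium_dff.tsv")),
                        read_matrix_tsv(file.path(dir, "calcium_deconv.tsv")),
                        as.matrix(meta$centroids), meta$frame_rate)
  if (!is.null(meta$ground_truth))
    attr(out, "ground_truth") <- meta$ground_truth
  out
}

#' Write a pose table as TSV
#'
#' @param pose Pose data.frame (`frame`, `label`, `x_px`, `y_px`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_pose_table <- function(pose, path) {
  utils::write.table(pose, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
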