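# Plain-text readers and writers.
#
# Rasters (masks, parameter maps) travel as headerless CSV matrices,
# signal stacks as long-format CSV, acquisition protocols and run configs
# as YAML, reports as JSON. No binary formats.

#' Write / read a numeric matrix as headerless CSV
#'
#' @param m numeric or logical matrix (logical is stored as 0/1).
#' @param path file path.
#' @return `read_matrix_csv` returns a numeric matrix.
#' @export
write_matrix_csv <- function(m, path) {
  if (is.logical(m)) m <- m * 1L
  utils::write.table(m, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_csv
#' @export
read_matrix_csv <- function(path) {
  as.matrix(utils::read.csv(path, header = FALSE))
}

#' Write a signal stack as long-format CSV
#'
#' Columns `row`, `col` (0-based pixel indices), `index` (acquisition
#' point, 1-based), `time_ms`, `value`.
#'
#' @param stack a `signal_stack`.
#' @param path file path.
#' @export
write_stack_csv <- function(stack, path) {
  stopifnot(inherits(stack, "signal_stack"))
  d <- dim(stack$signal)
  df <- data.frame(
    row = rep(rep(0:(d[1] - 1), d[2]), d[3]),
    col = rep(rep(0:(d[2] - 1), each = d[1]), d[3]),
    index = rep(seq_len(d[3]), each = d[1] * d[2]),
    time_ms = rep(stack$times, each = d[1] * d[2]),
    value = as.vector(stack$signal))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write / read an acquisition protocol as YAML
#'
#' @param protocol an `acquisition_protocol`.
#' @param path file path.
#' @export
write_protocol_yaml <- function(protocol, path) {
  stopifnot(inherits(protocol, "acquisition_protocol"))
  yaml::write_yaml(list(kind = protocol$kind,
                        times_ms = protocol$times,
                        tr_ms = protocol$tr_ms), path)
  invisible(path)
}

#' @rdname write_protocol_yaml
#' @export
read_protocol_yaml <- function(path) {
  p <- yaml::read_yaml(path)
  acquisition_protocol(p$kind, p$times_ms, tr_ms = p$tr_ms)
}

#' Per-pixel label table
#'
#' Combines depth, zone and region labels into a tidy per-pixel table with
#' 0-based coordinates (`x` = column, `y` = row).
#'
#' @param depth a `depth_field`.
#' @param zones a `zone_labels`.
#' @param regions a `region_labels`.
#' @return data.frame with columns `x`, `y`, `z_depth`, `zone`, `region`.
#' @export
pixel_table <- function(depth, zones, regions) {
  msk <- depth$mask
  idx <- which(msk, arr.ind = TRUE)
  ord <- order(idx[, 2], idx[, 1])
  idx <- idx[ord, , drop = FALSE]
  data.frame(x = idx[, 2] - 1L, y = idx[, 1] - 1L,
             z_depth = depth$z[msk][ord],
             zone = zones$labels[msk][ord],
             region = regions$labels[msk][ord],
             stringsAsFactors = FALSE)
}
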