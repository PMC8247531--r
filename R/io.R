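#' Write / read a gridded daily surface as long-format CSV
#'
#' Plain-text interchange for exposure surfaces: one row per cell-day with
#' columns \code{day, x, y, mean, variance}.
#'
#' @param x an \code{\link{exposure_surface}}.
#' @param path output CSV path.
#' @return \code{write_surface_csv} returns \code{path} invisibly;
#'   \code{read_surface_csv} returns an \code{exposure_surface}.
#' @export
write_surface_csv <- function(x, path) {
  stopifnot(inherits(x, "exposure_surface"))
  d <- dim(x$mean)
  grid <- expand.grid(y = seq_len(d[1]), x = seq_len(d[2]),
                      day = seq_len(d[3]))
  df <- data.frame(day = grid$day, x = grid$x, y = grid$y,
                   mean = as.vector(x$mean),
                   variance = as.vector(x$variance))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_surface_csv
#' @param method,cell_size metadata for the reconstructed surface.
#' @export
read_surface_csv <- function(path, method = "unknown", cell_size = 1) {
  df <- utils::read.csv(path)
  req <- c("day", "x", "y", "mean", "variance")
  if (!all(req %in% names(df)))
    stop("surface CSV needs columns: ", paste(req, collapse = ", "))
  ny <- max(df$y); nx <- max(df$x); nd <- max(df$day)
  if (nrow(df) != ny * nx * nd)
    stop("surface CSV is not a complete grid")
  o <- order(df$day, df$x, df$y)
  exposure_surface(array(df$mean[o], c(ny, nx, nd)),
                   array(df$variance[o], c(ny, nx, nd)),
                   method = method, cell_size = cell_size)
}
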