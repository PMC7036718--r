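# Plain-text serialization: trajectories as delimited text with a JSON
# sidecar (parameters + seed), branches and landscapes as delimited text,
# run configurations as JSON.

#' Write / read a trajectory as delimited text
#'
#' The trajectory is written as a tab-separated table (time column plus
#' one column per state variable, input and response) together with a
#' `<path>.json` sidecar holding the model name, parameters, protocol and
#' seed.
#'
#' @param traj a `ghost_trajectory`.
#' @param path output file path (TSV).
#' @return `read_trajectory()` returns a list `data` (data frame),
#'   `meta` (sidecar contents).
#' @export
write_trajectory <- function(traj, path) {
  write.table(as.data.frame(traj), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  meta <- list(model = traj$model, params = unclass(traj$params),
               protocol = if (!is.null(traj$protocol))
                 unclass(traj$protocol),
               seed = traj$seed)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  list(data = read.table(path, header = TRUE, sep = "\t"),
       meta = jsonlite::read_json(paste0(path, ".json"),
                                  simplifyVector = TRUE))
}

#' Write a continuation branch or fold curve as delimited text
#'
#' @param branch a `ghost_branch` or plain data frame.
#' @param path output file path (TSV).
#' @export
write_branch <- function(branch, path) {
  write.table(as.data.frame(branch), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Write a quasi-potential landscape as delimited grid text
#'
#' Long-format table with one row per grid node: the two coordinates and
#' the interpolated potential.
#'
#' @param land a `ghost_landscape`.
#' @param path output file path (TSV).
#' @export
write_landscape <- function(land, path) {
  df <- expand.grid(x = land$x, y = land$y)
  df$U <- as.vector(land$U)
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
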