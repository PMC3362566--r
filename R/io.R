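# Provenance header lines embedded at the top of every output file:
# effective configuration and code version, as '#'-prefixed comments.
provenance_lines <- function(config = list()) {
  ver <- as.character(utils::packageVersion("npzdcolumn"))
  flat <- unlist(config)
  c(sprintf("# generator: npzdcolumn %s", ver),
    sprintf("# %s: %s", names(flat), as.character(flat)))
}

write_csv_with_header <- function(df, path, config = list()) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(provenance_lines(config), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a column run to CSV files
#'
#' Writes \code{surface.csv} (surface series plus the nitrogen inventory)
#' and \code{fields.csv} (long-format depth-time snapshots of all tracers,
#' theta and PAR) into a directory. Both files carry the effective
#' configuration and package version as comment headers.
#'
#' @param run an \code{npzd_run} from \code{\link{run_column}}
#' @param dir output directory (created if needed)
#' @return the directory, invisibly
#' @export
write_run_csv <- function(run, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cfg <- run$config
  write_csv_with_header(run$surface, file.path(dir, "surface.csv"), cfg)
  f <- run$fields
  nz <- length(f$z_centers); nt <- length(f$time_days)
  long <- data.frame(
    time_days = rep(f$time_days, each = nz),
    z_m = rep(f$z_centers, times = nt),
    N = as.vector(f$N), P = as.vector(f$P), Z = as.vector(f$Z),
    D = as.vector(f$D), Chl = as.vector(f$Chl), theta = as.vector(f$theta),
    PAR = as.vector(f$PAR))
  write_csv_with_header(long, file.path(dir, "fields.csv"), cfg)
  invisible(dir)
}

#' Write a box run to CSV
#'
#' @param box data.frame from \code{\link{run_box}}
#' @param path output CSV path
#' @param config optional configuration list echoed into the header
#' @return the path, invisibly
#' @export
write_box_csv <- function(box, path, config = list()) {
  write_csv_with_header(box, path, config)
  invisible(path)
}
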