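#' Read and write region-by-region matrices as delimited text
#'
#' Tab-delimited with a header row of region labels and one row per
#' region; values are written at 15 significant digits.
#'
#' @param x Numeric matrix with region dimnames.
#' @param path File path.
#' @export
write_matrix_txt <- function(x, path) {
  x <- as.matrix(x)
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("R", seq_len(ncol(x)))
  lines <- c(paste(labels, collapse = "\t"),
             apply(x, 1, function(row)
               paste(format(row, digits = 15), collapse = "\t")))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_matrix_txt
#' @export
read_matrix_txt <- function(path) {
  lines <- readLines(path)
  labels <- strsplit(lines[1], "\t")[[1]]
  m <- do.call(rbind, lapply(lines[-1], function(l)
    as.numeric(strsplit(l, "\t")[[1]])))
  dimnames(m) <- list(labels, labels)
  m
}

#' Read and write subject time series as delimited text
#'
#' Header row of region labels; one row per time point.
#'
#' @param x Numeric matrix, rows = time points.
#' @param path File path.
#' @export
write_timeseries_txt <- function(x, path) {
  x <- as.matrix(x)
  labels <- colnames(x)
  if (is.null(labels)) labels <- paste0("R", seq_len(ncol(x)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(labels, collapse = "\t"), con)
  utils::write.table(format(x, digits = 15), con, sep = "\t",
                     row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_timeseries_txt
#' @export
read_timeseries_txt <- function(path) {
  m <- utils::read.table(path, header = TRUE, sep = "\t",
                         check.names = FALSE)
  as.matrix(m)
}

#' Check structural and functional region labels agree
#'
#' @param C Structural matrix with dimnames.
#' @param labels Region labels of the time series.
#' @export
check_region_labels <- function(C, labels) {
  cl <- colnames(C)
  if (is.null(cl) || is.null(labels)) return(invisible(TRUE))
  if (!identical(cl, labels)) {
    stop("region labels differ between structural connectivity and ",
         "time series: ",
         paste(union(setdiff(cl, labels), setdiff(labels, cl)),
               collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Read a run configuration file
#'
#' YAML file whose keys mirror the arguments of [sim_config()] (plus
#' optional `grid`: `alpha_points`, `beta_points`, `delta`).  Unknown
#' keys are a hard error rather than being silently ignored.
#'
#' @param path Path to the YAML configuration.
#' @return List with elements `sim` (a [sim_config()]) and `grid`
#'   (a [grid_spec()]).
#' @export
read_run_config <- function(path) {
  # YAML 1.1 would otherwise resolve the key "n" (regions) to FALSE
  keep <- function(x) x
  cfg <- yaml::read_yaml(path, handlers = list("bool#yes" = keep,
                                               "bool#no" = keep))
  grid_part <- cfg$grid
  cfg$grid <- NULL
  allowed <- names(formals(sim_config))
  unknown <- setdiff(names(cfg), allowed)
  if (length(unknown) > 0) {
    stop("unknown configuration key(s): ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  gs <- if (is.null(grid_part)) grid_spec() else {
    g_allowed <- names(formals(grid_spec))
    g_unknown <- setdiff(names(grid_part), g_allowed)
    if (length(g_unknown) > 0) {
      stop("unknown grid configuration key(s): ",
           paste(g_unknown, collapse = ", "), call. = FALSE)
    }
    do.call(grid_spec, grid_part)
  }
  list(sim = do.call(sim_config, cfg), grid = gs)
}
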