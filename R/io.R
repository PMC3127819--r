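#' Read and write fluorescence time-course CSV files
#'
#' The on-disk format is a single CSV dialect (comma separator, dot
#' decimal, mandatory header) with columns
#' `network,dox_nM,replicate,time_min,fluorescence`; one row per sample.
#' Lines starting with `#` are provenance comments (seed, generating
#' config) and are ignored on read.  Each (network, dox, replicate) group
#' must form a strictly increasing uniform time grid with finite,
#' nonnegative fluorescence; violations are reported with the offending
#' course named.
#'
#' @param path CSV file path.
#' @return `read_timecourses()`: a list of [time_course] objects, ordered
#'   by network, dose, replicate (input row order is irrelevant).
#' @export
read_timecourses <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("network", "dox_nM", "replicate", "time_min", "fluorescence")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("time-course file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  if (any(!is.finite(df$fluorescence)))
    stop("non-finite fluorescence in ", path, " (row ",
         which(!is.finite(df$fluorescence))[1], " of the data)")
  if (any(df$fluorescence < 0))
    stop("negative fluorescence in ", path, " (row ",
         which(df$fluorescence < 0)[1], " of the data)")
  split_timecourses(df)
}

split_timecourses <- function(df) {
  key <- interaction(df$network, df$dox_nM, df$replicate, drop = TRUE)
  groups <- split(df, key)
  ord <- order(vapply(groups, function(g) g$network[1], character(1)),
               vapply(groups, function(g) g$dox_nM[1], numeric(1)),
               vapply(groups, function(g) g$replicate[1], numeric(1)))
  lapply(groups[ord], function(g) {
    g <- g[order(g$time_min), ]
    tryCatch(
      time_course(g$network[1], g$dox_nM[1], g$replicate[1],
                  g$time_min, g$fluorescence),
      error = function(e)
        stop("invalid course (network=", g$network[1], ", dox=", g$dox_nM[1],
             ", replicate=", g$replicate[1], "): ", conditionMessage(e)))
  })
}

#' @rdname read_timecourses
#' @param tcs list of [time_course] objects (or a `switch_experiment`,
#'   whose courses and provenance are used).
#' @param provenance named list written as `# key: value` comment lines.
#' @export
write_timecourses <- function(tcs, path, provenance = list()) {
  if (inherits(tcs, "switch_experiment")) {
    provenance <- c(list(seed = tcs$seed,
                         dox_levels = paste(tcs$design$dox_levels, collapse = " "),
                         replicates = paste(tcs$design$replicates, collapse = " "),
                         noise_cv = tcs$design$noise_cv),
                    provenance)
    tcs <- tcs$courses
  }
  df <- do.call(rbind, lapply(tcs, as.data.frame))
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(paste0("# ", nm, ": ", provenance[[nm]]), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read/write the per-point replicate variance table
#'
#' Columns `network,dox_nM,time_min,variance`, same CSV dialect as
#' [read_timecourses].
#'
#' @param path CSV file path.
#' @export
read_variance <- function(path) {
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("network", "dox_nM", "time_min", "variance")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("variance file ", path, " lacks column(s): ",
         paste(miss, collapse = ", "))
  df
}

#' @rdname read_variance
#' @param variance data.frame as produced by [generate_experiment].
#' @param provenance named list written as comment lines.
#' @export
write_variance <- function(variance, path, provenance = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(provenance))
    writeLines(paste0("# ", nm, ": ", provenance[[nm]]), con)
  utils::write.csv(variance, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}
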