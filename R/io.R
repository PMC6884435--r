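# Readers and writers for the four tabular artifacts.  All files are plain
# comma-delimited text with fixed headers; times are integer seconds.

check_header <- function(found, expected, what) {
  miss <- setdiff(expected, found)
  if (length(miss)) {
    stop(sprintf("format error in %s: missing column '%s'", what, miss[1]))
  }
}

#' Read/write raw RTLS tables (`tagID,tagRole,time,zID`)
#'
#' @param x data.frame of raw records.
#' @param path file path.
#' @return `read_raw_rtls` returns the data.frame; writers return the path
#'   invisibly.
#' @export
write_raw_rtls <- function(x, path) {
  write.csv(x[, c("tagID", "tagRole", "time", "zID")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_raw_rtls
#' @export
read_raw_rtls <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  check_header(names(x), c("tagID", "tagRole", "time", "zID"), "raw RTLS table")
  x$time <- as.integer(x$time)
  x$zID <- as.integer(x$zID)
  x
}

#' Read/write period tables (`tagID,st,et,zID,tagRole`)
#'
#' @param x period data.frame.
#' @param path file path.
#' @export
write_period_table <- function(x, path) {
  write.csv(x[, c("tagID", "st", "et", "zID", "tagRole")], path,
            row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_period_table
#' @export
read_period_table <- function(path) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  check_header(names(x), c("tagID", "st", "et", "zID", "tagRole"), "period table")
  x$st <- as.integer(x$st)
  x$et <- as.integer(x$et)
  x$zID <- as.integer(x$zID)
  attr(x, "role_scope") <- period_scope(x$tagRole)
  x
}

#' Read/write facing-time tables
#'
#' Layout: first column `nID`, then one `<TYPE>_<binlabel>` column per
#' (patient type, duration bin) in type-major order.
#' @param x a `facing_table`.
#' @param path file path.
#' @export
write_facing_table <- function(x, path) {
  df <- data.frame(nID = x$nurse_ids, x$counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_facing_table
#' @export
read_facing_table <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  check_header(names(df), "nID", "facing table")
  cols <- setdiff(names(df), "nID")
  parts <- regmatches(cols, regexpr("_", cols), invert = TRUE)
  types <- vapply(parts, `[`, "", 1)
  labels <- vapply(parts, `[`, "", 2)
  type_labels <- unique(types)
  bin_labels <- unique(labels)
  nb <- length(bin_labels)
  # recover the boundaries from the labels ("0-10", ..., ">60")
  boundaries <- if (nb >= 2) {
    as.integer(sub(".*-", "", bin_labels[-nb]))
  } else integer(0)
  bins <- time_bins(boundaries)
  counts <- as.matrix(df[, cols, drop = FALSE])
  storage.mode(counts) <- "integer"
  rownames(counts) <- df$nID
  structure(
    list(counts = counts, nurse_ids = df$nID, type_labels = type_labels, bins = bins),
    class = "facing_table"
  )
}

#' Read/write cluster assignments
#'
#' `nID,cluster` rows preceded by a one-line `# converged: <0|1>` flag.
#' @param assignments data.frame with columns `nID`, `cluster`, or a result
#'   from [facing_kmeans()] plus `nurse_ids`.
#' @param converged 0/1 convergence flag.
#' @param path file path.
#' @export
write_clusters <- function(assignments, converged, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# converged: %d", as.integer(converged)), con)
  writeLines("nID,cluster", con)
  writeLines(paste(assignments$nID, assignments$cluster, sep = ","), con)
  invisible(path)
}

#' @rdname write_clusters
#' @export
read_clusters <- function(path) {
  first <- readLines(path, n = 1)
  converged <- as.integer(sub("^# converged: *", "", first))
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  check_header(names(df), c("nID", "cluster"), "cluster table")
  attr(df, "converged") <- converged
  df
}
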