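#' Read a Tucson/.rwl decadal ring-width file
#'
#' Parses the standard decadal layout: series ID in columns 1-8, decade
#' start year in columns 9-12, then up to ten 6-character measurement
#' fields. Values are stored in units of 0.01 mm with the stop marker 999;
#' widths are returned in mm.
#'
#' @param path file path.
#' @return data frame with years as row names and one column per series
#'   (NA outside a series' span), mirroring the layout used by standard
#'   dendro software.
#' @export
read_rwl <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  series <- list()
  for (ln in lines) {
    id <- trimws(substr(ln, 1, 8))
    year <- as.integer(substr(ln, 9, 12))
    rest <- substring(ln, 13)
    nval <- floor(nchar(rest) / 6)
    vals <- vapply(seq_len(nval), function(i) {
      as.numeric(substr(rest, (i - 1) * 6 + 1, i * 6))
    }, numeric(1))
    vals <- vals[!is.na(vals)]
    stop_at <- which(vals == 999)
    if (length(stop_at)) vals <- vals[seq_len(stop_at[1] - 1)]
    if (length(vals) == 0 && !length(stop_at)) next
    if (is.null(series[[id]])) series[[id]] <- list(years = integer(), w = numeric())
    series[[id]]$years <- c(series[[id]]$years, seq(year, length.out = length(vals)))
    series[[id]]$w <- c(series[[id]]$w, vals / 100)
  }
  if (length(series) == 0) stop("no series found in ", path)
  all_years <- range(unlist(lapply(series, `[[`, "years")))
  years <- seq(all_years[1], all_years[2])
  out <- data.frame(row.names = years)
  for (id in names(series)) {
    col <- rep(NA_real_, length(years))
    col[match(series[[id]]$years, years)] <- series[[id]]$w
    out[[id]] <- col
  }
  out
}

#' Write ring-width series to a Tucson/.rwl decadal file
#'
#' @param rwl data frame as returned by [read_rwl()]: years as row names,
#'   one column per series, widths in mm.
#' @param path output file.
#' @param overwrite logical; refuse to clobber an existing file unless TRUE.
#' @return `path`, invisibly.
#' @export
write_rwl <- function(rwl, path, overwrite = FALSE) {
  if (file.exists(path) && !overwrite) stop("file exists: ", path,
                                            " (use overwrite = TRUE)")
  if (ncol(rwl) == 0) stop("no series to write")
  years <- as.integer(rownames(rwl))
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(rwl)) {
    w <- rwl[[id]]
    ok <- which(!is.na(w))
    if (length(ok) == 0) next
    yrs <- years[ok]
    vals <- c(round(w[ok] * 100), 999) # 0.01 mm units + stop marker
    vyrs <- c(yrs, max(yrs) + 1L)
    pos <- 1
    while (pos <= length(vals)) {
      y <- vyrs[pos]
      decade_end <- (y %/% 10) * 10 + 9
      n <- min(decade_end - y + 1, length(vals) - pos + 1)
      chunk <- vals[pos:(pos + n - 1)]
      cat(sprintf("%-8s%4d%s", substr(id, 1, 8), y,
                  paste(sprintf("%6d", chunk), collapse = "")),
          "\n", sep = "", file = con)
      pos <- pos + n
    }
  }
  invisible(path)
}

#' Combine per-stand ring-width tables into one wide table
#'
#' @param rwl_list named list of wide ring-width tables (years x trees).
#' @return single wide data frame on the union of years.
#' @export
combine_rwl <- function(rwl_list) {
  yrs <- range(unlist(lapply(rwl_list, function(x) as.integer(rownames(x)))))
  years <- seq(yrs[1], yrs[2])
  cols <- list()
  for (x in rwl_list) {
    xi <- match(as.integer(rownames(x)), years)
    for (id in names(x)) {
      col <- rep(NA_real_, length(years))
      col[xi] <- x[[id]]
      cols[[id]] <- col
    }
  }
  out <- as.data.frame(cols)
  rownames(out) <- years
  out
}
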