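#' Read a GROMACS index (.ndx) file
#'
#' Groups are introduced by `[ name ]` lines followed by whitespace-separated
#' 1-based atom indices. Indices are returned 1-based (R's native indexing,
#' which coincides with the NDX convention). Duplicate group names are
#' disambiguated deterministically by suffixing `_2`, `_3`, ...
#'
#' @param ndx_path Path to the index file.
#' @param natoms Optional atom count; indices greater than it are an error.
#' @return Named list of integer vectors.
#' @export
read_ndx <- function(ndx_path, natoms = NULL) {
  if (!file.exists(ndx_path)) stop2("index file not found: ", ndx_path)
  lines <- readLines(ndx_path, warn = FALSE)
  lines <- sub(";.*$", "", lines)  # trailing comments
  groups <- list()
  cur <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[\\s*(.+?)\\s*\\]$", ln))[[1]]
    if (length(m) == 2L) {
      cur <- m[[2]]
      nm <- cur
      k <- 2L
      while (nm %in% names(groups)) {
        nm <- paste0(cur, "_", k)
        k <- k + 1L
      }
      cur <- nm
      groups[[cur]] <- integer()
      next
    }
    if (is.null(cur))
      stop2("line ", i, " of '", ndx_path, "' has indices before any [group]")
    toks <- strsplit(ln, "\\s+")[[1]]
    idx <- suppressWarnings(as.integer(toks))
    if (any(is.na(idx)))
      stop2("non-numeric index on line ", i, " of '", ndx_path, "'")
    if (any(idx <= 0L))
      stop2("NDX indices are 1-based and must be positive (line ", i, ")")
    if (!is.null(natoms) && any(idx > natoms))
      stop2("NDX index ", max(idx), " exceeds atom count ", natoms,
            " (line ", i, ")")
    groups[[cur]] <- c(groups[[cur]], idx)
  }
  empty <- names(groups)[lengths(groups) == 0L]
  if (length(empty))
    warning("empty NDX group(s): ", paste(empty, collapse = ", "),
            call. = FALSE)
  groups
}

#' Write a GROMACS index (.ndx) file
#'
#' @param groups Named list of 1-based integer atom indices.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ndx <- function(groups, path) {
  stopifnot(is.list(groups), !is.null(names(groups)))
  con <- file(path, "wb")
  on.exit(close(con))
  for (nm in names(groups)) {
    writeLines(sprintf("[ %s ]", nm), con, sep = "\n")
    idx <- as.integer(groups[[nm]])
    if (any(idx <= 0L)) stop2("group '", nm, "' has non-positive indices")
    if (length(idx)) {
      rows <- split(idx, ceiling(seq_along(idx) / 15))
      writeLines(vapply(rows, paste, character(1), collapse = " "), con,
                 sep = "\n")
    }
  }
  invisible(path)
}
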