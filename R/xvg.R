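#' Write a time series as a Grace .xvg file
#'
#' Comment lines start with `#`, Grace directives with `@` (title, axis
#' labels, one legend entry per data column), followed by whitespace-separated
#' numeric rows: the x column (time or frame) then one column per series.
#' Values are printed with 6 significant digits, so re-parsing reproduces them
#' to that precision; missing values are serialized as `nan`.
#'
#' @param series Data frame whose first column is the x axis and remaining
#'   columns are series. Attributes `title`, `xlabel`, `ylabel` are used when
#'   present and can be overridden by the arguments.
#' @param path Output path.
#' @param title,xlabel,ylabel Plot annotations.
#' @return `path`, invisibly.
#' @export
write_xvg <- function(series, path, title = NULL, xlabel = NULL,
                      ylabel = NULL) {
  series <- as.data.frame(series)
  if (nrow(series) == 0L || ncol(series) < 2L)
    stop2("'series' must have at least one row and one data column")
  title <- title %||% attr(series, "title") %||% "lipidvoro time series"
  xlabel <- xlabel %||% attr(series, "xlabel") %||% names(series)[[1]]
  ylabel <- ylabel %||% attr(series, "ylabel") %||% "value"
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop2("cannot write '", path, "'"))
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n")
  wl("# written by lipidvoro")
  wl(sprintf("@    title \"%s\"", title))
  wl(sprintf("@    xaxis  label \"%s\"", xlabel))
  wl(sprintf("@    yaxis  label \"%s\"", ylabel))
  wl("@TYPE xy")
  for (k in seq_len(ncol(series) - 1L))
    wl(sprintf("@ s%d legend \"%s\"", k - 1L, names(series)[[k + 1L]]))
  num <- vapply(series, function(col) {
    out <- formatC(as.numeric(col), format = "g", digits = 6)
    out[!is.finite(as.numeric(col))] <- "nan"
    format(out, width = 12, justify = "right")
  }, character(nrow(series)))
  if (nrow(series) == 1L) num <- matrix(num, nrow = 1L)
  wl(apply(num, 1, paste, collapse = " "))
  invisible(path)
}

#' Read a .xvg file written by [write_xvg()] (or Grace/GROMACS tools)
#'
#' @param path Path to the file.
#' @return Data frame of the numeric payload; column names are taken from the
#'   legend directives when present. Attributes `title`, `xlabel`, `ylabel`
#'   carry the matching directives.
#' @export
read_xvg <- function(path) {
  if (!file.exists(path)) stop2("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  is_dir <- startsWith(lines, "@")
  is_com <- startsWith(lines, "#")
  data_lines <- lines[!is_dir & !is_com & nzchar(trimws(lines))]
  if (length(data_lines) == 0L) stop2("no numeric payload in '", path, "'")
  rows <- lapply(strsplit(trimws(data_lines), "\\s+"), function(tok)
    suppressWarnings(as.numeric(tok)))
  ncols <- unique(lengths(rows))
  if (length(ncols) != 1L) stop2("ragged rows in '", path, "'")
  df <- as.data.frame(do.call(rbind, rows))
  dirs <- lines[is_dir]
  legend <- regmatches(dirs, regexec("^@\\s*s(\\d+)\\s+legend\\s+\"(.*)\"", dirs))
  nm <- c("x", paste0("s", seq_len(ncols - 1L) - 1L))
  for (m in legend)
    if (length(m) == 3L) nm[as.integer(m[[2]]) + 2L] <- m[[3]]
  names(df) <- nm
  grab <- function(pat) {
    hit <- regmatches(dirs, regexec(pat, dirs))
    for (m in hit) if (length(m) == 2L) return(m[[2]])
    NULL
  }
  attr(df, "title") <- grab("^@\\s*title\\s+\"(.*)\"")
  attr(df, "xlabel") <- grab("^@\\s*xaxis\\s+label\\s+\"(.*)\"")
  attr(df, "ylabel") <- grab("^@\\s*yaxis\\s+label\\s+\"(.*)\"")
  df
}
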