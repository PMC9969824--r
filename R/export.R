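# Per-frame metric exports.
#
# TXT layout (tab-separated, one header line, '#' metadata comments):
#   lipid_id resname resid leaflet apl thickness n_neighbors
#   n_inclusion_neighbors neighbor_profile
# neighbor_profile is "RES:count,RES:count,...". Numeric fields use %.17g so
# the serialized values parse back exactly.
#
# XML schema: a single <frame index=".." time=".." lx=".." ly=".." lz="..">
# element with one <lipid> child per lipid carrying the same fields as
# attributes.

.profile_string <- function(profile) {
  vapply(profile, function(p) {
    if (length(p) == 0L) return("")
    paste(sprintf("%s:%d", names(p), as.integer(p)), collapse = ",")
  }, character(1))
}

.parse_profile <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || !nzchar(x)) return(integer())
    parts <- strsplit(strsplit(x, ",", fixed = TRUE)[[1]], ":", fixed = TRUE)
    setNames(vapply(parts, function(p) as.integer(p[[2]]), integer(1)),
             vapply(parts, `[[`, character(1), 1))
  })
}

.metrics_export_table <- function(metrics) {
  data.frame(lipid_id = metrics$lipid_id,
             resname = metrics$resname,
             resid = metrics$resid,
             leaflet = as.character(metrics$leaflet),
             apl = sprintf("%.17g", metrics$apl),
             thickness = sprintf("%.17g", metrics$thickness),
             n_neighbors = metrics$n_neighbors,
             n_inclusion_neighbors = metrics$n_inclusion_neighbors,
             neighbor_profile = .profile_string(metrics$neighbor_profile),
             stringsAsFactors = FALSE)
}

#' Export one frame's per-lipid metrics
#'
#' @param metrics A `lipid_metrics` data frame from
#'   [compute_frame_metrics()].
#' @param format `"txt"` (tab-separated table) or `"xml"`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @seealso [read_frame_xml()] for the inverse of the XML export.
#' @export
write_frame_export <- function(metrics, format = c("txt", "xml"), path) {
  if (!is.character(format) || length(format) != 1L ||
      !format %in% c("txt", "xml"))
    stop2("'format' must be \"txt\" or \"xml\"")
  tab <- .metrics_export_table(metrics)
  fi <- attr(metrics, "frame_index") %||% NA
  tm <- attr(metrics, "time") %||% NA
  box <- attr(metrics, "box") %||% rep(NA_real_, 3)
  if (format == "txt") {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(c(sprintf("# lipidvoro frame export; frame=%s time_ps=%s box_nm=%s",
                         fi, tm, paste(sprintf("%.17g", box), collapse = ",")),
                 paste(names(tab), collapse = "\t"),
                 do.call(paste, c(unname(tab), sep = "\t"))),
               con, sep = "\n")
  } else {
    doc <- xml2::xml_new_root("frame", index = as.character(fi),
                              time = sprintf("%.17g", as.numeric(tm)),
                              lx = sprintf("%.17g", box[[1]]),
                              ly = sprintf("%.17g", box[[2]]),
                              lz = sprintf("%.17g", box[[3]]))
    for (r in seq_len(nrow(tab))) {
      xml2::xml_add_child(doc, "lipid",
                          id = as.character(tab$lipid_id[[r]]),
                          resname = tab$resname[[r]],
                          resid = as.character(tab$resid[[r]]),
                          leaflet = tab$leaflet[[r]],
                          apl = tab$apl[[r]],
                          thickness = tab$thickness[[r]],
                          neighbors = as.character(tab$n_neighbors[[r]]),
                          inclusion_neighbors =
                            as.character(tab$n_inclusion_neighbors[[r]]),
                          profile = tab$neighbor_profile[[r]])
    }
    xml2::write_xml(doc, path)
  }
  invisible(path)
}

#' Re-read an XML frame export
#'
#' @param path Path written by `write_frame_export(..., format = "xml")`.
#' @return A data frame with the per-lipid fields (numeric values recovered
#'   exactly as serialized) plus `frame_index`, `time` and `box` attributes.
#' @export
read_frame_xml <- function(path) {
  doc <- xml2::read_xml(path)
  kids <- xml2::xml_find_all(doc, "lipid")
  a <- function(nm) xml2::xml_attr(kids, nm)
  df <- data.frame(lipid_id = as.integer(a("id")),
                   resname = a("resname"),
                   resid = as.integer(a("resid")),
                   leaflet = a("leaflet"),
                   apl = as.numeric(a("apl")),
                   thickness = as.numeric(a("thickness")),
                   n_neighbors = as.integer(a("neighbors")),
                   n_inclusion_neighbors = as.integer(a("inclusion_neighbors")),
                   stringsAsFactors = FALSE)
  df$neighbor_profile <- .parse_profile(a("profile"))
  attr(df, "frame_index") <- as.integer(xml2::xml_attr(doc, "index"))
  attr(df, "time") <- as.numeric(xml2::xml_attr(doc, "time"))
  attr(df, "box") <- as.numeric(c(xml2::xml_attr(doc, "lx"),
                                  xml2::xml_attr(doc, "ly"),
                                  xml2::xml_attr(doc, "lz")))
  df
}

#' Re-read a TXT frame export
#' @param path Path written by `write_frame_export(..., format = "txt")`.
#' @return A data frame with the per-lipid fields.
#' @export
read_frame_txt <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                   stringsAsFactors = FALSE,
                   colClasses = c(neighbor_profile = "character"))
  df$neighbor_profile <- .parse_profile(df$neighbor_profile)
  df
}
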