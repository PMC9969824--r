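#' Define a lipid species
#'
#' A lipid definition names the residue, the head "key atom" whose position
#' generates the lipid's tessellation cell (conventionally the phosphate
#' phosphorus, `"P"`), and the terminal tail atoms used to build the
#' head-to-tail orientation vector for orientation-based leaflet detection.
#'
#' @param resname Residue name as it appears in the topology (e.g. `"DPPC"`).
#' @param head_atom Atom name of the key atom. Default `"P"`.
#' @param tail_atoms Character vector of candidate tail (terminal acyl) atom
#'   names. Atoms listed here but absent from a residue are ignored; at least
#'   one must resolve for the orientation-based method to work.
#' @return An object of class `lipid_def`.
#' @examples
#' lipid_def("DPPC", head_atom = "P", tail_atoms = c("C2", "C3"))
#' @export
lipid_def <- function(resname, head_atom = "P", tail_atoms = character()) {
  if (!is.character(resname) || length(resname) != 1L || !nzchar(resname))
    stop2("'resname' must be a single non-empty string")
  if (!is.character(head_atom) || length(head_atom) != 1L || !nzchar(head_atom))
    stop2("'head_atom' must be a single non-empty string")
  tail_atoms <- as.character(tail_atoms)
  if (head_atom %in% tail_atoms)
    stop2("head atom '", head_atom, "' must not be listed among tail atoms")
  structure(list(resname = resname, head_atom = head_atom,
                 tail_atoms = tail_atoms),
            class = "lipid_def")
}

#' @export
print.lipid_def <- function(x, ...) {
  cat(sprintf("<lipid_def> %s  head: %s  tails: %s\n", x$resname, x$head_atom,
              if (length(x$tail_atoms)) paste(x$tail_atoms, collapse = ",")
              else "(none)"))
  invisible(x)
}

#' Built-in lipid definitions
#'
#' Definitions for common phosphoglycerides, all keyed on the phosphate
#' phosphorus `"P"`. Tail candidates cover both the minimal three-atom lipids
#' written by [generate_bilayer()] (`C2`, `C3`) and the terminal acyl carbons
#' of common all-atom naming schemes; names absent from a residue are simply
#' not resolved. Override or extend via a definitions file
#' ([read_lipid_defs()]) when your force field names differ.
#'
#' @return A list of [lipid_def()] objects.
#' @export
default_lipid_defs <- function() {
  tails <- c("C2", "C3", "C214", "C216", "C218", "C314", "C316", "C318",
             "C16A", "C16B")
  resnames <- c("DPPC", "DMPC", "DOPC", "POPC", "DPPE", "POPE", "DOPE",
                "POPG", "DOPG", "POPS", "DOPS", "DSPC", "DLPC")
  lapply(resnames, lipid_def, head_atom = "P", tail_atoms = tails)
}

#' Read lipid definitions from a key-value file
#'
#' One lipid per non-comment line, in the form
#' \preformatted{RESNAME: head=ATOM tails=A1,A2,...}
#' `tails=` may be omitted (orientation-based detection then refuses such
#' lipids). Lines starting with `#` and blank lines are ignored.
#'
#' @param path Path to the definitions file.
#' @return A list of [lipid_def()] objects.
#' @export
read_lipid_defs <- function(path) {
  if (!file.exists(path)) stop2("lipid definitions file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  defs <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[[i]])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    m <- regmatches(ln, regexec(
      "^([A-Za-z0-9_]+)\\s*:\\s*head\\s*=\\s*([A-Za-z0-9']+)(\\s+tails\\s*=\\s*([A-Za-z0-9',]+))?\\s*$",
      ln))[[1]]
    if (length(m) == 0L)
      stop2("cannot parse lipid definition on line ", i, ": '", ln, "'")
    tails <- if (nzchar(m[[5]])) strsplit(m[[5]], ",", fixed = TRUE)[[1]]
             else character()
    defs[[length(defs) + 1L]] <- lipid_def(m[[2]], m[[3]], tails)
  }
  defs
}
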