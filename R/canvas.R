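# Minimal deterministic raster canvas.
#
# Rendering avoids graphics devices entirely: images are RGB arrays filled
# by scanline/Bresenham primitives and written with png::writePNG, so output
# bytes depend only on the input (no fonts, locale or device state). Text
# uses a built-in 5x7 bitmap font (uppercase, digits, basic punctuation).

.new_canvas <- function(width, height, bg = c(1, 1, 1)) {
  arr <- array(0, c(height, width, 3))
  arr[, , 1] <- bg[[1]]; arr[, , 2] <- bg[[2]]; arr[, , 3] <- bg[[3]]
  arr
}

.cv_set <- function(cv, rows, cols, col) {
  h <- dim(cv)[1]; w <- dim(cv)[2]
  ok <- rows >= 1 & rows <= h & cols >= 1 & cols <= w
  rows <- rows[ok]; cols <- cols[ok]
  if (length(rows)) for (ch in 1:3) cv[cbind(rows, cols, ch)] <- col[[ch]]
  cv
}

.cv_rect <- function(cv, r1, c1, r2, c2, col) {
  px <- expand.grid(r = max(1, r1):min(dim(cv)[1], r2),
                    c = max(1, c1):min(dim(cv)[2], c2))
  .cv_set(cv, px$r, px$c, col)
}

# Bresenham-style line by dense parameter sampling (deterministic, simple)
.cv_line <- function(cv, r1, c1, r2, c2, col) {
  n <- max(abs(r2 - r1), abs(c2 - c1), 1) * 2L
  t <- seq(0, 1, length.out = n + 1L)
  .cv_set(cv, round(r1 + t * (r2 - r1)), round(c1 + t * (c2 - c1)), col)
}

.FONT57 <- local({
  raw <- c(
  "0" = "01110 10001 10011 10101 11001 10001 01110",
  "1" = "00100 01100 00100 00100 00100 00100 01110",
  "2" = "01110 10001 00001 00010 00100 01000 11111",
  "3" = "11110 00001 00001 01110 00001 00001 11110",
  "4" = "00010 00110 01010 10010 11111 00010 00010",
  "5" = "11111 10000 11110 00001 00001 10001 01110",
  "6" = "00110 01000 10000 11110 10001 10001 01110",
  "7" = "11111 00001 00010 00100 01000 01000 01000",
  "8" = "01110 10001 10001 01110 10001 10001 01110",
  "9" = "01110 10001 10001 01111 00001 00010 01100",
  "A" = "01110 10001 10001 11111 10001 10001 10001",
  "B" = "11110 10001 10001 11110 10001 10001 11110",
  "C" = "01110 10001 10000 10000 10000 10001 01110",
  "D" = "11110 10001 10001 10001 10001 10001 11110",
  "E" = "11111 10000 10000 11110 10000 10000 11111",
  "F" = "11111 10000 10000 11110 10000 10000 10000",
  "G" = "01110 10001 10000 10111 10001 10001 01111",
  "H" = "10001 10001 10001 11111 10001 10001 10001",
  "I" = "01110 00100 00100 00100 00100 00100 01110",
  "J" = "00111 00010 00010 00010 00010 10010 01100",
  "K" = "10001 10010 10100 11000 10100 10010 10001",
  "L" = "10000 10000 10000 10000 10000 10000 11111",
  "M" = "10001 11011 10101 10101 10001 10001 10001",
  "N" = "10001 11001 10101 10011 10001 10001 10001",
  "O" = "01110 10001 10001 10001 10001 10001 01110",
  "P" = "11110 10001 10001 11110 10000 10000 10000",
  "Q" = "01110 10001 10001 10001 10101 10010 01101",
  "R" = "11110 10001 10001 11110 10100 10010 10001",
  "S" = "01111 10000 10000 01110 00001 00001 11110",
  "T" = "11111 00100 00100 00100 00100 00100 00100",
  "U" = "10001 10001 10001 10001 10001 10001 01110",
  "V" = "10001 10001 10001 10001 10001 01010 00100",
  "W" = "10001 10001 10001 10101 10101 10101 01010",
  "X" = "10001 10001 01010 00100 01010 10001 10001",
  "Y" = "10001 10001 01010 00100 00100 00100 00100",
  "Z" = "11111 00001 00010 00100 01000 10000 11111",
  "." = "00000 00000 00000 00000 00000 01100 01100",
  "," = "00000 00000 00000 00000 01100 00100 01000",
  "-" = "00000 00000 00000 01110 00000 00000 00000",
  "+" = "00000 00100 00100 11111 00100 00100 00000",
  "=" = "00000 00000 11111 00000 11111 00000 00000",
  "_" = "00000 00000 00000 00000 00000 00000 11111",
  ":" = "00000 01100 01100 00000 01100 01100 00000",
  "/" = "00001 00010 00010 00100 01000 01000 10000",
  "(" = "00010 00100 01000 01000 01000 00100 00010",
  ")" = "01000 00100 00010 00010 00010 00100 01000",
  "[" = "01110 01000 01000 01000 01000 01000 01110",
  "]" = "01110 00010 00010 00010 00010 00010 01110",
  "^" = "00100 01010 10001 00000 00000 00000 00000",
  "%" = "11001 11010 00010 00100 01000 01011 10011",
  " " = "00000 00000 00000 00000 00000 00000 00000")
  lapply(raw, function(s) {
    rows <- strsplit(s, " ", fixed = TRUE)[[1]]
    do.call(rbind, lapply(rows, function(r)
      as.integer(strsplit(r, "")[[1]] == "1")))
  })
})

# draw text with its top-left corner at (row, col); unknown glyphs (after
# uppercasing) render as space
.cv_text <- function(cv, row, col, text, col_rgb = c(0, 0, 0), scale = 1L) {
  chars <- strsplit(toupper(text), "")[[1]]
  at <- col
  for (ch in chars) {
    glyph <- .FONT57[[ch]]
    if (!is.null(glyph)) {
      px <- which(glyph == 1L, arr.ind = TRUE)
      if (nrow(px)) {
        for (sr in seq_len(scale)) for (sc in seq_len(scale)) {
          cv <- .cv_set(cv, row + (px[, 1] - 1L) * scale + sr - 1L,
                        at + (px[, 2] - 1L) * scale + sc - 1L, col_rgb)
        }
      }
    }
    at <- at + 6L * scale
  }
  cv
}

.cv_write_png <- function(cv, path) {
  png::writePNG(cv, target = path)
  invisible(path)
}
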