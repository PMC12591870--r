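# Minimal built-in 5x7 bitmap font (uppercase letters, digits, punctuation)
# used to burn text into annotated frames without any graphics device.

font_5x7 <- local({
  raw <- list(
    "A" = c("01110","10001","10001","11111","10001","10001","10001"),
    "B" = c("11110","10001","10001","11110","10001","10001","11110"),
    "C" = c("01111","10000","10000","10000","10000","10000","01111"),
    "D" = c("11110","10001","10001","10001","10001","10001","11110"),
    "E" = c("11111","10000","10000","11110","10000","10000","11111"),
    "F" = c("11111","10000","10000","11110","10000","10000","10000"),
    "G" = c("01111","10000","10000","10011","10001","10001","01111"),
    "H" = c("10001","10001","10001","11111","10001","10001","10001"),
    "I" = c("11111","00100","00100","00100","00100","00100","11111"),
    "J" = c("00001","00001","00001","00001","10001","10001","01110"),
    "K" = c("10001","10010","10100","11000","10100","10010","10001"),
    "L" = c("10000","10000","10000","10000","10000","10000","11111"),
    "M" = c("10001","11011","10101","10101","10001","10001","10001"),
    "N" = c("10001","11001","10101","10011","10001","10001","10001"),
    "O" = c("01110","10001","10001","10001","10001","10001","01110"),
    "P" = c("11110","10001","10001","11110","10000","10000","10000"),
    "Q" = c("01110","10001","10001","10001","10101","10010","01101"),
    "R" = c("11110","10001","10001","11110","10100","10010","10001"),
    "S" = c("01111","10000","10000","01110","00001","00001","11110"),
    "T" = c("11111","00100","00100","00100","00100","00100","00100"),
    "U" = c("10001","10001","10001","10001","10001","10001","01110"),
    "V" = c("10001","10001","10001","10001","10001","01010","00100"),
    "W" = c("10001","10001","10001","10101","10101","11011","10001"),
    "X" = c("10001","01010","00100","00100","00100","01010","10001"),
    "Y" = c("10001","01010","00100","00100","00100","00100","00100"),
    "Z" = c("11111","00001","00010","00100","01000","10000","11111"),
    "0" = c("01110","10001","10011","10101","11001","10001","01110"),
    "1" = c("00100","01100","00100","00100","00100","00100","01110"),
    "2" = c("01110","10001","00001","00110","01000","10000","11111"),
    "3" = c("11110","00001","00001","01110","00001","00001","11110"),
    "4" = c("00010","00110","01010","10010","11111","00010","00010"),
    "5" = c("11111","10000","11110","00001","00001","10001","01110"),
    "6" = c("01110","10000","10000","11110","10001","10001","01110"),
    "7" = c("11111","00001","00010","00100","01000","01000","01000"),
    "8" = c("01110","10001","10001","01110","10001","10001","01110"),
    "9" = c("01110","10001","10001","01111","00001","00001","01110"),
    "." = c("00000","00000","00000","00000","00000","01100","01100"),
    "," = c("00000","00000","00000","00000","01100","00100","01000"),
    ":" = c("00000","01100","01100","00000","01100","01100","00000"),
    "%" = c("11001","11010","00010","00100","01000","01011","10011"),
    "-" = c("00000","00000","00000","01110","00000","00000","00000"),
    " " = c("00000","00000","00000","00000","00000","00000","00000")
  )
  lapply(raw, function(g) {
    do.call(rbind, lapply(g, function(row) as.integer(strsplit(row, "")[[1]] == "1")))
  })
})

# Draw text into an (H, W, 3) array. Unknown characters render as blanks.
draw_text <- function(img, text, x, y, colour = c(1, 1, 1), scale = 1) {
  chars <- strsplit(toupper(text), "")[[1]]
  H <- dim(img)[1]; W <- dim(img)[2]
  cx <- round(x)
  for (ch in chars) {
    glyph <- font_5x7[[ch]]
    if (!is.null(glyph)) {
      px <- which(glyph == 1, arr.ind = TRUE)
      for (p in seq_len(nrow(px))) {
        rr <- round(y) + (px[p, 1] - 1) * scale + seq_len(scale) - 1
        cc <- cx + (px[p, 2] - 1) * scale + seq_len(scale) - 1
        rr <- rr[rr >= 1 & rr <= H]; cc <- cc[cc >= 1 & cc <= W]
        if (length(rr) && length(cc)) {
          for (k in 1:3) img[rr, cc, k] <- colour[k]
        }
      }
    }
    cx <- cx + 6 * scale
  }
  img
}
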