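#' Default categorical palette
#'
#' Fixed 10-color cycle used for marker display colors, metadata borders and
#' scatter colors when the user supplies no color map. Colors repeat when
#' more than ten values are requested.
#'
#' @param n number of colors.
#' @return character vector of `n` hex colors.
#' @export
default_palette <- function(n) {
  base <- c("#FF0000", "#00FF00", "#0000FF", "#FFFF00", "#FF00FF",
            "#00FFFF", "#FF8000", "#8000FF", "#00FF80", "#FF0080")
  rep_len(base, n)
}

#' Canvas theme background colors
#'
#' @param theme one of `"black"`, `"gray"`, `"dark_blue"`.
#' @return hex color of the canvas background.
#' @export
theme_color <- function(theme = c("black", "gray", "dark_blue")) {
  theme <- match.arg(theme)
  c(black = "#000000", gray = "#404040", dark_blue = "#0B0B45")[[theme]]
}

# hex -> length-3 numeric rgb in 0..255
hex_to_rgb <- function(hex) as.numeric(grDevices::col2rgb(hex))
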