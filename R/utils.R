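# Shared internal helpers: token validation, numeric parsing, palette.

# Decimal/scientific numeric token as emitted by upstream mappers.
# Locale commas and bare "E" exponents without digits are rejected.
.num_token_re <- "^[+-]?[0-9]+(\\.[0-9]+)?([eE][+-]?[0-9]+)?$"
.int_token_re <- "^[0-9]+$"

.is_num_token <- function(x) grepl(.num_token_re, x)
.is_int_token <- function(x) grepl(.int_token_re, x)

# Bang Wong colorblind-accessible palette, assigned to categories by rank.
#' Bang Wong color palette
#'
#' Eight-color palette designed for accessibility by colorblind viewers,
#' used by all plotting functions in the package. Colors are assigned to
#' plot categories by rank order.
#'
#' @param n Number of colors requested; recycled past eight.
#' @return Character vector of hex colors of length `n`.
#' @export
#' @examples
#' wong_palette(3)
wong_palette <- function(n = 8L) {
  pal <- c("#000000", "#E69F00", "#56B4E9", "#009E73",
           "#F0E442", "#0072B2", "#D55E00", "#CC79A7")
  rep_len(pal, n)
}

# Format a numeric value for the hyb column when no original token exists.
.format_num <- function(x) {
  if (is.null(x) || is.na(x)) return(".")
  format(x, scientific = FALSE, trim = TRUE)
}

.stop_hyb <- function(code, msg, line = NULL) {
  prefix <- if (!is.null(line)) sprintf("line %d: ", line) else ""
  stop(structure(
    class = c("hyb_error", "error", "condition"),
    list(message = sprintf("[%s] %s%s", code, prefix, msg),
         call = sys.call(-1), code = code, line = line)
  ))
}

# open a text connection, auto-detecting gzip by magic bytes
.open_text <- function(path) {
  if (inherits(path, "connection")) return(path)
  magic <- readBin(path, "raw", n = 2L)
  if (length(magic) == 2L && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)) {
    gzfile(path, open = "rt")
  } else {
    file(path, open = "rt")
  }
}

.read_lines_auto <- function(path) {
  con <- .open_text(path)
  if (!inherits(path, "connection")) on.exit(close(con))
  readLines(con, warn = FALSE)
}
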