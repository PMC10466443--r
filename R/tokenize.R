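#' Normalize typographic quotes and apostrophes
#'
#' Maps Unicode curly double quotes to ASCII `"` and curly single
#' quotes/apostrophes to ASCII `'`. Applied to both rule text and note text
#' before any parsing or matching, so rules typed with word-processor quotes
#' and notes pasted from rich-text sources behave identically.
#'
#' @param x character vector.
#' @return character vector with quotes normalized.
#' @export
normalize_quotes <- function(x) {
  x <- gsub("“|”|„|‟", "\"", x)
  gsub("‘|’|‚|‛|′", "'", x)
}

#' Tokenize clinical note text
#'
#' Lossy normalization: curly quotes/apostrophes are mapped to ASCII, case is
#' folded to lower, and tokens are maximal runs of letters and digits with
#' internal apostrophes preserved ("doesn't" is one token). Every other
#' character is a separator. Digit runs are tokens in their own right, so
#' numeric exclusion phrases such as "isolation 14" can match.
#'
#' @param text a single character string (may be empty or `NA`).
#' @return a data frame with columns `surface` (text as it appeared), `norm`
#'   (lowercased normalized form) and `pos` (0-based token index). Zero rows
#'   for empty input.
#' @examples
#' tokenize("Food insecurity: none")$norm
#' tokenize("doesn't feel lonely")$norm
#' @export
tokenize <- function(text) {
  if (length(text) != 1L) stop("tokenize() expects a single string")
  if (is.na(text) || !nzchar(text)) {
    return(data.frame(surface = character(), norm = character(),
                      pos = integer(), stringsAsFactors = FALSE))
  }
  norm_text <- tolower(normalize_quotes(text))
  m <- gregexpr("[a-z0-9]+(?:'[a-z0-9]+)*", norm_text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(surface = character(), norm = character(),
                      pos = integer(), stringsAsFactors = FALSE))
  }
  norms <- regmatches(norm_text, list(m))[[1]]
  surfaces <- substring(text, m, m + attr(m, "match.length") - 1L)
  data.frame(surface = surfaces, norm = norms,
             pos = seq_along(norms) - 1L, stringsAsFactors = FALSE)
}

# Fast path used by the match engine: just the normalized token stream.
token_norms <- function(text) tokenize(text)$norm
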