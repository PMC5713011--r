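#' Parse a human-readable duration string
#'
#' Accepts strings like `"3 h 27 m 56 s"` or `"5 d 18 h 54 m 2 s"`: optional
#' day (`d`), hour (`h`), minute (`m`) and second (`s`) tokens, in that
#' order, each an integer followed by its unit letter. Commas between tokens
#' are ignored. Returns the exact total in integer seconds.
#'
#' @param text character vector of duration strings.
#' @return numeric vector of total seconds.
#' @export
parse_duration <- function(text) {
  vapply(text, function(s) {
    s <- trimws(gsub(",", " ", s))
    if (!nzchar(s)) stop("empty duration string", call. = FALSE)
    toks <- regmatches(s, gregexpr("[0-9]+\\s*[dhms]", s))[[1]]
    leftover <- gsub("\\s+", "", gsub("[0-9]+\\s*[dhms]", "", s))
    if (!length(toks) || nzchar(leftover))
      stop(sprintf("unrecognized duration syntax: '%s'", s), call. = FALSE)
    units <- c(d = 86400, h = 3600, m = 60, s = 1)
    u <- substring(toks, nchar(toks))
    if (anyDuplicated(u) || is.unsorted(match(u, names(units))))
      stop(sprintf("duration tokens out of order or repeated: '%s'", s),
           call. = FALSE)
    v <- as.numeric(sub("\\s*[dhms]$", "", toks))
    sum(v * units[u])
  }, numeric(1), USE.NAMES = FALSE)
}

#' Format seconds as a duration string
#'
#' Inverse of [parse_duration()] for non-negative integer seconds:
#' `format_duration(parse_duration(x)) == x` up to token normalization, and
#' `parse_duration(format_duration(n)) == n` for every non-negative integer
#' `n`.
#'
#' @param seconds non-negative numeric vector (fractional parts are an error).
#' @return character vector like `"1 h 29 m 18 s"`.
#' @export
format_duration <- function(seconds) {
  vapply(seconds, function(x) {
    if (is.na(x) || x < 0 || x != round(x))
      stop("seconds must be non-negative integers", call. = FALSE)
    x <- round(x)
    d <- x %/% 86400; x <- x %% 86400
    h <- x %/% 3600;  x <- x %% 3600
    m <- x %/% 60;    s <- x %% 60
    parts <- character(0)
    if (d > 0) parts <- c(parts, sprintf("%d d", d))
    if (h > 0 || length(parts)) parts <- c(parts, sprintf("%d h", h))
    if (m > 0 || length(parts)) parts <- c(parts, sprintf("%d m", m))
    parts <- c(parts, sprintf("%d s", s))
    paste(parts, collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}
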