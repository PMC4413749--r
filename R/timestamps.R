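#' Parse recording start times from file names
#'
#' Autonomous recorders typically encode the recording start time in the file
#' name (e.g. `"REC_20131019_120000.wav"`). `parse_timestamp()` extracts and
#' parses that time given a `strptime`-style pattern containing literal text
#' and date fields, e.g. `"REC_%Y%m%d_%H%M%S"`. The pattern is converted to a
#' regular expression to locate the date fields anywhere in the base name,
#' then parsed with [strptime()].
#'
#' @param x Character vector of file names or paths.
#' @param pattern `strptime`-style pattern with literals and any of
#'   `%Y %y %m %d %H %M %S %j`.
#' @param tz Time zone for the parsed times (default `"UTC"`); recorders
#'   stamp local time, and no daylight-saving adjustment is attempted.
#' @param on_fail `"error"` (default) to fail on the first unparseable name,
#'   `"na"` to return `NA` for it (callers may then fall back to file order).
#' @return A `POSIXct` vector, one element per file name.
#' @export
#' @examples
#' parse_timestamp("REC_20131019_120000.wav", "REC_%Y%m%d_%H%M%S")
parse_timestamp <- function(x, pattern, tz = "UTC",
                            on_fail = c("error", "na")) {
  on_fail <- match.arg(on_fail)
  rx <- pattern_to_regex(pattern)
  base <- basename(x)
  m <- regmatches(base, regexpr(rx, base))
  hit <- regexpr(rx, base) > 0
  out <- rep(as.POSIXct(NA), length(x))
  if (any(hit)) {
    parsed <- as.POSIXct(strptime(regmatches(base, regexpr(rx, base)),
                                  pattern, tz = tz))
    out[hit] <- parsed
  }
  bad <- !hit | is.na(out)
  if (any(bad) && on_fail == "error") {
    abort(sprintf(
      "Could not parse timestamp from '%s' with pattern '%s'.",
      base[bad][1L], pattern
    ))
  }
  attr(out, "tzone") <- tz
  out
}

# strptime pattern -> extraction regex: literals are escaped, date tokens
# become digit groups of the appropriate width.
pattern_to_regex <- function(pattern) {
  widths <- c(Y = 4L, y = 2L, m = 2L, d = 2L, H = 2L, M = 2L, S = 2L, j = 3L)
  out <- character(0)
  chars <- strsplit(pattern, "", fixed = TRUE)[[1L]]
  i <- 1L
  while (i <= length(chars)) {
    ch <- chars[i]
    if (ch == "%" && i < length(chars)) {
      tok <- chars[i + 1L]
      if (!tok %in% names(widths)) {
        abort(sprintf("Unsupported timestamp field '%%%s' in pattern.", tok))
      }
      out <- c(out, sprintf("\\d{%d}", widths[[tok]]))
      i <- i + 2L
    } else {
      specials <- c(".", "\\", "|", "(", ")", "[", "]", "{", "}",
                    "^", "$", "*", "+", "?")
      out <- c(out, if (ch %in% specials) paste0("\\", ch) else ch)
      i <- i + 1L
    }
  }
  paste0(out, collapse = "")
}

#' Format a timestamp back into a file-name fragment
#'
#' Inverse of [parse_timestamp()]: renders a `POSIXct` with the same pattern,
#' so `format_timestamp(parse_timestamp(x, p), p)` reproduces the matched
#' part of `x`.
#'
#' @param time A `POSIXct`.
#' @inheritParams parse_timestamp
#' @return Character vector.
#' @export
format_timestamp <- function(time, pattern, tz = "UTC") {
  format(time, pattern, tz = tz)
}
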