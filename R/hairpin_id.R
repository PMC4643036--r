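# Canonical hairpin identifier codec:
#   <contig>:<start>-<end>[<mature_start>,<mature_length>]
# Coordinates are 1-based inclusive on the contig; mature_start is the 1-based
# offset of the mature miRNA within the hairpin. Internal interval arithmetic
# elsewhere is 0-based half-open; conversion happens only at this boundary.

check_hairpin_fields <- function(contig, start, end, mature_start,
                                 mature_length) {
  ok <- start <= end &
    mature_start >= 1 &
    mature_start <= end - start + 1 &
    mature_start + mature_length - 1 <= end - start + 1 &
    mature_length >= 1
  if (any(!ok)) {
    stop("invalid hairpin identifier fields (start <= end, mature interval ",
         "must lie within the hairpin): first bad entry ",
         contig[!ok][1], ":", start[!ok][1], "-", end[!ok][1],
         "[", mature_start[!ok][1], ",", mature_length[!ok][1], "]")
  }
  invisible(TRUE)
}

#' Format hairpin identifiers
#'
#' Produces strings such as `"1AL_3896362:3010-3120[21,21]"`: contig, 1-based
#' inclusive hairpin coordinates, then the 1-based offset and length of the
#' mature miRNA within the hairpin. Always emits an ASCII hyphen.
#'
#' @param contig,start,end,mature_start,mature_length vectors of identifier
#'   fields (recycled).
#' @return character vector of identifiers.
#' @export
format_hairpin_identifier <- function(contig, start, end, mature_start,
                                      mature_length) {
  check_hairpin_fields(contig, start, end, mature_start, mature_length)
  sprintf("%s:%d-%d[%d,%d]", contig, as.integer(start), as.integer(end),
          as.integer(mature_start), as.integer(mature_length))
}

#' Parse hairpin identifiers
#'
#' Inverse of [format_hairpin_identifier()]. An en dash between the
#' coordinates (as printed in some renderings) is accepted as an alias for
#' the ASCII hyphen. Malformed strings or invariant violations (start > end,
#' mature interval outside the hairpin) are errors.
#'
#' @param s character vector of identifier strings.
#' @return data.frame with columns `contig`, `start`, `end`, `mature_start`,
#'   `mature_length`.
#' @export
parse_hairpin_identifier <- function(s) {
  s2 <- gsub("–", "-", s)
  pat <- "^(.+):([0-9]+)-([0-9]+)\\[([0-9]+),([0-9]+)\\]$"
  bad <- !grepl(pat, s2)
  if (any(bad)) stop("malformed hairpin identifier: ", s[bad][1])
  m <- regmatches(s2, regexec(pat, s2))
  contig <- vapply(m, `[`, character(1), 2)
  start <- as.integer(vapply(m, `[`, character(1), 3))
  end <- as.integer(vapply(m, `[`, character(1), 4))
  mature_start <- as.integer(vapply(m, `[`, character(1), 5))
  mature_length <- as.integer(vapply(m, `[`, character(1), 6))
  check_hairpin_fields(contig, start, end, mature_start, mature_length)
  data.frame(contig = contig, start = start, end = end,
             mature_start = mature_start, mature_length = mature_length,
             stringsAsFactors = FALSE)
}
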