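#' @keywords internal
"_PACKAGE"

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Parse a CDS block string
#'
#' Blocks are encoded as `"start-end,start-end"` in ascending genomic
#' order, 1-based inclusive.
#' @noRd
parse_blocks <- function(s) {
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  m <- regmatches(parts, regexec("^([0-9]+)-([0-9]+)$", parts))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad)) stop2("malformed CDS block spec: '", s, "'")
  starts <- as.integer(vapply(m, `[`, "", 2L))
  ends <- as.integer(vapply(m, `[`, "", 3L))
  data.frame(start = starts, end = ends)
}

format_blocks <- function(starts, ends) {
  paste(paste0(starts, "-", ends), collapse = ",")
}

#' Validate a set of CDS blocks
#' @return invisibly TRUE; errors otherwise
#' @noRd
check_blocks <- function(blocks, where = "gene model") {
  if (nrow(blocks) == 0L) stop2(where, ": no CDS blocks")
  if (any(blocks$end < blocks$start)) stop2(where, ": block end < start")
  if (is.unsorted(blocks$start, strictly = TRUE) && nrow(blocks) > 1L)
    stop2(where, ": CDS blocks not sorted ascending by start")
  if (nrow(blocks) > 1L &&
      any(blocks$start[-1L] <= blocks$end[-nrow(blocks)]))
    stop2(where, ": CDS blocks overlap")
  len <- sum(blocks$end - blocks$start + 1L)
  if (len %% 3L != 0L)
    stop2(where, ": total CDS length ", len, " not divisible by 3")
  invisible(TRUE)
}

#' Derive a stage seed from a global seed
#'
#' A single pipeline seed fans out to per-stage seeds by fixed offsets so
#' that stages are individually reproducible without colliding streams.
#' Kept well below .Machine$integer.max.
#' @noRd
stage_seed <- function(seed, stage) {
  offs <- c(simulate = 11L, build = 23L, decompose = 37L, map = 53L,
            stats = 71L, profile = 97L, mutations = 113L,
            conservation = 131L)
  if (!stage %in% names(offs)) stop2("unknown stage '", stage, "'")
  (as.integer(seed) %% 1000000L) * 1000L + offs[[stage]]
}
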