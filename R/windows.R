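# DIA/SWATH precursor isolation-window schemes.
#
# A scheme divides a precursor range into contiguous windows of fixed
# nominal width; every window after the first is widened by `left_overlap`
# Th on its low-m/z side (acquisition-side overlap). Assignment of a
# precursor to "its" window uses the non-overlapped cores, which tile the
# range exactly, so every in-range m/z maps to exactly one window.

#' Construct a SWATH isolation-window scheme
#'
#' @param range_start,range_end Precursor range bounds (Th);
#'   `range_end - range_start` must be an exact multiple of `width`.
#' @param width Nominal window width (Th).
#' @param left_overlap Extra width added on the left side of every window
#'   except the first (Th, default 1).
#' @return Object of class `window_scheme`: list with `windows` (data.frame
#'   `start`, `end`), `range_start`, `range_end`, `nominal_width`,
#'   `left_overlap`.
#' @examples
#' s <- make_window_scheme(400, 1200, 25)   # the 32 x 25 Da scheme
#' nrow(s$windows)                          # 32
#' s$windows[2, ]                           # 424 - 450
#' @export
make_window_scheme <- function(range_start, range_end, width,
                               left_overlap = 1) {
  stopifnot(range_end > range_start, width > 0, left_overlap >= 0)
  n <- (range_end - range_start) / width
  if (abs(n - round(n)) > 1e-9) {
    valid_end <- range_start + round(n) * width
    stop(sprintf(paste0("range span %.4g is not divisible by width %.4g; ",
                        "nearest valid range_end is %.4g"),
                 range_end - range_start, width, valid_end), call. = FALSE)
  }
  n <- as.integer(round(n))
  i <- seq_len(n)
  start <- range_start + (i - 1) * width - ifelse(i > 1, left_overlap, 0)
  end <- range_start + i * width
  structure(list(windows = data.frame(start = start, end = end),
                 range_start = range_start, range_end = range_end,
                 nominal_width = width, left_overlap = left_overlap),
            class = "window_scheme")
}

#' Assign a precursor m/z to its isolation window
#'
#' Assignment uses the half-open window cores
#' `[range_start + (i-1) * width, range_start + i * width)`; the left
#' overlap never creates double assignment.
#'
#' @param mz Numeric vector of precursor m/z values.
#' @param scheme A [make_window_scheme()] object.
#' @return Integer vector of 1-based window indices; out-of-range m/z give
#'   NA with a warning.
#' @export
assign_precursor_window <- function(mz, scheme) {
  idx <- floor((mz - scheme$range_start) / scheme$nominal_width) + 1
  out <- mz < scheme$range_start | mz >= scheme$range_end
  if (any(out)) {
    warning(sum(out), " m/z value(s) outside the precursor range",
            call. = FALSE)
    idx[out] <- NA
  }
  as.integer(idx)
}

#' @export
print.window_scheme <- function(x, ...) {
  cat(sprintf("SWATH window scheme: %d windows of %g Da over %g-%g Th (left overlap %g Da)\n",
              nrow(x$windows), x$nominal_width, x$range_start, x$range_end,
              x$left_overlap))
  invisible(x)
}

#' Write a window scheme as a swaths.txt file
#'
#' Two tab-separated columns (start, end), no header, one window per line.
#' `what = "core"` (default) writes the non-overlapped cores used for
#' analysis-side precursor assignment; `what = "acquisition"` writes the
#' windows as acquired, i.e. including the left overlap.
#'
#' @param scheme A `window_scheme`.
#' @param path Output file path.
#' @param what `"core"` or `"acquisition"`.
#' @return `path`, invisibly.
#' @export
write_swath_windows <- function(scheme, path,
                                what = c("core", "acquisition")) {
  what <- match.arg(what)
  w <- scheme$windows
  if (what == "core") {
    i <- seq_len(nrow(w))
    w$start <- scheme$range_start + (i - 1) * scheme$nominal_width
  }
  writeLines(sprintf("%.6g\t%.6g", w$start, w$end), path)
  invisible(path)
}

#' Read a swaths.txt window file back into a scheme
#'
#' The nominal width is taken from the first window and the left overlap is
#' inferred from the second window's start; a file of core windows yields a
#' scheme with `left_overlap = 0`.
#'
#' @param path Window file written by [write_swath_windows()].
#' @return A `window_scheme`.
#' @export
read_swath_windows <- function(path) {
  x <- utils::read.table(path, header = FALSE, sep = "\t",
                         col.names = c("start", "end"))
  if (nrow(x) == 0) stop("empty window file: ", path, call. = FALSE)
  width <- x$end[1] - x$start[1]
  overlap <- if (nrow(x) >= 2) (x$start[1] + width) - x$start[2] else 0
  make_window_scheme(x$start[1], x$end[nrow(x)], width, overlap)
}
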