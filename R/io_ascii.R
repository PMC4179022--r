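#' Describe one ASCII file flavor
#'
#' A dialect records how a potentiostat text export is laid out: which
#' characters separate items and lines, the decimal mark, whether columns are
#' paired `X1 Y1 X2 Y2 ...` or share a single X column (`X Y1 Y2 ...`), and
#' which curve to take.
#'
#' The decimal mark and the comma are mutually exclusive roles: with
#' `decimal_mark = ","` the comma cannot also delimit items, and with
#' `decimal_mark = "."` the comma is accepted as an additional item
#' delimiter. This mirrors the "system decimal delimiter" convention of
#' instrument exports from decimal-comma locales.
#'
#' @param item_delims Characters accepted between items. Defaults to space,
#'   tab and semicolon, plus comma when `decimal_mark = "."`.
#' @param decimal_mark `"."` or `","`.
#' @param layout `"paired_xy"` or `"shared_x"`.
#' @param curve Which XY pair (paired layout) or Y column (shared layout) to
#'   read; 1-based.
#' @return A list of class `dialect`.
#' @export
#' @examples
#' dialect(decimal_mark = ",", layout = "shared_x")
dialect <- function(item_delims = NULL, decimal_mark = c(".", ","),
                    layout = c("paired_xy", "shared_x"), curve = 1L) {
  decimal_mark <- match.arg(decimal_mark)
  layout <- match.arg(layout)
  if (is.null(item_delims)) {
    item_delims <- if (decimal_mark == ".") c(" ", "\t", ";", ",") else c(" ", "\t", ";")
  }
  if (decimal_mark == "," && "," %in% item_delims) {
    vk_abort("invalid_dialect",
             "With a decimal comma, the comma cannot also be an item delimiter.")
  }
  if (!all(item_delims %in% c(" ", "\t", ";", ","))) {
    vk_abort("invalid_dialect", "Item delimiters must be space, tab, semicolon or comma.")
  }
  curve <- as.integer(curve)
  if (curve < 1L) vk_abort("invalid_dialect", "`curve` must be >= 1.")
  structure(list(item_delims = item_delims, decimal_mark = decimal_mark,
                 layout = layout, curve = curve),
            class = "dialect")
}

#' @export
print.dialect <- function(x, ...) {
  show <- vapply(x$item_delims, function(d)
    switch(d, " " = "space", "\t" = "tab", ";" = "semicolon", "," = "comma"), "")
  cat(sprintf("<dialect> items: %s | decimal '%s' | %s | curve %d\n",
              paste(show, collapse = "/"), x$decimal_mark, x$layout, x$curve))
  invisible(x)
}

# --- low-level text handling -------------------------------------------------

# read a file as lines; UTF-8 with Latin-1 fallback; reject binary content
read_ascii_lines <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (any(raw == as.raw(0))) {
    vk_abort("binary_file", sprintf(
      "'%s' contains NUL bytes: binary instrument files are not supported, export as ASCII.",
      path))
  }
  txt <- rawToChar(raw)
  Encoding(txt) <- "UTF-8"
  if (!validEnc(txt)) {
    txt <- rawToChar(raw)
    Encoding(txt) <- "latin1"
    txt <- enc2utf8(txt)
  }
  split_ascii_lines(txt)
}

split_ascii_lines <- function(text) {
  strsplit(text, "\r\n|\r|\n")[[1]]
}

delim_regex <- function(item_delims) {
  # literal characters inside a bracket expression (escapes are not special
  # in POSIX classes, so the tab goes in as a real tab character)
  paste0("[", paste(item_delims, collapse = ""), "]+")
}

num_regex <- "^[+-]?([0-9]+\\.?[0-9]*|\\.[0-9]+)([eE][+-]?[0-9]+)?$"

# tokenize a line under a dialect and parse items; NULL if any item non-numeric
parse_numeric_line <- function(line, d) {
  line <- trimws(line)
  if (!nzchar(line)) return(NULL)
  toks <- strsplit(line, delim_regex(d$item_delims))[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) < 2L) return(NULL)
  if (d$decimal_mark == ",") toks <- gsub(",", ".", toks, fixed = TRUE)
  if (!all(grepl(num_regex, toks))) return(NULL)
  as.numeric(toks)
}

# maximal runs of numeric lines with a constant column count
numeric_blocks <- function(lines, d) {
  parsed <- lapply(lines, parse_numeric_line, d = d)
  ncols <- vapply(parsed, function(p) if (is.null(p)) 0L else length(p), integer(1))
  blocks <- list()
  i <- 1L
  n <- length(lines)
  last_end <- 0L
  while (i <= n) {
    if (ncols[i] >= 2L) {
      j <- i
      while (j < n && ncols[j + 1L] == ncols[i]) j <- j + 1L
      if (j - i + 1L >= 2L) {
        blocks[[length(blocks) + 1L]] <- list(
          rows = do.call(rbind, parsed[i:j]),
          header_lines = lines[seq_len(i - 1L)][seq_len(i - 1L) > last_end],
          start = i, end = j)
        last_end <- j
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  blocks
}

# --- sniffing ----------------------------------------------------------------

#' Guess the dialect of a potentiostat ASCII export
#'
#' Classifies each line as numeric or text, finds maximal blocks of numeric
#' rows with a constant column count, and returns a [dialect()] under which at
#' least one block of two or more rows parses. Header and footer text lines
#' are treated as non-numeric and ignored.
#'
#' A decimal point is tried first; `decimal_mark = ","` must be forced for
#' decimal-comma files, because such files are usually also valid under the
#' point-decimal reading (the comma then acts as an item delimiter).
#'
#' @param text Raw file content (single string), a character vector of lines,
#'   or a path to an existing file.
#' @param decimal_mark Force `"."` or `","`; `NULL` tries `"."` then `","`.
#' @return A `dialect`.
#' @export
#' @examples
#' sniff_dialect("Potential/V\tCurrent/A\n0.1\t1e-6\n0.2\t2e-6\n")
sniff_dialect <- function(text, decimal_mark = NULL) {
  lines <- as_lines(text)
  if (length(lines) == 0L || !any(nzchar(trimws(lines)))) {
    vk_abort("no_numeric_block", "Input is empty.")
  }
  marks <- if (is.null(decimal_mark)) c(".", ",") else decimal_mark
  for (mk in marks) {
    d0 <- dialect(decimal_mark = mk)
    blocks <- numeric_blocks(lines, d0)
    if (length(blocks) == 0L) next
    ncol1 <- ncol(blocks[[1L]]$rows)
    layout <- if (ncol1 > 2L && ncol1 %% 2L == 0L) "paired_xy" else "shared_x"
    # keep only the delimiters actually seen inside numeric rows
    data_lines <- lines[blocks[[1L]]$start:blocks[[1L]]$end]
    seen <- d0$item_delims[vapply(d0$item_delims, function(ch)
      any(grepl(ch, data_lines, fixed = TRUE)), logical(1))]
    if (length(seen) == 0L) seen <- d0$item_delims
    return(dialect(item_delims = seen, decimal_mark = mk, layout = layout))
  }
  vk_abort("no_numeric_block",
           "No line parses as two or more numbers under any candidate dialect.")
}

as_lines <- function(text) {
  if (length(text) == 1L && !grepl("[\r\n]", text) && file.exists(text)) {
    read_ascii_lines(text)
  } else if (length(text) == 1L) {
    split_ascii_lines(text)
  } else {
    as.character(text)
  }
}

# --- parsing -----------------------------------------------------------------

#' Parse potentiostat ASCII text into traces
#'
#' Splits the input into maximal numeric blocks (any text between blocks
#' separates traces), then extracts traces according to the dialect layout:
#' `paired_xy` takes the `curve`-th (X, Y) column pair of each block;
#' `shared_x` returns one trace per Y column, all sharing column 1 as X.
#'
#' @param text Raw content, lines, or a file path (see [sniff_dialect()]).
#' @param dialect A [dialect()]; sniffed from the text when `NULL`.
#' @param first_column_as_x Logical; `TRUE` forces the `shared_x` layout,
#'   `FALSE` forces `paired_xy`, `NULL` keeps the dialect's layout.
#' @param curve Overrides the dialect's curve index when not `NULL`. With
#'   `curve = NULL` and a `shared_x` layout, all Y columns are returned.
#' @param scan_rate Optional scan rate attached to every returned trace.
#' @return A list of [voltammogram()] objects. Each carries the text lines
#'   that preceded its block in attribute `header_lines` and a `label` of the
#'   form `"block k"` (prefixed by the file name when parsing a file).
#' @export
#' @examples
#' txt <- "header\n0.1\t1e-6\n0.2\t2e-6\n"
#' parse_voltammetry(txt)[[1]]
parse_voltammetry <- function(text, dialect = NULL, first_column_as_x = NULL,
                              curve = NULL, scan_rate = NULL) {
  lines <- as_lines(text)
  src <- if (length(text) == 1L && !grepl("[\r\n]", text) && file.exists(text))
    basename(text) else NULL
  if (is.null(dialect)) dialect <- sniff_dialect(lines)
  if (!is.null(first_column_as_x)) {
    dialect$layout <- if (isTRUE(first_column_as_x)) "shared_x" else "paired_xy"
  }
  if (!is.null(curve)) dialect$curve <- as.integer(curve)
  blocks <- numeric_blocks(lines, dialect)
  if (length(blocks) == 0L) {
    vk_abort("no_numeric_block", "No numeric block of two or more rows found.")
  }
  traces <- list()
  for (b in seq_along(blocks)) {
    rows <- blocks[[b]]$rows
    nc <- ncol(rows)
    lab <- paste0(if (!is.null(src)) paste0(src, " ") else "", "block ", b)
    if (dialect$layout == "paired_xy") {
      if (nc %% 2L != 0L) {
        vk_abort("ragged_row", sprintf(
          "Block %d has %d columns: the paired X1 Y1 X2 Y2 layout needs an even count.",
          b, nc))
      }
      ncurves <- nc %/% 2L
      idx <- if (is.null(curve) && nc == 2L) 1L else dialect$curve
      if (idx > ncurves) {
        vk_abort("curve_index_out_of_range", sprintf(
          "Curve %d requested but block %d holds only %d curve(s).", idx, b, ncurves))
      }
      tr <- list(voltammogram(rows[, 2L * idx - 1L], rows[, 2L * idx],
                              scan_rate = scan_rate, label = lab))
    } else {
      ycols <- 2:nc
      if (!is.null(curve) || dialect$curve > 1L || nc == 2L) {
        if (dialect$curve > nc - 1L) {
          vk_abort("curve_index_out_of_range", sprintf(
            "Curve %d requested but block %d holds only %d Y column(s).",
            dialect$curve, b, nc - 1L))
        }
        ycols <- dialect$curve + 1L
      }
      tr <- lapply(ycols, function(j)
        voltammogram(rows[, 1L], rows[, j], scan_rate = scan_rate,
                     label = if (length(ycols) > 1L) paste0(lab, " y", j - 1L) else lab))
    }
    for (k in seq_along(tr)) attr(tr[[k]], "header_lines") <- blocks[[b]]$header_lines
    traces <- c(traces, tr)
  }
  traces
}

#' Read a potentiostat ASCII export
#'
#' Convenience wrapper: sniffs the dialect (unless supplied) and parses the
#' file with [parse_voltammetry()].
#'
#' @inheritParams parse_voltammetry
#' @param path Path to the ASCII file.
#' @param decimal_mark Forwarded to [sniff_dialect()] when no dialect is given.
#' @return A list of voltammograms.
#' @export
read_voltammetry <- function(path, dialect = NULL, first_column_as_x = NULL,
                             curve = NULL, scan_rate = NULL, decimal_mark = NULL) {
  lines <- read_ascii_lines(path)
  if (is.null(dialect)) dialect <- sniff_dialect(lines, decimal_mark = decimal_mark)
  out <- parse_voltammetry(lines, dialect = dialect,
                           first_column_as_x = first_column_as_x,
                           curve = curve, scan_rate = scan_rate)
  for (i in seq_along(out)) {
    attr(out[[i]], "label") <- paste0(basename(path), " ", attr(out[[i]], "label"))
  }
  out
}

#' Write a voltammogram as canonical CSV
#'
#' Two columns, comma-separated, decimal point, header
#' `potential_V,current_A`, 17 significant digits so a read-back reproduces
#' the doubles exactly.
#'
#' @param vg A `voltammogram`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_canonical <- function(vg, path) {
  if (!is_voltammogram(vg) || nrow(vg) < 1L) {
    vk_abort("empty_trace", "Nothing to write: `vg` must be a non-empty voltammogram.")
  }
  lines <- c("potential_V,current_A",
             sprintf("%.17g,%.17g", vg$potential, vg$current))
  writeLines(lines, path)
  invisible(path)
}
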