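#' Praat TextGrid documents
#'
#' A `textgrid` object holds the interval tiers of a Praat TextGrid: the
#' document time range in seconds and an ordered list of tiers, each a
#' tibble of `(xmin, xmax, text)` intervals. Both the long ("full") and
#' short text dialects written by Praat are read; only the long dialect is
#' written, which is the canonical output of Praat scripting.
#'
#' Praat sometimes exports TextGrids as UTF-16. Those files must be
#' transcoded to UTF-8 before parsing; [read_textgrid()] detects the
#' UTF-16 byte-order mark and refuses with an explicit message rather than
#' silently mis-reading the file.
#'
#' @param xmin,xmax Document time range, seconds.
#' @param tiers A list of tiers. Each tier is a list with elements `name`
#'   (a string) and `intervals` (a data frame with columns `xmin`, `xmax`,
#'   `text`, times in seconds).
#' @return An object of class `textgrid`.
#' @examples
#' tg <- textgrid(0, 2, list(list(
#'   name = "words",
#'   intervals = data.frame(xmin = c(0, 0.5, 1.1), xmax = c(0.5, 1.1, 2),
#'                          text = c("", "snavel", "")))))
#' tg
#' @export
textgrid <- function(xmin, xmax, tiers = list()) {
  tiers <- lapply(tiers, function(tier) {
    list(name = as.character(tier$name),
         intervals = as_tibble(tier$intervals)[, c("xmin", "xmax", "text")])
  })
  doc <- structure(list(xmin = as.double(xmin), xmax = as.double(xmax),
                        tiers = tiers),
                   class = "textgrid")
  validate_textgrid(doc)
  doc
}

#' @export
print.textgrid <- function(x, ...) {
  cat(sprintf("<textgrid> [%g, %g] s, %d tier(s)\n", x$xmin, x$xmax,
              length(x$tiers)))
  for (tier in x$tiers) {
    cat(sprintf("  tier '%s': %d interval(s)\n", tier$name,
                nrow(tier$intervals)))
  }
  invisible(x)
}

#' Validate a textgrid object
#'
#' Checks the interval-tier invariants: within every tier the intervals
#' must be ordered, non-overlapping and contiguous (gaps or overlaps
#' larger than 1e-6 s are rejected), and tier time ranges must lie inside
#' the document range.
#'
#' @param doc A [textgrid()] object.
#' @return `doc`, invisibly. Errors on the first violated invariant.
#' @export
validate_textgrid <- function(doc, tol = 1e-6) {
  if (!is.finite(doc$xmin) || !is.finite(doc$xmax) || doc$xmax < doc$xmin) {
    abort("textgrid: document xmax must be >= xmin and finite")
  }
  for (ti in seq_along(doc$tiers)) {
    iv <- doc$tiers[[ti]]$intervals
    if (nrow(iv) == 0) next
    if (iv$xmin[1] < doc$xmin - tol || iv$xmax[nrow(iv)] > doc$xmax + tol) {
      abort(sprintf("textgrid: tier %d ('%s') exceeds document bounds",
                    ti, doc$tiers[[ti]]$name))
    }
    if (any(iv$xmax < iv$xmin - tol)) {
      abort(sprintf("textgrid: tier %d has an interval with xmax < xmin", ti))
    }
    if (nrow(iv) > 1) {
      gaps <- iv$xmin[-1] - iv$xmax[-nrow(iv)]
      if (any(abs(gaps) > tol)) {
        k <- which(abs(gaps) > tol)[1]
        abort(sprintf(
          "textgrid: tier %d ('%s') intervals %d and %d are not contiguous (gap %g s)",
          ti, doc$tiers[[ti]]$name, k, k + 1, gaps[k]))
      }
    }
  }
  invisible(doc)
}

# --- parsing ---------------------------------------------------------------

tg_unquote <- function(s) {
  s <- sub('^"', "", sub('"$', "", s))
  gsub('""', '"', s)
}

# Cursor over non-empty trimmed lines, remembering original line numbers so
# parse errors can name the offending line.
tg_cursor <- function(lines) {
  trimmed <- trimws(lines)
  keep <- which(nzchar(trimmed))
  env <- new.env(parent = emptyenv())
  env$lines <- trimmed[keep]
  env$nums <- keep
  env$i <- 0L
  env
}

tg_next <- function(cur, what) {
  cur$i <- cur$i + 1L
  if (cur$i > length(cur$lines)) {
    abort(sprintf("TextGrid parse error: unexpected end of input while reading %s", what))
  }
  list(text = cur$lines[cur$i], num = cur$nums[cur$i])
}

tg_peek <- function(cur) {
  if (cur$i + 1L > length(cur$lines)) return(NULL)
  cur$lines[cur$i + 1L]
}

# Long dialect: expect `key = value`; returns the value string.
tg_long_value <- function(cur, key) {
  ln <- tg_next(cur, key)
  pat <- paste0("^", key, "\\s*=\\s*(.*)$")
  if (!grepl(pat, ln$text)) {
    abort(sprintf("TextGrid parse error at line %d: expected '%s = ...', got '%s'",
                  ln$num, key, ln$text))
  }
  trimws(sub(pat, "\\1", ln$text))
}

tg_long_num <- function(cur, key) {
  v <- suppressWarnings(as.double(tg_long_value(cur, key)))
  if (is.na(v)) abort(sprintf("TextGrid parse error: non-numeric value for '%s'", key))
  v
}

# Short dialect: the next bare line, interpreted as number or quoted string.
tg_short_num <- function(cur, what) {
  ln <- tg_next(cur, what)
  v <- suppressWarnings(as.double(ln$text))
  if (is.na(v)) {
    abort(sprintf("TextGrid parse error at line %d: expected a number (%s), got '%s'",
                  ln$num, what, ln$text))
  }
  v
}

tg_short_str <- function(cur, what) {
  ln <- tg_next(cur, what)
  tg_unquote(ln$text)
}

#' Parse Praat TextGrid text
#'
#' Reads both the long (`xmin = 0`) and short (bare values) text dialects.
#' Interval tiers are preserved in file order with times in seconds as
#' written; point tiers (`TextTier`) are skipped with a warning since word
#' segmentation lives in interval tiers. Malformed input produces an error
#' naming the offending line.
#'
#' @param text A single string containing the whole file, or a character
#'   vector of lines.
#' @return A [textgrid()] object.
#' @seealso [read_textgrid()] to read from a file path, [write_textgrid()].
#' @export
parse_textgrid <- function(text) {
  lines <- if (length(text) == 1 && grepl("\n", text)) {
    strsplit(text, "\r?\n")[[1]]
  } else {
    as.character(text)
  }
  if (length(lines) > 0) lines[1] <- sub("^﻿", "", lines[1])

  cur <- tg_cursor(lines)
  hdr1 <- tg_next(cur, "file type header")
  if (!grepl("ooTextFile", hdr1$text)) {
    abort(sprintf("TextGrid parse error at line %d: missing 'File type = \"ooTextFile\"' header",
                  hdr1$num))
  }
  hdr2 <- tg_next(cur, "object class header")
  if (!grepl("TextGrid", hdr2$text)) {
    abort(sprintf("TextGrid parse error at line %d: object class is not TextGrid", hdr2$num))
  }

  long <- grepl("^xmin", tg_peek(cur) %||% "")
  if (long) tg_parse_long(cur) else tg_parse_short(cur)
}

tg_parse_long <- function(cur) {
  xmin <- tg_long_num(cur, "xmin")
  xmax <- tg_long_num(cur, "xmax")
  exists_line <- tg_next(cur, "tiers? flag")
  if (grepl("<absent>", exists_line$text)) {
    return(textgrid(xmin, xmax, list()))
  }
  size <- as.integer(tg_long_num(cur, "size"))
  tiers <- vector("list", size)
  keep <- logical(size)
  if (identical(tg_peek(cur), "item []:")) tg_next(cur, "item list header")
  for (t in seq_len(size)) {
    if (grepl("^item \\[", tg_peek(cur) %||% "")) tg_next(cur, "item header")
    klass <- tg_unquote(tg_long_value(cur, "class"))
    name <- tg_unquote(tg_long_value(cur, "name"))
    tg_long_num(cur, "xmin")
    tg_long_num(cur, "xmax")
    if (klass == "IntervalTier") {
      n <- as.integer(tg_long_num(cur, "intervals: size"))
      iv <- tibble(xmin = double(n), xmax = double(n), text = character(n))
      for (k in seq_len(n)) {
        if (grepl("^intervals \\[", tg_peek(cur) %||% "")) tg_next(cur, "interval header")
        iv$xmin[k] <- tg_long_num(cur, "xmin")
        iv$xmax[k] <- tg_long_num(cur, "xmax")
        iv$text[k] <- tg_unquote(tg_long_value(cur, "text"))
      }
      tiers[[t]] <- list(name = name, intervals = iv)
      keep[t] <- TRUE
    } else if (klass == "TextTier") {
      n <- as.integer(tg_long_num(cur, "points: size"))
      for (k in seq_len(n)) {
        if (grepl("^points \\[", tg_peek(cur) %||% "")) tg_next(cur, "point header")
        tg_long_num(cur, "number")
        tg_long_value(cur, "mark")
      }
      warn(sprintf("TextGrid: skipping point tier '%s' (only interval tiers are kept)", name))
    } else {
      abort(sprintf("TextGrid parse error: unknown tier class '%s'", klass))
    }
  }
  textgrid(xmin, xmax, tiers[keep])
}

tg_parse_short <- function(cur) {
  xmin <- tg_short_num(cur, "document xmin")
  xmax <- tg_short_num(cur, "document xmax")
  exists_line <- tg_next(cur, "tiers? flag")
  if (grepl("<absent>", exists_line$text)) {
    return(textgrid(xmin, xmax, list()))
  }
  size <- as.integer(tg_short_num(cur, "tier count"))
  tiers <- vector("list", size)
  keep <- logical(size)
  for (t in seq_len(size)) {
    klass <- tg_short_str(cur, "tier class")
    name <- tg_short_str(cur, "tier name")
    tg_short_num(cur, "tier xmin")
    tg_short_num(cur, "tier xmax")
    if (klass == "IntervalTier") {
      n <- as.integer(tg_short_num(cur, "interval count"))
      iv <- tibble(xmin = double(n), xmax = double(n), text = character(n))
      for (k in seq_len(n)) {
        iv$xmin[k] <- tg_short_num(cur, "interval xmin")
        iv$xmax[k] <- tg_short_num(cur, "interval xmax")
        iv$text[k] <- tg_short_str(cur, "interval text")
      }
      tiers[[t]] <- list(name = name, intervals = iv)
      keep[t] <- TRUE
    } else if (klass == "TextTier") {
      n <- as.integer(tg_short_num(cur, "point count"))
      for (k in seq_len(n)) {
        tg_short_num(cur, "point time")
        tg_short_str(cur, "point mark")
      }
      warn(sprintf("TextGrid: skipping point tier '%s' (only interval tiers are kept)", name))
    } else {
      abort(sprintf("TextGrid parse error: unknown tier class '%s'", klass))
    }
  }
  textgrid(xmin, xmax, tiers[keep])
}

#' Read a TextGrid file
#'
#' @param path Path to a UTF-8 TextGrid file (long or short dialect).
#'   UTF-16 exports (detected by their byte-order mark) are refused with a
#'   message asking for transcoding, never silently converted.
#' @return A [textgrid()] object.
#' @export
read_textgrid <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) >= 2 &&
      ((raw[1] == as.raw(0xFF) && raw[2] == as.raw(0xFE)) ||
       (raw[1] == as.raw(0xFE) && raw[2] == as.raw(0xFF)))) {
    abort(sprintf(
      "'%s' is UTF-16 encoded (Praat default export); transcode it to UTF-8 first, e.g. iconv -f UTF-16 -t UTF-8",
      path))
  }
  parse_textgrid(rawToChar(raw))
}

# Serialize a time with enough digits that a write/parse round trip is
# exact to well under 1e-6 s.
tg_fmt <- function(x) sprintf("%.12g", x)

#' Serialize a textgrid to long-dialect text
#'
#' @param doc A valid [textgrid()] object.
#' @param path Optional file path; when given, the text is also written to
#'   the file (UTF-8).
#' @return The TextGrid text as a single string, invisibly when `path` is
#'   given.
#' @export
write_textgrid <- function(doc, path = NULL) {
  validate_textgrid(doc)
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    paste0("xmin = ", tg_fmt(doc$xmin)),
    paste0("xmax = ", tg_fmt(doc$xmax)),
    "tiers? <exists> ",
    paste0("size = ", length(doc$tiers)),
    "item []: "
  )
  for (t in seq_along(doc$tiers)) {
    tier <- doc$tiers[[t]]
    iv <- tier$intervals
    t_xmin <- if (nrow(iv) > 0) iv$xmin[1] else doc$xmin
    t_xmax <- if (nrow(iv) > 0) iv$xmax[nrow(iv)] else doc$xmax
    out <- c(out,
             sprintf("    item [%d]:", t),
             '        class = "IntervalTier" ',
             sprintf('        name = "%s" ', gsub('"', '""', tier$name)),
             paste0("        xmin = ", tg_fmt(t_xmin)),
             paste0("        xmax = ", tg_fmt(t_xmax)),
             paste0("        intervals: size = ", nrow(iv)))
    for (k in seq_len(nrow(iv))) {
      out <- c(out,
               sprintf("        intervals [%d]:", k),
               paste0("            xmin = ", tg_fmt(iv$xmin[k])),
               paste0("            xmax = ", tg_fmt(iv$xmax[k])),
               sprintf('            text = "%s" ', gsub('"', '""', iv$text[k])))
    }
  }
  text <- paste0(paste(out, collapse = "\n"), "\n")
  if (!is.null(path)) {
    writeLines(text, path, useBytes = TRUE, sep = "")
    return(invisible(text))
  }
  text
}

#' Extract boundary annotations from a TextGrid tier
#'
#' Every interval with a non-empty label on the named tier yields two
#' boundary annotations: the word onset at the interval `xmin` and the
#' word offset at the interval `xmax`, converted from seconds to
#' milliseconds. Tokens are identified positionally (interval order within
#' the tier) under a caller-supplied trial id; no label matching is
#' attempted.
#'
#' @param doc A [textgrid()] object.
#' @param tier_name Name of the interval tier holding word segments.
#' @param annotator_id,modality Annotator label and modality
#'   (`"ponss"` or `"baseline"`) stamped onto every emitted record.
#' @param trial_id Trial identifier used to build `token_id`s
#'   (`<trial_id>_w<position>`).
#' @return A tibble of boundary annotations with columns `token_id`,
#'   `trial_id`, `position`, `label`, `annotator_id`, `modality`,
#'   `boundary`, `time_ms`.
#' @export
textgrid_to_annotations <- function(doc, tier_name, annotator_id, modality,
                                    trial_id = "trial1") {
  assert_enum(modality, MODALITY_LEVELS, "modality")
  tier_names <- vapply(doc$tiers, function(t) t$name, character(1))
  idx <- which(tier_names == tier_name)
  if (length(idx) == 0) {
    abort(sprintf("tier '%s' not found; available tiers: %s", tier_name,
                  paste(sprintf("'%s'", tier_names), collapse = ", ")))
  }
  iv <- doc$tiers[[idx[1]]]$intervals
  iv <- iv[nzchar(trimws(iv$text)), , drop = FALSE]
  n <- nrow(iv)
  if (n == 0) {
    return(tibble(token_id = character(), trial_id = character(),
                  position = integer(), label = character(),
                  annotator_id = character(), modality = character(),
                  boundary = character(), time_ms = double()))
  }
  tibble(
    token_id = rep(sprintf("%s_w%d", trial_id, seq_len(n)), each = 2),
    trial_id = trial_id,
    position = rep(seq_len(n), each = 2),
    label = rep(iv$text, each = 2),
    annotator_id = as.character(annotator_id),
    modality = modality,
    boundary = rep(c("onset", "offset"), times = n),
    time_ms = as.double(rbind(iv$xmin, iv$xmax)) * 1000
  )
}
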