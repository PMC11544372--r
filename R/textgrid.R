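# Praat TextGrid reading/writing.
#
# Internally tiers are tibbles of labelled intervals only: silence is
# represented by gaps between intervals, never by empty-label rows. On write,
# gaps are filled with empty-label intervals so the file tiles [xmin, xmax]
# as Praat requires; on read, empty labels are turned back into gaps.

#' Write word and phone tiers to a Praat TextGrid (long text format)
#'
#' @param tiers Named list of interval tibbles (columns `label`, `start`,
#'   `end`), e.g. `list(words = ..., phones = ...)`. Extra columns are
#'   ignored.
#' @param path Output file path.
#' @param xmin,xmax Time domain of the grid; `xmax` defaults to the latest
#'   interval end.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tiers, path, xmin = 0, xmax = NULL) {
  if (is.null(names(tiers)) || any(!nzchar(names(tiers)))) {
    stop_config("tiers must be a named list")
  }
  if (is.null(xmax)) {
    xmax <- max(vapply(tiers, function(t) {
      if (nrow(t)) max(t$end) else xmin
    }, numeric(1)))
  }
  num <- function(x) sprintf("%.17g", x)
  esc <- function(x) gsub('"', '""', x)
  out <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    paste0("xmin = ", num(xmin)),
    paste0("xmax = ", num(xmax)),
    "tiers? <exists>",
    paste0("size = ", length(tiers)),
    "item []:"
  )
  for (i in seq_along(tiers)) {
    tier <- tiers[[i]]
    tier <- tier[order(tier$start), , drop = FALSE]
    # fill gaps with empty-label intervals so intervals tile [xmin, xmax]
    filled <- list()
    cursor <- xmin
    for (j in seq_len(nrow(tier))) {
      if (tier$start[j] > cursor + 1e-12) {
        filled[[length(filled) + 1L]] <- list(xmin = cursor,
                                              xmax = tier$start[j], text = "")
      }
      filled[[length(filled) + 1L]] <- list(xmin = tier$start[j],
                                            xmax = tier$end[j],
                                            text = tier$label[j])
      cursor <- tier$end[j]
    }
    if (cursor < xmax - 1e-12 || length(filled) == 0L) {
      filled[[length(filled) + 1L]] <- list(xmin = cursor, xmax = xmax,
                                            text = "")
    }
    out <- c(out,
             sprintf("    item [%d]:", i),
             '        class = "IntervalTier"',
             sprintf('        name = "%s"', esc(names(tiers)[i])),
             paste0("        xmin = ", num(xmin)),
             paste0("        xmax = ", num(xmax)),
             paste0("        intervals: size = ", length(filled)))
    for (j in seq_along(filled)) {
      iv <- filled[[j]]
      out <- c(out,
               sprintf("        intervals [%d]:", j),
               paste0("            xmin = ", num(iv$xmin)),
               paste0("            xmax = ", num(iv$xmax)),
               sprintf('            text = "%s"', esc(iv$text)))
    }
  }
  writeLines(out, path, useBytes = FALSE)
  invisible(path)
}

# Read all lines of a TextGrid, accepting UTF-8 and UTF-16 (Praat writes
# UTF-16 with a byte-order mark when labels are non-ASCII).
read_textgrid_lines <- function(path) {
  bom <- readBin(path, "raw", n = 2L)
  enc <- if (length(bom) == 2L &&
             ((bom[1] == as.raw(0xFF) && bom[2] == as.raw(0xFE)) ||
              (bom[1] == as.raw(0xFE) && bom[2] == as.raw(0xFF)))) {
    "UTF-16"
  } else {
    "UTF-8"
  }
  con <- file(path, encoding = enc)
  on.exit(close(con))
  readLines(con, warn = FALSE)
}

#' Read a Praat TextGrid into word and phone tiers
#'
#' Accepts the long (default) text format and the short format. The file
#' must contain at least two interval tiers whose names identify them as the
#' word and the phone tier (names matching `word` and `phone`/`phoneme`,
#' case-insensitively). Empty-label intervals are treated as silence and
#' returned as gaps, not as intervals; zero-length intervals are dropped
#' with a warning.
#'
#' @param path TextGrid file path.
#' @param vowel_categories Phone labels to flag as target vowels.
#' @return List with `words` (tibble `label`, `start`, `end`) and `phones`
#'   (tibble `label`, `start`, `end`, `is_target_vowel`, `vowel_category`,
#'   `parent_word`, where `parent_word` indexes the word tier row containing
#'   the phone, by midpoint, or `NA`).
#' @export
read_textgrid <- function(path, vowel_categories = vowel_inventory()$categories) {
  lines <- read_textgrid_lines(path)
  tiers <- if (any(grepl("^\\s*item\\s*\\[", lines))) {
    parse_textgrid_long(lines)
  } else {
    parse_textgrid_short(lines)
  }
  if (length(tiers) < 2L) {
    stop_config("TextGrid must contain at least two interval tiers")
  }
  nm <- tolower(vapply(tiers, function(t) t$name, character(1)))
  wi <- grep("word", nm)
  pi <- grep("phone", nm)
  if (length(wi) != 1L || length(pi) != 1L) {
    stop_config("cannot identify word/phone tiers among names: %s",
                paste(nm, collapse = ", "))
  }
  clean <- function(tb, what) {
    zero <- tb$end <= tb$start
    if (any(zero)) {
      warning(sprintf("dropped %d zero-length interval(s) from %s tier",
                      sum(zero), what), call. = FALSE)
      tb <- tb[!zero, , drop = FALSE]
    }
    tb <- tb[nzchar(trimws(tb$label)), , drop = FALSE]
    tb[order(tb$start), , drop = FALSE]
  }
  words <- clean(tiers[[wi]]$intervals, "word")
  phones <- clean(tiers[[pi]]$intervals, "phone")
  mid <- (phones$start + phones$end) / 2
  parent <- vapply(mid, function(m) {
    hit <- which(words$start <= m & m < words$end)
    if (length(hit)) hit[1] else NA_integer_
  }, integer(1))
  phones$is_target_vowel <- phones$label %in% vowel_categories
  phones$vowel_category <- ifelse(phones$is_target_vowel, phones$label,
                                  NA_character_)
  phones$parent_word <- parent
  list(words = tibble::as_tibble(words), phones = tibble::as_tibble(phones))
}

tg_num <- function(x, line_no) {
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) {
    stop_config("malformed TextGrid: expected a number at line %d", line_no)
  }
  v
}

tg_unquote <- function(x) {
  gsub('""', '"', sub('^"', "", sub('"$', "", trimws(x))))
}

parse_textgrid_long <- function(lines) {
  tiers <- list()
  cur <- NULL
  iv <- NULL
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (grepl("^class\\s*=", ln)) {
      if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- finish_tier(cur, iv)
      cls <- tg_unquote(sub("^class\\s*=\\s*", "", ln))
      cur <- list(class = cls, name = "", rows = list())
      iv <- NULL
      if (cls != "IntervalTier") {
        stop_config("unsupported tier class '%s' at line %d", cls, i)
      }
    } else if (!is.null(cur) && grepl("^name\\s*=", ln)) {
      cur$name <- tg_unquote(sub("^name\\s*=\\s*", "", ln))
    } else if (!is.null(cur) && grepl("^intervals\\s*\\[", ln)) {
      if (!is.null(iv)) cur$rows[[length(cur$rows) + 1L]] <- iv
      iv <- list()
    } else if (!is.null(iv) && grepl("^xmin\\s*=", ln)) {
      iv$start <- tg_num(sub("^xmin\\s*=\\s*", "", ln), i)
    } else if (!is.null(iv) && grepl("^xmax\\s*=", ln)) {
      iv$end <- tg_num(sub("^xmax\\s*=\\s*", "", ln), i)
    } else if (!is.null(iv) && grepl("^text\\s*=", ln)) {
      iv$label <- tg_unquote(sub("^text\\s*=\\s*", "", ln))
      cur$rows[[length(cur$rows) + 1L]] <- iv
      iv <- NULL
    }
  }
  if (!is.null(cur)) tiers[[length(tiers) + 1L]] <- finish_tier(cur, iv)
  tiers
}

finish_tier <- function(cur, iv) {
  if (!is.null(iv) && !is.null(iv$label)) {
    cur$rows[[length(cur$rows) + 1L]] <- iv
  }
  rows <- cur$rows
  if (length(rows)) {
    intervals <- tibble::tibble(
      label = vapply(rows, function(r) r$label %||% "", character(1)),
      start = vapply(rows, function(r) r$start, numeric(1)),
      end = vapply(rows, function(r) r$end, numeric(1))
    )
  } else {
    intervals <- tibble::tibble(label = character(0), start = numeric(0),
                                end = numeric(0))
  }
  list(name = cur$name, intervals = intervals)
}

parse_textgrid_short <- function(lines) {
  # short format: header lines then a flat sequence of values
  vals <- trimws(lines)
  vals <- vals[nzchar(vals)]
  if (length(vals) < 6 || !grepl("ooTextFile", vals[1])) {
    stop_config("malformed TextGrid: missing ooTextFile header at line 1")
  }
  idx <- 3L  # skip file type and object class
  take <- function() {
    v <- vals[idx]
    idx <<- idx + 1L
    v
  }
  take(); take()                       # global xmin, xmax
  take()                               # <exists>
  n_tiers <- tg_num(take(), idx - 1L)
  tiers <- vector("list", n_tiers)
  for (k in seq_len(n_tiers)) {
    cls <- tg_unquote(take())
    if (cls != "IntervalTier") {
      stop_config("unsupported tier class '%s' at line %d", cls, idx - 1L)
    }
    name <- tg_unquote(take())
    take(); take()                     # tier xmin, xmax
    n_int <- tg_num(take(), idx - 1L)
    start <- end <- numeric(n_int)
    label <- character(n_int)
    for (j in seq_len(n_int)) {
      start[j] <- tg_num(take(), idx - 1L)
      end[j] <- tg_num(take(), idx - 1L)
      label[j] <- tg_unquote(take())
    }
    tiers[[k]] <- list(name = name,
                       intervals = tibble::tibble(label = label,
                                                  start = start, end = end))
  }
  tiers
}
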