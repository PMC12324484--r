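# Minimal CIF reader/writer for the two dictionary dialects used here
# (CCD chem_comp component entries and monomer-library restraint blocks).
# Supported grammar: one or more data_ blocks, key-value items, loop_
# constructs, '...'/"..." quoted values, '#' comments, '.'/'?' as missing.
# Multi-line ';' text fields are not part of either dialect and raise an
# error if encountered.

cif_tokenize <- function(text) {
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  toks <- character(0)
  for (ln in lines) {
    if (startsWith(trimws(ln), ";")) {
      stop("unsupported CIF construct: multi-line ';' text field")
    }
    pos <- 1L
    n <- nchar(ln)
    while (pos <= n) {
      ch <- substr(ln, pos, pos)
      if (ch %in% c(" ", "\t")) {
        pos <- pos + 1L
      } else if (ch == "#") {
        break
      } else if (ch %in% c("'", '"')) {
        rest <- substr(ln, pos + 1L, n)
        end <- regexpr(ch, rest, fixed = TRUE)
        if (end < 0) stop("unterminated quoted value in CIF line: ", ln)
        toks <- c(toks, paste0("\x01", substr(rest, 1L, end - 1L)))
        pos <- pos + end + 1L
      } else {
        rest <- substr(ln, pos, n)
        m <- regexpr("^[^ \t]+", rest)
        tok <- regmatches(rest, m)
        toks <- c(toks, tok)
        pos <- pos + attr(m, "match.length")
      }
    }
  }
  toks
}

cif_untag <- function(tok) {
  # strip the quoted-value marker; map CIF missing markers to NA
  if (startsWith(tok, "\x01")) return(substring(tok, 2L))
  if (tok %in% c(".", "?")) return(NA_character_)
  tok
}

is_reserved <- function(tok) {
  !startsWith(tok, "\x01") &&
    (startsWith(tok, "_") || startsWith(tolower(tok), "data_") ||
       tolower(tok) == "loop_")
}

#' Parse a CIF document into data blocks
#'
#' Returns a list of blocks; each block is a list with `name` (the text after
#' `data_`), `items` (named character vector of scalar key-value pairs) and
#' `loops` (list of data.frames, one per `loop_`, columns named by tags).
#' Quoted values are unescaped; `.` and `?` become `NA`.
#'
#' @param text CIF document as a single string or character vector of lines.
#' @return list of block lists.
#' @keywords internal
#' @noRd
cif_parse <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  toks <- cif_tokenize(text)
  blocks <- list()
  blk <- NULL
  i <- 1L
  n <- length(toks)
  while (i <= n) {
    tok <- toks[i]
    if (!startsWith(tok, "\x01") && startsWith(tolower(tok), "data_")) {
      if (!is.null(blk)) blocks[[length(blocks) + 1L]] <- blk
      blk <- list(name = substring(tok, 6L), items = list(), loops = list())
      i <- i + 1L
    } else if (is.null(blk)) {
      stop("malformed CIF: content before any data_ block near '", tok, "'")
    } else if (!startsWith(tok, "\x01") && tolower(tok) == "loop_") {
      i <- i + 1L
      tags <- character(0)
      while (i <= n && !startsWith(toks[i], "\x01") && startsWith(toks[i], "_")) {
        tags <- c(tags, toks[i])
        i <- i + 1L
      }
      if (length(tags) == 0L) stop("malformed CIF: loop_ with no tags")
      vals <- character(0)
      while (i <= n && !is_reserved(toks[i])) {
        vals <- c(vals, cif_untag(toks[i]))
        i <- i + 1L
      }
      if (length(vals) %% length(tags) != 0L) {
        stop("malformed CIF: loop '", tags[1],
             "' has a row count that does not divide its tag count")
      }
      m <- matrix(vals, ncol = length(tags), byrow = TRUE)
      df <- as.data.frame(m, stringsAsFactors = FALSE)
      names(df) <- tags
      blk$loops[[length(blk$loops) + 1L]] <- df
    } else if (!startsWith(tok, "\x01") && startsWith(tok, "_")) {
      if (i + 1L > n || is_reserved(toks[i + 1L])) {
        stop("malformed CIF: tag '", tok, "' has no value")
      }
      blk$items[[tok]] <- cif_untag(toks[i + 1L])
      i <- i + 2L
    } else {
      stop("malformed CIF: unexpected token '", cif_untag(tok), "'")
    }
  }
  if (!is.null(blk)) blocks[[length(blocks) + 1L]] <- blk
  blocks
}

cif_quote <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return(".")
    if (v == "" || grepl("[ \t']", v) || grepl("^[_#$\\[\\]]", v) ||
        tolower(v) %in% c("loop_", "stop_", "global_") ||
        startsWith(tolower(v), "data_")) {
      if (grepl("'", v, fixed = TRUE)) return(paste0('"', v, '"'))
      return(paste0("'", v, "'"))
    }
    v
  }, character(1), USE.NAMES = FALSE)
}

# numbers are serialised with 9 significant digits: enough that a
# write -> read -> write cycle is byte-stable
cif_num <- function(x) {
  ifelse(is.na(x), ".", sprintf("%.9g", x))
}

cif_write_block <- function(name, items, loops) {
  out <- c(paste0("data_", name))
  if (length(items)) {
    w <- max(nchar(names(items))) + 3L
    out <- c(out, sprintf("%-*s%s", w, names(items), cif_quote(unlist(items))))
  }
  for (df in loops) {
    out <- c(out, "loop_", names(df))
    if (nrow(df)) {
      cols <- lapply(df, function(col) {
        q <- cif_quote(as.character(col))
        formatC(q, width = max(nchar(q)), flag = "-")
      })
      out <- c(out, trimws(do.call(paste, cols), which = "right"))
    }
    out <- c(out, "")
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
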