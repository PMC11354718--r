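#' @name toml
#' @title Minimal TOML subset reader/writer
#' @description
#' The scene configuration schema only needs tables and scalar key/value
#' pairs (strings, numbers, booleans), so a compact TOML subset is parsed
#' here directly. Arrays of scalars are supported; nested inline tables,
#' dates and multi-line strings are not. Numbers are written with 17
#' significant digits so that write/read round-trips are bit-stable.
#' @keywords internal
NULL

parse_toml <- function(path) {
  lines <- readLines(path, warn = FALSE)
  out <- list()
  table_path <- character(0)
  for (ln in seq_along(lines)) {
    line <- strip_toml_comment(lines[[ln]])
    line <- trimws(line)
    if (!nzchar(line)) next
    if (grepl("^\\[[^]]+\\]$", line)) {
      table_path <- strsplit(gsub("^\\[|\\]$", "", line), ".", fixed = TRUE)[[1]]
      table_path <- trimws(table_path)
      next
    }
    m <- regmatches(line, regexec("^([A-Za-z0-9_.-]+)\\s*=\\s*(.+)$", line))[[1]]
    if (length(m) != 3) {
      stop(sprintf("TOML parse error at line %d: '%s'", ln, line), call. = FALSE)
    }
    out <- toml_assign(out, c(table_path, m[[2]]), parse_toml_value(m[[3]], ln))
  }
  out
}

strip_toml_comment <- function(line) {
  in_str <- FALSE
  chars <- strsplit(line, "", fixed = TRUE)[[1]]
  for (i in seq_along(chars)) {
    if (chars[[i]] == '"') in_str <- !in_str
    if (chars[[i]] == "#" && !in_str) return(substr(line, 1, i - 1))
  }
  line
}

parse_toml_value <- function(txt, ln = NA) {
  txt <- trimws(txt)
  if (grepl("^\\[.*\\]$", txt)) {
    inner <- trimws(gsub("^\\[|\\]$", "", txt))
    if (!nzchar(inner)) return(list())
    parts <- trimws(strsplit(inner, ",")[[1]])
    vals <- lapply(parts, parse_toml_value)
    return(unlist(vals))
  }
  if (grepl('^".*"$', txt)) return(gsub('^"|"$', "", txt))
  if (txt %in% c("true", "false")) return(txt == "true")
  num <- suppressWarnings(as.numeric(txt))
  if (!is.na(num)) return(num)
  stop(sprintf("TOML parse error at line %s: cannot interpret value '%s'", ln, txt),
       call. = FALSE)
}

toml_assign <- function(x, path, value) {
  if (length(path) == 1) {
    x[[path]] <- value
    return(x)
  }
  head <- path[[1]]
  if (is.null(x[[head]])) x[[head]] <- list()
  x[[head]] <- toml_assign(x[[head]], path[-1], value)
  x
}

format_toml_value <- function(v) {
  fmt1 <- function(x) {
    if (is.character(x)) return(sprintf('"%s"', x))
    if (is.logical(x)) return(if (x) "true" else "false")
    if (x == trunc(x) && abs(x) < 1e15) return(sprintf("%.0f", x))
    sprintf("%.17g", x)
  }
  if (length(v) > 1) {
    return(sprintf("[%s]", paste(vapply(v, fmt1, character(1)), collapse = ", ")))
  }
  fmt1(v)
}

write_toml <- function(x, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  emit <- function(tbl, prefix) {
    scalars <- Filter(function(nm) !is.list(tbl[[nm]]), names(tbl))
    tables <- Filter(function(nm) is.list(tbl[[nm]]), names(tbl))
    if (length(prefix) > 0 && (length(scalars) > 0 || length(tables) == 0)) {
      writeLines(sprintf("[%s]", paste(prefix, collapse = ".")), con)
    }
    for (nm in scalars) {
      writeLines(sprintf("%s = %s", nm, format_toml_value(tbl[[nm]])), con)
    }
    if (length(scalars) > 0 || length(prefix) == 0) writeLines("", con)
    for (nm in tables) emit(tbl[[nm]], c(prefix, nm))
  }
  emit(x, character(0))
  invisible(path)
}
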