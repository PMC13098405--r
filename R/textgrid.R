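#' Write interval tiers to a Praat TextGrid (long format)
#'
#' @param tiers Named list of data frames, each with columns `tmin`, `tmax`,
#'   `label`. Intervals must be ordered and non-overlapping within a tier;
#'   gaps are written as empty-label intervals so every tier tiles
#'   `[0, duration]`, as Praat requires.
#' @param path Output path.
#' @param duration Total duration in seconds; defaults to the largest `tmax`.
#' @return `path`, invisibly.
#' @export
write_textgrid <- function(tiers, path, duration = NULL) {
  stopifnot(is.list(tiers), length(tiers) > 0, !is.null(names(tiers)))
  for (nm in names(tiers)) {
    tier <- tiers[[nm]]
    assert_cols(tier, c("tmin", "tmax", "label"), sprintf("tier '%s'", nm))
    if (any(tier$tmax < tier$tmin)) stopf("tier '%s': negative durations", nm)
    if (nrow(tier) > 1 && any(diff(tier$tmin) < 0)) stopf("tier '%s': unordered", nm)
  }
  duration <- duration %||% max(vapply(tiers, function(t) max(t$tmax, 0), 0))
  fmt <- function(x) sprintf("%.10g", x)
  lines <- c(
    'File type = "ooTextFile"',
    'Object class = "TextGrid"',
    "",
    "xmin = 0",
    paste0("xmax = ", fmt(duration)),
    "tiers? <exists>",
    paste0("size = ", length(tiers)),
    "item []:"
  )
  for (i in seq_along(tiers)) {
    tier <- tiers[[i]]
    ## fill gaps with empty intervals so the tier tiles [0, duration]
    full <- tile_tier(tier, duration)
    lines <- c(lines,
      sprintf("    item [%d]:", i),
      '        class = "IntervalTier"',
      sprintf('        name = "%s"', names(tiers)[i]),
      "        xmin = 0",
      paste0("        xmax = ", fmt(duration)),
      paste0("        intervals: size = ", nrow(full)))
    for (j in seq_len(nrow(full))) {
      lines <- c(lines,
        sprintf("        intervals [%d]:", j),
        paste0("            xmin = ", fmt(full$tmin[j])),
        paste0("            xmax = ", fmt(full$tmax[j])),
        sprintf('            text = "%s"', gsub('"', '""', full$label[j])))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

tile_tier <- function(tier, duration) {
  if (!nrow(tier)) {
    return(data.frame(tmin = 0, tmax = duration, label = "",
                      stringsAsFactors = FALSE))
  }
  out <- list()
  cursor <- 0
  for (j in seq_len(nrow(tier))) {
    if (tier$tmin[j] > cursor + 1e-12) {
      out[[length(out) + 1]] <- data.frame(tmin = cursor, tmax = tier$tmin[j],
                                           label = "", stringsAsFactors = FALSE)
    }
    out[[length(out) + 1]] <- tier[j, c("tmin", "tmax", "label")]
    cursor <- tier$tmax[j]
  }
  if (cursor < duration - 1e-12) {
    out[[length(out) + 1]] <- data.frame(tmin = cursor, tmax = duration,
                                         label = "", stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read a Praat TextGrid (long or short format)
#'
#' Empty-label intervals (silences) are dropped; only labelled intervals are
#' returned, matching the interval sets handed to [write_textgrid()].
#'
#' @param path TextGrid file path.
#' @param keep_empty Keep empty-label intervals? Default `FALSE`.
#' @return Named list of tiers (data frames `tmin`, `tmax`, `label`), with
#'   attribute `duration`.
#' @export
read_textgrid <- function(path, keep_empty = FALSE) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  long <- any(grepl("item *\\[", lines))
  tiers <- if (long) parse_textgrid_long(lines) else parse_textgrid_short(lines)
  duration <- attr(tiers, "duration")
  if (!keep_empty) {
    tiers[] <- lapply(tiers, function(t) {
      t <- t[nzchar(t$label), , drop = FALSE]
      rownames(t) <- NULL
      t
    })
  }
  attr(tiers, "duration") <- duration
  tiers
}

tg_num <- function(line) as.numeric(sub(".*= *", "", line))
tg_str <- function(line) {
  m <- regmatches(line, regexpr('"(?:[^"]|"")*"', line))
  if (!length(m)) return("")
  gsub('""', '"', substr(m, 2, nchar(m) - 1))
}

parse_textgrid_long <- function(lines) {
  duration <- tg_num(grep("^ *xmax", lines, value = TRUE)[1])
  item_starts <- grep("item *\\[[0-9]+\\]", lines)
  tiers <- list()
  bounds <- c(item_starts, length(lines) + 1)
  for (i in seq_along(item_starts)) {
    chunk <- lines[bounds[i]:(bounds[i + 1] - 1)]
    if (!any(grepl("IntervalTier", chunk))) next
    name <- tg_str(grep("name *=", chunk, value = TRUE)[1])
    xmins <- tg_num_all(chunk, "xmin")[-1]  # first xmin/xmax are the tier's
    xmaxs <- tg_num_all(chunk, "xmax")[-1]
    texts <- vapply(grep("text *=", chunk, value = TRUE), tg_str, "")
    tiers[[name]] <- data.frame(tmin = xmins, tmax = xmaxs,
                                label = unname(texts), stringsAsFactors = FALSE)
  }
  attr(tiers, "duration") <- duration
  tiers
}

tg_num_all <- function(chunk, key) {
  vapply(grep(paste0(key, " *="), chunk, value = TRUE), tg_num, 0, USE.NAMES = FALSE)
}

parse_textgrid_short <- function(lines) {
  ## short format: after the 2 header lines and a blank, a stream of tokens
  toks <- lines[nzchar(trimws(lines))][-(1:2)]
  i <- 1
  take <- function() { v <- toks[i]; i <<- i + 1; v }
  xmin <- as.numeric(take()); duration <- as.numeric(take())
  flag <- take()  # <exists>
  n_tiers <- as.numeric(take())
  tiers <- list()
  for (t in seq_len(n_tiers)) {
    cls <- tg_str(take())
    name <- tg_str(take())
    t_min <- as.numeric(take()); t_max <- as.numeric(take())
    n_int <- as.numeric(take())
    tmin <- tmax <- numeric(n_int); lab <- character(n_int)
    for (j in seq_len(n_int)) {
      tmin[j] <- as.numeric(take()); tmax[j] <- as.numeric(take())
      lab[j] <- tg_str(take())
    }
    tiers[[name]] <- data.frame(tmin = tmin, tmax = tmax, label = lab,
                                stringsAsFactors = FALSE)
  }
  attr(tiers, "duration") <- duration
  tiers
}
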