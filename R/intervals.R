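# Half-open interval arithmetic on [start, end) in Mb.  All region and
# segment bookkeeping in the package goes through these helpers so the
# tiling/union/complement conventions are defined in exactly one place.

# Merge overlapping or touching intervals.  `df` has columns start, end and
# optionally `founders` (character; merged by set union, "|"-free sorted
# concatenation like "DG").
merge_intervals <- function(df) {
  if (nrow(df) == 0L) return(df)
  df <- df[order(df$start, df$end), , drop = FALSE]
  has_f <- "founders" %in% names(df)
  out_s <- df$start[1]; out_e <- df$end[1]
  out_f <- if (has_f) df$founders[1] else NA_character_
  res <- list()
  push <- function() {
    res[[length(res) + 1L]] <<- list(start = out_s, end = out_e, founders = out_f)
  }
  if (nrow(df) > 1L) for (i in 2:nrow(df)) {
    if (df$start[i] <= out_e) {
      out_e <- max(out_e, df$end[i])
      if (has_f) out_f <- founder_union(out_f, df$founders[i])
    } else {
      push()
      out_s <- df$start[i]; out_e <- df$end[i]
      out_f <- if (has_f) df$founders[i] else NA_character_
    }
  }
  push()
  out <- data.frame(start = vapply(res, `[[`, 0, "start"),
                    end = vapply(res, `[[`, 0, "end"),
                    stringsAsFactors = FALSE)
  if (has_f) out$founders <- vapply(res, `[[`, "", "founders")
  out
}

# Sorted concatenation of founder-letter sets given as strings ("BD", "DG").
founder_union <- function(...) {
  letters8 <- unique(unlist(strsplit(c(...), "", fixed = TRUE)))
  paste(sort(letters8), collapse = "")
}

# Complement of a set of intervals within [0, len).
complement_intervals <- function(df, len) {
  if (nrow(df) == 0L)
    return(data.frame(start = 0, end = len))
  m <- merge_intervals(df[, c("start", "end"), drop = FALSE])
  starts <- c(0, m$end)
  ends <- c(m$start, len)
  keep <- ends > starts
  data.frame(start = starts[keep], end = ends[keep])
}

# Total length of a set of (possibly overlapping) intervals.
interval_length <- function(df) {
  if (nrow(df) == 0L) return(0)
  m <- merge_intervals(df[, c("start", "end"), drop = FALSE])
  sum(m$end - m$start)
}

# Cut points -> atomic intervals: given a sorted unique breakpoint vector
# including 0 and len, return data.frame(start, end) of consecutive pieces.
atomic_intervals <- function(breaks) {
  breaks <- sort(unique(breaks))
  n <- length(breaks)
  if (n < 2L) return(data.frame(start = numeric(0), end = numeric(0)))
  data.frame(start = breaks[-n], end = breaks[-1])
}

# Value of a piecewise-constant track (data.frame start,end,<value col>) at
# positions `pos` (vector).  Intervals are half-open; positions must fall in
# [min(start), max(end)).  Returns the value column entries.
track_at <- function(track, pos, value_col) {
  idx <- findInterval(pos, track$start)
  idx[idx < 1L] <- 1L
  track[[value_col]][idx]
}
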