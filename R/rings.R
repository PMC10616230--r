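## Ring-width data: Tucson/rwl and long-CSV readers and writers, conversion
## of widths to basal area increments, juvenile-ring filtering, and site
## structure summaries.

#' Create a ring-width series
#'
#' @param tree_id,site_id,species Identifiers.
#' @param first_year Calendar year of the innermost measured ring.
#' @param widths Ring widths in mm, innermost first; all > 0, contiguous years.
#' @return A `ring_series` object.
#' @export
ring_series <- function(tree_id, site_id = NA_character_,
                        species = NA_character_, first_year, widths) {
  if (length(widths) < 1) stop_config("series '%s' has no rings", tree_id)
  if (any(!is.finite(widths) | widths <= 0))
    stop_config("series '%s': widths must be positive", tree_id)
  structure(list(tree_id = as.character(tree_id),
                 site_id = as.character(site_id),
                 species = as.character(species),
                 first_year = as.integer(first_year),
                 last_year = as.integer(first_year) + length(widths) - 1L,
                 widths = as.numeric(widths)),
            class = "ring_series")
}

#' @export
print.ring_series <- function(x, ...) {
  cat(sprintf("<ring_series %s> site %s, %s, %d-%d (%d rings)\n",
              x$tree_id, x$site_id, x$species, x$first_year, x$last_year,
              length(x$widths)))
  invisible(x)
}

#' Write ring series to a Tucson (rwl) file
#'
#' Decade-formatted Tucson output. The dialect is chosen by `precision`:
#' 0.01 mm uses the stop marker 999, 0.001 mm uses -9999.
#'
#' @param series_list List of `ring_series`.
#' @param path Output file.
#' @param precision Width quantum in mm: 0.01 or 0.001.
#' @export
write_rwl <- function(series_list, path, precision = 0.001) {
  if (length(series_list) == 0) stop_config("no series to write")
  if (!precision %in% c(0.01, 0.001))
    stop_config("precision must be 0.01 or 0.001 mm")
  stop_marker <- if (precision == 0.01) 999L else -9999L
  con <- file(path, "w")
  on.exit(close(con))
  for (s in series_list) {
    vals <- as.integer(round(s$widths / precision))
    if (any(vals >= 100000L) || any(vals == stop_marker))
      stop_config("series '%s': width too large for rwl dialect", s$tree_id)
    years <- s$first_year:s$last_year
    tokens <- c(vals, stop_marker)
    tok_year <- c(years, s$last_year + 1L)
    i <- 1L
    while (i <= length(tokens)) {
      y <- tok_year[i]
      n_row <- 10L - (y %% 10L)  # fill to the next decade boundary
      idx <- i:min(i + n_row - 1L, length(tokens))
      writeLines(sprintf("%-8s%4d%s", substr(s$tree_id, 1, 8), y,
                         paste(sprintf("%6d", tokens[idx]), collapse = "")),
                 con)
      i <- idx[length(idx)] + 1L
    }
  }
  invisible(path)
}

#' Read a Tucson (rwl) ring-width file
#'
#' The precision dialect is auto-detected from the stop marker: 999 implies
#' 0.01 mm, -9999 implies 0.001 mm.
#'
#' @param path Path to an rwl file.
#' @param site_id,species Optional metadata attached to every series.
#' @return List of `ring_series`. An empty file yields an empty list with a
#'   warning.
#' @export
read_rwl <- function(path, site_id = NA_character_, species = NA_character_) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    warning("empty rwl file: ", path, call. = FALSE)
    return(list())
  }
  acc <- list()  # per id: list(first_year, vals, closed)
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    id <- trimws(substr(line, 1, 8))
    rest <- strsplit(trimws(substr(line, 9, nchar(line))), "\\s+")[[1]]
    if (length(rest) < 2)
      stop_config("malformed decade row at line %d", ln)
    year <- suppressWarnings(as.integer(rest[1]))
    vals <- suppressWarnings(as.integer(rest[-1]))
    if (is.na(year) || any(is.na(vals)))
      stop_config("malformed decade row at line %d", ln)
    if (is.null(acc[[id]])) {
      acc[[id]] <- list(first_year = year, vals = integer(), closed = FALSE,
                        next_year = year)
    } else {
      if (acc[[id]]$closed)
        stop_config("duplicate series ID '%s' at line %d", id, ln)
      if (year != acc[[id]]$next_year)
        stop_config("non-contiguous decade row for '%s' at line %d", id, ln)
    }
    acc[[id]]$vals <- c(acc[[id]]$vals, vals)
    acc[[id]]$next_year <- year + length(vals)
    if (vals[length(vals)] %in% c(999L, -9999L)) acc[[id]]$closed <- TRUE
  }
  out <- list()
  for (id in names(acc)) {
    a <- acc[[id]]
    vals <- a$vals
    marker <- vals[length(vals)]
    precision <- if (!a$closed) 0.01
    else if (marker == 999L) 0.01 else 0.001
    if (a$closed) vals <- vals[-length(vals)]
    out[[id]] <- ring_series(id, site_id, species, a$first_year,
                             vals * precision)
  }
  unname(out)
}

#' Read ring widths from a long-format CSV
#'
#' Expects columns `tree_id, site_id, species, year, width_mm`.
#'
#' @param path CSV path.
#' @return List of `ring_series`.
#' @export
read_rings_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("tree_id", "site_id", "species", "year", "width_mm")
  if (!all(need %in% names(d)))
    stop_config("ring CSV must have columns %s", paste(need, collapse = ", "))
  lapply(split(d, d$tree_id), function(g) {
    g <- g[order(g$year), ]
    if (any(diff(g$year) != 1))
      stop_config("series '%s': non-contiguous years", g$tree_id[1])
    ring_series(g$tree_id[1], g$site_id[1], g$species[1], g$year[1], g$width_mm)
  }) |> unname()
}

#' Convert ring widths to basal area increments
#'
#' Radii are accumulated from the innermost ring (optionally offset by a
#' missing-pith radius), and the basal area increment of year t is the
#' annulus area `BAI_t = pi * (R_t^2 - R_{t-1}^2)`. Widths are mm, radii cm,
#' areas cm^2. Age counts rings from the innermost measured ring (minimum
#' age), starting at 1.
#'
#' @param series A `ring_series`.
#' @param pith_offset_cm Radius already present inside the innermost ring
#'   (default 0).
#' @return A `bai_series`: data frame with `tree_id`, `site_id`, `species`,
#'   `year`, `age`, `bai` (cm^2), `ba_prev` (cm^2, basal area at the start of
#'   the year), plus attribute `excluded` (FALSE here).
#' @export
widths_to_bai <- function(series, pith_offset_cm = 0) {
  stopifnot(inherits(series, "ring_series"))
  r <- pith_offset_cm + cumsum(series$widths) / 10  # mm -> cm
  r_prev <- c(pith_offset_cm, r[-length(r)])
  out <- data.frame(tree_id = series$tree_id, site_id = series$site_id,
                    species = series$species,
                    year = series$first_year:series$last_year,
                    age = seq_along(series$widths),
                    bai = pi * (r^2 - r_prev^2),
                    ba_prev = pi * r_prev^2)
  class(out) <- c("bai_series", "data.frame")
  attr(out, "excluded") <- FALSE
  out
}

#' Drop juvenile rings from a BAI series
#'
#' Removes the first `n_exclude` rings (default 10): rings formed in a
#' tree's first years reflect overstory competition more than climate. Ages
#' and cumulative basal area are kept relative to the innermost measured
#' ring, so `ba_prev` still includes the juvenile wood. Trees left with
#' fewer than `min_years` rings are flagged excluded (attribute `excluded`
#' with a `reason`), not dropped silently.
#'
#' @param bai A `bai_series`.
#' @param n_exclude Rings to drop (default 10).
#' @param min_years Minimum retained rings to keep the tree (default 25).
#' @return Filtered `bai_series` (possibly zero rows) with attributes
#'   `excluded` and `reason`.
#' @export
apply_juvenile_filter <- function(bai, n_exclude = 10, min_years = 25) {
  stopifnot(inherits(bai, "bai_series"), n_exclude >= 0)
  keep <- bai$age > n_exclude
  out <- bai[keep, , drop = FALSE]
  class(out) <- c("bai_series", "data.frame")
  if (nrow(out) < min_years) {
    attr(out, "excluded") <- TRUE
    attr(out, "reason") <- "insufficient rings"
  } else {
    attr(out, "excluded") <- FALSE
  }
  out
}

#' Per-site forest structure summaries
#'
#' Mean tree age (ring counts from the innermost measured ring) and mean
#' basal area (final cumulative `pi R^2`) per site and species: the two
#' forest-structure predictors used downstream.
#'
#' @param bai_list List of `bai_series` (post-filter; excluded trees are
#'   skipped).
#' @return Data frame: `site_id`, `species`, `n_trees`, `mean_age` (yr),
#'   `mean_ba` (cm^2).
#' @export
site_summary <- function(bai_list) {
  rows <- lapply(bai_list, function(b) {
    if (isTRUE(attr(b, "excluded")) || nrow(b) == 0) return(NULL)
    last <- b[nrow(b), ]
    data.frame(site_id = last$site_id, species = last$species,
               age = last$age, ba = last$ba_prev + last$bai)
  })
  d <- do.call(rbind, rows)
  if (is.null(d)) stop_config("no retained trees to summarize")
  agg <- aggregate(cbind(age, ba) ~ site_id + species, data = d, FUN = mean)
  n <- aggregate(age ~ site_id + species, data = d, FUN = length)
  out <- merge(agg, n, by = c("site_id", "species"),
               suffixes = c("", "_n"))
  data.frame(site_id = out$site_id, species = out$species,
             n_trees = out$age_n, mean_age = out$age, mean_ba = out$ba)
}

#' Flatten ring series to a long data frame
#' @param series_list List of `ring_series`.
#' @return Data frame `tree_id, site_id, species, year, width_mm`.
#' @export
rings_to_long <- function(series_list) {
  do.call(rbind, lapply(series_list, function(s)
    data.frame(tree_id = s$tree_id, site_id = s$site_id, species = s$species,
               year = s$first_year:s$last_year, width_mm = s$widths)))
}
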