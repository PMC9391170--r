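#' Severity-band labels
#'
#' The seven ordered bands locating a laboratory measurement relative to its
#' reference range, from most depressed to most elevated. Band four
#' (`"normal"`) is the reference interval itself.
#'
#' @format Character vector of length 7.
#' @export
BAND_LABELS <- c(
  "severely_low", "generally_low", "slightly_low", "normal",
  "slightly_high", "generally_high", "severely_high"
)

SPECIAL_ENTITIES <- c("<UNK>", "<HIGHEST>", "<LOWEST>")

#' Reference range of a laboratory indicator
#'
#' Describes the clinically normal interval of one analyte together with the
#' discretization policy used to turn the continuous measurement axis into a
#' finite grid of value entities.
#'
#' @param indicator Name of the indicator (e.g. `"triglycerides"`).
#' @param low,high Lower and upper bounds of the normal interval, in the
#'   analyte's units; `low < high` is required.
#' @param units Unit string (e.g. `"mmol/L"`); may be empty.
#' @param grid_step Spacing of the value grid. Defaults to one hundredth of
#'   the range width, rounded to the decimal precision at which `low`/`high`
#'   are stated (never finer than that precision allows).
#' @param span_factor How many range-widths the grid extends beyond
#'   `[low, high]` on each side. Default 1.
#' @param nonnegative Clamp the grid at zero? Laboratory analytes are
#'   concentrations or activities and cannot be negative, so the default is
#'   `TRUE`; set `FALSE` for signed quantities.
#'
#' @return An object of class `"reference_range"`.
#' @examples
#' reference_range("triglycerides", 0.45, 1.81, "mmol/L")
#' @export
reference_range <- function(indicator, low, high, units = "",
                            grid_step = NULL, span_factor = 1,
                            nonnegative = TRUE) {
  stopifnot(is.character(indicator), length(indicator) == 1L, nzchar(indicator))
  if (!is.finite(low) || !is.finite(high)) {
    stop("reference range bounds must be finite", call. = FALSE)
  }
  if (low >= high) {
    stop("reference range requires low < high (got [", low, ", ", high, "])",
         call. = FALSE)
  }
  width <- high - low
  dec <- max(n_decimals(low), n_decimals(high))
  if (is.null(grid_step)) {
    grid_step <- max(round(width / 100, dec), 10^(-dec))
  }
  if (!is.finite(grid_step) || grid_step <= 0) {
    stop("grid_step must be a positive real", call. = FALSE)
  }
  if (!is.finite(span_factor) || span_factor <= 0) {
    stop("span_factor must be a positive real", call. = FALSE)
  }
  structure(
    list(indicator = indicator, low = low, high = high, units = units,
         grid_step = grid_step, span_factor = span_factor,
         nonnegative = isTRUE(nonnegative)),
    class = "reference_range"
  )
}

#' @export
print.reference_range <- function(x, ...) {
  cat(sprintf("<reference_range> %s: [%g, %g] %s (step %g, span %g)\n",
              x$indicator, x$low, x$high, x$units, x$grid_step, x$span_factor))
  invisible(x)
}

# decimal places needed to print x exactly (capped at 6)
n_decimals <- function(x) {
  for (d in 0:6) {
    if (isTRUE(all.equal(x, round(x, d), tolerance = 1e-9))) return(d)
  }
  6L
}

#' Severity-band parameters
#'
#' The non-normal bands are delimited by two fractions of the range width
#' `W = high - low`: deviations up to `alpha1 * W` beyond the normal interval
#' are "slight", up to `alpha2 * W` are "general", and anything farther is
#' "severe".
#'
#' @param alpha1 Fraction in (0, 1) ending the "slight" deviation band.
#' @param alpha2 Fraction greater than `alpha1` ending the "general" band.
#' @return An object of class `"band_params"`.
#' @export
band_params <- function(alpha1 = 0.25, alpha2 = 0.75) {
  if (!(is.finite(alpha1) && is.finite(alpha2) &&
        alpha1 > 0 && alpha1 < 1 && alpha2 > alpha1)) {
    stop("band_params requires 0 < alpha1 < 1 and alpha2 > alpha1",
         call. = FALSE)
  }
  structure(list(alpha1 = alpha1, alpha2 = alpha2), class = "band_params")
}

#' Locate a measurement in one of the seven severity bands
#'
#' With `W = high - low`, the bands are: severely low (`v < low - alpha2*W`),
#' generally low (`[low - alpha2*W, low - alpha1*W)`), slightly low
#' (`[low - alpha1*W, low)`), normal (`[low, high]`, closed on both ends),
#' slightly high (`(high, high + alpha1*W]`), generally high
#' (`(high + alpha1*W, high + alpha2*W]`), and severely high beyond that.
#'
#' @param value Numeric vector of measured values (finite).
#' @param range A [reference_range()].
#' @param bands A [band_params()].
#' @return Character vector of band labels (see [BAND_LABELS]).
#' @examples
#' rng <- reference_range("glucose", 3.9, 6.1, "mmol/L")
#' band_of(7.1, rng)  # "generally_high"
#' @export
band_of <- function(value, range, bands = band_params()) {
  stopifnot(inherits(range, "reference_range"), inherits(bands, "band_params"))
  if (any(!is.finite(value))) {
    stop("band_of requires finite values", call. = FALSE)
  }
  BAND_LABELS[band_index(value, range, bands) + 4L]
}

# signed band index in -3..+3 (0 = normal); vectorized
band_index <- function(value, range, bands = band_params()) {
  w <- range$high - range$low
  lo <- range$low
  hi <- range$high
  a1 <- bands$alpha1 * w
  a2 <- bands$alpha2 * w
  idx <- integer(length(value))
  idx[value < lo - a2] <- -3L
  idx[value >= lo - a2 & value < lo - a1] <- -2L
  idx[value >= lo - a1 & value < lo] <- -1L
  idx[value >= lo & value <= hi] <- 0L
  idx[value > hi & value <= hi + a1] <- 1L
  idx[value > hi + a1 & value <= hi + a2] <- 2L
  idx[value > hi + a2] <- 3L
  idx
}

#' Discretize a reference range into a grid of value entities
#'
#' The grid runs from `low - span_factor*W` (clamped at 0 for nonnegative
#' analytes) to `high + span_factor*W` in steps of `grid_step`, each value
#' rounded to the decimal precision of `grid_step`.
#'
#' @param range A [reference_range()].
#' @return A data frame with columns `value` (numeric, strictly increasing)
#'   and `entity_id` (character).
#' @export
value_grid <- function(range) {
  stopifnot(inherits(range, "reference_range"))
  w <- range$high - range$low
  lo <- range$low - range$span_factor * w
  hi <- range$high + range$span_factor * w
  if (range$nonnegative) lo <- max(0, lo)
  dec <- n_decimals(range$grid_step)
  vals <- seq(lo, hi + range$grid_step / 2, by = range$grid_step)
  vals <- unique(round(vals, dec))
  vals <- vals[vals <= round(hi, dec) + 1e-12]
  if (range$nonnegative) vals <- vals[vals >= 0]
  data.frame(
    value = vals,
    entity_id = value_entity_id(range, vals, dec),
    stringsAsFactors = FALSE
  )
}

# "<indicator>::<value>.<units>"; value formatted at grid precision so that
# ids are stable and parseable
value_entity_id <- function(range, values, dec = n_decimals(range$grid_step)) {
  num <- formatC(values, format = "f", digits = dec)
  suffix <- if (nzchar(range$units)) paste0(".", range$units) else ""
  paste0(range$indicator, "::", num, suffix)
}

#' Build the indicator-value knowledge graph
#'
#' Every (indicator, grid value) pair becomes one triple
#' `(indicator, band, value)` whose relation is the severity band of the value
#' within the indicator's reference range. All seven band relations are
#' registered even when some are unused by the given grids, and the three
#' special entities `<UNK>`, `<HIGHEST>`, `<LOWEST>` are always present (they
#' carry no triples; they are matched at encoding time).
#'
#' @param ranges A list of [reference_range()] objects with unique indicator
#'   names.
#' @param bands A [band_params()].
#' @return A list with components `catalog` (an `entity_catalog`) and
#'   `triples` (data frame of 0-based integer columns `head`, `relation`,
#'   `tail`).
#' @export
build_graph <- function(ranges, bands = band_params()) {
  if (inherits(ranges, "reference_range")) ranges <- list(ranges)
  stopifnot(length(ranges) >= 1L,
            all(vapply(ranges, inherits, TRUE, "reference_range")))
  ind <- vapply(ranges, `[[`, "", "indicator")
  if (anyDuplicated(ind)) {
    stop("duplicate indicator names: ",
         paste(unique(ind[duplicated(ind)]), collapse = ", "), call. = FALSE)
  }
  grids <- lapply(ranges, value_grid)
  names(grids) <- ind
  names(ranges) <- ind

  entity_ids <- c(ind, unlist(lapply(grids, `[[`, "entity_id"),
                              use.names = FALSE), SPECIAL_ENTITIES)
  stopifnot(!anyDuplicated(entity_ids))
  entity_to_int <- stats::setNames(seq_along(entity_ids) - 1L, entity_ids)
  kind <- c(rep("indicator", length(ind)),
            rep("value", length(entity_ids) - length(ind) - 3L),
            rep("special", 3L))

  catalog <- structure(
    list(indicators = ind,
         grids = grids,
         ranges = ranges,
         bands = bands,
         entity_ids = entity_ids,
         entity_to_int = entity_to_int,
         entity_kind = kind,
         relation_to_int = stats::setNames(0:6, BAND_LABELS)),
    class = "entity_catalog"
  )

  triples <- do.call(rbind, lapply(ind, function(nm) {
    g <- grids[[nm]]
    data.frame(
      head = unname(entity_to_int[nm]),
      relation = unname(catalog$relation_to_int[
        band_of(g$value, ranges[[nm]], bands)]),
      tail = unname(entity_to_int[g$entity_id])
    )
  }))
  rownames(triples) <- NULL
  list(catalog = catalog, triples = triples)
}

#' @export
print.entity_catalog <- function(x, ...) {
  cat(sprintf(
    "<entity_catalog> %d indicators, %d value entities, 3 specials, %d relations\n",
    length(x$indicators), sum(x$entity_kind == "value"),
    length(x$relation_to_int)))
  invisible(x)
}

n_entities <- function(catalog) length(catalog$entity_ids)

# 0-based ids of all indicator / value entities (used for corruption sampling)
indicator_ids <- function(catalog) {
  unname(catalog$entity_to_int[catalog$entity_kind == "indicator"])
}
value_ids <- function(catalog) {
  unname(catalog$entity_to_int[catalog$entity_kind == "value"])
}

#' Write / read a knowledge graph directory
#'
#' `write_graph()` serializes a graph as plain tab-separated files:
#' `entity2id.tsv` (`entity_id<TAB>int`), `relation2id.tsv`
#' (`relation_label<TAB>int`), `triples.tsv`
#' (`head<TAB>relation<TAB>tail`, 0-based integers), plus `ranges.csv` and
#' `meta.json` holding the discretization and band parameters so that
#' `read_graph()` can rebuild the catalog. The round trip is the identity.
#'
#' @param catalog An `entity_catalog`.
#' @param triples Triple data frame as returned by [build_graph()].
#' @param dir Directory to create/fill.
#' @return `write_graph()` returns `dir` invisibly; `read_graph()` returns a
#'   list with `catalog` and `triples`.
#' @export
write_graph <- function(catalog, triples, dir) {
  stopifnot(inherits(catalog, "entity_catalog"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ent <- data.frame(id = catalog$entity_ids,
                    int = unname(catalog$entity_to_int))
  utils::write.table(ent, file.path(dir, "entity2id.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  rel <- data.frame(label = names(catalog$relation_to_int),
                    int = unname(catalog$relation_to_int))
  utils::write.table(rel, file.path(dir, "relation2id.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  utils::write.table(triples, file.path(dir, "triples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE, col.names = FALSE)
  write_ranges(catalog$ranges, file.path(dir, "ranges.csv"))
  jsonlite::write_json(
    list(alpha1 = catalog$bands$alpha1, alpha2 = catalog$bands$alpha2,
         nonnegative = vapply(catalog$ranges, `[[`, TRUE, "nonnegative")),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_graph
#' @export
read_graph <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"))
  ranges <- read_ranges(file.path(dir, "ranges.csv"),
                        nonnegative = unlist(meta$nonnegative))
  graph <- build_graph(ranges, band_params(meta$alpha1, meta$alpha2))

  ent <- read_two_col_tsv(file.path(dir, "entity2id.tsv"))
  if (!identical(ent$key, graph$catalog$entity_ids) ||
      !identical(as.integer(ent$int), unname(graph$catalog$entity_to_int))) {
    stop("entity2id.tsv does not match the catalog implied by ranges.csv",
         call. = FALSE)
  }
  rel <- read_two_col_tsv(file.path(dir, "relation2id.tsv"))
  if (!identical(rel$key, BAND_LABELS)) {
    stop("relation2id.tsv must list the 7 band labels in order", call. = FALSE)
  }
  triples <- read_triples(file.path(dir, "triples.tsv"), graph$catalog)
  list(catalog = graph$catalog, triples = triples)
}

read_two_col_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad)) {
    stop(sprintf("%s: malformed line %d (expected 2 tab-separated fields)",
                 basename(path), bad[1]), call. = FALSE)
  }
  data.frame(key = vapply(parts, `[[`, "", 1L),
             int = as.integer(vapply(parts, `[[`, "", 2L)),
             stringsAsFactors = FALSE)
}

read_triples <- function(path, catalog) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    return(data.frame(head = integer(), relation = integer(),
                      tail = integer()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad)) {
    stop(sprintf("triples.tsv: malformed line %d (expected 3 fields)", bad[1]),
         call. = FALSE)
  }
  m <- matrix(suppressWarnings(as.integer(unlist(parts))),
              ncol = 3, byrow = TRUE)
  bad <- which(apply(m, 1, function(r) any(is.na(r))))
  if (length(bad)) {
    stop(sprintf("triples.tsv: malformed line %d (non-integer field)", bad[1]),
         call. = FALSE)
  }
  n_ent <- n_entities(catalog)
  bad <- which(m[, 2] < 0L | m[, 2] >= 7L)
  if (length(bad)) {
    stop(sprintf("triples.tsv: line %d: relation id %d outside 0..6",
                 bad[1], m[bad[1], 2]), call. = FALSE)
  }
  bad <- which(m[, 1] < 0L | m[, 1] >= n_ent | m[, 3] < 0L | m[, 3] >= n_ent)
  if (length(bad)) {
    stop(sprintf("triples.tsv: line %d: entity id outside catalog", bad[1]),
         call. = FALSE)
  }
  data.frame(head = m[, 1], relation = m[, 2], tail = m[, 3])
}

#' Read / write a reference-range table
#'
#' CSV with header `indicator,low,high,units,grid_step,span_factor`; the last
#' two columns are optional and fall back to the [reference_range()] defaults.
#'
#' @param path CSV file path.
#' @param nonnegative Logical scalar or vector: clamp grids at zero.
#' @return A list of [reference_range()] objects.
#' @export
read_ranges <- function(path, nonnegative = TRUE) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("indicator", "low", "high", "units")
  if (!all(need %in% names(df))) {
    stop("ranges csv must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  nonnegative <- rep_len(nonnegative, nrow(df))
  lapply(seq_len(nrow(df)), function(i) {
    reference_range(
      df$indicator[i], df$low[i], df$high[i],
      units = if (is.na(df$units[i])) "" else df$units[i],
      grid_step = if ("grid_step" %in% names(df) && !is.na(df$grid_step[i]))
        df$grid_step[i] else NULL,
      span_factor = if ("span_factor" %in% names(df) &&
                        !is.na(df$span_factor[i]))
        df$span_factor[i] else 1,
      nonnegative = nonnegative[i]
    )
  })
}

#' @rdname read_ranges
#' @param ranges List of [reference_range()] objects to write.
#' @export
write_ranges <- function(ranges, path) {
  df <- data.frame(
    indicator = vapply(ranges, `[[`, "", "indicator"),
    low = vapply(ranges, `[[`, 0, "low"),
    high = vapply(ranges, `[[`, 0, "high"),
    units = vapply(ranges, `[[`, "", "units"),
    grid_step = vapply(ranges, `[[`, 0, "grid_step"),
    span_factor = vapply(ranges, `[[`, 0, "span_factor")
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
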