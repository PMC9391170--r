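#' Match a measured value to a value entity
#'
#' Missing values map to `<UNK>`; values above the indicator's grid maximum to
#' `<HIGHEST>`; below the minimum to `<LOWEST>`; anything else to the nearest
#' grid value, rounding half up at exact midpoints.
#'
#' @param indicator Indicator name (must exist in the catalog).
#' @param value Measured value, or `NA` for missing.
#' @param catalog An `entity_catalog`.
#' @return The matched entity id (character scalar).
#' @export
match_entity <- function(indicator, value, catalog) {
  stopifnot(inherits(catalog, "entity_catalog"))
  if (!indicator %in% catalog$indicators) {
    stop("unknown indicator: ", indicator, call. = FALSE)
  }
  if (is.na(value)) return("<UNK>")
  g <- catalog$grids[[indicator]]
  if (value > g$value[nrow(g)]) return("<HIGHEST>")
  if (value < g$value[1]) return("<LOWEST>")
  d <- abs(g$value - value)
  hits <- which(d <= min(d) + 1e-12)
  g$entity_id[max(hits)]  # midpoint ties round toward the larger value
}

match_entity_int <- function(indicator, value, catalog) {
  unname(catalog$entity_to_int[match_entity(indicator, value, catalog)])
}

#' Relation vector of a matched value
#'
#' The component-wise difference `e_v - e_c` between the value entity's vector
#' and the indicator entity's vector; under a well-trained translational model
#' this approximates the relation (severity-band) vector linking them.
#'
#' @param e_v Entity vector of the matched test value.
#' @param e_c Entity vector of the indicator.
#' @return Numeric vector `e_v - e_c`.
#' @export
relation_vector <- function(e_v, e_c) {
  if (length(e_v) != length(e_c)) {
    stop("relation_vector requires equal-length vectors", call. = FALSE)
  }
  e_v - e_c
}

#' Encode a patient record as a relation matrix
#'
#' Builds the `k x m` matrix whose column `j` is
#' `e(value entity of indicator j) - e(indicator j)`, with value entities
#' matched by [match_entity()]. Column order follows `order`.
#'
#' @param record Named list or named numeric vector of indicator values
#'   (`NA` = missing).
#' @param catalog An `entity_catalog`.
#' @param params A trained `trans_params` (or any object with an `entities`
#'   matrix aligned to the catalog).
#' @param order Indicator names defining the column order; defaults to the
#'   catalog's indicator order.
#' @return A `k x m` numeric matrix with `colnames = order`.
#' @export
encode_record <- function(record, catalog, params,
                          order = catalog$indicators) {
  stopifnot(all(order %in% catalog$indicators), !anyDuplicated(order))
  k <- ncol(params$entities)
  E <- matrix(0, k, length(order))
  colnames(E) <- order
  for (j in seq_along(order)) {
    ind <- order[j]
    v_int <- match_entity_int(ind, record_value(record, ind), catalog)
    c_int <- unname(catalog$entity_to_int[ind])
    E[, j] <- relation_vector(params$entities[v_int + 1L, ],
                              params$entities[c_int + 1L, ])
  }
  E
}

record_value <- function(record, ind) {
  v <- record[[ind]]
  if (is.null(v) || length(v) == 0L) NA_real_ else as.numeric(v)
}

#' Encode a whole cohort
#'
#' Applies [encode_record()] to each row of a patient table and stacks the
#' results into a `k x m x n` array (the input consumed by
#' [train_sac()]).
#'
#' @param patients Data frame with one column per indicator (an optional
#'   `label` column is ignored); empty/`NA` cells are missing values.
#' @inheritParams encode_record
#' @return Numeric array of dimension `k x m x nrow(patients)` with
#'   `dimnames[[2]] = order`.
#' @export
encode_cohort <- function(patients, catalog, params,
                          order = catalog$indicators) {
  stopifnot(all(order %in% names(patients)))
  k <- ncol(params$entities)
  n <- nrow(patients)
  m <- length(order)
  # match each distinct (indicator, value) once, then gather
  out <- array(0, c(k, m, n), dimnames = list(NULL, order, NULL))
  for (j in seq_len(m)) {
    ind <- order[j]
    vals <- as.numeric(patients[[ind]])
    uv <- unique(vals)
    ids <- vapply(uv, function(v) match_entity_int(ind, v, catalog),
                  integer(1))
    v_int <- ids[match(vals, uv)]
    c_vec <- params$entities[unname(catalog$entity_to_int[ind]) + 1L, ]
    cols <- params$entities[v_int + 1L, , drop = FALSE]
    out[, j, ] <- t(cols) - c_vec
  }
  out
}

#' Encode with a free embedding table (ablation)
#'
#' The learned-embedding baseline replaces the knowledge-graph relation
#' vectors by direct lookups into a trainable table: column `j` is the table
#' row of the matched value entity of indicator `j` (equivalently, the one-hot
#' encoding of the entity multiplied by the table). The output has the same
#' shape contract as [encode_cohort()], so the downstream classifier is
#' unchanged; pass `train_table = TRUE` to [train_sac()] to fit the table
#' jointly with the classifier.
#'
#' @param patients Data frame of patient values.
#' @param catalog An `entity_catalog` (used only for entity matching).
#' @param table Numeric matrix `n_entities x k`: the embedding table.
#' @param order Column order of indicators.
#' @return A list with `E` (the `k x m x n` array) and `index`
#'   (`m x n` integer matrix of 1-based table rows, for joint training).
#' @export
encode_learned <- function(patients, catalog, table,
                           order = catalog$indicators) {
  stopifnot(all(order %in% names(patients)),
            nrow(table) == n_entities(catalog))
  k <- ncol(table)
  n <- nrow(patients)
  m <- length(order)
  idx <- matrix(0L, m, n)
  for (j in seq_len(m)) {
    ind <- order[j]
    vals <- as.numeric(patients[[ind]])
    uv <- unique(vals)
    ids <- vapply(uv, function(v) match_entity_int(ind, v, catalog),
                  integer(1))
    idx[j, ] <- ids[match(vals, uv)] + 1L
  }
  E <- array(0, c(k, m, n), dimnames = list(NULL, order, NULL))
  for (s in seq_len(n)) E[, , s] <- t(table[idx[, s], , drop = FALSE])
  list(E = E, index = idx)
}
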