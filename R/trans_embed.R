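#' Training configuration for translational embeddings
#'
#' Margin-based ranking training with uniform negative sampling, optimized by
#' Adam. These defaults govern the embedding stage; the classifier has its own
#' hyperparameters (see [sac_config()]).
#'
#' @param margin Margin gamma of the ranking loss (default 1).
#' @param epochs Number of passes over the triple set (default 500).
#' @param batch_size Triples per parameter update (default 128).
#' @param learning_rate Adam step size (default 1e-3).
#' @param negative_ratio Corrupted triples drawn per positive (default 1).
#' @param seed Integer seed controlling initialization, shuffling and
#'   negative sampling.
#' @return An object of class `"trans_config"`.
#' @export
trans_config <- function(margin = 1.0, epochs = 500, batch_size = 128,
                         learning_rate = 1e-3, negative_ratio = 1,
                         seed = 1L) {
  stopifnot(margin > 0, epochs >= 0, batch_size >= 1, learning_rate > 0,
            negative_ratio >= 1)
  structure(list(margin = margin, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 negative_ratio = as.integer(negative_ratio),
                 seed = as.integer(seed)),
            class = "trans_config")
}

TRANS_MODELS <- c("TransE", "TransH", "TransR")

#' Initialize translational embedding parameters
#'
#' Entities and relations start uniform in `(-6/sqrt(k), 6/sqrt(k))` with
#' relation vectors normalized to unit length and entity norms clipped to 1;
#' TransH hyperplane normals start as random unit vectors; TransR projection
#' matrices start as identities.
#'
#' @param catalog An `entity_catalog` from [build_graph()].
#' @param model One of `"TransE"`, `"TransH"`, `"TransR"`.
#' @param dim Embedding dimension k (default 256).
#' @param norm_order 1 or 2: the distance norm of the score function.
#' @param seed Integer seed.
#' @return An object of class `"trans_params"`.
#' @export
init_trans_params <- function(catalog, model = c("TransH", "TransE", "TransR"),
                              dim = 256, norm_order = 2, seed = 1L) {
  model <- match.arg(model)
  stopifnot(inherits(catalog, "entity_catalog"), dim >= 1,
            norm_order %in% c(1, 2))
  ne <- n_entities(catalog)
  nr <- length(catalog$relation_to_int)
  set.seed(seed)
  b <- 6 / sqrt(dim)
  ent <- matrix(stats::runif(ne * dim, -b, b), ne, dim)
  nrm <- sqrt(rowSums(ent^2))
  ent <- ent / pmax(nrm, 1)
  rel <- matrix(stats::runif(nr * dim, -b, b), nr, dim)
  rel <- rel / sqrt(rowSums(rel^2))
  normals <- NULL
  proj <- NULL
  if (model == "TransH") {
    normals <- matrix(stats::runif(nr * dim, -b, b), nr, dim)
    normals <- normals / sqrt(rowSums(normals^2))
  }
  if (model == "TransR") {
    proj <- array(0, c(dim, dim, nr))
    for (r in seq_len(nr)) proj[, , r] <- diag(dim)
  }
  structure(
    list(model = model, dim = as.integer(dim), norm_order = norm_order,
         entities = ent, relations = rel, normals = normals, proj = proj,
         entity_ids = catalog$entity_ids,
         relation_labels = names(catalog$relation_to_int)),
    class = "trans_params"
  )
}

#' @export
print.trans_params <- function(x, ...) {
  cat(sprintf("<trans_params> %s, %d entities x %d dims, L%d norm\n",
              x$model, nrow(x$entities), x$dim, x$norm_order))
  invisible(x)
}

#' Project a vector onto a relation hyperplane
#'
#' Removes the component of `e` along the unit normal `w_r`:
#' `e - (w_r' e) w_r`. The result is orthogonal to `w_r` and the operation is
#' idempotent.
#'
#' @param e Numeric vector.
#' @param w_r Unit-length numeric vector of the same length.
#' @param tol Tolerance on `||w_r|| - 1`.
#' @return The projected vector.
#' @export
project_hyperplane <- function(e, w_r, tol = 1e-6) {
  stopifnot(length(e) == length(w_r))
  if (abs(sqrt(sum(w_r^2)) - 1) > tol) {
    stop("w_r must have unit Euclidean norm", call. = FALSE)
  }
  e - sum(w_r * e) * w_r
}

check_entity_id <- function(params, id) {
  if (any(id < 0L) || any(id >= nrow(params$entities))) {
    stop("entity id out of range", call. = FALSE)
  }
}

#' Score a triple under a translational model
#'
#' Returns `||proj(l_h) + l_r - proj(l_t)||` in the configured norm, where the
#' projection is the identity (TransE), the relation-hyperplane projection
#' (TransH), or multiplication by the relation matrix (TransR). Lower scores
#' mean more plausible triples.
#'
#' @param params A `trans_params` object.
#' @param h,r,t 0-based head entity, relation, and tail entity ids.
#' @return Nonnegative scalar score.
#' @export
score_triple <- function(params, h, r, t) {
  check_entity_id(params, c(h, t))
  if (r < 0L || r >= nrow(params$relations)) {
    stop("relation id out of range", call. = FALSE)
  }
  eh <- params$entities[h + 1L, ]
  et <- params$entities[t + 1L, ]
  lr <- params$relations[r + 1L, ]
  if (params$model == "TransH") {
    w <- params$normals[r + 1L, ]
    eh <- eh - sum(w * eh) * w
    et <- et - sum(w * et) * w
  } else if (params$model == "TransR") {
    M <- params$proj[, , r + 1L]
    eh <- drop(M %*% eh)
    et <- drop(M %*% et)
  }
  d <- eh + lr - et
  if (params$norm_order == 1) sum(abs(d)) else sqrt(sum(d^2))
}

# scores of (cand, r, t) for all candidate heads, or (h, r, cand) for all
# candidate tails; cand are 0-based ids. Vectorized over candidates.
score_candidates <- function(params, r, fixed, cand, side = c("head", "tail")) {
  side <- match.arg(side)
  E <- params$entities[cand + 1L, , drop = FALSE]
  ef <- params$entities[fixed + 1L, ]
  lr <- params$relations[r + 1L, ]
  if (params$model == "TransH") {
    w <- params$normals[r + 1L, ]
    E <- E - (E %*% w) %*% t(w)
    ef <- ef - sum(w * ef) * w
  } else if (params$model == "TransR") {
    M <- params$proj[, , r + 1L]
    E <- E %*% t(M)
    ef <- drop(M %*% ef)
  }
  d <- if (side == "head") {
    sweep(E, 2, lr - ef, "+")        # cand + r - t
  } else {
    sweep(-E, 2, ef + lr, "+")       # h + r - cand
  }
  if (params$norm_order == 1) rowSums(abs(d)) else sqrt(rowSums(d^2))
}

#' Corrupt a triple for negative sampling
#'
#' With probability 1/2 replaces the head by a uniformly drawn indicator
#' entity, otherwise the tail by a uniformly drawn value entity; the corrupted
#' triple always differs from the original and the relation is never touched.
#' Uses R's RNG (seed with [set.seed()]).
#'
#' @param triple List or vector with elements `head`, `relation`, `tail`
#'   (0-based ids).
#' @param catalog The `entity_catalog` the triple belongs to.
#' @return A list with `head`, `relation`, `tail`.
#' @export
negative_sample <- function(triple, catalog) {
  h <- triple$head; r <- triple$relation; t <- triple$tail
  heads <- indicator_ids(catalog)
  tails <- value_ids(catalog)
  can_head <- length(setdiff(heads, h)) > 0
  can_tail <- length(setdiff(tails, t)) > 0
  if (!can_head && !can_tail) {
    stop("catalog has a single entity of each kind; cannot corrupt",
         call. = FALSE)
  }
  corrupt_head <- if (can_head && can_tail) stats::runif(1) < 0.5 else can_head
  if (corrupt_head) {
    pool <- setdiff(heads, h)
    list(head = pool[sample.int(length(pool), 1L)], relation = r, tail = t)
  } else {
    pool <- setdiff(tails, t)
    list(head = h, relation = r, tail = pool[sample.int(length(pool), 1L)])
  }
}

#' Train translational embeddings by margin ranking
#'
#' Minimizes `sum max(0, score(pos) + margin - score(neg))` over uniformly
#' corrupted negatives with Adam, enforcing the model constraints (entity
#' norms at most 1; unit hyperplane normals) after every batch. Deterministic
#' given `config$seed`.
#'
#' @param triples Triple data frame from [build_graph()].
#' @param catalog The matching `entity_catalog`.
#' @param model One of `"TransE"`, `"TransH"`, `"TransR"`.
#' @param dim Embedding dimension.
#' @param norm_order 1 or 2.
#' @param config A [trans_config()].
#' @return A trained `trans_params` object.
#' @export
train_trans <- function(triples, catalog, model = c("TransH", "TransE", "TransR"),
                        dim = 256, norm_order = 2, config = trans_config()) {
  model <- match.arg(model)
  if (is.null(triples) || nrow(triples) == 0L) {
    stop("cannot train on an empty triple list", call. = FALSE)
  }
  params <- init_trans_params(catalog, model, dim, norm_order,
                              seed = config$seed)
  if (config$epochs == 0L) return(params)
  # set.seed was consumed by init; reseed so training draws are reproducible
  set.seed(config$seed + 1L)
  fit <- trans_train_cpp(
    head = as.integer(triples$head), rel = as.integer(triples$relation),
    tail = as.integer(triples$tail),
    ent = params$entities, relmat = params$relations,
    normals = if (is.null(params$normals)) matrix(0, 0, 0) else params$normals,
    proj = if (is.null(params$proj)) array(0, c(1, 1, 1)) else params$proj,
    model = match(model, TRANS_MODELS), norm_order = as.integer(norm_order),
    margin = config$margin, lr = config$learning_rate,
    epochs = config$epochs, batch_size = config$batch_size,
    neg_ratio = config$negative_ratio,
    head_cand = as.integer(indicator_ids(catalog)),
    tail_cand = as.integer(value_ids(catalog)))
  params$entities <- fit$ent
  params$relations <- fit$rel
  if (model == "TransH") params$normals <- fit$normals
  if (model == "TransR") params$proj <- fit$proj
  params$loss_history <- drop(fit$loss)
  params
}

#' Rank a triple against all entity corruptions
#'
#' Replaces the entity on `side` by every entity of the catalog in turn,
#' scores all corrupted triples, and returns `1 +` the number of replacements
#' scoring strictly below the true triple (optimistic ties; raw setting).
#'
#' @param params Trained `trans_params`.
#' @param triple List with `head`, `relation`, `tail` (0-based).
#' @param catalog The `entity_catalog`.
#' @param side `"head"` or `"tail"`: which slot to corrupt.
#' @return Integer rank, at least 1.
#' @export
rank_triple <- function(params, triple, catalog, side = c("head", "tail")) {
  side <- match.arg(side)
  cand <- seq_len(n_entities(catalog)) - 1L
  true_score <- score_triple(params, triple$head, triple$relation, triple$tail)
  orig <- if (side == "head") triple$head else triple$tail
  fixed <- if (side == "head") triple$tail else triple$head
  cand <- cand[cand != orig]
  sc <- score_candidates(params, triple$relation, fixed, cand, side)
  1L + sum(sc < true_score)
}

#' Link-prediction evaluation: Mean Rank and Hit@10
#'
#' Ranks every test triple with [rank_triple()] and reports
#' `MR = mean(rank_i)` and `Hit@10 = 100 * #\{rank_i <= 10\} / N_T` (percent).
#' Smaller MR and larger Hit@10 indicate a better embedding.
#'
#' @inheritParams rank_triple
#' @param triples Data frame of test triples.
#' @return An object of class `"ranking_result"` with `mean_rank`,
#'   `hit_at_10`, and `per_triple_ranks`.
#' @export
evaluate_ranking <- function(params, triples, catalog,
                             side = c("head", "tail")) {
  side <- match.arg(side)
  if (is.null(triples) || nrow(triples) == 0L) {
    stop("empty test triple set", call. = FALSE)
  }
  ranks <- vapply(seq_len(nrow(triples)), function(i) {
    rank_triple(params,
                list(head = triples$head[i], relation = triples$relation[i],
                     tail = triples$tail[i]),
                catalog, side)
  }, integer(1))
  structure(
    list(mean_rank = mean(ranks),
         hit_at_10 = 100 * mean(ranks <= 10),
         per_triple_ranks = ranks),
    class = "ranking_result"
  )
}

#' @export
print.ranking_result <- function(x, ...) {
  cat(sprintf("<ranking_result> MR = %.2f, Hit@10 = %.1f%% (N = %d)\n",
              x$mean_rank, x$hit_at_10, length(x$per_triple_ranks)))
  invisible(x)
}

#' Write / read trained embeddings
#'
#' Serializes a `trans_params` object as a directory of plain-text files:
#' `meta.json` plus TSV tables of reals at full double precision, so the round
#' trip reproduces the parameters exactly.
#'
#' @param params A `trans_params`.
#' @param dir Directory to create/fill.
#' @return `write_embeddings()` returns `dir` invisibly; `read_embeddings()`
#'   the reconstructed `trans_params`.
#' @export
write_embeddings <- function(params, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(model = params$model, dim = params$dim,
         norm_order = params$norm_order,
         entity_ids = params$entity_ids,
         relation_labels = params$relation_labels),
    file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  write_real_tsv(params$entities, file.path(dir, "entities.tsv"))
  write_real_tsv(params$relations, file.path(dir, "relations.tsv"))
  if (!is.null(params$normals)) {
    write_real_tsv(params$normals, file.path(dir, "normals.tsv"))
  }
  if (!is.null(params$proj)) {
    nr <- dim(params$proj)[3]
    flat <- do.call(rbind, lapply(seq_len(nr), function(r) params$proj[, , r]))
    write_real_tsv(flat, file.path(dir, "proj.tsv"))
  }
  invisible(dir)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  k <- as.integer(meta$dim)
  out <- list(model = meta$model, dim = k, norm_order = meta$norm_order,
              entities = read_real_tsv(file.path(dir, "entities.tsv")),
              relations = read_real_tsv(file.path(dir, "relations.tsv")),
              normals = NULL, proj = NULL,
              entity_ids = meta$entity_ids,
              relation_labels = meta$relation_labels)
  if (file.exists(file.path(dir, "normals.tsv"))) {
    out$normals <- read_real_tsv(file.path(dir, "normals.tsv"))
  }
  if (file.exists(file.path(dir, "proj.tsv"))) {
    flat <- read_real_tsv(file.path(dir, "proj.tsv"))
    nr <- nrow(flat) / k
    out$proj <- array(0, c(k, k, nr))
    for (r in seq_len(nr)) out$proj[, , r] <- flat[((r - 1) * k + 1):(r * k), ]
  }
  structure(out, class = "trans_params")
}

write_real_tsv <- function(m, path) {
  txt <- apply(m, 1, function(row) {
    paste(formatC(row, format = "g", digits = 17), collapse = "\t")
  })
  writeLines(txt, path)
}

read_real_tsv <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  matrix(as.numeric(unlist(rows)), nrow = length(rows), byrow = TRUE)
}
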