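# Shared fixtures: small graphs and cohorts built in code.

# two coarse-grid indicators (few value entities, fast to train on)
toy_ranges <- function() {
  list(
    reference_range("alpha", 1.0, 2.0, "mmol/L", grid_step = 0.5,
                    span_factor = 1),
    reference_range("beta", 10, 20, "U/L", grid_step = 5, span_factor = 1)
  )
}

toy_graph <- function() build_graph(toy_ranges())

# catalog whose first indicator has grid exactly {1.0, 1.5}
two_point_catalog <- function() {
  r <- reference_range("x", 1.0, 1.5, "mmol/L", grid_step = 0.5,
                       span_factor = 1e-6)
  build_graph(list(r))$catalog
}

# hand-built embedding parameters over a catalog (no training)
hand_params <- function(catalog, dim = 4, model = "TransE", norm_order = 2,
                        seed = 11) {
  init_trans_params(catalog, model, dim = dim, norm_order = norm_order,
                    seed = seed)
}

# independent exhaustive-corruption ranking: plain loop + sort, no shared
# vectorized code path
brute_force_rank <- function(params, triple, catalog, side) {
  n_ent <- length(catalog$entity_ids)
  true_score <- score_triple(params, triple$head, triple$relation,
                             triple$tail)
  worse <- 0L
  for (e in seq_len(n_ent) - 1L) {
    if (side == "head") {
      if (e == triple$head) next
      s <- score_triple(params, e, triple$relation, triple$tail)
    } else {
      if (e == triple$tail) next
      s <- score_triple(params, triple$head, triple$relation, e)
    }
    if (s < true_score) worse <- worse + 1L
  }
  worse + 1L
}

# independent convolution + max-pooling oracle: explicit double loop
brute_force_conv_pool <- function(E_attn, conv) {
  out <- c()
  m <- ncol(E_attn)
  for (cw in conv) {
    h <- cw$h
    for (f in seq_len(nrow(cw$W))) {
      best <- -Inf
      for (p in seq_len(m - h + 1)) {
        window <- as.vector(E_attn[, p:(p + h - 1)])
        best <- max(best, max(0, sum(cw$W[f, ] * window) + cw$b[f]))
      }
      out <- c(out, best)
    }
  }
  out
}

# small labelled dataset whose classes are linearly separable in the
# relation-matrix entries
separable_encoding <- function(k = 6, m = 5, n = 60, seed = 5) {
  set.seed(seed)
  y <- rep(c(0L, 1L), length.out = n)
  shift <- ifelse(y == 1, 0.7, -0.7)
  E <- array(stats::rnorm(k * m * n, mean = rep(shift, each = k * m), sd = 0.3),
             c(k, m, n))
  list(E = E, y = y)
}
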