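# Shared fixtures, built in code at test time.

# small aligned grid of given values (row 1 = top), 100 m cells at origin 0/ymax
grid_of <- function(values, cell_size = 100, crs = "test-metric", legend = NULL) {
  raster_grid(as.matrix(values), cell_size = cell_size, crs = crs, legend = legend)
}

# stack of constant-valued layers sharing one geometry
constant_stack <- function(nr = 6, nc = 6, values = c(a = 1, b = 2), cell_size = 100) {
  raster_stack(lapply(values, function(v) grid_of(matrix(v, nr, nc), cell_size)))
}

# a small landscape reused across tests (32 x 32 keeps module tests quick);
# memoised per session
small_landscape <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- make_landscape(landscape_spec(shape = c(32, 32), seed = seed))
    }
    cache[[key]]
  }
})

# 64 x 64 landscape for the two-step selection tests: large enough for the
# presence-only members to be informative, small enough to stay fast
medium_landscape <- local({
  cache <- new.env(parent = emptyenv())
  function(seed = 42) {
    key <- paste0("s", seed)
    if (is.null(cache[[key]])) {
      cache[[key]] <- make_landscape(landscape_spec(shape = c(64, 64), seed = seed))
    }
    cache[[key]]
  }
})

# brute-force rank AUC by exhaustive pairwise comparison (independent oracle)
pairwise_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}

# brute-force TSS maximization over all midpoint thresholds (independent oracle)
brute_tss <- function(scores, labels) {
  u <- sort(unique(scores))
  cand <- (u[-length(u)] + u[-1]) / 2
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  tss <- sapply(cand, function(t) {
    sum(scores >= t & labels == 1) / n1 + sum(scores < t & labels == 0) / n0 - 1
  })
  list(threshold = cand[which.max(tss)], tss = max(tss))
}

# hand-buildable ensemble whose members predict constants
constant_ensemble <- function(preds, aucs) {
  members <- lapply(seq_along(preds), function(i) {
    force(i)
    list(
      tag = paste0("m", i), model = preds[i],
      predict = function(model, x) rep(model, nrow(x)),
      auc = aucs[i], p_test = rep(preds[i], 3)
    )
  })
  names(members) <- vapply(members, `[[`, character(1), "tag")
  w <- aucs / sum(aucs)
  structure(
    list(
      members = members, weights = setNames(w, names(members)),
      feature_vars = "v", registry = "custom", weight_mode = "auc",
      dropped = character(0), test_scores = rep(0.5, 3),
      test_labels = c(0L, 1L, 1L), seed = 1L
    ),
    class = "classifier_ensemble"
  )
}
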