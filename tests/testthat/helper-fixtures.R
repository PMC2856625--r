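# shared fixtures: built in code, cached per test file

tiny_layout <- function(n_allergens = 6) {
  array_layout(
    tibble::tibble(
      name = paste0("alg", sprintf("%02d", seq_len(n_allergens))),
      class = rep_len(c("surface", "cytoplasm", "pollen_extract"),
                      n_allergens)
    ),
    standard_concentrations = 200 / 2^(0:3)
  )
}

tiny_config <- function(seed = 101, ...) {
  simulation_config(layout = tiny_layout(), seed = seed, ...)
}

# small but full-design study on the default 80-allergen layout, cached
default_study <- local({
  cache <- NULL
  function(seed = 101) {
    if (is.null(cache)) {
      cfg <- simulation_config(seed = seed)
      cache <<- list(config = cfg, study = simulate_study(cfg))
    }
    cache
  }
})

# independent UPGMA oracle: recomputes every cluster-pair distance from the
# original matrix instead of Lance-Williams updates
brute_upgma <- function(dm) {
  dm <- as.matrix(dm)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(nrow(dm)))
  clusters <- lapply(seq_len(nrow(dm)), identity)
  heights <- numeric(0)
  clades <- list()
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (j <= i) next
        d <- mean(dm[clusters[[i]], clusters[[j]]])
        key <- paste(sort(c(min(labels[clusters[[i]]]),
                            min(labels[clusters[[j]]]))), collapse = "\r")
        if (is.null(best) || d < best$d - 1e-12 ||
            (abs(d - best$d) <= 1e-12 && key < best$key)) {
          best <- list(i = i, j = j, d = d, key = key)
        }
      }
    }
    merged <- c(clusters[[best$i]], clusters[[best$j]])
    heights <- c(heights, best$d)
    clades <- c(clades, list(sort(labels[merged])))
    clusters[[best$i]] <- merged
    clusters[[best$j]] <- NULL
  }
  list(heights = heights, clades = clades)
}

# canonical clade-set + height representation for tree comparison
tree_signature <- function(dend) {
  keys <- vapply(dendrogram_clades(dend), paste, character(1),
                 collapse = "|")
  stats::setNames(dend$height, keys)[order(keys)]
}
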