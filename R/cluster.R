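#' Correlation distance between allergen profiles
#'
#' `d(a, b) = 1 - r(a, b)` with Pearson correlation computed over the rows
#' (sera) where both columns are observed. Columns with zero variance (or
#' fewer than 2 complete values against every partner) are excluded with a
#' warning, since their correlation is undefined.
#'
#' @param wide Wide sera-by-allergens data frame ([ige_matrix_wide()]); any
#'   non-numeric columns (e.g. `serum_id`) are ignored.
#' @return A [stats::dist] over the retained allergen columns.
#' @export
correlation_distance <- function(wide) {
  num <- wide[, vapply(wide, is.numeric, logical(1)), drop = FALSE]
  if (nrow(num) < 3) stop("need >= 3 sera rows", call. = FALSE)
  v <- vapply(num, function(x) stats::var(x, na.rm = TRUE), double(1))
  bad <- names(num)[is.na(v) | v == 0]
  if (length(bad)) {
    warning("zero-variance column(s) excluded: ",
            paste(bad, collapse = ", "), call. = FALSE)
    num <- num[, setdiff(names(num), bad), drop = FALSE]
  }
  if (ncol(num) < 2) stop("fewer than 2 usable columns", call. = FALSE)
  r <- stats::cor(as.matrix(num), use = "pairwise.complete.obs")
  stats::as.dist(1 - r)
}

#' Average-linkage (UPGMA) hierarchical clustering
#'
#' Agglomerative clustering where the distance between clusters is the mean
#' of all pairwise item distances. Ties in the minimum inter-cluster
#' distance are broken deterministically: the merging pair whose (sorted)
#' smallest-leaf-label pair is lexicographically smallest wins, so the tree
#' is invariant to input item order.
#'
#' @param d A [stats::dist] (or symmetric matrix) with labels.
#' @return An object of class `ige_dendrogram` (also `hclust`-compatible:
#'   fields `merge`, `height`, `order`, `labels`), usable with
#'   [stats::cutree()] and plotting.
#' @export
average_linkage_cluster <- function(d) {
  dm <- as.matrix(d)
  n <- nrow(dm)
  if (n < 2) stop("need >= 2 items to cluster", call. = FALSE)
  labels <- rownames(dm)
  if (is.null(labels)) labels <- as.character(seq_len(n))

  # active clusters: membership (leaf indices), hclust node code, size,
  # representative label = lexicographically smallest leaf label
  members <- as.list(seq_len(n))
  code <- -seq_len(n)
  sizes <- rep(1L, n)
  rep_label <- labels
  active <- rep(TRUE, n)
  D <- dm
  diag(D) <- Inf
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  merged_members <- vector("list", n - 1)

  for (step in seq_len(n - 1)) {
    idx <- which(active)
    sub <- D[idx, idx, drop = FALSE]
    hmin <- min(sub)
    hit <- which(sub <= hmin + 1e-12 & upper.tri(sub), arr.ind = TRUE)
    # deterministic tie-break on sorted representative-label pairs
    pair_lab <- apply(hit, 1, function(ij) {
      paste(sort(c(rep_label[idx[ij[1]]], rep_label[idx[ij[2]]])),
            collapse = "\r")
    })
    k <- order(pair_lab)[1]
    i <- idx[hit[k, 1]]; j <- idx[hit[k, 2]]
    # hclust convention: leaf codes are negative and listed first
    a <- code[i]; b <- code[j]
    merge[step, ] <- if (a < 0 && b < 0) sort(c(a, b), decreasing = TRUE)
                     else if (a < 0) c(a, b)
                     else if (b < 0) c(b, a)
                     else sort(c(a, b))
    height[step] <- D[i, j]
    # Lance-Williams update for average linkage
    new_members <- c(members[[i]], members[[j]])
    others <- setdiff(idx, c(i, j))
    if (length(others)) {
      newd <- (sizes[i] * D[i, others] + sizes[j] * D[j, others]) /
        (sizes[i] + sizes[j])
      D[i, others] <- newd
      D[others, i] <- newd
    }
    members[[i]] <- new_members
    sizes[i] <- sizes[i] + sizes[j]
    rep_label[i] <- min(rep_label[i], rep_label[j])
    code[i] <- step
    active[j] <- FALSE
    merged_members[[step]] <- new_members
  }

  obj <- structure(
    list(merge = merge, height = height, order = order_leaves(merge, n),
         labels = labels, method = "average",
         dist.method = "correlation", call = match.call()),
    class = c("ige_dendrogram", "hclust")
  )
  attr(obj, "clades") <- lapply(merged_members,
                                function(mm) sort(labels[mm]))
  obj
}

# leaf ordering by tree traversal (left-to-right)
order_leaves <- function(merge, n) {
  walk <- function(node) {
    if (node < 0) return(-node)
    c(walk(merge[node, 1]), walk(merge[node, 2]))
  }
  walk(n - 1)
}

#' Leaf sets of a dendrogram's internal nodes
#'
#' @param dend An `ige_dendrogram`.
#' @return List (one element per merge, root last) of sorted leaf-label
#'   character vectors.
#' @export
dendrogram_clades <- function(dend) {
  cl <- attr(dend, "clades")
  if (!is.null(cl)) return(cl)
  lapply(seq_len(nrow(dend$merge)), function(k) {
    walk <- function(node) {
      if (node < 0) return(-node)
      c(walk(dend$merge[node, 1]), walk(dend$merge[node, 2]))
    }
    sort(dend$labels[walk(k)])
  })
}

clade_keys <- function(dend) {
  vapply(dendrogram_clades(dend), paste, character(1), collapse = "\r")
}

# one bootstrap pass: resample n_row rows, recluster, return clade keys
boot_clades <- function(num, n_row) {
  rows <- sample.int(nrow(num), n_row, replace = TRUE)
  sub <- num[rows, , drop = FALSE]
  r <- suppressWarnings(stats::cor(sub, use = "pairwise.complete.obs"))
  r[!is.finite(r)] <- 0
  d <- stats::as.dist(1 - r)
  clade_keys(average_linkage_cluster(d))
}

#' Ordinary bootstrap support (BP) for dendrogram clades
#'
#' Resamples sera (rows) with replacement `B` times, reclusters the allergen
#' columns each time, and reports per internal node of the full-data tree the
#' fraction of bootstrap trees containing exactly that leaf set as a clade.
#'
#' @param wide Wide sera-by-allergens data frame.
#' @param B Bootstrap replicates (default 1000).
#' @param seed Integer seed.
#' @return A tibble of class `cluster_support`: `node`, `clade` (list of
#'   labels), `n_leaves`, `bp`; the reference `ige_dendrogram` is in
#'   attribute `"dendrogram"`.
#' @export
bootstrap_support <- function(wide, B = 1000, seed = 1L) {
  if (B <= 0) stop("B must be positive", call. = FALSE)
  dend <- average_linkage_cluster(correlation_distance(wide))
  num <- as.matrix(wide[, vapply(wide, is.numeric, logical(1)), drop = FALSE])
  num <- num[, dend$labels, drop = FALSE]
  keys <- clade_keys(dend)
  hits <- integer(length(keys))
  withr::with_seed(seed, {
    for (b in seq_len(B)) {
      bk <- boot_clades(num, nrow(num))
      hits <- hits + (keys %in% bk)
    }
  })
  out <- tibble::tibble(
    node = seq_along(keys),
    clade = dendrogram_clades(dend),
    n_leaves = lengths(dendrogram_clades(dend)),
    bp = hits / B
  )
  structure(out, class = c("cluster_support", class(out)), dendrogram = dend,
            B = B)
}

#' Fit the multiscale-bootstrap curve for one clade
#'
#' Given bootstrap probabilities `bp_r` observed at resample-size scales `r`,
#' transforms to probits `z_r = qnorm(1 - bp_r)` (with `bp_r` clipped to
#' `[1/(B+1), B/(B+1)]`), fits `z_r = v * sqrt(r) + c / sqrt(r)` by weighted
#' least squares (delta-method binomial weights), and returns the
#' approximately unbiased p-value `AU = 1 - pnorm(v - c)`. Curves observed at
#' frequency 0 or 1 at every scale are degenerate: AU is clipped to 0 or 1.
#'
#' @param bp Bootstrap probabilities, one per scale.
#' @param r Scales (resample size / n).
#' @param B Replicates per scale (scalar or vector).
#' @return Tibble `au`, `v`, `c`, `degenerate`.
#' @export
fit_au <- function(bp, r, B) {
  stopifnot(length(bp) == length(r))
  B <- rep_len(B, length(bp))
  if (all(bp >= 1)) {
    return(tibble::tibble(au = 1, v = -Inf, c = 0, degenerate = TRUE))
  }
  if (all(bp <= 0)) {
    return(tibble::tibble(au = 0, v = Inf, c = 0, degenerate = TRUE))
  }
  bpc <- pmin(pmax(bp, 1 / (B + 1)), B / (B + 1))
  z <- stats::qnorm(1 - bpc)
  X <- cbind(sqrt(r), 1 / sqrt(r))
  w <- B * stats::dnorm(z)^2 / (bpc * (1 - bpc))
  fit <- stats::lm.wfit(X, z, w)
  v <- unname(fit$coefficients[1])
  c <- unname(fit$coefficients[2])
  tibble::tibble(au = 1 - stats::pnorm(v - c), v = v, c = c,
                 degenerate = FALSE)
}

#' Multiscale bootstrap (AU) support
#'
#' Runs the bootstrap at several resample sizes `round(r * n)` and
#' extrapolates each clade's probit-transformed support curve ([fit_au()]) to
#' obtain approximately unbiased p-values alongside the ordinary BP at scale
#' 1.
#'
#' @param wide Wide sera-by-allergens data frame.
#' @param scales Relative resample sizes (default 0.5 to 1.4 by 0.1).
#' @param B Replicates per scale (default 1000).
#' @param seed Integer seed.
#' @return A `cluster_support` tibble: `node`, `clade`, `n_leaves`, `bp`
#'   (scale closest to 1), `au`, `v`, `c`, `degenerate`; per-scale counts in
#'   attribute `"scale_table"`, reference tree in `"dendrogram"`.
#' @export
multiscale_au <- function(wide, scales = seq(0.5, 1.4, by = 0.1), B = 1000,
                          seed = 1L) {
  if (B <= 0) stop("B must be positive", call. = FALSE)
  dend <- average_linkage_cluster(correlation_distance(wide))
  num <- as.matrix(wide[, vapply(wide, is.numeric, logical(1)), drop = FALSE])
  num <- num[, dend$labels, drop = FALSE]
  n <- nrow(num)
  sizes <- pmax(round(scales * n), 3L)
  if (any(round(scales * n) < 3)) {
    stop("scaled resample sizes round(r * n) must be >= 3; matrix too small ",
         "for the smallest scale", call. = FALSE)
  }
  keys <- clade_keys(dend)
  hit_mat <- matrix(0L, length(keys), length(scales))
  withr::with_seed(seed, {
    for (s in seq_along(scales)) {
      for (b in seq_len(B)) {
        bk <- boot_clades(num, sizes[s])
        hit_mat[, s] <- hit_mat[, s] + (keys %in% bk)
      }
    }
  })
  bp_mat <- hit_mat / B
  r_eff <- sizes / n
  fits <- purrr::map_dfr(seq_along(keys),
                         function(k) fit_au(bp_mat[k, ], r_eff, B))
  near1 <- which.min(abs(r_eff - 1))
  out <- tibble::tibble(
    node = seq_along(keys),
    clade = dendrogram_clades(dend),
    n_leaves = lengths(dendrogram_clades(dend)),
    bp = bp_mat[, near1]
  ) |>
    dplyr::bind_cols(fits)
  scale_table <- tibble::tibble(
    node = rep(seq_along(keys), length(scales)),
    scale = rep(r_eff, each = length(keys)),
    bp = as.vector(bp_mat), B = B
  )
  structure(out, class = c("cluster_support", class(out)), dendrogram = dend,
            B = B, scale_table = scale_table)
}

newick_quote <- function(x) {
  needs <- grepl("[][ ():;,']", x)
  x[needs] <- paste0("'", gsub("'", "''", x[needs]), "'")
  x
}

#' Export a dendrogram as a Newick string
#'
#' Ultrametric export: each leaf sits at depth 0 and each internal node at
#' half its merge height, so a two-leaf merge at height 0.4 renders as
#' `(A:0.2,B:0.2);`. Internal nodes are labelled `AU/BP` when support is
#' supplied; labels containing spaces or Newick metacharacters are quoted.
#'
#' @param dend An `ige_dendrogram`.
#' @param support Optional `cluster_support` for the same tree.
#' @param digits Branch-length digits (default 6).
#' @return A single Newick string (terminated by `;`).
#' @export
export_newick <- function(dend, support = NULL, digits = 6) {
  depth <- dend$height / 2
  node_label <- function(k) {
    if (is.null(support)) return("")
    row <- support[support$node == k, ]
    if (!nrow(row)) return("")
    if ("au" %in% names(row)) {
      sprintf("'%.2f/%.2f'", row$au[1], row$bp[1])
    } else sprintf("'%.2f'", row$bp[1])
  }
  fmt <- function(x) sprintf("%.*g", digits, x)
  build <- function(node, parent_depth) {
    if (node < 0) {
      return(paste0(newick_quote(dend$labels[-node]), ":",
                    fmt(parent_depth)))
    }
    left <- build(dend$merge[node, 1], depth[node])
    right <- build(dend$merge[node, 2], depth[node])
    paste0("(", left, ",", right, ")", node_label(node), ":",
           fmt(parent_depth - depth[node]))
  }
  root <- nrow(dend$merge)
  left <- build(dend$merge[root, 1], depth[root])
  right <- build(dend$merge[root, 2], depth[root])
  paste0("(", left, ",", right, ")", node_label(root), ";")
}
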