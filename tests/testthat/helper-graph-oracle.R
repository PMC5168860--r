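# brute-force oracles for the CC detector and the Davies-Bouldin index

# connected components by union-find over an explicit edge list
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (length(edges) > 0 && nrow(edges) > 0) {
    for (r in seq_len(nrow(edges))) {
      a <- find(edges[r, 1])
      b <- find(edges[r, 2])
      if (a != b) parent[a] <- b
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

# mutual k-NN edge list from the full distance matrix (ties broken by index,
# matching the documented convention; fixtures use continuous coordinates)
brute_mutual_edges <- function(coords, k) {
  n <- nrow(coords)
  d <- as.matrix(stats::dist(coords))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(row) order(row)[seq_len(min(k, n - 1))]))
  edges <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j %in% nn[i, ] && i %in% nn[j, ]) edges <- rbind(edges, c(i, j))
  }
  if (is.null(edges)) matrix(integer(), ncol = 2) else edges
}

# Davies-Bouldin by direct evaluation of the formula
brute_davies_bouldin <- function(coords, labels) {
  ids <- sort(unique(labels[labels != 0]))
  k <- length(ids)
  cent <- list(); scat <- numeric(k)
  for (i in seq_len(k)) {
    m <- coords[labels == ids[i], , drop = FALSE]
    cent[[i]] <- colMeans(m)
    scat[i] <- mean(apply(m, 1, function(p) sqrt(sum((p - cent[[i]])^2))))
  }
  total <- 0
  for (i in seq_len(k)) {
    worst <- -Inf
    for (j in seq_len(k)) {
      if (i == j) next
      dij <- sqrt(sum((cent[[i]] - cent[[j]])^2))
      worst <- max(worst, (scat[i] + scat[j]) / dij)
    }
    total <- total + worst
  }
  total / k
}
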