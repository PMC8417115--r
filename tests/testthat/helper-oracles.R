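# Independent oracles used across tests. Each is deliberately naive
# (loops, enumeration) and shares no code with the package internals.

# two-sample KS statistic by direct ECDF evaluation at pooled points
ksStatOracle <- function(x, y) {
  pts <- sort(unique(c(x, y)))
  max(abs(vapply(pts, function(p) mean(x <= p) - mean(y <= p), 0)))
}

# exact permutation p-value: enumerate all group labelings of the pool
ksPermutationP <- function(x, y) {
  pool <- c(x, y)
  n1 <- length(x)
  obs <- ksStatOracle(x, y)
  combos <- utils::combn(length(pool), n1)
  ds <- apply(combos, 2, function(idx)
    ksStatOracle(pool[idx], pool[-idx]))
  mean(ds >= obs - 1e-12)
}

# brute-force Ward agglomeration: at each step merge the pair of
# clusters whose union minimizes the increase in within-cluster SS
wardBruteForce <- function(x) {
  clusters <- lapply(seq_len(nrow(x)), identity)
  ss <- function(idx) {
    m <- x[idx, , drop = FALSE]
    sum(sweep(m, 2, colMeans(m))^2)
  }
  merges <- list()
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- NULL
    for (i in seq_along(clusters)[-length(clusters)])
      for (j in (i + 1):length(clusters)) {
        cost <- ss(c(clusters[[i]], clusters[[j]])) -
          ss(clusters[[i]]) - ss(clusters[[j]])
        if (is.null(best) || cost < best$cost)
          best <- list(i = i, j = j, cost = cost)
      }
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    merges <- c(merges, list(merged))
    heights <- c(heights, best$cost)
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(members = merges, heights = heights)
}

# member sets of each merge in an hclust tree, in merge order
hclustMemberSets <- function(tree) {
  n <- nrow(tree$merge) + 1
  sets <- vector("list", nrow(tree$merge))
  for (k in seq_len(nrow(tree$merge))) {
    take <- function(v) if (v < 0) -v else sets[[v]]
    sets[[k]] <- sort(c(take(tree$merge[k, 1]), take(tree$merge[k, 2])))
  }
  sets
}

# pooled two-sample t-test statistic and p, hand-coded
pooledTOracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  s2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (n1 + n2 - 2)
  t <- (mean(a) - mean(b)) / sqrt(s2 * (1 / n1 + 1 / n2))
  list(t = t, p = 2 * stats::pt(-abs(t), n1 + n2 - 2))
}

# full design table used by matrix-level DE tests
nullDesign <- function(nReps = 4, timepoint = "2d") {
  data.frame(group = rep(c("YB1", "PBS"), each = nReps),
             timepoint = timepoint)
}
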