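# Independent oracles used across test files. These deliberately avoid the
# package's own linear-algebra route so that agreement is informative.

# Signed-walk enumeration: influence entry (i, j) as the average over walk
# lengths 1..lmax of (sum of sign products over directed walks i -> j of
# length l) / (number of walks in the unsigned graph), 0/0 -> 0.
walk_influence_oracle <- function(topo, lmax) {
  genes <- topo$genes
  n <- length(genes)
  edges <- topo$edges
  out_nbrs <- lapply(genes, function(g) which(edges$source == g))
  infl <- matrix(0, n, n, dimnames = list(genes, genes))
  for (i in seq_len(n)) {
    # walks[[l]] entries: list of (current node index, sign product)
    for (j in seq_len(n)) {
      total <- 0
      signed <- unsigned <- numeric(lmax)
      # depth-first enumeration of walks starting at i
      rec <- function(node, depth, sgn) {
        if (depth > 0) {
          if (node == j) {
            signed[depth] <<- signed[depth] + sgn
            unsigned[depth] <<- unsigned[depth] + 1
          }
        }
        if (depth == lmax) return()
        for (e in out_nbrs[[node]]) {
          nxt <- match(edges$target[e], genes)
          rec(nxt, depth + 1L, sgn * edges$sign[e])
        }
      }
      rec(i, 0L, 1)
      contrib <- ifelse(unsigned == 0, 0, signed / unsigned)
      infl[i, j] <- sum(contrib) / lmax
    }
  }
  infl
}

# All bipartitions of genes into two non-empty teams; returns the partition
# maximizing the team-strength objective.
best_partition_oracle <- function(infl) {
  genes <- rownames(infl)
  n <- length(genes)
  best <- NULL; best_ts <- -Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(n) - 1L)) > 0)
    t1 <- genes[sel]; t2 <- genes[!sel]
    ts <- team_strength(infl, list(team1 = t1, team2 = t2))$total
    if (ts > best_ts) { best_ts <- ts; best <- list(team1 = t1, team2 = t2) }
  }
  best$total <- best_ts
  best
}

random_small_topology <- function(n_genes, n_edges) {
  genes <- LETTERS[seq_len(n_genes)]
  slots <- sample.int(n_genes^2, n_edges)
  data.frame(source = genes[((slots - 1L) %% n_genes) + 1L],
             target = genes[((slots - 1L) %/% n_genes) + 1L],
             sign = sample(c(-1L, 1L), n_edges, replace = TRUE)) |>
    topology(genes = genes)
}

# fixed symmetric strong toggle-switch parameterization (bistable by design)
toggle_params <- function(topo) {
  list(g = c(A = 50, B = 50), k = c(A = 0.5, B = 0.5),
       edges = cbind(topo$edges,
                     data.frame(n = c(4L, 4L), x0 = c(50, 50),
                                lam = c(0.01, 0.01))))
}
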