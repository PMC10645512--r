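#' Influence matrix of a signed network
#'
#' Direct regulation is only part of the story in a feedback-dense circuit:
#' a gene also acts on every node it can reach through directed walks. The
#' influence matrix averages, over walk lengths `1..lmax`, the signed walk
#' count between each ordered gene pair normalized by the walk count of the
#' corresponding unsigned network, so each entry lies in `[-1, 1]`:
#'
#' \deqn{Infl = \frac{1}{l_{max}} \sum_{l=1}^{l_{max}}
#'       Adj^{l} \oslash Adj_{max}^{l}}
#'
#' where `Adj_max` is the adjacency matrix with all inhibitions replaced by
#' activations and the division is element-wise with the convention
#' 0/0 = 0 (pairs joined by no walk of length `l` contribute nothing).
#'
#' @param adj integer adjacency matrix as returned by [adjacency_matrix()],
#'   or a [topology()] object.
#' @param lmax maximum walk length (default 8).
#' @return Real matrix in `[-1, 1]` with attribute `lmax`.
#' @export
influence_matrix <- function(adj, lmax = 8L) {
  if (inherits(adj, "topology")) adj <- adjacency_matrix(adj)
  stopifnot(is.matrix(adj), nrow(adj) == ncol(adj))
  lmax <- as.integer(lmax)
  if (is.na(lmax) || lmax < 1L) stop("`lmax` must be a positive integer")
  amax <- abs(adj)
  p <- diag(nrow(adj)); pm <- p
  acc <- matrix(0, nrow(adj), ncol(adj))
  for (l in seq_len(lmax)) {
    p <- p %*% adj
    pm <- pm %*% amax
    acc <- acc + ifelse(pm == 0, 0, p / pm)
  }
  infl <- acc / lmax
  dimnames(infl) <- dimnames(adj)
  attr(infl, "lmax") <- lmax
  infl
}

#' Partition network genes into two antagonistic teams
#'
#' Hierarchically clusters the rows of the influence matrix (Euclidean
#' distance) and cuts the tree at two clusters. In team-structured circuits
#' the rows of genes that effectively activate the same partners and
#' inhibit the rest are nearly identical, so the two clusters recover the
#' mutually inhibiting teams. The result is deterministic given the matrix.
#'
#' @param infl influence matrix from [influence_matrix()].
#' @param linkage agglomeration method passed to [stats::hclust()]
#'   (default "complete").
#' @return List with character vectors `team1` and `team2` (disjoint,
#'   covering all genes). `team1` is the cluster containing the first gene.
#' @export
cluster_teams <- function(infl, linkage = "complete") {
  stopifnot(is.matrix(infl))
  n <- nrow(infl)
  if (n < 2L) stop("need at least 2 genes to partition into teams")
  genes <- rownames(infl)
  if (is.null(genes)) genes <- as.character(seq_len(n))
  cut <- stats::cutree(stats::hclust(stats::dist(infl), method = linkage), 2L)
  list(team1 = genes[cut == cut[1L]], team2 = genes[cut != cut[1L]])
}

#' Team strength of a two-team partition
#'
#' For teams K, L the block strength is the mean influence over all ordered
#' gene pairs of the block, \eqn{T_{KL} = \sum_{i \in K, j \in L}
#' Infl_{ij} / (|K||L|)} (diagonal included), and the network-level team
#' strength is \eqn{T_S = (|T_{11}| + |T_{12}| + |T_{21}| + |T_{22}|)/4},
#' which lies in `[0, 1]`. A value near 1 means near-perfect mutual
#' activation within teams and mutual inhibition across them.
#'
#' @param infl influence matrix.
#' @param partition list with `team1`, `team2` as from [cluster_teams()].
#' @return List with `team1`, `team2`, `block` (2x2 matrix of T_KL values)
#'   and `total` (T_S).
#' @export
team_strength <- function(infl, partition = cluster_teams(infl)) {
  stopifnot(is.matrix(infl))
  genes <- rownames(infl)
  t1 <- partition$team1; t2 <- partition$team2
  if (length(t1) == 0L || length(t2) == 0L) stop("teams must be non-empty")
  if (!setequal(c(t1, t2), genes) || length(intersect(t1, t2)))
    stop("teams must partition the genes of the influence matrix")
  block <- matrix(NA_real_, 2L, 2L,
                  dimnames = list(c("team1", "team2"), c("team1", "team2")))
  teams <- list(t1, t2)
  for (k in 1:2) for (l in 1:2) {
    sub <- infl[teams[[k]], teams[[l]], drop = FALSE]
    block[k, l] <- sum(sub) / length(sub)
  }
  list(team1 = t1, team2 = t2, block = block,
       total = sum(abs(block)) / 4)
}

#' Shuffle the edges of a topology
#'
#' Generates one randomized network conserving the node set, the edge
#' count, and the numbers of activating and inhibiting edges. Two modes:
#'
#' * `"degree"` (default): repeated double-edge swaps — two edges
#'   `a -> b`, `c -> d` become `a -> d`, `c -> b` — preserving every
#'   node's in- and out-degree; the sign multiset is then re-dealt across
#'   the rewired edges.
#' * `"uniform"`: source/target endpoints re-drawn uniformly at random
#'   over all gene pairs (degrees not preserved).
#'
#' Both modes forbid duplicate (source, target) pairs; self-loops are
#' allowed, as in the wild-type network.
#'
#' @param t a [topology()] object with at least 2 edges.
#' @param mode `"degree"` or `"uniform"`.
#' @param nswap number of accepted swaps in `"degree"` mode (default
#'   `10 *` edge count).
#' @return A new [topology()] object on the same gene set.
#' @export
randomize_topology <- function(t, mode = c("degree", "uniform"),
                               nswap = NULL) {
  stopifnot(inherits(t, "topology"))
  mode <- match.arg(mode)
  ne <- nrow(t$edges)
  if (ne < 2L) stop("need at least 2 edges to randomize")
  n <- length(t$genes)
  if (ne > n * n) stop("more edges than gene pairs; cannot avoid duplicates")
  signs <- sample(t$edges$sign)
  if (mode == "uniform") {
    slots <- sample.int(n * n, ne)
    src <- t$genes[((slots - 1L) %% n) + 1L]
    tgt <- t$genes[((slots - 1L) %/% n) + 1L]
  } else {
    src <- t$edges$source
    tgt <- t$edges$target
    if (is.null(nswap)) nswap <- 10L * ne
    done <- 0L; tries <- 0L; max_tries <- 100L * nswap
    while (done < nswap && tries < max_tries) {
      tries <- tries + 1L
      ij <- sample.int(ne, 2L)
      i <- ij[1L]; j <- ij[2L]
      # proposed: src[i] -> tgt[j], src[j] -> tgt[i]
      key <- paste(src, tgt, sep = "\r")
      k1 <- paste(src[i], tgt[j], sep = "\r")
      k2 <- paste(src[j], tgt[i], sep = "\r")
      if (k1 %in% key || k2 %in% key) next
      tmp <- tgt[i]; tgt[i] <- tgt[j]; tgt[j] <- tmp
      done <- done + 1L
    }
  }
  topology(data.frame(source = src, target = tgt, sign = signs),
           genes = t$genes)
}

#' Team-strength null distribution from randomized networks
#'
#' Re-computes the full pipeline — influence matrix, two-team clustering,
#' team strength — for `n_random` edge-shuffled versions of the input
#' network, giving the null distribution against which the wild-type team
#' strength is judged. Teams are re-clustered for every random network.
#' The empirical p-value uses the add-one convention
#' `(# random >= observed + 1) / (n_random + 1)`.
#'
#' @param t a [topology()] object.
#' @param n_random number of randomized networks (default 1000).
#' @param lmax maximum walk length for the influence matrix.
#' @param seed optional integer seed for reproducibility.
#' @param mode randomization mode, see [randomize_topology()].
#' @return List with `wt_strength`, `random_strengths` (length `n_random`),
#'   `p_value` and `seed`.
#' @export
null_distribution <- function(t, n_random = 1000L, lmax = 8L, seed = NULL,
                              mode = "degree") {
  stopifnot(inherits(t, "topology"))
  n_random <- as.integer(n_random)
  if (is.na(n_random) || n_random < 1L) stop("`n_random` must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  wt <- team_strength(influence_matrix(adjacency_matrix(t), lmax))$total
  rnd <- vapply(seq_len(n_random), function(i) {
    rt <- randomize_topology(t, mode = mode)
    team_strength(influence_matrix(adjacency_matrix(rt), lmax))$total
  }, numeric(1L))
  list(wt_strength = wt, random_strengths = rnd,
       p_value = (sum(rnd >= wt) + 1) / (n_random + 1), seed = seed)
}
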