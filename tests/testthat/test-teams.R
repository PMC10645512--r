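toys <- toy_topologies()

test_that("influence matrix matches closed forms on the toggle switch", {
  adj <- adjacency_matrix(toys$toggle)
  expect_equal(unname(influence_matrix(adj, lmax = 1)),
               matrix(c(0, -1, -1, 0), 2, byrow = TRUE), ignore_attr = TRUE)
  # Adj^2 = I and Adjmax^2 = I, so averaging l = 1, 2 gives +-0.5
  expect_equal(unname(influence_matrix(adj, lmax = 2)),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, byrow = TRUE),
               ignore_attr = TRUE)
  expect_error(influence_matrix(adj, lmax = 0), "lmax")
})

test_that("influence matrix agrees with exhaustive signed-walk enumeration", {
  set.seed(421)
  adj3 <- adjacency_matrix(toys$cycle3)
  expect_equal(unname(influence_matrix(adj3, lmax = 3)),
               unname(walk_influence_oracle(toys$cycle3, 3)),
               ignore_attr = TRUE)
  for (rep in 1:8) {
    n <- sample(2:5, 1)
    tp <- random_small_topology(n, sample.int(n^2, 1))
    for (lmax in 1:4)
      expect_equal(unname(influence_matrix(adjacency_matrix(tp), lmax)),
                   unname(walk_influence_oracle(tp, lmax)),
                   tolerance = 1e-12, ignore_attr = TRUE)
  }
})

test_that("two-team clustering recovers planted and mutual-inhibition teams", {
  tgl <- influence_matrix(adjacency_matrix(toys$toggle), 2)
  pt <- cluster_teams(tgl)
  expect_equal(sort(c(pt$team1, pt$team2)), c("A", "B"))
  expect_equal(lengths(pt[c("team1", "team2")]), c(team1 = 1L, team2 = 1L))

  # planted block structure: +0.8 within, -0.8 across
  genes <- paste0("G", 1:6)
  blk <- matrix(-0.8, 6, 6, dimnames = list(genes, genes))
  blk[1:3, 1:3] <- 0.8; blk[4:6, 4:6] <- 0.8
  pt <- cluster_teams(blk)
  expect_true(setequal(pt$team1, genes[1:3]) || setequal(pt$team1, genes[4:6]))
  # exhaustive-search oracle finds the same optimum
  oracle <- best_partition_oracle(blk)
  expect_true(setequal(oracle$team1, pt$team1) || setequal(oracle$team1, pt$team2))

  expect_error(cluster_teams(blk[1, , drop = FALSE]), "at least 2")
})

test_that("wild-type network splits into the epithelial and mesenchymal teams", {
  infl <- influence_matrix(adjacency_matrix(toys$wt), 8)
  pt <- cluster_teams(infl)
  mes <- c("ZEB1", "SNAIL", "SLUG", "LIN28", "OCT4", "ERa36", "BACH1")
  epi <- c("miR200", "let7", "miR145", "CDH1", "ERa66", "RKIP")
  expect_true(setequal(pt$team1, mes) || setequal(pt$team1, epi))
  expect_true(setequal(c(pt$team1, pt$team2), c(mes, epi)))
})

test_that("team strength follows its block-mean definition", {
  tgl <- influence_matrix(adjacency_matrix(toys$toggle), 2)
  ts <- team_strength(tgl, list(team1 = "A", team2 = "B"))
  expect_equal(ts$total, 0.5)
  expect_equal(unname(ts$block), matrix(c(0.5, -0.5, -0.5, 0.5), 2))

  zero <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_equal(team_strength(zero, list(team1 = "a", team2 = c("b", "c")))$total, 0)
  expect_error(team_strength(tgl, list(team1 = c("A", "B"), team2 = character())),
               "non-empty")
})

test_that("team strength is invariant to team relabeling and node permutation", {
  set.seed(77)
  for (rep in 1:5) {
    tp <- random_small_topology(5, 12)
    infl <- influence_matrix(adjacency_matrix(tp), 4)
    pt <- cluster_teams(infl)
    t_ab <- team_strength(infl, pt)$total
    t_ba <- team_strength(infl, list(team1 = pt$team2, team2 = pt$team1))$total
    expect_equal(t_ab, t_ba)
    perm <- sample(nrow(infl))
    t_perm <- team_strength(infl[perm, perm],
                            list(team1 = pt$team1, team2 = pt$team2))$total
    expect_equal(t_ab, t_perm)
  }
})

test_that("randomization conserves nodes, edge count and sign composition", {
  wt <- toys$wt
  set.seed(5)
  for (mode in c("degree", "uniform")) {
    for (rep in 1:10) {
      r <- randomize_topology(wt, mode = mode)
      expect_identical(r$genes, wt$genes)
      expect_equal(nrow(r$edges), nrow(wt$edges))
      expect_equal(sum(r$edges$sign == -1L), sum(wt$edges$sign == -1L))
      expect_false(anyDuplicated(paste(r$edges$source, r$edges$target)) > 0)
    }
  }
  # degree mode additionally preserves in/out degrees
  set.seed(6)
  r <- randomize_topology(wt, mode = "degree")
  expect_equal(table(factor(r$edges$source, wt$genes)),
               table(factor(wt$edges$source, wt$genes)))
  expect_equal(table(factor(r$edges$target, wt$genes)),
               table(factor(wt$edges$target, wt$genes)))
})

test_that("different seeds give different shuffles", {
  wt <- toys$wt
  set.seed(1); r1 <- randomize_topology(wt)
  set.seed(2); r2 <- randomize_topology(wt)
  expect_false(identical(r1$edges, r2$edges))
  set.seed(1); r1b <- randomize_topology(wt)
  expect_identical(r1$edges, r1b$edges)
})

test_that("uniform mode relocates a lone edge uniformly over gene pairs", {
  # 2 edges (minimum allowed); track where the first lands among 3^2 slots
  tp <- topology(data.frame(source = c("A", "B"), target = c("B", "C"),
                            sign = c(1L, -1L)),
                 genes = c("A", "B", "C"))
  set.seed(99)
  draws <- replicate(4000, {
    r <- randomize_topology(tp, mode = "uniform")
    paste(r$edges$source, r$edges$target)[1]
  })
  counts <- table(factor(draws, levels = outer(c("A","B","C"), c("A","B","C"),
                                               paste)[1:9]))
  # each of the 9 slots should be hit ~ uniformly
  expect_gt(stats::chisq.test(counts)$p.value, 1e-4)
})

test_that("null distribution re-clusters teams and yields a valid p-value", {
  expect_error(null_distribution(toys$wt, n_random = 0), "n_random")
  nd <- null_distribution(toys$two_team, n_random = 30, lmax = 4, seed = 3)
  expect_length(nd$random_strengths, 30)
  expect_true(all(nd$random_strengths >= 0 & nd$random_strengths <= 1))
  expect_true(nd$p_value > 0 && nd$p_value <= 1)
  expect_equal(nd$p_value,
               (sum(nd$random_strengths >= nd$wt_strength) + 1) / 31)
})

test_that("a randomized network is typical within its own null", {
  wt <- toys$wt
  set.seed(11)
  ps <- replicate(3, {
    rnd <- randomize_topology(wt)
    null_distribution(rnd, n_random = 60, lmax = 8, seed = sample.int(1e6, 1))$p_value
  })
  # at least one non-extreme p among replicates (extreme would mean
  # randomized networks carry systematic team structure)
  expect_true(any(ps > 0.05))
})
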