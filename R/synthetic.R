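#' Wild-type 13-node RKIP/BACH1 plasticity network
#'
#' The breast cancer gene regulatory network coupling the
#' epithelial-mesenchymal transition module (SNAIL, SLUG, ZEB1, miR-200,
#' CDH1), the stemness module (OCT4, LIN28, let-7, miR-145) and the
#' tamoxifen-resistance module (ERa66, ERa36) with RKIP and BACH1.
#' 13 genes, 30 signed edges; BACH1 carries a self-inhibition. The edge
#' list is shipped as a `.topo` fixture under `extdata` and is the input
#' to all wild-type analyses — nothing downstream hard-codes it.
#'
#' @return A [topology()] object.
#' @examples
#' wt <- wt_topology()
#' team_strength(influence_matrix(wt, lmax = 8))$total
#' @export
wt_topology <- function() {
  read_topo(system.file("extdata", "wt_rkip_bach1.topo",
                        package = "plastinet", mustWork = TRUE))
}

#' Toy topologies with known answers
#'
#' Small fixture networks used throughout the test-suite and vignette:
#'
#' * `toggle`: two genes inhibiting each other — the canonical bistable
#'   switch; the two teams are the two genes.
#' * `cycle3`: three genes in an all-activation cycle (monostable-prone,
#'   every influence entry positive).
#' * `repressilator`: three genes in an all-inhibition cycle — the classic
#'   oscillator, used to exercise the no-stable-state path.
#' * `two_team`: A<->B and C<->D mutual activation with A and C mutually
#'   inhibiting; teams \{A, B\} vs \{C, D\} by construction.
#' * `wt`: the 13-node wild-type network (see [wt_topology()]).
#'
#' @return Named list of [topology()] objects.
#' @export
toy_topologies <- function() {
  ed <- function(s, t, g) data.frame(source = s, target = t, sign = g)
  list(
    toggle = topology(ed(c("A", "B"), c("B", "A"), c(-1L, -1L))),
    cycle3 = topology(ed(c("A", "B", "C"), c("B", "C", "A"), c(1L, 1L, 1L))),
    repressilator = topology(ed(c("A", "B", "C"), c("B", "C", "A"),
                                c(-1L, -1L, -1L))),
    two_team = topology(ed(c("A", "B", "C", "D", "A", "C"),
                           c("B", "A", "D", "C", "C", "A"),
                           c(1L, 1L, 1L, 1L, -1L, -1L))),
    wt = wt_topology()
  )
}

#' Generate a team-structured synthetic expression matrix
#'
#' Emulates the two-block correlation pattern of transcriptomic cohorts in
#' which one set of genes (an "epithelial team") is positively
#' inter-correlated, a second set (a "mesenchymal team") likewise, and the
#' two sets anti-correlate. The generative model is a two-factor Gaussian:
#' each sample draws latent team activities `f1` and `f2` with correlation
#' `rho_f = cross_cor / within_cor <= 0`, and gene `g` of team `k` is
#' `a * f_k + noise_sd * eps` with `a` chosen so the expected within-team
#' correlation equals `within_cor` (`a^2/(a^2 + noise_sd^2) = within_cor`).
#' A constant offset shifts values positive, mimicking a log2 expression
#' scale.
#'
#' @param n_samples number of samples (columns).
#' @param genes_per_team integer: genes in each of the two teams.
#' @param within_cor target within-team correlation, in (0, 1).
#' @param cross_cor target cross-team correlation, in (-1, 0); must satisfy
#'   `abs(cross_cor) <= within_cor`.
#' @param noise_sd standard deviation of the per-gene noise (default 1).
#' @param offset constant added to shift the matrix positive (default 10).
#' @param seed optional integer seed.
#' @return List with `expr` (genes x samples matrix, rownames
#'   `T1_01.. / T2_01..`), and `teams` (ground-truth team label per gene).
#' @export
synth_expression <- function(n_samples, genes_per_team = 10L,
                             within_cor = 0.6, cross_cor = -0.6,
                             noise_sd = 1, offset = 10, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_samples >= 2L, genes_per_team >= 1L, noise_sd > 0)
  if (!(within_cor > 0 && within_cor < 1))
    stop("`within_cor` must lie in (0, 1)")
  if (!(cross_cor < 0 && cross_cor > -1))
    stop("`cross_cor` must lie in (-1, 0)")
  if (abs(cross_cor) > within_cor)
    stop("unachievable targets: need |cross_cor| <= within_cor")
  a <- noise_sd * sqrt(within_cor / (1 - within_cor))
  rho_f <- cross_cor / within_cor
  f1 <- stats::rnorm(n_samples)
  f2 <- rho_f * f1 + sqrt(1 - rho_f^2) * stats::rnorm(n_samples)
  m <- genes_per_team
  loadings <- rbind(matrix(rep(f1, each = m), m, n_samples),
                    matrix(rep(f2, each = m), m, n_samples))
  noise <- matrix(stats::rnorm(2L * m * n_samples, sd = noise_sd),
                  2L * m, n_samples)
  expr <- offset + a * loadings + noise
  rownames(expr) <- c(sprintf("T1_%02d", seq_len(m)),
                      sprintf("T2_%02d", seq_len(m)))
  colnames(expr) <- sprintf("S%03d", seq_len(n_samples))
  list(expr = expr,
       teams = setNames(rep(c("team1", "team2"), each = m), rownames(expr)))
}
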