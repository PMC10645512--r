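#' Shifted Hill regulation factor
#'
#' The multiplicative factor a regulator `X` applies to its target's
#' production rate: `lam + (1 - lam) / (1 + (x/x0)^n)`. It equals 1 when the
#' regulator is absent, `(1 + lam)/2` at the threshold `x0`, and saturates
#' at the fold change `lam` — greater than 1 for activation, below 1 for
#' inhibition.
#'
#' @param x regulator concentration (>= 0).
#' @param x0 threshold concentration (> 0).
#' @param n Hill coefficient (>= 1).
#' @param lam fold change (> 0); activation if `lam > 1`, inhibition if
#'   `lam < 1`.
#' @return Dimensionless factor, vectorized over `x`.
#' @export
shifted_hill <- function(x, x0, n, lam) {
  if (any(x0 <= 0)) stop("`x0` must be positive")
  if (any(n < 1)) stop("Hill coefficient `n` must be >= 1")
  lam + (1 - lam) / (1 + (x / x0)^n)
}

#' Default kinetic parameter ranges
#'
#' The sampling ranges of the random circuit perturbation convention:
#' production `g ~ U(1, 100)`, degradation `k ~ U(0.1, 1)`, integer Hill
#' coefficient `n ~ U{1..6}`, fold change `lam ~ U(1, 100)` (taken as its
#' reciprocal on inhibitory edges), and thresholds drawn by the
#' half-functional rule `x0 ~ U(0.02 M, 1.98 M)` with
#' `M = median(g-range) / median(k-range)` the scale of an unregulated
#' steady state, so a regulator sits near half-effect on average.
#'
#' @param g production-rate range, length-2 numeric.
#' @param k degradation-rate range.
#' @param hill integer Hill coefficient range.
#' @param fold fold-change range (values > 1).
#' @return List of ranges with the derived threshold range `x0`.
#' @export
parameter_ranges <- function(g = c(1, 100), k = c(0.1, 1),
                             hill = c(1L, 6L), fold = c(1, 100)) {
  stopifnot(all(g > 0), all(k > 0), all(hill >= 1), all(fold >= 1))
  m <- stats::median(g) / stats::median(k)
  list(g = g, k = k, hill = as.integer(hill), fold = fold,
       x0 = c(0.02 * m, 1.98 * m))
}

#' Per-gene operating medians for the half-functional threshold rule
#'
#' The threshold of a regulatory link should sit where the regulator
#' actually operates, so that the link has roughly even odds of being
#' functional across random models. An unregulated gene operates around
#' `median(g)/median(k)`, but regulation shifts that scale by the incoming
#' shifted-Hill factors — a gene under two strong inhibitors lives orders
#' of magnitude lower. This routine estimates each gene's operating median
#' by Monte Carlo: starting from unregulated `g/k` samples, it repeatedly
#' re-draws each gene's level as `g/k` times random incoming Hill factors
#' evaluated at regulator levels drawn from the regulators' current
#' samples (thresholds drawn around the regulators' current medians).
#' A few fixed-point iterations suffice for the medians to settle.
#'
#' @param t a [topology()] object.
#' @param ranges from [parameter_ranges()].
#' @param nsamp Monte Carlo sample size per gene (default 2000).
#' @param iters fixed-point iterations (default 3).
#' @return Named numeric vector: operating median per gene.
#' @export
estimate_operating_medians <- function(t, ranges = parameter_ranges(),
                                       nsamp = 2000L, iters = 3L) {
  stopifnot(inherits(t, "topology"))
  genes <- t$genes
  ng <- length(genes)
  draw_gk <- function() stats::runif(nsamp, ranges$g[1], ranges$g[2]) /
    stats::runif(nsamp, ranges$k[1], ranges$k[2])
  lev <- replicate(ng, draw_gk(), simplify = FALSE)
  names(lev) <- genes
  inc <- split(seq_len(nrow(t$edges)), factor(t$edges$target, levels = genes))
  for (it in seq_len(iters)) {
    med <- vapply(lev, stats::median, numeric(1L))
    lev <- lapply(genes, function(gn) {
      x <- draw_gk()
      for (e in inc[[gn]]) {
        src <- t$edges$source[e]
        xs <- sample(lev[[src]], nsamp, replace = TRUE)
        x0 <- stats::runif(nsamp, 0.02 * med[src], 1.98 * med[src])
        n <- sample(seq(ranges$hill[1], ranges$hill[2]), nsamp, replace = TRUE)
        lam <- stats::runif(nsamp, ranges$fold[1], ranges$fold[2])
        x <- x * if (t$edges$sign[e] == -1L) shifted_hill(xs, x0, n, 1 / lam)
                 else shifted_hill(xs, x0, n, lam) / lam
      }
      x
    })
    names(lev) <- genes
  }
  vapply(lev, stats::median, numeric(1L))
}

#' Sample one random kinetic model for a topology
#'
#' Draws per-gene production and degradation rates and per-edge Hill
#' coefficients, thresholds and fold changes from `ranges`. Inhibitory
#' edges get reciprocal fold changes (`lam < 1`), activating edges
#' `lam > 1`. Thresholds follow the half-functional rule: the threshold of
#' a link from gene `s` is `U(0.02 M_s, 1.98 M_s)` with `M_s` the
#' regulator's operating median (see [estimate_operating_medians()]).
#' Reproducible under the R random number generator state.
#'
#' @param t a [topology()] object.
#' @param ranges from [parameter_ranges()].
#' @param medians per-gene operating medians; computed on the fly when
#'   `NULL`. Ensemble drivers compute them once per topology and pass them
#'   down.
#' @return List with `g`, `k` (named per gene) and data.frame `edges`
#'   (source, target, sign, n, x0, lam).
#' @export
sample_parameters <- function(t, ranges = parameter_ranges(),
                              medians = NULL) {
  stopifnot(inherits(t, "topology"))
  if (is.null(medians)) medians <- estimate_operating_medians(t, ranges)
  ng <- length(t$genes)
  ne <- nrow(t$edges)
  g <- stats::runif(ng, ranges$g[1], ranges$g[2])
  k <- stats::runif(ng, ranges$k[1], ranges$k[2])
  names(g) <- names(k) <- t$genes
  n <- sample(seq(ranges$hill[1], ranges$hill[2]), ne, replace = TRUE)
  msrc <- medians[t$edges$source]
  x0 <- stats::runif(ne, 0.02 * msrc, 1.98 * msrc)
  lam <- stats::runif(ne, ranges$fold[1], ranges$fold[2])
  lam <- ifelse(t$edges$sign == 1L, lam, 1 / lam)
  list(g = g, k = k,
       edges = cbind(t$edges, data.frame(n = n, x0 = unname(x0), lam = lam)))
}

# edges grouped by target, 0-based, CSR-style offsets for the C++ core
.pack_edges <- function(t, params) {
  ng <- length(t$genes)
  e <- params$edges
  ord <- order(match(e$target, t$genes))
  e <- e[ord, , drop = FALSE]
  tgt <- match(e$target, t$genes)
  eoff <- c(0L, cumsum(tabulate(tgt, nbins = ng)))
  list(eoff = as.integer(eoff),
       esrc = as.integer(match(e$source, t$genes) - 1L),
       en = as.integer(e$n), ex0 = e$x0, elam = e$lam)
}

#' Right-hand side of the circuit ODE system
#'
#' `dX_i/dt = g_i * prod_j HS(X_j; x0_ji, n_ji, lam_ji) - k_i X_i`, the
#' product running over all regulators `j` of gene `i` (empty product = 1).
#' `g_i` is the *maximal* production rate: inhibitory factors run from 1
#' down to `lam < 1`, and activating factors are normalized shifted Hills
#' `HS/lam` running from `1/lam` up to 1, so production never exceeds
#' `g_i` and every unregulated steady state is bounded by `g/k`.
#' Pure-R reference implementation used for testing and for interfacing
#' with general-purpose integrators; the ensemble simulator uses a
#' compiled equivalent.
#'
#' @param state named nonnegative concentration vector (gene order of `t`).
#' @param params from [sample_parameters()].
#' @param t a [topology()] object.
#' @return Derivative vector, same order as `state`.
#' @export
ode_rhs <- function(state, params, t) {
  stopifnot(inherits(t, "topology"), length(state) == length(t$genes))
  e <- params$edges
  prod_terms <- params$g
  if (nrow(e) > 0L) {
    si <- match(e$source, t$genes)
    ti <- match(e$target, t$genes)
    hs <- shifted_hill(state[si], e$x0, e$n, e$lam)
    hs <- ifelse(e$sign == 1L, hs / e$lam, hs)
    for (r in seq_len(nrow(e)))
      prod_terms[ti[r]] <- prod_terms[ti[r]] * hs[r]
  }
  unname(prod_terms - params$k * state)
}

#' Stable steady states of one kinetic model
#'
#' Integrates the circuit from `n_inits` random initial conditions
#' (log-uniform over `[0.01 g_min/k_max, g_max/k_min]`, spanning from two
#' decades below the weakest unregulated steady state up to the strongest,
#' so that basins of strongly inhibited attractors are sampled too) until
#' the relative derivative norm falls
#' below `conv_tol`, refines converged endpoints to machine-accurate fixed
#' points by Newton iteration, keeps only linearly stable ones (all
#' Jacobian eigenvalues with negative real part), and merges states closer
#' than `merge_tol` in log2 coordinates.
#'
#' @param params from [sample_parameters()].
#' @param t a [topology()] object.
#' @param n_inits number of initial conditions (default 100).
#' @param ranges parameter ranges (sets the initial-condition window).
#' @param dt Euler step (default 0.1 time units).
#' @param t_max integration horizon per trajectory (default 200).
#' @param conv_tol relative convergence tolerance on `||dX/dt||_inf /
#'   ||X||_inf` (default 1e-6).
#' @param merge_tol distinct-state tolerance in log2 space (default 0.01).
#' @return List with `states` (distinct stable states x genes, raw
#'   concentrations), `basin_counts` (initial conditions reaching each) and
#'   `n_unconverged`.
#' @export
find_steady_states <- function(params, t, n_inits = 100L,
                               ranges = parameter_ranges(), dt = 0.1,
                               t_max = 200, conv_tol = 1e-6,
                               merge_tol = 0.01) {
  stopifnot(inherits(t, "topology"), n_inits >= 1L)
  ng <- length(t$genes)
  hi <- max(ranges$g) / min(ranges$k)
  lo <- 0.01 * min(ranges$g) / max(ranges$k)
  inits <- matrix(exp(stats::runif(ng * n_inits, log(lo), log(hi))),
                  nrow = ng)
  # g is the maximal production rate: normalized activation factors HS/lam
  # are folded into an effective basal rate g / prod(lam_act)
  g_eff <- params$g
  act <- which(params$edges$sign == 1L)
  for (i in act) {
    tg <- params$edges$target[i]
    g_eff[tg] <- g_eff[tg] / params$edges$lam[i]
  }
  pk <- .pack_edges(t, params)
  out <- .steady_states_cpp(unname(g_eff), unname(params$k),
                            pk$eoff, pk$esrc, pk$en, pk$ex0, pk$elam,
                            inits, dt, t_max, conv_tol, merge_tol)
  colnames(out$states) <- t$genes
  out
}

#' Simulate a random-circuit-perturbation ensemble
#'
#' Samples `n_models` random kinetic models of the topology, finds each
#' model's distinct stable steady states from `n_inits` initial conditions,
#' and pools everything: a per-model count of coexisting states (the
#' multistability profile) and the pooled matrix of log2-transformed,
#' gene-wise z-normalized stable states (each distinct state counted once).
#' `replicates` independent repeats quantify run-to-run spread; the pooled
#' matrix concatenates all replicates and carries the replicate id.
#'
#' @param t a [topology()] object.
#' @param n_models random parameter sets per replicate (default 10000).
#' @param n_inits initial conditions per model (default 100).
#' @param ranges from [parameter_ranges()].
#' @param seed integer seed; replicate r uses `seed + r - 1`.
#' @param replicates number of independent repeats (default 3).
#' @param ... further arguments to [find_steady_states()].
#' @return Object of class `"ssensemble"`: list with
#'   * `z`: pooled states x genes matrix, log2 + z-normalized;
#'   * `log2`: same states before z-normalization;
#'   * `replicate`, `model`, `n_states_model`: per pooled state, which
#'     replicate/model produced it and that model's total state count;
#'   * `multistability`: data.frame of per-replicate fractions (percent) of
#'     models with 1, 2, 3, 4+ states or none converged;
#'   * `genes`, `seed`.
#' @export
simulate_ensemble <- function(t, n_models = 10000L, n_inits = 100L,
                              ranges = parameter_ranges(), seed = 1L,
                              replicates = 3L, ...) {
  stopifnot(inherits(t, "topology"), n_models >= 1L, replicates >= 1L)
  genes <- t$genes
  all_states <- list(); all_rep <- list(); all_model <- list()
  all_nstates <- list()
  multi <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    set.seed(seed + r - 1L)
    med <- estimate_operating_medians(t, ranges)
    counts <- integer(n_models)
    states_r <- vector("list", n_models)
    for (m in seq_len(n_models)) {
      p <- sample_parameters(t, ranges, medians = med)
      ss <- find_steady_states(p, t, n_inits = n_inits, ranges = ranges, ...)
      counts[m] <- nrow(ss$states)
      if (counts[m] > 0L) states_r[[m]] <- ss$states
    }
    bins <- c(none = mean(counts == 0L), mono = mean(counts == 1L),
              bi = mean(counts == 2L), tri = mean(counts == 3L),
              multi4 = mean(counts >= 4L)) * 100
    multi[[r]] <- bins
    keep <- which(counts > 0L)
    st <- do.call(rbind, states_r[keep])
    all_states[[r]] <- st
    all_rep[[r]] <- rep.int(r, nrow(st))
    all_model[[r]] <- rep.int(keep, counts[keep])
    all_nstates[[r]] <- rep.int(counts[keep], counts[keep])
  }
  raw <- do.call(rbind, all_states)
  l2 <- log2(pmax(raw, 1e-12))
  multistability <- as.data.frame(do.call(rbind, multi))
  multistability$replicate <- seq_len(replicates)
  out <- list(z = .zscore_cols(l2), log2 = l2,
              replicate = unlist(all_rep), model = unlist(all_model),
              n_states_model = unlist(all_nstates),
              multistability = multistability, genes = genes, seed = seed)
  class(out) <- "ssensemble"
  out
}

#' @export
print.ssensemble <- function(x, ...) {
  cat(sprintf("steady-state ensemble: %d pooled states, %d genes, %d replicate(s)\n",
              nrow(x$z), length(x$genes), max(x$replicate)))
  m <- colMeans(x$multistability[, c("none", "mono", "bi", "tri", "multi4")])
  cat(sprintf("models: %.2f%% none | %.2f%% monostable | %.2f%% bistable | %.2f%% tristable | %.2f%% 4+\n",
              m[1], m[2], m[3], m[4], m[5]))
  invisible(x)
}

.zscore_cols <- function(m) {
  mu <- colMeans(m)
  # population standard deviation: a pool of two states maps to exactly +-1
  sd <- sqrt(colMeans(sweep(m, 2L, mu)^2))
  zero <- sd < .Machine$double.eps
  if (any(zero))
    stop("zero-variance gene(s): ", paste(colnames(m)[zero], collapse = ", "))
  out <- scale(m, center = mu, scale = sd)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  out
}

#' Log2 + z-normalize a pooled state matrix
#'
#' Applies the standard ensemble normalization: log2 transform, then
#' per-gene z-score over all pooled states (population standard
#' deviation). Columns of the result have mean 0 and standard deviation 1.
#'
#' @param raw states x genes matrix of raw steady-state concentrations.
#' @return z-normalized matrix of the same shape.
#' @export
normalize_ensemble <- function(raw) {
  stopifnot(is.matrix(raw), nrow(raw) >= 2L)
  .zscore_cols(log2(pmax(raw, 1e-12)))
}
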