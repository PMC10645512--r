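#' Principal component analysis of a state ensemble
#'
#' PCA of the pooled z-normalized steady states. In team-structured
#' circuits the first component separates the two antagonistic expression
#' programs, so its loadings recover team membership. The sign of each
#' component is fixed so that CDH1 (or, absent CDH1, the first gene) loads
#' positively on PC1, orienting the epithelial team positive.
#'
#' @param z states x genes z-normalized matrix (or an `"ssensemble"`).
#' @return List with `var_frac` (variance fractions, summing to 1),
#'   `loadings` (genes x PCs), `scores` (states x PCs).
#' @export
pca_ensemble <- function(z) {
  if (inherits(z, "ssensemble")) z <- z$z
  stopifnot(is.matrix(z), nrow(z) >= 2L, ncol(z) >= 2L)
  p <- stats::prcomp(z, center = TRUE, scale. = FALSE)
  if (all(p$sdev < .Machine$double.eps)) stop("degenerate (rank-0) matrix")
  anchor <- if ("CDH1" %in% rownames(p$rotation)) "CDH1" else rownames(p$rotation)[1L]
  flip <- ifelse(p$rotation[anchor, ] < 0, -1, 1)
  list(var_frac = p$sdev^2 / sum(p$sdev^2),
       loadings = sweep(p$rotation, 2L, flip, `*`),
       scores = sweep(p$x, 2L, flip, `*`))
}

#' Epithelial-mesenchymal and stemness scores of z-normalized states
#'
#' `em_score = (ZEB1 + SLUG - miR200 - CDH1) / 4`: higher means more
#' mesenchymal. `sn_score = (OCT4 + LIN28 - miR145 - let7) / 4`:
#' intermediate values mark stem-like states, extremes non-stem-like.
#' Both operate on z-normalized expression values and ignore all other
#' genes.
#'
#' @param z states x genes z-normalized matrix (or an `"ssensemble"`), or
#'   a single named state vector.
#' @return Numeric score per state.
#' @export
em_score <- function(z) .axis_score(z, c("ZEB1", "SLUG"), c("miR200", "CDH1"))

#' @rdname em_score
#' @export
sn_score <- function(z) .axis_score(z, c("OCT4", "LIN28"), c("miR145", "let7"))

.axis_score <- function(z, up, down) {
  if (inherits(z, "ssensemble")) z <- z$z
  if (is.null(dim(z))) z <- matrix(z, 1L, dimnames = list(NULL, names(z)))
  missing <- setdiff(c(up, down), colnames(z))
  if (length(missing))
    stop("state matrix lacks gene(s): ", paste(missing, collapse = ", "))
  (rowSums(z[, up, drop = FALSE]) - rowSums(z[, down, drop = FALSE])) / 4
}

#' Phenotype thresholds from Gaussian-mixture density minima
#'
#' Fits an `n_components` Gaussian mixture (unequal variances) to a score
#' distribution and places class boundaries at the minima of the fitted
#' density between adjacent component means, located by grid search
#' (1000 points per interval). Three components on the
#' epithelial-mesenchymal axis give the epithelial | hybrid | mesenchymal
#' cuts; three on the stemness axis give the non-stem | stem | non-stem
#' cuts.
#'
#' @param scores numeric vector (length >= 50).
#' @param n_components 2 or 3.
#' @return Ascending numeric vector of `n_components - 1` thresholds, with
#'   the fitted `mclust` model as attribute `"fit"`.
#' @export
fit_density_minima <- function(scores, n_components = 3L) {
  stopifnot(length(scores) >= 50L, n_components %in% c(2L, 3L))
  mclustBIC <- mclust::mclustBIC  # Mclust resolves this in the caller env
  fit <- mclust::Mclust(scores, G = n_components, modelNames = "V",
                        verbose = FALSE)
  if (is.null(fit)) stop("Gaussian mixture fit failed; inspect the score distribution")
  mu <- fit$parameters$mean
  sdv <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sdv) == 1L) sdv <- rep(sdv, n_components)
  pro <- fit$parameters$pro
  ord <- order(mu)
  mu <- mu[ord]; sdv <- sdv[ord]; pro <- pro[ord]
  dens <- function(x)
    rowSums(vapply(seq_along(mu),
                   function(i) pro[i] * stats::dnorm(x, mu[i], sdv[i]),
                   numeric(length(x))))
  cuts <- numeric(n_components - 1L)
  for (i in seq_len(n_components - 1L)) {
    grid <- seq(mu[i], mu[i + 1L], length.out = 1000L)
    d <- dens(grid)
    j <- which.min(d)
    if (j == 1L || j == length(grid))
      warning("density minimum sits at a component mean; components may not be separated")
    cuts[i] <- grid[j]
  }
  structure(sort(cuts), fit = fit)
}

#' Classify states along the EM and SN axes
#'
#' Epithelial-mesenchymal classes: score below the lower cut is
#' epithelial (`"E"`), between the cuts hybrid (`"hybrid"`), above the
#' upper cut mesenchymal (`"M"`). Stemness classes: between the cuts is
#' `"stem"`, outside `"non-stem"`. A score exactly on a cut goes to the
#' lower class. Per-gene status is `"+ve"` when the z-value is strictly
#' positive, else `"-ve"`.
#'
#' @param z states x genes z-normalized matrix (or an `"ssensemble"`).
#' @param em_cuts,sn_cuts length-2 ascending thresholds (see
#'   [fit_density_minima()]).
#' @return data.frame with `em_score`, `sn_score`, `em_class`, `sn_class`
#'   and one `<gene>_status` factor column per gene.
#' @export
classify_states <- function(z, em_cuts, sn_cuts) {
  if (inherits(z, "ssensemble")) z <- z$z
  stopifnot(length(em_cuts) == 2L, length(sn_cuts) == 2L,
            !is.unsorted(em_cuts), !is.unsorted(sn_cuts))
  em <- em_score(z); sn <- sn_score(z)
  em_class <- cut(em, c(-Inf, em_cuts, Inf), labels = c("E", "hybrid", "M"),
                  right = TRUE)
  sn_class <- factor(ifelse(sn > sn_cuts[1L] & sn <= sn_cuts[2L],
                            "stem", "non-stem"),
                     levels = c("non-stem", "stem"))
  out <- data.frame(em_score = em, sn_score = sn,
                    em_class = em_class, sn_class = sn_class)
  status <- ifelse(z > 0, "+ve", "-ve")
  colnames(status) <- paste0(colnames(z), "_status")
  cbind(out, as.data.frame(status))
}

#' Conditional probability of gene status given phenotype
#'
#' For each phenotype class, the percentage of states in which the gene's
#' z-normalized expression is positive versus negative — e.g. the
#' probability that a hybrid epithelial/mesenchymal state is BACH1-high.
#' Rows sum to 100.
#'
#' @param calls data.frame from [classify_states()].
#' @param gene gene symbol.
#' @param axis `"em"` (classes E / hybrid / M) or `"sn"`
#'   (non-stem / stem).
#' @return data.frame with columns `class`, `n`, `pos_pct`, `neg_pct`.
#' @export
conditional_probabilities <- function(calls, gene, axis = c("em", "sn")) {
  axis <- match.arg(axis)
  col <- paste0(gene, "_status")
  if (!col %in% names(calls)) stop("no status column for gene ", gene)
  cls <- calls[[paste0(axis, "_class")]]
  out <- do.call(rbind, lapply(levels(cls), function(lv) {
    idx <- cls == lv
    n <- sum(idx)
    pos <- if (n == 0L) NA_real_ else 100 * mean(calls[[col]][idx] == "+ve")
    data.frame(class = lv, n = n, pos_pct = pos, neg_pct = 100 - pos)
  }))
  if (anyNA(out$pos_pct)) warning("empty phenotype class; probabilities undefined")
  out
}

#' Sarle's bimodality coefficient
#'
#' `BC = (s^2 + 1) / (k + 3 (n-1)^2 / ((n-2)(n-3)))` with `s` the sample
#' skewness and `k` the sample excess kurtosis (normal = 0). BC is about
#' 1/3 for a normal sample, 5/9 for a uniform one, and approaches 1 for a
#' symmetric two-point distribution; values above 0.55 are conventionally
#' read as bimodal.
#'
#' @param values numeric vector, length >= 4.
#' @return BC in (0, 1].
#' @export
bimodality_coefficient <- function(values) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 4L) stop("need at least 4 values")
  m <- mean(values)
  m2 <- mean((values - m)^2)
  if (m2 < .Machine$double.eps) stop("zero-variance input")
  s <- mean((values - m)^3) / m2^1.5
  k <- mean((values - m)^4) / m2^2 - 3
  (s^2 + 1) / (k + 3 * (n - 1)^2 / ((n - 2) * (n - 3)))
}
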