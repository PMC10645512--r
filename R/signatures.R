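#' Read a log2 expression matrix
#'
#' Genes in rows (first column = gene symbols), samples in columns.
#' Delimiter is inferred from the file extension (`.csv` = comma,
#' otherwise tab). Duplicate gene symbols or missing values are errors:
#' scoring assumes a clean log2-scale matrix.
#'
#' @param path TSV/CSV file path.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                          stringsAsFactors = FALSE)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stop("duplicate gene symbols in ", path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  if (anyNA(m)) stop("missing values in ", path)
  rownames(m) <- genes
  m
}

#' Read a gene signature file
#'
#' One gene symbol per line; blank lines and `#` comments are ignored;
#' duplicates are dropped.
#'
#' @param path plain-text file path.
#' @param name signature name (defaults to the file base name).
#' @return Character vector of gene symbols with attribute `"name"`.
#' @export
read_signature <- function(path, name = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  genes <- unique(lines)
  if (!length(genes)) stop("empty signature: ", path)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  structure(genes, name = name)
}

#' Single-sample gene-set enrichment scores
#'
#' The standard single-sample running-sum statistic: per sample, genes are
#' ranked by expression (descending); walking down the ranking, signature
#' genes add their rank weight `|r|^weight` (normalized to sum 1) and
#' non-signature genes subtract `1/(N - n_sig)`; the score is the sum of
#' the running-sum deviations over all positions. Scores are then
#' min-max normalized across samples. Being rank-based, the score is
#' invariant to any strictly increasing transform of a sample's values.
#'
#' @param expr genes x samples log2 expression matrix.
#' @param signature character vector of gene symbols (see
#'   [read_signature()]); genes absent from `expr` are dropped with a
#'   warning provided at least one remains.
#' @param weight rank weighting exponent (default 0.25).
#' @param normalize `"minmax"` (default, across-sample range
#'   normalization), `"zscore"`, or `"none"` (raw running-sum totals).
#' @return Named numeric vector of per-sample scores.
#' @export
ssgsea_scores <- function(expr, signature, weight = 0.25,
                          normalize = c("minmax", "zscore", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(is.matrix(expr), !is.null(rownames(expr)))
  sig <- intersect(signature, rownames(expr))
  if (!length(sig))
    stop("no signature gene present in the expression matrix")
  if (length(sig) < length(unique(signature)))
    warning(sprintf("%d signature gene(s) absent from the matrix, dropped",
                    length(unique(signature)) - length(sig)))
  n_tot <- nrow(expr)
  in_sig <- rownames(expr) %in% sig
  if (all(in_sig)) stop("signature covers every gene; score undefined")
  raw <- vapply(seq_len(ncol(expr)), function(j) {
    ord <- order(expr[, j], decreasing = TRUE)
    hit <- in_sig[ord]
    r <- rank(expr[, j], ties.method = "average")[ord]  # high expr = high rank
    w <- abs(r)^weight
    pos <- ifelse(hit, w, 0)
    pos <- pos / sum(pos)
    neg <- ifelse(hit, 0, 1 / (n_tot - length(sig)))
    sum(cumsum(pos - neg))
  }, numeric(1L))
  names(raw) <- colnames(expr)
  switch(normalize,
         none = raw,
         zscore = (raw - mean(raw)) / stats::sd(raw),
         minmax = {
           rng <- range(raw)
           if (diff(rng) < .Machine$double.eps) return(stats::setNames(rep(0, length(raw)), names(raw)))
           (raw - rng[1L]) / diff(rng)
         })
}

#' Signed Kolmogorov-Smirnov epithelial-mesenchymal score
#'
#' Compares the empirical CDFs of a sample's epithelial-signature and
#' mesenchymal-signature expression values:
#' `score = sup(F_epi - F_mes) - sup(F_mes - F_epi)`, bounded in
#' `[-1, 1]`. When epithelial genes are expressed below mesenchymal genes
#' their CDF dominates and the score is positive — the higher the score,
#' the more mesenchymal the sample. Antisymmetric under swapping the two
#' signatures.
#'
#' @param values named numeric vector of one sample's log2 expression, or
#'   a genes x samples matrix (then a vector of scores is returned).
#' @param epi_sig,mes_sig character vectors of epithelial / mesenchymal
#'   signature genes; at least 2 of each must be present.
#' @return Score(s) in `[-1, 1]`.
#' @export
ks_emt_score <- function(values, epi_sig, mes_sig) {
  if (is.matrix(values))
    return(vapply(seq_len(ncol(values)), function(j)
      ks_emt_score(values[, j], epi_sig, mes_sig), numeric(1L)))
  e <- values[names(values) %in% epi_sig]
  m <- values[names(values) %in% mes_sig]
  if (length(e) < 2L || length(m) < 2L)
    stop("need at least 2 usable genes in each signature")
  grid <- sort(unique(c(e, m)))
  fe <- stats::ecdf(e)(grid)
  fm <- stats::ecdf(m)(grid)
  max(c(fe - fm, 0)) - max(c(fm - fe, 0))
}

#' Spearman correlation matrix with p-values
#'
#' Pairwise Spearman rank correlations (average ranks on ties) between the
#' columns of a samples x variables table, with two-sided p-values from
#' [stats::cor.test()]. Constant columns yield `NA` correlations and a
#' warning.
#'
#' @param table samples x variables numeric matrix or data.frame (e.g.
#'   signature scores cbind-ed with selected gene rows of an expression
#'   matrix, samples in rows).
#' @return List with matrices `rho` (unit diagonal, symmetric) and `p`.
#' @export
spearman_matrix <- function(table) {
  m <- as.matrix(table)
  stopifnot(nrow(m) >= 3L)
  nv <- ncol(m)
  constant <- apply(m, 2L, function(x) stats::sd(x) < .Machine$double.eps)
  if (any(constant))
    warning("constant column(s): ", paste(colnames(m)[constant], collapse = ", "))
  rho <- diag(nv); p <- matrix(NA_real_, nv, nv)
  dimnames(rho) <- dimnames(p) <- list(colnames(m), colnames(m))
  diag(p) <- 0
  for (i in seq_len(nv - 1L)) for (j in (i + 1L):nv) {
    if (constant[i] || constant[j]) { rho[i, j] <- rho[j, i] <- NA_real_; next }
    ct <- suppressWarnings(stats::cor.test(m[, i], m[, j], method = "spearman",
                                           exact = FALSE))
    rho[i, j] <- rho[j, i] <- unname(ct$estimate)
    p[i, j] <- p[j, i] <- ct$p.value
  }
  list(rho = rho, p = p)
}
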