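#' Construct a signed gene regulatory network topology
#'
#' A topology is the single source of truth for every downstream analysis:
#' an ordered set of gene symbols plus a signed directed edge list. Signs
#' follow the usual convention of transcriptional circuit models: `+1` for
#' activation, `-1` for inhibition. Self-loops are allowed (the wild-type
#' breast cancer network contains a BACH1 self-inhibition).
#'
#' @param edges data.frame with columns `source`, `target` (gene symbols)
#'   and `sign` (+1 or -1). Gene names are matched exactly and
#'   case-sensitively; no alias resolution is attempted.
#' @param genes optional character vector fixing the gene order. Defaults to
#'   first-appearance order in `edges`. Genes with no edges may be included
#'   here.
#' @return An object of class `"topology"`: a list with elements `genes`
#'   (character) and `edges` (data.frame with `source`, `target`, `sign`).
#' @examples
#' toggle <- topology(data.frame(source = c("A", "B"), target = c("B", "A"),
#'                               sign = c(-1L, -1L)))
#' adjacency_matrix(toggle)
#' @export
topology <- function(edges, genes = NULL) {
  stopifnot(is.data.frame(edges))
  if (nrow(edges) > 0L) {
    need <- c("source", "target", "sign")
    if (!all(need %in% names(edges)))
      stop("`edges` must have columns source, target, sign")
    edges <- edges[, need]
    edges$source <- as.character(edges$source)
    edges$target <- as.character(edges$target)
    edges$sign <- as.integer(edges$sign)
    if (!all(edges$sign %in% c(-1L, 1L)))
      stop("edge sign must be +1 (activation) or -1 (inhibition)")
    key <- paste(edges$source, edges$target, sep = "\r")
    if (anyDuplicated(key)) {
      d <- key[duplicated(key)][1L]
      stop("duplicate edge: ", sub("\r", " -> ", d))
    }
  } else {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer())
  }
  seen <- unique(c(rbind(edges$source, edges$target)))
  if (is.null(genes)) {
    genes <- seen
  } else {
    genes <- as.character(genes)
    if (anyDuplicated(genes)) stop("duplicate gene names in `genes`")
    missing <- setdiff(seen, genes)
    if (length(missing))
      stop("edge endpoints not in `genes`: ", paste(missing, collapse = ", "))
  }
  structure(list(genes = genes, edges = edges), class = "topology")
}

#' @export
print.topology <- function(x, ...) {
  cat(sprintf("topology: %d genes, %d edges (%d activating, %d inhibiting)\n",
              length(x$genes), nrow(x$edges),
              sum(x$edges$sign == 1L), sum(x$edges$sign == -1L)))
  invisible(x)
}

#' @export
`==.topology` <- function(e1, e2) {
  identical(e1$genes, e2$genes) &&
    nrow(e1$edges) == nrow(e2$edges) &&
    all(e1$edges == e2$edges)
}

#' Read a topology file
#'
#' Parses the whitespace-delimited `.topo` dialect used by random circuit
#' perturbation tools: a header line `Source Target Type` followed by one
#' edge per line, `Type` 1 meaning activation and 2 meaning inhibition.
#' Gene order in the returned topology is first-appearance order.
#'
#' @param path path to a `.topo` file.
#' @return A [topology()] object.
#' @seealso [write_topo()]
#' @export
read_topo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 1L) stop("empty topology file: ", path)
  header <- toupper(strsplit(trimws(lines[[1L]]), "\\s+")[[1L]])
  if (!identical(header[1:3], c("SOURCE", "TARGET", "TYPE")))
    stop("expected header 'Source Target Type' in ", path)
  body <- lines[-1L]
  src <- tgt <- character(length(body))
  sgn <- integer(length(body))
  for (i in seq_along(body)) {
    f <- strsplit(trimws(body[[i]]), "\\s+")[[1L]]
    if (length(f) != 3L)
      stop(sprintf("%s: line %d: expected 3 fields, got %d",
                   path, i + 1L, length(f)))
    if (!f[3L] %in% c("1", "2"))
      stop(sprintf("%s: line %d: unknown interaction Type '%s' (must be 1 or 2)",
                   path, i + 1L, f[3L]))
    src[i] <- f[1L]; tgt[i] <- f[2L]
    sgn[i] <- if (f[3L] == "1") 1L else -1L
  }
  key <- paste(src, tgt, sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1L]
    stop(sprintf("%s: line %d: duplicate edge %s -> %s",
                 path, i + 1L, src[i], tgt[i]))
  }
  topology(data.frame(source = src, target = tgt, sign = sgn))
}

#' Write a topology file
#'
#' Inverse of [read_topo()]: writes the `Source Target Type` format with
#' Type 1 for activation and 2 for inhibition. Reading the file back yields
#' a topology identical to `t` provided `t`'s gene order is first-appearance
#' order (isolated genes are not representable in the format).
#'
#' @param t a [topology()] object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_topo <- function(t, path) {
  stopifnot(inherits(t, "topology"))
  type <- ifelse(t$edges$sign == 1L, 1L, 2L)
  lines <- c("Source\tTarget\tType",
             sprintf("%s\t%s\t%d", t$edges$source, t$edges$target, type))
  writeLines(lines, path)
  invisible(path)
}

#' Adjacency matrix of a topology
#'
#' Rows index source genes and columns index target genes; entry (i, j) is
#' the sign of the edge i -> j, or 0 when there is none.
#'
#' @param t a [topology()] object.
#' @return An integer matrix with entries in \{-1, 0, +1\} and `dimnames`
#'   equal to the topology's gene order.
#' @export
adjacency_matrix <- function(t) {
  stopifnot(inherits(t, "topology"))
  n <- length(t$genes)
  adj <- matrix(0L, n, n, dimnames = list(t$genes, t$genes))
  if (nrow(t$edges) > 0L) {
    i <- match(t$edges$source, t$genes)
    j <- match(t$edges$target, t$genes)
    adj[cbind(i, j)] <- t$edges$sign
  }
  adj
}
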