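#' All-vs-all log10 p-value matrix
#'
#' Computes, for every unordered genome pair, the similarity S at the
#' best strand orientation and converts it to a log10 p-value under the
#' significance model. The result is the clustering substrate: a
#' symmetric matrix of log10 p with a -Inf diagonal sentinel
#' (self-similarity is excluded from clustering edges). Values are kept
#' on the log10 scale throughout so cutoffs far below the double
#' underflow limit (e.g. 1e-86) remain representable; entries below
#' `clamp` are clamped to it.
#'
#' @param genomes a genome set, >= 2 genomes, each at least w long.
#' @param params a [wmer_params()].
#' @param model a [evd_model()]; defaults to the packaged constants
#'   when `params` is the standard setting.
#' @param both_strands evaluate each pair on both strands of the second
#'   genome (use `FALSE` only for strand-corresponded input).
#' @param clamp lower bound applied to log10 p (underflow sentinel).
#' @return object of class `pvgc_pmatrix`: `ids`, `log10p` (symmetric
#'   matrix), `S` (scores), `orientations` (strand of the column genome
#'   at the best score), `params`, `model`.
#' @export
pairwise_pmatrix <- function(genomes, params = wmer_params(),
                             model = default_evd_model(params),
                             both_strands = TRUE, clamp = -10000) {
  if (length(genomes) < 2) stop("need at least 2 genomes")
  short <- Biostrings::width(genomes) < params$w
  if (any(short)) {
    stop("genome(s) shorter than w = ", params$w, ": ",
         paste(names(genomes)[short], collapse = ", "))
  }
  n <- length(genomes)
  ids <- names(genomes)
  S <- matrix(0, n, n, dimnames = list(ids, ids))
  ori <- matrix("forward", n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sc <- if (both_strands) {
        best_orientation_score(genomes[i], genomes[j], params)
      } else {
        count_wmer_pairs(genomes[i], genomes[j], params)
      }
      S[i, j] <- S[j, i] <- sc$S
      ori[i, j] <- ori[j, i] <- sc$orientation_b
    }
  }
  lp <- matrix(evd_pvalue(as.vector(S), model)$log10p, n, n,
               dimnames = list(ids, ids))
  lp[lp < clamp] <- clamp
  diag(lp) <- -Inf
  diag(S) <- NA_real_
  structure(list(ids = ids, log10p = lp, S = S, orientations = ori,
                 params = params, model = model),
            class = "pvgc_pmatrix")
}

#' @export
print.pvgc_pmatrix <- function(x, ...) {
  off <- x$log10p[upper.tri(x$log10p)]
  cat(sprintf(
    "p-matrix: %d genomes, %d pairs; log10 p range [%.1f, %.1f]\n",
    length(x$ids), length(off), min(off), max(off)))
  invisible(x)
}

#' Cluster genomes at a p-value cutoff
#'
#' Builds the similarity graph whose edges are the genome pairs with
#' log10 p <= `cutoff_log10p` (smaller p = stronger similarity) and
#' returns its connected components. Component labels are deterministic:
#' each component is named after its lexicographically smallest member
#' id.
#'
#' @param pmatrix a [pairwise_pmatrix()].
#' @param cutoff_log10p finite log10 p cutoff (e.g. -69 for p = 1e-69).
#' @return object of class `pvgc_clusters`: `cutoff_log10p`,
#'   `membership` (named vector id -> component label), `components`
#'   (list of id vectors), `singletons`, `edge_count`.
#' @export
threshold_clusters <- function(pmatrix, cutoff_log10p) {
  stopifnot(is.finite(cutoff_log10p))
  adj <- pmatrix$log10p <= cutoff_log10p
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  labels <- vapply(split(pmatrix$ids, comp),
                   function(m) min(m), character(1))
  membership <- setNames(labels[as.character(comp)], pmatrix$ids)
  components <- split(pmatrix$ids, membership)
  structure(list(
    cutoff_log10p = cutoff_log10p,
    membership = membership,
    components = components,
    singletons = names(membership)[membership %in%
      names(which(table(membership) == 1))],
    edge_count = sum(adj) / 2
  ), class = "pvgc_clusters")
}

#' @export
print.pvgc_clusters <- function(x, ...) {
  cat(sprintf(
    "clusters at log10 p <= %g: %d component(s), %d singleton(s), %d edge(s)\n",
    x$cutoff_log10p, length(x$components), length(x$singletons),
    x$edge_count))
  invisible(x)
}

#' Sweep clustering cutoffs and locate separation levels
#'
#' Clusters the genome set at each cutoff of a descending (loosest to
#' strictest) sequence of log10 p levels — the standard way to expose
#' hierarchical relationships: at loose cutoffs everything joins one
#' component; tightening the cutoff progressively separates genera and
#' then species groups. For every genome pair the sweep also records its
#' separation level: the loosest (largest) cutoff in the sequence at
#' which the pair already sits in different components (`NA` when the
#' pair stays connected throughout).
#'
#' @param pmatrix a [pairwise_pmatrix()].
#' @param cutoffs numeric log10 p levels sorted in decreasing order
#'   (e.g. `c(-10, -39, -56, -69, -86)`).
#' @return object of class `pvgc_sweep`: `cutoffs`, `clusters` (list of
#'   [threshold_clusters()] results) and `separation` (symmetric matrix
#'   of separation levels).
#' @export
cutoff_sweep <- function(pmatrix, cutoffs) {
  stopifnot(!is.unsorted(rev(cutoffs)))
  clusters <- lapply(cutoffs, function(co) threshold_clusters(pmatrix, co))
  n <- length(pmatrix$ids)
  sep <- matrix(NA_real_, n, n, dimnames = list(pmatrix$ids, pmatrix$ids))
  for (k in seq_along(cutoffs)) {          # loosest first
    mem <- clusters[[k]]$membership
    apart <- outer(mem, mem, "!=")
    fill <- apart & is.na(sep)
    sep[fill] <- cutoffs[k]
  }
  structure(list(cutoffs = cutoffs, clusters = clusters,
                 separation = sep),
            class = "pvgc_sweep")
}

#' @export
print.pvgc_sweep <- function(x, ...) {
  for (cl in x$clusters) {
    cat(sprintf("  log10 p <= %6g: %d component(s)\n",
                cl$cutoff_log10p, length(cl$components)))
  }
  invisible(x)
}

#' Export a p-matrix in CLANS format
#'
#' Writes the similarity network in the file format consumed by
#' force-directed sequence clustering viewers: a `sequences=<N>` header,
#' a `<seq>` block with the FASTA records in matrix order, and an
#' `<hsp>` block with one `i j:p` line per informative pair (0-based
#' indices, linear-scale p in exponent notation; pairs with p = 1 are
#' omitted). A plain edge-list TSV (`id_a`, `id_b`, `log10p`) is written
#' alongside when `edges_tsv` is given.
#'
#' @param pmatrix a [pairwise_pmatrix()].
#' @param genomes the genome set the matrix was built from (sequences
#'   for the `<seq>` block).
#' @param path output CLANS file path.
#' @param edges_tsv optional path for the edge-list TSV.
#' @return `path`, invisibly.
#' @export
clans_export <- function(pmatrix, genomes, path, edges_tsv = NULL) {
  stopifnot(identical(names(genomes), pmatrix$ids))
  n <- length(pmatrix$ids)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("sequences=%d", n), con)
  writeLines("<seq>", con)
  for (i in seq_len(n)) {
    writeLines(c(paste0(">", pmatrix$ids[i]), .seq_chr(genomes, i)), con)
  }
  writeLines("</seq>", con)
  writeLines("<hsp>", con)
  rows <- character(0)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      lp <- pmatrix$log10p[i, j]
      if (lp >= 0) next                    # p = 1: uninformative
      # linear-scale p in exponent notation, built from log10 p so
      # values below double underflow still serialize (m.mmme-xxx)
      expo <- floor(lp)
      mant <- 10^(lp - expo)
      rows <- c(rows, sprintf("%d %d:%.6fe%d", i - 1L, j - 1L, mant, expo))
    }
  }
  writeLines(rows, con)
  writeLines("</hsp>", con)
  if (!is.null(edges_tsv)) {
    idx <- which(upper.tri(pmatrix$log10p), arr.ind = TRUE)
    utils::write.table(
      data.frame(id_a = pmatrix$ids[idx[, 1]],
                 id_b = pmatrix$ids[idx[, 2]],
                 log10p = signif(pmatrix$log10p[idx], 6)),
      edges_tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read back an edge-list TSV written by [clans_export()]
#'
#' @param path edge-list TSV path.
#' @return data frame with `id_a`, `id_b`, `log10p`.
#' @export
read_edge_list <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}

#' Simple force-directed 2D layout of the similarity graph
#'
#' Cosmetic companion to [threshold_clusters()]: pairs below the cutoff
#' attract with strength proportional to min(-log10 p, cap)/cap, all
#' pairs repel inversely with distance, and positions are relaxed
#' iteratively from a seeded random start. Cluster membership should be
#' read from the connected components, which are exact; the layout only
#' arranges them for display.
#'
#' @param pmatrix a [pairwise_pmatrix()].
#' @param cutoff_log10p attraction cutoff on log10 p.
#' @param iterations relaxation steps (>= 1).
#' @param seed integer seed for the initial coordinates.
#' @param cap saturation constant for the attraction strength.
#' @return object of class `pvgc_layout`: `ids`, `coords` (n x 2),
#'   `iterations`, `seed`.
#' @export
force_layout <- function(pmatrix, cutoff_log10p = -10, iterations = 200L,
                         seed = 1L, cap = 100) {
  n <- length(pmatrix$ids)
  stopifnot(iterations >= 1)
  xy <- .with_seed(seed, matrix(runif(n * 2, -1, 1), ncol = 2))
  if (n == 1) xy <- matrix(0, 1, 2)
  strength <- pmin(-pmatrix$log10p, cap) / cap
  strength[pmatrix$log10p > cutoff_log10p] <- 0
  diag(strength) <- 0
  step <- 0.05
  for (it in seq_len(iterations)) {
    disp <- matrix(0, n, 2)
    for (i in seq_len(n)) {
      d <- sweep(xy, 2, xy[i, ])           # vectors i -> others
      dist2 <- rowSums(d^2)
      dist2[i] <- Inf
      rep_f <- -0.01 * d / dist2           # uniform repulsion
      att_f <- d * strength[i, ]           # attraction along edges
      disp[i, ] <- colSums(rep_f + att_f)
    }
    xy <- xy + step * disp
  }
  structure(list(ids = pmatrix$ids,
                 coords = `dimnames<-`(xy, list(pmatrix$ids, c("x", "y"))),
                 iterations = iterations, seed = seed),
            class = "pvgc_layout")
}

#' Write a p-matrix as a square TSV
#'
#' Header row and first column carry the genome ids; entries are log10 p
#' (the diagonal sentinel is written as `-Inf`).
#'
#' @param pmatrix a [pairwise_pmatrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pmatrix <- function(pmatrix, path) {
  m <- pmatrix$log10p
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmatrix
#' @export
read_pmatrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$id
  structure(list(ids = df$id, log10p = m, S = NULL, orientations = NULL,
                 params = NULL, model = NULL),
            class = "pvgc_pmatrix")
}
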