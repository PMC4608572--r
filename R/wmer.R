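#' Parameters of the w-mer pair-count similarity
#'
#' The similarity statistic S between two genomes counts pairs of length-w
#' windows (one from each genome, every start position, step 1) whose
#' ungapped alignment contains strictly more than `n` identical
#' nucleotides. The defaults, w = 50 and n = 30, are the setting under
#' which the packaged significance model (`u` = 18, `lambda` = 0.1) was
#' fitted for ~5-kb polyomavirus genomes.
#'
#' @param w window length in nucleotides.
#' @param n critical identity count; a window pair qualifies when its
#'   identity count exceeds `n` (strictly, by default).
#' @param mode `"all_pairs"` counts every qualifying ordered window pair
#'   (symmetric in the two genomes); `"best_pair"` counts query windows
#'   whose best match in the other genome qualifies.
#' @param circular treat sequences as circular molecules: windows may
#'   span the junction between the last and first nucleotide.
#' @param strict if `TRUE` (default) a pair needs identity > n; if
#'   `FALSE`, identity >= n (sensitivity analyses only).
#' @return an object of class `pvgc_wmer_params`.
#' @examples
#' wmer_params()            # the standard setting: w = 50, n = 30
#' wmer_params(w = 25, n = 15, mode = "best_pair")
#' @export
wmer_params <- function(w = 50L, n = 30L,
                        mode = c("all_pairs", "best_pair"),
                        circular = FALSE, strict = TRUE) {
  mode <- match.arg(mode)
  w <- as.integer(w); n <- as.integer(n)
  if (!(n >= 1L && n < w)) stop("require 1 <= n < w")
  structure(list(w = w, n = n, mode = mode, circular = circular,
                 strict = strict),
            class = "pvgc_wmer_params")
}

#' @export
print.pvgc_wmer_params <- function(x, ...) {
  cat(sprintf("w-mer parameters: w = %d, n = %d (%s), mode = %s%s\n",
              x$w, x$n, if (x$strict) "identity > n" else "identity >= n",
              x$mode, if (x$circular) ", circular" else ""))
  invisible(x)
}

# internal: count on two character sequences; returns S and per-window
# best identity of `a` windows. Circular mode appends the first w-1
# bases so every rotation start contributes a window.
.wmer_count_chr <- function(a, b, params) {
  w <- params$w
  if (params$circular) {
    a <- paste0(a, substr(a, 1L, w - 1L))
    b <- paste0(b, substr(b, 1L, w - 1L))
  }
  ea <- .encode_seq(a)
  eb <- .encode_seq(b)
  if (length(ea) < w || length(eb) < w) {
    stop("sequence shorter than w = ", w)
  }
  res <- .wmer_scan_cpp(ea, eb, w, params$n, params$strict)
  S <- if (params$mode == "all_pairs") res$all_pairs else
    as.numeric(res$best_pairs)
  list(S = S, best_identity = res$best_identity)
}

#' Count qualifying w-mer pairs between two genomes
#'
#' Computes the similarity statistic S: every length-w window of `a` is
#' compared, ungapped, against every length-w window of `b` (sliding step
#' 1 on both), and window pairs whose identity count strictly exceeds
#' `params$n` are counted. Ambiguity codes never match any base,
#' themselves included. The scan visits each of the (La-w+1)(Lb-w+1)
#' window pairs through a per-diagonal rolling identity update (subtract
#' the leaving position, add the entering one), so the total cost is
#' O(La * Lb) rather than O(La * Lb * w).
#'
#' @param a,b genomes: single-element genome sets, or plain named
#'   character strings.
#' @param params a [wmer_params()] object.
#' @return an object of class `pvgc_similarity`: fields `id_a`, `id_b`,
#'   `S`, `orientation_b` (`"forward"` here; see
#'   [best_orientation_score()]), and `params`.
#' @examples
#' p <- wmer_params()
#' a <- genome_set(c(x = strrep("A", 55)))
#' b <- genome_set(c(y = strrep("A", 55)))
#' count_wmer_pairs(a, b, p)$S  # 36: all 6 x 6 window pairs identical
#' @export
count_wmer_pairs <- function(a, b, params = wmer_params()) {
  a <- .as_single_genome(a); b <- .as_single_genome(b)
  r <- .wmer_count_chr(a$seq, b$seq, params)
  .similarity(a$id, b$id, r$S, "forward", params)
}

#' Best-orientation w-mer score
#'
#' Computes S for `b` as given and for its reverse complement, and
#' returns the larger (ties keep the forward strand). This is the
#' pairwise scorer used when building corresponding strands and the
#' all-vs-all p-value matrix, where deposited genomes may sit on either
#' strand of the circular molecule.
#'
#' @inheritParams count_wmer_pairs
#' @return a `pvgc_similarity` with `orientation_b` recording the strand
#'   of `b` that achieved the score.
#' @export
best_orientation_score <- function(a, b, params = wmer_params()) {
  a <- .as_single_genome(a); b <- .as_single_genome(b)
  fwd <- .wmer_count_chr(a$seq, b$seq, params)$S
  rev <- .wmer_count_chr(a$seq, .revcomp_chr(b$seq), params)$S
  if (rev > fwd) {
    .similarity(a$id, b$id, rev, "reverse_complemented", params)
  } else {
    .similarity(a$id, b$id, fwd, "forward", params)
  }
}

.similarity <- function(id_a, id_b, S, orientation_b, params) {
  structure(list(id_a = id_a, id_b = id_b, S = S,
                 orientation_b = orientation_b, params = params),
            class = "pvgc_similarity")
}

#' @export
print.pvgc_similarity <- function(x, ...) {
  cat(sprintf("S(%s, %s) = %s  [b strand: %s; w = %d, n = %d, %s]\n",
              x$id_a, x$id_b, format(x$S), x$orientation_b,
              x$params$w, x$params$n, x$params$mode))
  invisible(x)
}

# accept a 1-element genome set, a named character scalar, or a bare
# string; returns list(id, seq)
.as_single_genome <- function(x) {
  if (is(x, "DNAStringSet")) {
    if (length(x) != 1) stop("expected a single genome, got ", length(x))
    return(list(id = names(x) %||% "genome", seq = as.character(x[[1]])))
  }
  if (is(x, "DNAString")) return(list(id = "genome", seq = as.character(x)))
  stopifnot(is.character(x), length(x) == 1)
  list(id = names(x) %||% "genome", seq = toupper(chartr("Uu", "Tt", x)))
}

#' Sliding-window conservation profile of a query genome
#'
#' For every length-w window of the query (start positions 1-based, step
#' 1), reports the percentage of database genomes that contain at least
#' one window whose ungapped identity with the query window exceeds
#' `params$n`. Both strands of every database genome are searched by
#' default. Plotted along the genome, the profile exposes which regions
#' (e.g. the LTag ATPase domain, the VP1 core) are conserved across a
#' virus family and which are lineage-specific.
#'
#' @param query a single genome (genome set of length 1 or named string).
#' @param database a genome set; an entry sharing the query's id is
#'   excluded.
#' @param params a [wmer_params()] object (`mode` is irrelevant here).
#' @param both_strands search database genomes on both strands.
#' @return object of class `pvgc_profile`: `query_id`, `positions`
#'   (window starts), `percent_similar` (per-window percentage in
#'   [0, 100]), `hits` (0/1 matrix, windows x database genomes), and
#'   `params`.
#' @export
conservation_profile <- function(query, database, params = wmer_params(),
                                 both_strands = TRUE) {
  q <- .as_single_genome(query)
  database <- database[setdiff(names(database), q$id)]
  if (length(database) == 0) stop("database is empty (after excluding the query)")
  w <- params$w
  qseq <- q$seq
  if (params$circular) qseq <- paste0(qseq, substr(qseq, 1L, w - 1L))
  eq_ <- .encode_seq(qseq)
  if (length(eq_) < w) stop("query shorter than w = ", w)
  nwin <- length(eq_) - w + 1L
  thr <- if (params$strict) params$n + 1L else params$n
  hits <- matrix(0L, nrow = nwin, ncol = length(database),
                 dimnames = list(NULL, names(database)))
  for (j in seq_along(database)) {
    dseq <- .seq_chr(database, j)
    if (params$circular) dseq <- paste0(dseq, substr(dseq, 1L, w - 1L))
    best <- .wmer_scan_cpp(eq_, .encode_seq(dseq), w, params$n,
                           params$strict)$best_identity
    if (both_strands) {
      best_rc <- .wmer_scan_cpp(eq_, .encode_seq(.revcomp_chr(dseq)), w,
                                params$n, params$strict)$best_identity
      best <- pmax(best, best_rc)
    }
    hits[, j] <- as.integer(best >= thr)
  }
  structure(list(
    query_id = q$id,
    positions = seq_len(nwin),
    percent_similar = 100 * rowMeans(hits),
    hits = hits,
    params = params
  ), class = "pvgc_profile")
}

#' @export
print.pvgc_profile <- function(x, ...) {
  cat(sprintf(
    "Conservation profile of %s: %d windows vs %d genomes; mean %.1f%%\n",
    x$query_id, length(x$positions), ncol(x$hits),
    mean(x$percent_similar)))
  invisible(x)
}

#' Write a conservation profile as TSV
#'
#' Columns: `window_start_1based`, `percent`. With `hits = TRUE` a second
#' file `<path>.hits.tsv` holds the per-genome 0/1 qualifying matrix.
#'
#' @param profile a `pvgc_profile`.
#' @param path output TSV path.
#' @param hits also write the per-genome hit matrix.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path, hits = FALSE) {
  utils::write.table(
    data.frame(window_start_1based = profile$positions,
               percent = profile$percent_similar),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (hits) {
    utils::write.table(
      cbind(window_start_1based = profile$positions, profile$hits),
      paste0(path, ".hits.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
  }
  invisible(path)
}
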