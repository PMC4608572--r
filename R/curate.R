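#' Filter genomes by length
#'
#' Keeps genomes whose length lies within `[min_len, max_len]` (inclusive
#' bounds). The defaults drop partial genomes and host-integrated
#' sequences when screening public polyomavirus records: molecules
#' shorter than 3500 nt or longer than 8000 nt are discarded.
#'
#' @param genomes a genome set.
#' @param min_len,max_len inclusive length bounds in nucleotides.
#' @return a list with `genomes` (the kept subset, order preserved) and
#'   `report` (a [curation_report]).
#' @export
length_filter <- function(genomes, min_len = 3500L, max_len = 8000L) {
  stopifnot(min_len <= max_len)
  len <- Biostrings::width(genomes)
  keep <- len >= min_len & len <= max_len
  dropped <- data.frame(
    id = names(genomes)[!keep],
    reason = ifelse(len[!keep] < min_len, "too_short", "too_long"),
    length = len[!keep]
  )
  list(
    genomes = genomes[keep],
    report = curation_report(kept = names(genomes)[keep],
                             dropped_length = dropped)
  )
}

#' Resolve ambiguous nucleotides from reference context
#'
#' Replaces each non-ACGT position of every genome by the base found at
#' the aligned center of the best-matching context window among the
#' reference genomes. The context is a window of `context` nucleotides
#' (default 41) centered on the ambiguous position, truncated at sequence
#' ends; ambiguity codes inside the context count as mismatches during
#' the search. A window only provides evidence when its identity fraction
#' strictly exceeds `min_identity` (default 0.6, the same proportion the
#' w-mer similarity rule uses with its default w = 50, n = 30). Among
#' tied best windows the most frequent center base wins; remaining ties
#' break alphabetically. Positions with no qualifying window are left
#' unchanged and flagged unresolved.
#'
#' @param genomes genome set to repair.
#' @param reference_set genome set searched for context evidence; a
#'   genome never serves as its own reference (matched by id).
#' @param context odd context window length in nucleotides.
#' @param min_identity minimum identity fraction (strict) for a context
#'   window to count as evidence.
#' @param both_strands also search the reverse complement of each
#'   reference. Off by default: resolution normally runs before strand
#'   correspondence, and the forward search keeps the evidence trail
#'   simple to audit.
#' @return list with `genomes` (repaired set) and `replacements` (data
#'   frame: id, position, original, replacement, resolved).
#' @export
resolve_ambiguous <- function(genomes, reference_set, context = 41L,
                              min_identity = 0.6, both_strands = FALSE) {
  stopifnot(context %% 2L == 1L, length(reference_set) > 0)
  reps <- list()
  out <- as.character(genomes)
  for (i in seq_along(genomes)) {
    id <- names(genomes)[i]
    seq_chr <- out[[i]]
    amb <- which(!strsplit(seq_chr, "")[[1]] %in% c("A", "C", "G", "T"))
    if (length(amb) == 0) next
    refs <- reference_set[setdiff(names(reference_set), id)]
    if (length(refs) == 0) {
      stop("no reference genomes available for ", id)
    }
    ref_enc <- lapply(as.character(refs), .encode_seq)
    if (both_strands) {
      ref_enc <- c(ref_enc, lapply(as.character(revcomp_genomes(refs)),
                                   .encode_seq))
    }
    chars <- strsplit(seq_chr, "")[[1]]
    for (p in amb) {
      res <- .resolve_one(chars, p, ref_enc, context, min_identity)
      reps[[length(reps) + 1L]] <- data.frame(
        id = id, position = p, original = chars[p],
        replacement = res$base, resolved = res$resolved
      )
      if (res$resolved) chars[p] <- res$base
    }
    out[[i]] <- paste(chars, collapse = "")
  }
  repl <- if (length(reps)) do.call(rbind, reps) else
    data.frame(id = character(0), position = integer(0),
               original = character(0), replacement = character(0),
               resolved = logical(0))
  fixed <- genome_set(out, ids = names(genomes),
                      circular = S4Vectors::mcols(genomes)$circular)
  S4Vectors::mcols(fixed)$source_orientation <-
    S4Vectors::mcols(genomes)$source_orientation
  list(genomes = fixed, replacements = repl)
}

# best-window search for a single ambiguous position.
# chars: query as character vector; p: ambiguous position; ref_enc:
# encoded reference sequences. Returns center base + resolved flag.
.resolve_one <- function(chars, p, ref_enc, context, min_identity) {
  half <- (context - 1L) %/% 2L
  lo <- max(1L, p - half)
  hi <- min(length(chars), p + half)
  ctx <- .encode_seq(paste(chars[lo:hi], collapse = ""))
  lc <- length(ctx)
  center <- p - lo + 1L
  best_score <- -1L
  votes <- integer(0)
  for (re in ref_enc) {
    noff <- length(re) - lc + 1L
    if (noff < 1L) next
    m <- integer(noff)
    idx <- seq_len(noff)
    for (k in seq_len(lc)) {
      if (ctx[k] < 0L) next  # ambiguity in the context never matches
      m <- m + (re[idx + k - 1L] == ctx[k])
    }
    top <- max(m)
    if (top < best_score) next
    cand <- re[which(m == top) + center - 1L]
    cand <- cand[cand >= 0L]  # center must be a concrete base
    if (length(cand) == 0L) next
    tab <- tabulate(cand + 1L, nbins = 4L)
    if (top > best_score) {
      best_score <- top
      votes <- tab
    } else {
      votes <- votes + tab
    }
  }
  qualifies <- best_score > min_identity * lc
  if (!qualifies || sum(votes) == 0L) {
    return(list(base = NA_character_, resolved = FALSE))
  }
  # most frequent center base among tied best windows; ties alphabetical
  base <- c("A", "C", "G", "T")[which.max(votes)]
  list(base = base, resolved = TRUE)
}

#' Orient genomes onto corresponding strands
#'
#' Builds a strand-corresponded genome set: a reference genome (the first
#' in input order unless `reference` names another id) stays forward, and
#' every other genome is kept on whichever strand scores higher against
#' the reference under `scorer`. Ties keep the forward strand. The chosen
#' strand is recorded in the `source_orientation` metadata column, so
#' re-running the operation on its own output changes nothing.
#'
#' @param genomes a genome set.
#' @param scorer function of two nucleotide strings returning an integer
#'   similarity; defaults to the w-mer pair count under `params`.
#' @param reference id of the anchor genome (default: first in input).
#' @param params a [wmer_params()] object for the default scorer.
#' @return the genome set with strands harmonized.
#' @export
orient_strands <- function(genomes, scorer = NULL, reference = NULL,
                           params = wmer_params()) {
  if (length(genomes) == 0) return(genomes)
  if (is.null(scorer)) {
    scorer <- function(x, y) .wmer_count_chr(x, y, params)$S
  }
  ref_idx <- if (is.null(reference)) 1L else match(reference, names(genomes))
  if (is.na(ref_idx)) stop("reference id not found: ", reference)
  ref_seq <- .seq_chr(genomes, ref_idx)
  seqs <- as.character(genomes)
  mc <- S4Vectors::mcols(genomes)
  zero_ids <- character(0)
  for (i in seq_along(genomes)) {
    if (i == ref_idx) next
    fwd <- scorer(ref_seq, seqs[[i]])
    rc <- .revcomp_chr(seqs[[i]])
    rev <- scorer(ref_seq, rc)
    if (fwd == 0 && rev == 0) zero_ids <- c(zero_ids, names(genomes)[i])
    if (rev > fwd) {
      seqs[[i]] <- rc
      mc$source_orientation[i] <-
        if (mc$source_orientation[i] == "forward")
          "reverse_complemented" else "forward"
    }
  }
  if (length(zero_ids)) {
    warning("zero similarity to reference on both strands; kept forward: ",
            paste(zero_ids, collapse = ", "))
  }
  out <- genome_set(seqs, ids = names(genomes), circular = mc$circular)
  S4Vectors::mcols(out)$source_orientation <- mc$source_orientation
  out
}

#' Remove exactly identical genome sequences
#'
#' Drops genomes whose sequence string equals that of an earlier genome
#' in the set (first occurrence retained). Sequences should already be
#' strand-corresponded ([orient_strands()]); circular rotations of the
#' same molecule are deliberately not collapsed.
#'
#' @param genomes a genome set.
#' @return list with `genomes` (unique set) and `report` (a
#'   [curation_report] whose `dropped_duplicates` maps each removed id to
#'   the retained representative).
#' @export
dedup_identical <- function(genomes) {
  seqs <- as.character(genomes)
  dup <- duplicated(seqs)
  rep_of <- names(genomes)[match(seqs, seqs)]
  dropped <- data.frame(id = names(genomes)[dup],
                        representative = rep_of[dup])
  list(
    genomes = genomes[!dup],
    report = curation_report(kept = names(genomes)[!dup],
                             dropped_duplicates = dropped)
  )
}

#' Curation report
#'
#' Bundles the outcome of curation steps: ids kept, ids dropped by the
#' length filter (with reasons), ambiguity replacements, and duplicate
#' ids mapped to their retained representative. The kept ids together
#' with the dropped ids partition the input ids.
#'
#' @param kept character vector of retained ids.
#' @param dropped_length data frame (id, reason, length).
#' @param replaced_ambiguities data frame (id, position, original,
#'   replacement, resolved).
#' @param dropped_duplicates data frame (id, representative).
#' @return an object of class `pvgc_curation_report`.
#' @export
curation_report <- function(kept = character(0),
                            dropped_length = NULL,
                            replaced_ambiguities = NULL,
                            dropped_duplicates = NULL) {
  structure(list(
    kept = kept,
    dropped_length = dropped_length %||%
      data.frame(id = character(0), reason = character(0),
                 length = integer(0)),
    replaced_ambiguities = replaced_ambiguities %||%
      data.frame(id = character(0), position = integer(0),
                 original = character(0), replacement = character(0),
                 resolved = logical(0)),
    dropped_duplicates = dropped_duplicates %||%
      data.frame(id = character(0), representative = character(0))
  ), class = "pvgc_curation_report")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.pvgc_curation_report <- function(x, ...) {
  cat("Curation report:", length(x$kept), "genome(s) kept,",
      nrow(x$dropped_length), "dropped by length,",
      nrow(x$dropped_duplicates), "duplicate(s) removed,",
      nrow(x$replaced_ambiguities), "ambiguity replacement(s)\n")
  invisible(x)
}

# merge two reports produced by consecutive curation steps
.merge_reports <- function(a, b) {
  curation_report(
    kept = b$kept,
    dropped_length = rbind(a$dropped_length, b$dropped_length),
    replaced_ambiguities = rbind(a$replaced_ambiguities,
                                 b$replaced_ambiguities),
    dropped_duplicates = rbind(a$dropped_duplicates, b$dropped_duplicates)
  )
}

#' Write a curation report to TSV and/or JSON
#'
#' The TSV is a long table with columns `id`, `action`
#' (kept / dropped_length / dropped_duplicate / ambiguity_replaced /
#' ambiguity_unresolved) and `detail`.
#'
#' @param report a [curation_report].
#' @param tsv,json output paths (either may be `NULL`).
#' @return invisibly, the long-format data frame written to the TSV.
#' @export
write_curation_report <- function(report, tsv = NULL, json = NULL) {
  empty <- data.frame(id = character(0), action = character(0),
                      detail = character(0))
  block <- function(id, action, detail) {
    if (length(id) == 0) empty else
      data.frame(id = id, action = action, detail = detail)
  }
  rows <- rbind(
    block(report$kept, "kept", ""),
    block(report$dropped_length$id, "dropped_length",
          paste0(report$dropped_length$reason, ":",
                 report$dropped_length$length)),
    block(report$dropped_duplicates$id, "dropped_duplicate",
          report$dropped_duplicates$representative),
    block(report$replaced_ambiguities$id,
          ifelse(report$replaced_ambiguities$resolved,
                 "ambiguity_replaced", "ambiguity_unresolved"),
          paste0(report$replaced_ambiguities$position, ":",
                 report$replaced_ambiguities$original, ">",
                 report$replaced_ambiguities$replacement))
  )
  if (!is.null(tsv)) {
    utils::write.table(rows, tsv, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(unclass(report), json, auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(rows)
}

#' One-call genome curation pipeline
#'
#' Applies, in order: length filtering, optional ambiguity resolution
#' against the surviving set, optional strand correspondence, and
#' optional exact deduplication — the standard preparation of a public
#' genome collection for all-vs-all comparison.
#'
#' @param genomes a genome set.
#' @param min_len,max_len inclusive length bounds (see [length_filter()]).
#' @param resolve resolve ambiguous nucleotides against the kept set.
#' @param orient harmonize strands (see [orient_strands()]).
#' @param dedup drop exact duplicates after orientation.
#' @param params [wmer_params()] for the orientation scorer.
#' @return list with `genomes` and a merged `report`.
#' @export
curate_genomes <- function(genomes, min_len = 3500L, max_len = 8000L,
                           resolve = FALSE, orient = TRUE, dedup = TRUE,
                           params = wmer_params()) {
  lf <- length_filter(genomes, min_len, max_len)
  gs <- lf$genomes
  report <- lf$report
  if (resolve && length(gs) > 1) {
    ra <- resolve_ambiguous(gs, gs)
    gs <- ra$genomes
    report <- .merge_reports(report, curation_report(
      kept = report$kept, replaced_ambiguities = ra$replacements))
  }
  if (orient && length(gs) > 1) gs <- orient_strands(gs, params = params)
  if (dedup) {
    dd <- dedup_identical(gs)
    gs <- dd$genomes
    report <- curation_report(
      kept = dd$report$kept,
      dropped_length = report$dropped_length,
      replaced_ambiguities = report$replaced_ambiguities,
      dropped_duplicates = dd$report$dropped_duplicates)
  }
  list(genomes = gs, report = report)
}
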