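#' Draw a random genome
#'
#' I.i.d. nucleotides from a base composition. The default length and
#' mildly AT-rich composition (A/C/G/T = 0.30/0.20/0.20/0.30) imitate a
#' ~5-kb polyomavirus genome.
#'
#' @param length genome length in nt (>= 1).
#' @param composition probabilities for A, C, G, T (must sum to 1).
#' @param seed optional integer for reproducibility.
#' @param id genome id.
#' @return a single-element genome set.
#' @export
random_genome <- function(length = 5000L,
                          composition = c(A = 0.30, C = 0.20,
                                          G = 0.20, T = 0.30),
                          seed = NULL, id = "random") {
  stopifnot(length >= 1)
  if (length(composition) != 4 || any(composition < 0) ||
      abs(sum(composition) - 1) > 1e-8) {
    stop("composition must be 4 non-negative probabilities summing to 1")
  }
  seq <- .with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE,
           prob = composition), collapse = ""))
  genome_set(setNames(seq, id))
}

#' Mutate a genome with substitutions and indels
#'
#' Each site independently substitutes to a uniformly chosen different
#' base with probability `divergence` (a Jukes-Cantor-like uniform
#' model; tests only need controlled identity levels, so no
#' transition/transversion bias is modeled). Indels occur at rate
#' `indel_rate` per site with geometric lengths (mean
#' `mean_indel_len`), equally likely insertion or deletion. Every event
#' is logged so the mutant can be reconstructed from the ancestor,
#' giving ground truth for downstream tests.
#'
#' @param genome single genome (genome set of length 1 or named string).
#' @param divergence per-site substitution probability, < 0.75.
#' @param indel_rate per-site indel initiation probability.
#' @param mean_indel_len mean indel length (geometric, >= 1).
#' @param seed optional integer.
#' @param id id for the mutant (default `<id>_mut`).
#' @return list with `genome` (mutant set) and `log` (data frame:
#'   type, position, ref, alt), positions on the ancestor, applied in
#'   order: substitutions first, then indels right to left.
#' @export
mutate_genome <- function(genome, divergence = 0.05, indel_rate = 0,
                          mean_indel_len = 2, seed = NULL, id = NULL) {
  stopifnot(divergence >= 0, divergence < 0.75, indel_rate >= 0,
            mean_indel_len >= 1)
  g <- .as_single_genome(genome)
  if (is.null(id)) id <- paste0(g$id, "_mut")
  .with_seed(seed, {
    chars <- strsplit(g$seq, "")[[1]]
    L <- length(chars)
    bases <- c("A", "C", "G", "T")
    log_rows <- list()
    # substitutions
    hit <- which(runif(L) < divergence & chars %in% bases)
    for (p in hit) {
      alt <- sample(setdiff(bases, chars[p]), 1)
      log_rows[[length(log_rows) + 1L]] <- data.frame(
        type = "substitution", position = p, ref = chars[p], alt = alt)
      chars[p] <- alt
    }
    # indels, applied right to left so ancestor positions stay valid
    if (indel_rate > 0) {
      ipos <- which(runif(L) < indel_rate)
      for (p in rev(ipos)) {
        len <- 1L + stats::rgeom(1, 1 / mean_indel_len)
        if (runif(1) < 0.5) {       # deletion of [p, p+len-1]
          len <- min(len, length(chars) - p + 1L)
          if (len < 1) next
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            type = "deletion", position = p,
            ref = paste(chars[p:(p + len - 1L)], collapse = ""),
            alt = "")
          chars <- chars[-(p:(p + len - 1L))]
        } else {                    # insertion after position p
          ins <- sample(bases, len, replace = TRUE)
          log_rows[[length(log_rows) + 1L]] <- data.frame(
            type = "insertion", position = p, ref = "",
            alt = paste(ins, collapse = ""))
          chars <- append(chars, ins, after = p)
        }
      }
    }
    log <- if (length(log_rows)) do.call(rbind, log_rows) else
      data.frame(type = character(0), position = integer(0),
                 ref = character(0), alt = character(0))
    list(genome = genome_set(setNames(paste(chars, collapse = ""), id)),
         log = log)
  })
}

#' Simulate genome families with controlled relatedness
#'
#' Draws an independent random ancestor per family and derives each
#' member by mutating the ancestor, yielding a planted partition whose
#' ground truth is returned alongside the sequences. A configurable
#' fraction of members is stored reverse-complemented, so strand
#' correspondence can be exercised. This is the package's test-bed
#' stand-in for a public virus genome collection: within-family
#' divergence plays the role of strain/species-level variation,
#' between-family sequences are unrelated.
#'
#' @param n_families number of families.
#' @param members members per family (recycled).
#' @param ancestor_length ancestor genome length in nt.
#' @param divergence per-site substitution probability applied to each
#'   member independently (recycled per family).
#' @param indel_rate,mean_indel_len member indel parameters.
#' @param composition ancestor base composition.
#' @param revcomp_fraction fraction of members stored on the opposite
#'   strand.
#' @param seed integer seed; the whole simulation is reproducible.
#' @return list with `genomes` (one set, ids `F<f>_M<m>`) and `truth`
#'   (data frame: id, family, divergence, revcomp).
#' @export
simulate_families <- function(n_families = 3L, members = 4L,
                              ancestor_length = 5000L, divergence = 0.05,
                              indel_rate = 0, mean_indel_len = 2,
                              composition = c(A = 0.30, C = 0.20,
                                              G = 0.20, T = 0.30),
                              revcomp_fraction = 0, seed = 1L) {
  stopifnot(n_families >= 1)
  members <- rep_len(as.integer(members), n_families)
  divergence <- rep_len(divergence, n_families)
  .with_seed(seed, {
    seqs <- character(0)
    truth <- list()
    for (f in seq_len(n_families)) {
      anc <- paste(sample(c("A", "C", "G", "T"), ancestor_length,
                          replace = TRUE, prob = composition),
                   collapse = "")
      for (m in seq_len(members[f])) {
        id <- sprintf("F%d_M%d", f, m)
        mut <- mutate_genome(c(x = anc), divergence = divergence[f],
                             indel_rate = indel_rate,
                             mean_indel_len = mean_indel_len,
                             id = id)$genome
        s <- as.character(mut[[1]])
        rc <- runif(1) < revcomp_fraction
        if (rc) s <- .revcomp_chr(s)
        seqs[id] <- s
        truth[[id]] <- data.frame(id = id, family = f,
                                  divergence = divergence[f],
                                  revcomp = rc)
      }
    }
    list(genomes = genome_set(seqs),
         truth = do.call(rbind, c(truth, make.row.names = FALSE)))
  })
}
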