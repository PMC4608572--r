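#' Find open reading frames with AUG/GUG starts
#'
#' Scans both strands in all three frames for ORFs that begin at a
#' traditional initiation codon (ATG or GTG on the DNA level) and end at
#' the first in-frame stop (TAA/TAG/TGA). By default one ORF is reported
#' per stop-delimited frame segment, opened at the segment's first start
#' codon; `all_starts = TRUE` additionally reports every nested start.
#' A start without a downstream in-frame stop yields no ORF in linear
#' mode; in circular mode the scan continues across the junction, so
#' coordinates may wrap (end < start).
#'
#' Reported coordinates are 1-based inclusive on the forward strand and
#' always include the stop codon, hence `length_bp = 3 *
#' (protein_length_aa + 1)`.
#'
#' @param genome a single genome (genome set of length 1 or named
#'   string).
#' @param min_length_bp minimum ORF length including the stop codon;
#'   multiple of 3, >= 6.
#' @param starts allowed initiation codons.
#' @param circular permit ORFs spanning the circular junction.
#' @param all_starts report nested in-frame starts as separate ORFs.
#' @return data frame with columns `start`, `end`, `strand`, `frame`,
#'   `start_codon`, `length_bp`, `protein_length_aa`, sorted by
#'   (strand, start).
#' @examples
#' find_orfs(c(g = "ATGAAATAA"), min_length_bp = 6)
#' @export
find_orfs <- function(genome, min_length_bp = 150L,
                      starts = c("ATG", "GTG"), circular = FALSE,
                      all_starts = FALSE) {
  stopifnot(min_length_bp >= 6, min_length_bp %% 3 == 0)
  g <- .as_single_genome(genome)
  L <- nchar(g$seq)
  res <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$seq else .revcomp_chr(g$seq)
    scan_seq <- if (circular) paste0(s, s) else s
    orfs <- .orf_scan(scan_seq, starts, min_length_bp, all_starts,
                      max_start = if (circular) L else NA_integer_,
                      max_len = if (circular) L else NA_integer_)
    if (nrow(orfs) == 0) next
    if (strand == "-") {
      # map [a, b] on the reverse strand to forward coordinates
      a <- orfs$start; b <- orfs$end
      orfs$start <- L - ((b - 1L) %% L + 1L) + 1L
      orfs$end <- L - a + 1L
    } else if (circular) {
      orfs$end <- (orfs$end - 1L) %% L + 1L
    }
    orfs$strand <- strand
    res[[strand]] <- orfs
  }
  out <- if (length(res)) do.call(rbind, res) else
    data.frame(start = integer(0), end = integer(0), frame = integer(0),
               start_codon = character(0), length_bp = integer(0),
               strand = character(0))
  out$protein_length_aa <- out$length_bp %/% 3L - 1L
  out <- out[order(out$strand, out$start), c("start", "end", "strand",
                                             "frame", "start_codon",
                                             "length_bp",
                                             "protein_length_aa")]
  rownames(out) <- NULL
  out
}

# scan one strand; coordinates are on the scanned sequence (possibly the
# doubled circular sequence). max_start/max_len bound circular scans so
# each wrapped ORF is reported once and never exceeds the genome length.
.orf_scan <- function(s, starts, min_len, all_starts, max_start = NA,
                      max_len = NA) {
  L <- nchar(s)
  rows <- list()
  for (f in 0:2) {
    ncod <- (L - f) %/% 3L
    if (ncod < 2) next
    pos <- f + 1L + 3L * (seq_len(ncod) - 1L)
    codons <- substring(s, pos, pos + 2L)
    is_stop <- codons %in% c("TAA", "TAG", "TGA")
    is_start <- codons %in% starts
    prev <- 0L                       # codon index of the previous stop
    for (si in which(is_stop)) {
      cand <- which(is_start[(prev + 1L):si]) + prev
      prev <- si
      if (length(cand) == 0) next
      if (!all_starts) cand <- cand[1]
      for (ci in cand) {
        len <- (si - ci + 1L) * 3L
        a <- pos[ci]
        if (len < min_len) next
        if (!is.na(max_len) && len > max_len) next
        if (!is.na(max_start) && a > max_start) next
        rows[[length(rows) + 1L]] <- data.frame(
          start = a, end = pos[si] + 2L, frame = f + 1L,
          start_codon = codons[ci], length_bp = len)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), frame = integer(0),
               start_codon = character(0), length_bp = integer(0))
}

#' Translate a coding sequence
#'
#' Standard nuclear genetic code (table 1). The trailing stop, when
#' present, is rendered as `*` in `aa` but excluded from
#' `protein_length_aa`. An internal stop truncates the reported protein
#' at the first stop and sets the `internal_stop` flag.
#'
#' @param cds nucleotide string, length a multiple of 3.
#' @return list with `aa` (full translation, `*` for stops), `protein`
#'   (up to the first stop), `protein_length_aa`, and `internal_stop`.
#' @examples
#' translate_cds("ATGGCATAA")  # protein "MA", 2 aa
#' @export
translate_cds <- function(cds) {
  cds <- toupper(chartr("Uu", "Tt", as.character(cds)))
  if (nchar(cds) %% 3 != 0) {
    stop("coding sequence length is not a multiple of 3")
  }
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds),
                                           if.fuzzy.codon = "X"))
  stops <- gregexpr("\\*", aa)[[1]]
  has_terminal <- substring(aa, nchar(aa)) == "*"
  internal <- any(stops > 0 & stops < nchar(aa))
  protein <- if (stops[1] > 0) substr(aa, 1, stops[1] - 1) else aa
  list(aa = aa, protein = protein,
       protein_length_aa = nchar(protein),
       internal_stop = internal,
       terminal_stop = has_terminal)
}

.iupac_sets <- c(A = "A", C = "C", G = "G", T = "T", R = "AG", Y = "CT",
                 S = "CG", W = "AT", K = "GT", M = "AC", B = "CGT",
                 D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

#' Scan a genome for a (possibly degenerate) motif
#'
#' Reports every occurrence of the motif, overlapping ones included.
#' IUPAC ambiguity codes in the motif match their base sets; ambiguity
#' codes in the genome match nothing. Hits on the minus strand are
#' occurrences of the motif read 5'->3' on the reverse complement;
#' their coordinates are the leftmost/rightmost forward-strand
#' positions of the matching stretch. The classic use is locating the
#' GAGGC LTag-binding pentanucleotides that mark the polyomavirus
#' origin of replication.
#'
#' @param genome single genome (genome set of length 1 or named string).
#' @param motif IUPAC nucleotide pattern, e.g. `"GAGGC"`.
#' @param both_strands also scan the minus strand.
#' @param flank context nucleotides reported on each side of the hit.
#' @return data frame: `start`, `end`, `strand`, `motif`, `context`.
#' @export
scan_motif <- function(genome, motif, both_strands = TRUE, flank = 5L) {
  g <- .as_single_genome(genome)
  motif <- toupper(motif)
  if (nchar(motif) == 0) stop("empty motif")
  bad <- setdiff(strsplit(motif, "")[[1]], names(.iupac_sets))
  if (length(bad)) {
    stop("invalid IUPAC letter(s) in motif: ", paste(bad, collapse = ", "))
  }
  subject <- Biostrings::DNAString(g$seq)
  hit_rows <- function(pattern, strand) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                  fixed = "subject")
    if (length(m) == 0) return(NULL)
    st <- Biostrings::start(m); en <- Biostrings::end(m)
    data.frame(start = st, end = en, strand = strand, motif = motif,
               context = substring(g$seq, pmax(1, st - flank),
                                   pmin(nchar(g$seq), en + flank)))
  }
  out <- hit_rows(motif, "+")
  if (both_strands) {
    rc <- .revcomp_chr(motif)
    out <- rbind(out, hit_rows(rc, "-"))
  }
  if (is.null(out)) {
    out <- data.frame(start = integer(0), end = integer(0),
                      strand = character(0), motif = character(0),
                      context = character(0))
  }
  out <- out[order(out$start, out$strand), ]
  rownames(out) <- NULL
  out
}

#' Find reverse-complement palindromes
#'
#' Maximal palindromic regions (arm length >= `min_arm`, loop length <=
#' `max_loop`, no mismatches); sub-arms of a longer palindrome are not
#' reported separately. These are the palindromic repeats and "early
#' palindrome" elements of viral replication origins.
#'
#' @param region nucleotide string or single-genome set.
#' @param min_arm minimum arm length (>= 3).
#' @param max_loop maximum loop (spacer) length.
#' @return data frame: `start`, `end`, `arm`, `loop`.
#' @examples
#' find_palindromes("GAATTC", min_arm = 3)  # the EcoRI site
#' @export
find_palindromes <- function(region, min_arm = 3L, max_loop = 4L) {
  stopifnot(min_arm >= 3)
  g <- .as_single_genome(region)
  v <- Biostrings::findPalindromes(Biostrings::DNAString(g$seq),
                                   min.armlength = min_arm,
                                   max.looplength = max_loop)
  if (length(v) == 0) {
    return(data.frame(start = integer(0), end = integer(0),
                      arm = integer(0), loop = integer(0)))
  }
  arm <- Biostrings::palindromeArmLength(v)
  data.frame(start = Biostrings::start(v), end = Biostrings::end(v),
             arm = arm,
             loop = Biostrings::width(v) - 2L * arm)
}

#' Locate AT-rich spans
#'
#' Slides a window along the sequence, keeps windows whose A+T fraction
#' meets `min_fraction`, and merges overlapping qualifying windows into
#' maximal spans — the way the AT-rich tract / TATA region of a viral
#' origin is delimited.
#'
#' @param region nucleotide string or single-genome set.
#' @param window window length in nt.
#' @param min_fraction minimum A+T fraction within a window (0, 1].
#' @return data frame with `start`, `end` of merged spans.
#' @export
at_rich_regions <- function(region, window = 10L, min_fraction = 0.8) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  g <- .as_single_genome(region)
  chars <- strsplit(g$seq, "")[[1]]
  L <- length(chars)
  if (L < window) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  at <- as.integer(chars %in% c("A", "T"))
  cs <- c(0L, cumsum(at))
  starts <- seq_len(L - window + 1L)
  frac <- (cs[starts + window] - cs[starts]) / window
  ok <- which(frac >= min_fraction)
  if (length(ok) == 0) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # merge overlapping/adjacent qualifying windows
  runs <- split(ok, cumsum(c(1L, diff(ok) > window)))
  do.call(rbind, lapply(runs, function(r) {
    data.frame(start = r[1], end = r[length(r)] + window - 1L)
  })) -> spans
  rownames(spans) <- NULL
  spans
}

#' Enumerate GT..AG splice-site candidates
#'
#' Lists every donor/acceptor pair: GT at `donor_pos..donor_pos+1` and
#' AG at `acceptor_pos-1..acceptor_pos`, with the intron spanning
#' `donor_pos..acceptor_pos` inclusive. Candidates are annotated with
#' the intron length and whether its removal preserves the reading
#' frame (length divisible by 3). Filtering by the protein a splice
#' would produce is the caller's concern.
#'
#' @param region nucleotide string or single-genome set; pass the
#'   reverse complement to scan the minus strand.
#' @param min_intron minimum intron length (>= 4: GT + AG).
#' @param max_intron maximum intron length.
#' @return data frame: `donor_pos`, `acceptor_pos`, `intron_length`,
#'   `frame_preserving`.
#' @export
splice_candidates <- function(region, min_intron = 4L,
                              max_intron = Inf) {
  stopifnot(min_intron >= 4)
  g <- .as_single_genome(region)
  chars <- strsplit(g$seq, "")[[1]]
  L <- length(chars)
  donors <- which(chars[-L] == "G" & chars[-1] == "T")          # GT start
  acceptors <- which(chars[-1] == "G" & chars[-L] == "A") + 1L  # AG end
  rows <- list()
  for (d in donors) {
    a_ok <- acceptors[acceptors - d + 1L >= min_intron &
                      acceptors - d + 1L <= max_intron]
    if (length(a_ok) == 0) next
    rows[[length(rows) + 1L]] <- data.frame(
      donor_pos = d, acceptor_pos = a_ok,
      intron_length = a_ok - d + 1L)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(donor_pos = integer(0), acceptor_pos = integer(0),
               intron_length = integer(0))
  out$frame_preserving <- out$intron_length %% 3L == 0L
  out <- out[order(out$donor_pos, out$acceptor_pos), ]
  rownames(out) <- NULL
  out
}

#' Count SNPs between two equal-length sequences
#'
#' Position-by-position comparison (no alignment is performed): the
#' count and list of mismatching positions. Sequences with indels must
#' be aligned or trimmed to a common frame first.
#'
#' @param a,b nucleotide strings (or single-genome sets) of equal
#'   length.
#' @return list with `n_snps` and `snps` (data frame: position,
#'   ref_base, alt_base).
#' @export
hamming_snps <- function(a, b) {
  ga <- .as_single_genome(a); gb <- .as_single_genome(b)
  if (nchar(ga$seq) != nchar(gb$seq)) {
    stop("sequences differ in length (", nchar(ga$seq), " vs ",
         nchar(gb$seq), "); align or trim them to a common frame first")
  }
  ca <- strsplit(ga$seq, "")[[1]]
  cb <- strsplit(gb$seq, "")[[1]]
  pos <- which(ca != cb)
  list(n_snps = length(pos),
       snps = data.frame(position = pos, ref_base = ca[pos],
                         alt_base = cb[pos]))
}

#' Classify coding SNPs as synonymous or nonsynonymous
#'
#' Compares two equal-length in-frame coding sequences codon by codon.
#' Every mismatching nucleotide yields one record carrying its codon
#' index, the two encoded amino acids, the effect, and the conventional
#' substitution notation `<ref_aa><codon_index><alt_aa>` (1-based
#' codons), e.g. `A327T` for an alanine-to-threonine change at codon
#' 327.
#'
#' @param cds_a,cds_b coding sequences, equal length, multiples of 3.
#' @return list with `snps` (data frame: position, ref_base, alt_base,
#'   codon_index, ref_aa, alt_aa, effect, notation), `total`, and
#'   `nonsynonymous`.
#' @export
classify_coding_snps <- function(cds_a, cds_b) {
  ga <- .as_single_genome(cds_a); gb <- .as_single_genome(cds_b)
  if (nchar(ga$seq) %% 3 != 0 || nchar(gb$seq) %% 3 != 0) {
    stop("coding sequence length is not a multiple of 3")
  }
  hs <- hamming_snps(ga$seq, gb$seq)
  snps <- hs$snps
  if (nrow(snps) > 0) {
    snps$codon_index <- (snps$position - 1L) %/% 3L + 1L
    cod_a <- substring(ga$seq, (snps$codon_index - 1L) * 3L + 1L,
                       snps$codon_index * 3L)
    cod_b <- substring(gb$seq, (snps$codon_index - 1L) * 3L + 1L,
                       snps$codon_index * 3L)
    snps$ref_aa <- vapply(cod_a, function(x) translate_cds(x)$aa,
                          character(1), USE.NAMES = FALSE)
    snps$alt_aa <- vapply(cod_b, function(x) translate_cds(x)$aa,
                          character(1), USE.NAMES = FALSE)
    snps$effect <- ifelse(snps$ref_aa == snps$alt_aa, "synonymous",
                          "nonsynonymous")
    snps$notation <- paste0(snps$ref_aa, snps$codon_index, snps$alt_aa)
  } else {
    snps <- data.frame(position = integer(0), ref_base = character(0),
                       alt_base = character(0), codon_index = integer(0),
                       ref_aa = character(0), alt_aa = character(0),
                       effect = character(0), notation = character(0))
  }
  list(snps = snps, total = nrow(snps),
       nonsynonymous = sum(snps$effect == "nonsynonymous"))
}

#' Annotate a genome and write GFF3
#'
#' Runs the annotation scanners (ORFs, a motif, palindromes, AT-rich
#' spans, splice candidates) and writes the combined result as GFF3
#' with 1-based inclusive coordinates.
#'
#' @param genome single genome.
#' @param path output GFF3 path.
#' @param min_orf minimum ORF length in bp.
#' @param motif IUPAC motif to scan (default the LTag-binding
#'   pentanucleotide GAGGC); `NULL` to skip.
#' @param min_arm,max_loop palindrome parameters.
#' @param at_window,at_fraction AT-rich span parameters.
#' @param splice include GT..AG splice candidates (can be numerous).
#' @return invisibly, the list of annotation data frames.
#' @export
annotate_gff3 <- function(genome, path, min_orf = 150L, motif = "GAGGC",
                          min_arm = 3L, max_loop = 4L, at_window = 10L,
                          at_fraction = 0.8, splice = FALSE) {
  g <- .as_single_genome(genome)
  feats <- list()
  orfs <- find_orfs(g$seq, min_length_bp = min_orf)
  if (nrow(orfs)) {
    feats$ORF <- data.frame(start = orfs$start, end = orfs$end,
                            strand = orfs$strand,
                            attr = sprintf("start_codon=%s;protein_aa=%d",
                                           orfs$start_codon,
                                           orfs$protein_length_aa))
  }
  if (!is.null(motif)) {
    mh <- scan_motif(g$seq, motif)
    if (nrow(mh)) {
      feats$motif <- data.frame(start = mh$start, end = mh$end,
                                strand = mh$strand,
                                attr = paste0("motif=", mh$motif))
    }
  }
  pal <- find_palindromes(g$seq, min_arm = min_arm, max_loop = max_loop)
  if (nrow(pal)) {
    feats$palindrome <- data.frame(start = pal$start, end = pal$end,
                                   strand = "+",
                                   attr = sprintf("arm=%d;loop=%d",
                                                  pal$arm, pal$loop))
  }
  atr <- at_rich_regions(g$seq, window = at_window,
                         min_fraction = at_fraction)
  if (nrow(atr)) {
    feats$AT_rich <- data.frame(start = atr$start, end = atr$end,
                                strand = "+", attr = "")
  }
  if (splice) {
    sp <- splice_candidates(g$seq)
    if (nrow(sp)) {
      feats$splice_candidate <- data.frame(
        start = sp$donor_pos, end = sp$acceptor_pos, strand = "+",
        attr = sprintf("intron_length=%d;frame_preserving=%s",
                       sp$intron_length, tolower(sp$frame_preserving)))
    }
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  writeLines(sprintf("##sequence-region %s 1 %d", g$id, nchar(g$seq)),
             con)
  for (type in names(feats)) {
    f <- feats[[type]]
    writeLines(sprintf("%s\tpvgc\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       g$id, type, f$start, f$end, f$strand,
                       ifelse(nzchar(f$attr), f$attr, ".")), con)
  }
  invisible(feats)
}
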