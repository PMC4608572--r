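# brute-force scanners used as oracles -------------------------------------

oracle_palindromes <- function(s, min_arm, max_loop) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  hits <- list()
  for (start in seq_len(L)) {
    for (end in start:L) {
      len <- end - start + 1
      arm <- 0
      while (arm < len %/% 2 &&
             ch[start + arm] == comp[ch[end - arm]]) {
        arm <- arm + 1
      }
      loop <- len - 2 * arm
      if (arm >= min_arm && loop <= max_loop &&
          # maximality: arms cannot extend outward
          (start == 1 || end == L ||
           ch[start - 1] != comp[ch[end + 1]]) &&
          # the reported arm is the full arm for this span
          arm == (len - loop) / 2) {
        hits[[length(hits) + 1]] <- c(start, end, arm, loop)
      }
    }
  }
  if (!length(hits)) {
    return(data.frame(start = integer(0), end = integer(0),
                      arm = integer(0), loop = integer(0)))
  }
  out <- as.data.frame(do.call(rbind, hits))
  names(out) <- c("start", "end", "arm", "loop")
  out
}

oracle_at_rich <- function(s, window, min_fraction) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  ok <- logical(0)
  for (i in seq_len(max(L - window + 1, 0))) {
    ok[i] <- mean(ch[i:(i + window - 1)] %in% c("A", "T")) >= min_fraction
  }
  starts <- which(ok)
  if (!length(starts)) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  # merge overlapping/adjacent qualifying windows into maximal spans
  spans <- list(c(starts[1], starts[1] + window - 1L))
  for (i in starts[-1]) {
    last <- spans[[length(spans)]]
    if (i <= last[2] + 1L) {
      spans[[length(spans)]][2] <- i + window - 1L
    } else {
      spans[[length(spans) + 1L]] <- c(i, i + window - 1L)
    }
  }
  df <- as.data.frame(do.call(rbind, spans))
  names(df) <- c("start", "end")
  df
}

oracle_splices <- function(s, min_intron, max_intron) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  out <- list()
  for (d in seq_len(L - 1)) {
    if (ch[d] != "G" || ch[d + 1] != "T") next
    for (a in seq(d + 1, L)) {
      if (ch[a] != "G" || ch[a - 1] != "A") next
      len <- a - d + 1
      if (len >= min_intron && len <= max_intron) {
        out[[length(out) + 1]] <- c(d, a, len)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(donor_pos = integer(0), acceptor_pos = integer(0),
                      intron_length = integer(0)))
  }
  df <- as.data.frame(do.call(rbind, out))
  names(df) <- c("donor_pos", "acceptor_pos", "intron_length")
  df[order(df$donor_pos, df$acceptor_pos), ]
}

# ORFs ----------------------------------------------------------------------

test_that("the minimal ORF and the stop-codon arithmetic check out", {
  orfs <- find_orfs(c(g = "ATGTAA"), min_length_bp = 6)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, 1L)
  expect_equal(orfs$end, 6L)
  expect_equal(orfs$length_bp, 6L)
  expect_equal(orfs$protein_length_aa, 1L)
  # ORF length in bp maps to protein length as length/3 - 1
  for (n_codons in c(52, 61, 140)) {          # 162, 189, 426 bp
    cds <- paste0("ATG", strrep("GCA", n_codons), "TAA")
    o <- find_orfs(c(g = cds), min_length_bp = 6)
    o <- o[o$strand == "+", ]
    expect_equal(o$length_bp, 3L * (n_codons + 2L))
    expect_equal(o$protein_length_aa, n_codons + 1L)
  }
})

test_that("a start without a downstream in-frame stop yields no ORF", {
  orfs <- find_orfs(c(g = "ATGAAAAAAAAA"), min_length_bp = 6)
  expect_equal(nrow(orfs[orfs$strand == "+", ]), 0)
})

test_that("GTG starts are honored and nested starts only appear on request", {
  s <- paste0("GTG", "AAA", "ATG", "CCC", "TAA")
  first <- find_orfs(c(g = s), min_length_bp = 6)
  first <- first[first$strand == "+", ]
  expect_equal(first$start_codon, "GTG")
  expect_equal(first$start, 1L)
  all_o <- find_orfs(c(g = s), min_length_bp = 6, all_starts = TRUE)
  all_o <- all_o[all_o$strand == "+", ]
  expect_setequal(all_o$start_codon, c("GTG", "ATG"))
})

test_that("minus-strand ORFs carry forward-strand coordinates", {
  plus <- "ATGGCCTAA"
  s <- rc_chr(plus)  # the ORF lives on the minus strand
  orfs <- find_orfs(c(g = s), min_length_bp = 6)
  orfs <- orfs[orfs$strand == "-", ]
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$start, 1L)
  expect_equal(orfs$end, 9L)
  # re-extracting at the coordinates and translating gives the protein
  sub <- substr(s, orfs$start, orfs$end)
  tr <- translate_cds(rc_chr(sub))
  expect_equal(tr$protein_length_aa, orfs$protein_length_aa)
})

test_that("circular mode finds junction-spanning ORFs with wrapped ends", {
  # rotate ATG AAA TAA so it spans the junction: starts at 7, ends at 6
  s <- "AAATAAATG"
  lin <- find_orfs(c(g = s), min_length_bp = 6)
  expect_equal(nrow(lin[lin$strand == "+", ]), 0)
  circ <- find_orfs(c(g = s), min_length_bp = 6, circular = TRUE)
  circ <- circ[circ$strand == "+", ]
  expect_equal(circ$start, 7L)
  expect_equal(circ$end, 6L)
  expect_equal(circ$length_bp, 9L)
})

test_that("every reported ORF re-translates to its declared protein length", {
  set.seed(12)
  for (rep in 1:5) {
    s <- rand_seq(600)
    orfs <- find_orfs(c(g = s), min_length_bp = 30)
    for (r in seq_len(nrow(orfs))) {
      cds <- if (orfs$strand[r] == "+") {
        substr(s, orfs$start[r], orfs$end[r])
      } else {
        rc_chr(substr(s, orfs$start[r], orfs$end[r]))
      }
      expect_equal(substr(cds, 1, 3), orfs$start_codon[r])
      tr <- translate_cds(cds)
      expect_true(tr$terminal_stop)
      expect_false(tr$internal_stop)
      expect_equal(tr$protein_length_aa, orfs$protein_length_aa[r])
      expect_equal(orfs$length_bp[r],
                   3L * (orfs$protein_length_aa[r] + 1L))
    }
  }
})

# translation ---------------------------------------------------------------

test_that("translation handles stops, internal stops, and frame errors", {
  expect_equal(translate_cds("ATGGCA")$protein, "MA")
  expect_false(translate_cds("ATGGCA")$terminal_stop)
  t2 <- translate_cds("ATGTAA")
  expect_equal(t2$protein, "M")
  expect_equal(t2$aa, "M*")
  expect_equal(t2$protein_length_aa, 1L)
  t3 <- translate_cds("ATGTAAGCATAA")
  expect_true(t3$internal_stop)
  expect_equal(t3$protein, "M")
  expect_error(translate_cds("ATGG"), "multiple of 3")
  # 189-bp coding sequence gives a 62-aa protein
  cds <- paste0("ATG", strrep("TGG", 61), "TGA")
  expect_equal(nchar(cds), 189)
  expect_equal(translate_cds(cds)$protein_length_aa, 62L)
})

# motifs --------------------------------------------------------------------

test_that("motif scanning finds overlapping hits with exact coordinates", {
  hits <- scan_motif(c(g = "GAGGCGAGGC"), "GAGGC", both_strands = FALSE)
  expect_equal(hits$start, c(1L, 6L))
  expect_equal(hits$end, c(5L, 10L))
  expect_equal(nrow(scan_motif(c(g = strrep("A", 30)), "GAGGC")), 0)
  # overlapping occurrences are all reported
  ov <- scan_motif(c(g = "AAAA"), "AA", both_strands = FALSE)
  expect_equal(ov$start, 1:3)
  expect_error(scan_motif(c(g = "ACGT"), "GAQ"), "invalid IUPAC")
  expect_error(scan_motif(c(g = "ACGT"), ""), "empty")
})

test_that("IUPAC degeneracy and strand symmetry behave", {
  # R = A or G
  hits <- scan_motif(c(g = "TATGTAAG"), "TRTG", both_strands = FALSE)
  expect_equal(hits$start, 1L)
  # a minus-strand hit appears where the revcomp matches
  s <- "AAGCCTCAA"  # GAGGC revcomp = GCCTC at 3..7
  m <- scan_motif(c(g = s), "GAGGC")
  minus <- m[m$strand == "-", ]
  expect_equal(minus$start, 3L)
  expect_equal(minus$end, 7L)
  expect_equal(rc_chr(substr(s, minus$start, minus$end)), "GAGGC")
  # scanning the revcomp'd genome flips strand labels and coordinates
  m2 <- scan_motif(c(g = rc_chr(s)), "GAGGC")
  expect_equal(nrow(m2[m2$strand == "+", ]), nrow(m[m$strand == "-", ]))
  expect_equal(m2[m2$strand == "+", "start"],
               nchar(s) - m[m$strand == "-", "end"] + 1L)
})

# palindromes ---------------------------------------------------------------

test_that("reverse-complement palindromes match the brute-force checker", {
  hit <- find_palindromes("GAATTC", min_arm = 3)
  expect_equal(hit$start, 1L)
  expect_equal(hit$end, 6L)
  expect_equal(hit$arm, 3L)
  expect_equal(hit$loop, 0L)
  expect_equal(nrow(find_palindromes("AAAAAA", min_arm = 3)), 0)
  set.seed(14)
  for (rep in 1:3) {
    s <- rand_seq(200)
    got <- find_palindromes(s, min_arm = 4, max_loop = 3)
    want <- oracle_palindromes(s, min_arm = 4, max_loop = 3)
    key <- function(d) sort(paste(d$start, d$end, d$arm, d$loop))
    expect_equal(key(got), key(want))
  }
})

# AT-rich spans -------------------------------------------------------------

test_that("AT-rich spans merge qualifying windows like the oracle", {
  expect_equal(at_rich_regions("ATATATATAT", min_fraction = 0.9),
               data.frame(start = 1L, end = 10L))
  expect_equal(nrow(at_rich_regions("GCGCGCGCGC", min_fraction = 0.5)), 0)
  set.seed(15)
  for (rep in 1:5) {
    s <- rand_seq(300)
    spans <- at_rich_regions(s, window = 10, min_fraction = 0.7)
    want <- oracle_at_rich(s, 10, 0.7)
    expect_equal(unname(as.matrix(spans)), unname(as.matrix(want)))
  }
})

# splice candidates ---------------------------------------------------------

test_that("GT..AG enumeration matches hand counts and the brute force", {
  cand <- splice_candidates("AAGTAAAGAA")
  expect_equal(cand$donor_pos, 3L)
  expect_equal(cand$acceptor_pos, 8L)
  expect_equal(cand$intron_length, 6L)
  expect_true(cand$frame_preserving)
  expect_equal(nrow(splice_candidates("AAAACCCC")), 0)
  set.seed(16)
  s <- rand_seq(300)
  got <- splice_candidates(s, min_intron = 10, max_intron = 80)
  want <- oracle_splices(s, 10, 80)
  expect_equal(got$donor_pos, want$donor_pos)
  expect_equal(got$acceptor_pos, want$acceptor_pos)
  expect_equal(got$intron_length, want$intron_length)
})

# SNPs ----------------------------------------------------------------------

test_that("hamming SNP counting is exact, symmetric, and length-checked", {
  expect_equal(hamming_snps("ACGT", "ACGT")$n_snps, 0)
  h <- hamming_snps("ACGT", "ACGA")
  expect_equal(h$n_snps, 1)
  expect_equal(h$snps$position, 4L)
  expect_equal(h$snps$ref_base, "T")
  expect_equal(h$snps$alt_base, "A")
  expect_error(hamming_snps("ACGT", "ACG"), "align or trim")
  set.seed(18)
  a <- rand_seq(300); b <- rand_seq(300); c <- rand_seq(300)
  expect_equal(hamming_snps(a, b)$n_snps, hamming_snps(b, a)$n_snps)
  expect_lte(hamming_snps(a, c)$n_snps,
             hamming_snps(a, b)$n_snps + hamming_snps(b, c)$n_snps)
})

test_that("coding SNPs classify effects and use standard notation", {
  syn <- classify_coding_snps("GGA", "GGG")
  expect_equal(syn$total, 1)
  expect_equal(syn$nonsynonymous, 0)
  expect_equal(syn$snps$effect, "synonymous")
  non <- classify_coding_snps("GCA", "ACA")
  expect_equal(non$snps$notation, "A1T")
  expect_equal(non$snps$effect, "nonsynonymous")
  expect_error(classify_coding_snps("GCAA", "ACAA"), "multiple of 3")
  # effects are invariant under swapping the two sequences
  set.seed(20)
  a <- paste0("ATG", rand_seq(60), "TAA")
  b <- mutate_genome(c(x = a), 0.05, seed = 2)$genome
  b <- as.character(b[[1]])
  ab <- classify_coding_snps(a, b)
  ba <- classify_coding_snps(b, a)
  expect_equal(ab$total, ba$total)
  expect_equal(ab$snps$effect, ba$snps$effect)
})

# GFF3 ----------------------------------------------------------------------

test_that("GFF3 annotation writes well-formed 1-based features", {
  s <- paste0("ATG", strrep("GCA", 60), "TAA",   # a 189-bp ORF
              "GAGGC", "GAATTC", strrep("AT", 8))
  f <- withr::local_tempfile(fileext = ".gff3")
  feats <- annotate_gff3(c(genome = s), f, min_orf = 150)
  lines <- readLines(f)
  expect_equal(lines[1], "##gff-version 3")
  body <- lines[!startsWith(lines, "#")]
  cols <- strsplit(body, "\t")
  expect_true(all(lengths(cols) == 9))
  types <- vapply(cols, `[`, "", 3)
  expect_true(all(c("ORF", "motif", "AT_rich") %in% types))
  starts <- as.integer(vapply(cols, `[`, "", 4))
  ends <- as.integer(vapply(cols, `[`, "", 5))
  expect_true(all(starts >= 1 & ends <= nchar(s) & starts <= ends))
})
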