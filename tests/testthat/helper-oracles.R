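# Independent oracles for the w-mer statistic. Both work from character
# strings and share nothing with the package's C++ rolling-update path.

# double-loop brute force: every window pair recounted from scratch.
# O(La * Lb * w); small inputs only.
oracle_wmer_brute <- function(a, b, w, n, strict = TRUE) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  acgt <- c("A", "C", "G", "T")
  thr <- if (strict) n + 1L else n
  na_ <- length(av) - w + 1L
  nb_ <- length(bv) - w + 1L
  S <- 0L
  best <- rep(0L, na_)
  for (i in seq_len(na_)) {
    x <- av[i:(i + w - 1L)]
    for (j in seq_len(nb_)) {
      y <- bv[j:(j + w - 1L)]
      id <- sum(x == y & x %in% acgt)
      if (id >= thr) S <- S + 1L
      if (id > best[i]) best[i] <- id
    }
  }
  list(all_pairs = S, best_pairs = sum(best >= thr), best = best)
}

# per-diagonal cumulative-sum recount: window identities come from
# differences of a cumsum, not from an incremental add/subtract update.
oracle_wmer_cumsum <- function(a, b, w, n, strict = TRUE) {
  ea <- match(strsplit(a, "")[[1]], c("A", "C", "G", "T"))
  eb <- match(strsplit(b, "")[[1]], c("A", "C", "G", "T"))
  La <- length(ea); Lb <- length(eb)
  thr <- if (strict) n + 1L else n
  S <- 0
  for (s in (-(La - w)):(Lb - w)) {
    k0 <- max(1L, 1L - s)
    k1 <- min(La, Lb - s)
    len <- k1 - k0 + 1L
    if (len < w) next
    m <- ea[k0:k1] == eb[(k0:k1) + s]
    m[is.na(m)] <- FALSE
    cs <- c(0, cumsum(m))
    ident <- cs[(w + 1):(len + 1)] - cs[1:(len - w + 1)]
    S <- S + sum(ident >= thr)
  }
  S
}

# uniform random ACGT string
rand_seq <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# reverse complement, independent of the package
rc_chr <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}
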