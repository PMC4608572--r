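#' Extreme-value significance model for w-mer pair counts
#'
#' The chance level of the similarity statistic S between unrelated
#' genomes is modeled by a Gumbel (type-I extreme value) law:
#' \deqn{p(S \ge x) = 1 - \exp(-e^{-\lambda (x - u)})}
#' with characteristic (location) value `u` and scale `lambda`. The
#' packaged default, u = 18 and lambda = 0.1, was fitted on comparisons
#' of shuffled ~5-kb polyomavirus genomes under the standard setting
#' w = 50, n = 30, and is only meaningful for that setting: requesting
#' the default model under other parameters is an error unless
#' `override` is set, and calibration ([calibrate_evd()]) is the
#' supported route.
#'
#' @param u characteristic value (location).
#' @param lam scale parameter, > 0.
#' @param params the [wmer_params()] the model belongs to.
#' @param provenance `"default"` for the packaged constants,
#'   `"calibrated"` for fitted models.
#' @param calibration_seed seed used during calibration, if any.
#' @return an object of class `pvgc_evd_model`.
#' @export
evd_model <- function(u, lam, params = wmer_params(),
                      provenance = c("calibrated", "default"),
                      calibration_seed = NULL) {
  provenance <- match.arg(provenance)
  stopifnot(is.finite(u), is.finite(lam), lam > 0)
  structure(list(u = u, lam = lam, params = params,
                 provenance = provenance,
                 calibration_seed = calibration_seed),
            class = "pvgc_evd_model")
}

#' @rdname evd_model
#' @param override accept the default constants under non-default
#'   `params` (at your own risk).
#' @export
default_evd_model <- function(params = wmer_params(), override = FALSE) {
  if (!override &&
      !(params$w == 50L && params$n == 30L && params$strict)) {
    stop("the default model (u = 18, lambda = 0.1) is only valid for ",
         "w = 50, n = 30 with the strict threshold; calibrate with ",
         "calibrate_evd() or pass override = TRUE")
  }
  evd_model(u = 18, lam = 0.1, params = params,
            provenance = "default")
}

#' @export
print.pvgc_evd_model <- function(x, ...) {
  cat(sprintf(
    "Gumbel model: u = %g, lambda = %g (%s; w = %d, n = %d, %s)\n",
    x$u, x$lam, x$provenance, x$params$w, x$params$n, x$params$mode))
  invisible(x)
}

#' Tail probability of a similarity score
#'
#' Evaluates p(S >= x) = 1 - exp(-e^(-lambda (x - u))) and its base-10
#' logarithm. The log value is computed in the log domain so that
#' scores far into the tail (where the linear-scale p underflows to 0)
#' still yield a finite, accurate log10 p; downstream clustering works
#' on the log10 scale throughout for exactly this reason.
#'
#' @param x similarity score(s); vectorized.
#' @param model a [evd_model()].
#' @return list with numeric vectors `p` and `log10p`. `p` is 0 where
#'   the linear scale underflows; `log10p` is always finite.
#' @examples
#' m <- default_evd_model()
#' evd_pvalue(18, m)$p        # 1 - 1/e ~ 0.632
#' evd_pvalue(5000, m)$log10p # ~ -216.4, far below double underflow
#' @export
evd_pvalue <- function(x, model) {
  stopifnot(inherits(model, "pvgc_evd_model"))
  if (any(!is.finite(x))) stop("non-finite score(s)")
  logt <- -model$lam * (x - model$u)      # log of the inner exponential
  t <- exp(logt)
  p <- -expm1(-t)                          # 1 - exp(-t), stable small t
  # -expm1(-t) carries full relative precision for any normal double t,
  # so log(p) is exact to rounding wherever t itself does not underflow;
  # below that, p = t to within 2^-1023 and log p = log t = logt.
  logp <- ifelse(logt > -700, log(-expm1(-t)), logt)
  list(p = p, log10p = logp / log(10))
}

#' Shuffle a genome's nucleotides
#'
#' Uniformly random permutation of the sequence positions: length and
#' exact mononucleotide composition are preserved while all positional
#' signal is destroyed. This is the null model used to calibrate the
#' significance distribution of S.
#'
#' @param genome a single genome (genome set of length 1 or named
#'   string).
#' @param seed optional integer; when given, the permutation is drawn
#'   from a local RNG stream and the caller's RNG state is untouched.
#' @return single-element genome set with id `<id>_shuffled`.
#' @export
shuffle_genome <- function(genome, seed = NULL) {
  g <- .as_single_genome(genome)
  shuf <- .with_seed(seed, {
    chars <- strsplit(g$seq, "")[[1]]
    paste(sample(chars), collapse = "")
  })
  genome_set(setNames(shuf, paste0(g$id, "_shuffled")))
}

# evaluate `expr` under an optional local seed without disturbing the
# caller's RNG state
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Method-of-moments Gumbel fit
#'
#' Closed-form fit of the Gumbel location/scale from a score sample:
#' lambda = pi / sqrt(6 * var), u = mean - gamma / lambda, with gamma
#' the Euler-Mascheroni constant and the sample variance using the
#' n - 1 denominator (the formulas are sensitive to this at small
#' samples).
#'
#' @param scores numeric sample (length >= 2, nonzero variance).
#' @return list with `u` and `lam`.
#' @export
fit_gumbel_moments <- function(scores) {
  if (length(scores) < 2) stop("need at least 2 scores")
  v <- stats::var(scores)
  if (!is.finite(v) || v <= 0) {
    stop("zero variance in scores; use more or longer genomes")
  }
  lam <- pi / sqrt(6 * v)
  u <- mean(scores) - .euler_gamma / lam
  list(u = u, lam = lam)
}

.euler_gamma <- 0.57721566490153286

#' Maximum-likelihood Gumbel fit
#'
#' Numerical maximization of the Gumbel log-likelihood, initialized at
#' the moments fit.
#'
#' @inheritParams fit_gumbel_moments
#' @return list with `u`, `lam` and the `optim` convergence code.
#' @export
fit_gumbel_mle <- function(scores) {
  init <- fit_gumbel_moments(scores)
  nll <- function(par) {
    u <- par[1]; lam <- exp(par[2])
    z <- lam * (scores - u)
    -sum(log(lam) - z - exp(-z))
  }
  fit <- stats::optim(c(init$u, log(init$lam)), nll, method = "BFGS")
  list(u = fit$par[1], lam = exp(fit$par[2]),
       convergence = fit$convergence)
}

#' Calibrate the significance model on shuffled genomes
#'
#' Shuffles each genome (one replicate per genome per round), computes S
#' over a sample of shuffled pairs, and fits the Gumbel parameters to
#' the resulting null scores. The sampling plan is explicit: `"all"`
#' uses every unordered pair once per round, `pairs = k` draws `k`
#' random unordered pairs (with replacement across rounds).
#'
#' @param genomes a genome set (>= 2 genomes).
#' @param params a [wmer_params()].
#' @param pairs `"all"` or a positive integer of random pairs per round.
#' @param rounds shuffle rounds; each round reshuffles every genome.
#' @param seed integer seed making the calibration reproducible.
#' @param fit_method `"moments"` (default) or `"mle"`.
#' @return object of class `pvgc_calibration`: `model` (a
#'   [evd_model()] with provenance `"calibrated"`), `sample_scores`,
#'   `fit_method`, and `diagnostics` (sample mean/variance/size).
#' @export
calibrate_evd <- function(genomes, params = wmer_params(), pairs = "all",
                          rounds = 1L, seed = 1L,
                          fit_method = c("moments", "mle")) {
  fit_method <- match.arg(fit_method)
  if (length(genomes) < 2) stop("need at least 2 genomes to calibrate")
  scores <- .with_seed(seed, {
    out <- numeric(0)
    for (r in seq_len(rounds)) {
      shuf <- vapply(as.character(genomes), function(s) {
        paste(sample(strsplit(s, "")[[1]]), collapse = "")
      }, character(1))
      idx <- if (identical(pairs, "all")) {
        utils::combn(length(shuf), 2)
      } else {
        k <- as.integer(pairs)
        stopifnot(k >= 1)
        vapply(seq_len(k), function(i) sort(sample(length(shuf), 2)),
               integer(2))
      }
      out <- c(out, vapply(seq_len(ncol(idx)), function(j) {
        .wmer_count_chr(shuf[[idx[1, j]]], shuf[[idx[2, j]]], params)$S
      }, numeric(1)))
    }
    out
  })
  fit <- if (fit_method == "moments") fit_gumbel_moments(scores)
  else fit_gumbel_mle(scores)
  structure(list(
    model = evd_model(fit$u, fit$lam, params = params,
                      provenance = "calibrated", calibration_seed = seed),
    sample_scores = scores,
    fit_method = fit_method,
    diagnostics = list(mean = mean(scores), variance = stats::var(scores),
                       n_scores = length(scores))
  ), class = "pvgc_calibration")
}

#' @export
print.pvgc_calibration <- function(x, ...) {
  cat(sprintf(
    "EVD calibration (%s, %d null scores): u = %.3f, lambda = %.4f\n",
    x$fit_method, x$diagnostics$n_scores, x$model$u, x$model$lam))
  invisible(x)
}

#' Choose the critical identity value n from background statistics
#'
#' For each candidate n, measures the mean null score (S between
#' shuffled genomes) and the minimum real-pair score, and recommends the
#' smallest candidate whose background does not exceed `max_background`
#' (default 15%) of the weakest real similarity — i.e. the loosest
#' threshold at which random hits stay a small fraction of the faintest
#' genuine signal. The full table is returned so other rules can be
#' applied.
#'
#' @param genomes a genome set of related (real) genomes, >= 2.
#' @param w window length.
#' @param candidate_ns integer candidates within (0, w).
#' @param seed shuffle seed.
#' @param max_background background-to-real ratio ceiling.
#' @param params_mode counting mode passed through to [wmer_params()].
#' @return list with `recommended_n` (or `NA` with a warning when no
#'   candidate qualifies) and `table` (n, background_mean_S, min_real_S,
#'   ratio).
#' @export
select_critical_value <- function(genomes, w = 50L, candidate_ns,
                                  seed = 1L, max_background = 0.15,
                                  params_mode = "all_pairs") {
  if (length(genomes) < 2) stop("need >= 2 genomes")
  stopifnot(all(candidate_ns > 0 & candidate_ns < w))
  shuf <- .with_seed(seed, lapply(as.character(genomes), function(s) {
    paste(sample(strsplit(s, "")[[1]]), collapse = "")
  }))
  idx <- utils::combn(length(genomes), 2)
  rows <- lapply(sort(as.integer(candidate_ns)), function(n) {
    p <- wmer_params(w = w, n = n, mode = params_mode)
    bg <- mean(vapply(seq_len(ncol(idx)), function(j) {
      .wmer_count_chr(shuf[[idx[1, j]]], shuf[[idx[2, j]]], p)$S
    }, numeric(1)))
    real <- min(vapply(seq_len(ncol(idx)), function(j) {
      .wmer_count_chr(.seq_chr(genomes, idx[1, j]),
                      .seq_chr(genomes, idx[2, j]), p)$S
    }, numeric(1)))
    data.frame(n = n, background_mean_S = bg, min_real_S = real,
               ratio = if (real > 0) bg / real else Inf)
  })
  tab <- do.call(rbind, rows)
  ok <- tab$ratio <= max_background
  rec <- if (any(ok)) tab$n[which(ok)[1]] else NA_integer_
  if (is.na(rec)) {
    warning("no candidate n meets the background ceiling of ",
            max_background)
  }
  list(recommended_n = rec, table = tab)
}

#' Write / read a significance model as JSON
#'
#' @param model a [evd_model()].
#' @param path JSON path.
#' @return `path` (write) or the model (read).
#' @export
write_evd_model <- function(model, path) {
  jsonlite::write_json(list(
    u = model$u, lam = model$lam, w = model$params$w, n = model$params$n,
    mode = model$params$mode, circular = model$params$circular,
    strict = model$params$strict, provenance = model$provenance,
    calibration_seed = model$calibration_seed
  ), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_evd_model
#' @export
read_evd_model <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  evd_model(j$u, j$lam,
            params = wmer_params(j$w, j$n, j$mode,
                                 circular = isTRUE(j$circular),
                                 strict = !isFALSE(j$strict)),
            provenance = j$provenance,
            calibration_seed = j$calibration_seed)
}
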