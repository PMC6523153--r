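#' Identify transcription factors among network genes
#'
#' Intersects the network node ids with a TF symbol list, case-insensitively
#' and after deduplication, returning the node ids in their original case.
#'
#' @param network_genes character vector of network node ids.
#' @param tf_list character vector of known TF symbols.
#' @return character vector of network nodes that are TFs.
#' @export
match_tfs <- function(network_genes, tf_list) {
  if (!length(tf_list)) stop("match_tfs: tf_list is empty")
  hit <- toupper(network_genes) %in% unique(toupper(tf_list))
  unique(network_genes[hit])
}

#' Log-odds score matrix of a PWM
#'
#' Adds a pseudocount to the base probabilities, renormalises each position,
#' and takes `log2` against the background:
#' `score[b, i] = log2(p'[b, i] / background[b])`.
#'
#' @param pwm 4 x L matrix of base probabilities (rows A, C, G, T; columns
#'   sum to 1).
#' @param background base frequencies (positive, summing to 1); uniform by
#'   default.
#' @param pseudocount added to every probability before renormalisation
#'   (default 0.01).
#' @return 4 x L log2-odds matrix with rows A, C, G, T.
#' @export
log_odds <- function(pwm, background = rep(0.25, 4), pseudocount = 0.01) {
  pwm <- as.matrix(pwm)
  if (nrow(pwm) != 4) stop("log_odds: PWM must have 4 rows (A, C, G, T)")
  if (any(background <= 0)) stop("log_odds: background frequencies must be positive")
  if (abs(sum(background) - 1) > 1e-6) stop("log_odds: background must sum to 1")
  if (max(abs(colSums(pwm) - 1)) > 1e-6)
    stop("log_odds: PWM columns must sum to 1")
  padj <- sweep(pwm + pseudocount, 2, colSums(pwm + pseudocount), "/")
  S <- log2(padj / background)
  rownames(S) <- c("A", "C", "G", "T")
  S
}

# Exact distribution of the motif score of a random background sequence,
# over integer-discretized scores (units of `granularity`). Returns the
# contiguous support `vals` (integers), point probabilities and the upper
# tail P(S >= vals[i]).
pwm_score_dist <- function(scores, background = rep(0.25, 4),
                           granularity = 1e-3) {
  S <- round(scores / granularity)
  L <- ncol(S)
  cur <- 1
  curlo <- 0
  for (i in seq_len(L)) {
    smin <- min(S[, i])
    nxt <- numeric(length(cur) + max(S[, i]) - smin)
    for (b in 1:4) {
      off <- S[b, i] - smin
      rng <- (off + 1):(off + length(cur))
      nxt[rng] <- nxt[rng] + cur * background[b]
    }
    cur <- nxt
    curlo <- curlo + smin
  }
  vals <- curlo + seq_along(cur) - 1
  list(vals = vals, prob = cur, tail = rev(cumsum(rev(cur))),
       granularity = granularity)
}

#' Exact p-value of a motif score
#'
#' Probability that a random sequence of motif length drawn from the
#' background attains a score at least `threshold`, computed exactly by
#' dynamic programming over integer-discretized scores (default granularity
#' 1e-3 log2 units; the threshold is discretized to the same grid).
#'
#' @param scores log-odds matrix from [log_odds()].
#' @param threshold score threshold.
#' @param background base frequencies.
#' @param granularity discretization step for scores.
#' @return `P(score >= threshold)` in \[0,1\].
#' @export
pwm_pvalue <- function(scores, threshold, background = rep(0.25, 4),
                       granularity = 1e-3) {
  if (any(!is.finite(scores))) stop("pwm_pvalue: scores must be finite")
  d <- pwm_score_dist(scores, background, granularity)
  t_int <- round(threshold / granularity)
  if (t_int <= d$vals[1]) return(1)
  if (t_int > d$vals[length(d$vals)]) return(0)
  d$tail[t_int - d$vals[1] + 1]
}

#' Scan a promoter with a PWM
#'
#' Slides the motif along the forward strand; windows containing `N` are
#' skipped; hits are windows whose exact score p-value (see [pwm_pvalue()])
#' is at most `p_max`. Start coordinates are 1-based.
#'
#' @param scores log-odds matrix from [log_odds()].
#' @param sequence a single string over A, C, G, T, N.
#' @param p_max p-value cutoff (default 0.001).
#' @param background base frequencies used for both scoring p-values.
#' @param granularity score discretization step.
#' @return data.frame `start`, `score`, `p` (possibly 0 rows).
#' @export
scan_promoter <- function(scores, sequence, p_max = 0.001,
                          background = rep(0.25, 4), granularity = 1e-3) {
  L <- ncol(scores)
  sequence <- toupper(as.character(sequence))
  codes <- match(strsplit(sequence, "")[[1]], c("A", "C", "G", "T", "N"))
  if (anyNA(codes))
    stop("scan_promoter: sequence contains characters outside {A,C,G,T,N}")
  codes[codes == 5L] <- NA_integer_
  n <- length(codes)
  empty <- data.frame(start = integer(), score = numeric(), p = numeric())
  if (n < L) return(empty)
  S <- round(scores / granularity)
  n_win <- n - L + 1L
  wsum <- numeric(n_win)
  for (off in seq_len(L)) {
    v <- S[cbind(codes[off:(off + n_win - 1L)], off)]
    wsum <- wsum + v                     # NA propagates for N windows
  }
  ok <- !is.na(wsum)
  if (!any(ok)) return(empty)
  d <- pwm_score_dist(scores, background, granularity)
  p <- rep(NA_real_, n_win)
  p[ok] <- d$tail[wsum[ok] - d$vals[1] + 1]
  hit <- ok & p <= p_max
  data.frame(start = which(hit), score = wsum[hit] * granularity,
             p = p[hit], row.names = NULL)
}

#' Predict TF target genes by promoter scanning
#'
#' A gene is a predicted target of a TF iff its promoter carries at least
#' one motif hit at `p <= p_max`. TFs without a motif are dropped with a
#' warning; genes without a promoter are skipped with a warning.
#'
#' @param tfs character vector of TF ids.
#' @param pwms named list of 4 x L probability PWMs (names = TF ids).
#' @param promoters named character vector (or `DNAStringSet`) of promoter
#'   sequences, names = gene ids.
#' @param genes gene ids to scan; defaults to `names(promoters)`.
#' @param p_max hit p-value cutoff (default 0.001).
#' @param background base frequencies for scoring.
#' @param pseudocount PWM pseudocount, see [log_odds()].
#' @return named list (one element per scanned TF) of data.frames
#'   `gene`, `best_score`, `best_p` — the predicted targets.
#' @export
assign_targets <- function(tfs, pwms, promoters, genes = NULL,
                           p_max = 0.001, background = rep(0.25, 4),
                           pseudocount = 0.01) {
  promoters <- vapply(as.list(promoters), as.character, character(1))
  if (is.null(genes)) genes <- names(promoters)
  missing_prom <- setdiff(genes, names(promoters))
  if (length(missing_prom)) {
    warning("assign_targets: no promoter for gene(s) ",
            paste(head(missing_prom, 5), collapse = ", "),
            if (length(missing_prom) > 5) ", ..." else "", "; skipped")
    genes <- intersect(genes, names(promoters))
  }
  no_motif <- setdiff(tfs, names(pwms))
  if (length(no_motif))
    warning("assign_targets: no motif for TF(s) ",
            paste(no_motif, collapse = ", "), "; dropped")
  tfs <- intersect(tfs, names(pwms))
  modules <- vector("list", length(tfs))
  names(modules) <- tfs
  for (tf in tfs) {
    sc <- log_odds(pwms[[tf]], background, pseudocount)
    res <- lapply(genes, function(g) {
      h <- scan_promoter(sc, promoters[[g]], p_max, background)
      if (nrow(h) == 0) return(NULL)
      best <- which.min(h$p)
      data.frame(gene = g, best_score = h$score[best], best_p = h$p[best],
                 stringsAsFactors = FALSE)
    })
    res <- res[!vapply(res, is.null, logical(1))]
    modules[[tf]] <- if (length(res)) do.call(rbind, res) else
      data.frame(gene = character(), best_score = numeric(),
                 best_p = numeric())
  }
  modules
}

#' Maximum-coverage transcription-factor trio
#'
#' Exhaustively searches all 3-subsets of TF modules and returns the trio
#' whose target sets jointly cover the most genes. Ties are broken
#' lexicographically on the sorted TF id triple, making the result
#' deterministic.
#'
#' @param modules named list of target sets: data.frames with a `gene`
#'   column (as from [assign_targets()]) or plain character vectors.
#' @return list `tfs` (three ids), `coverage` (count), `targets` (covered
#'   gene ids, sorted).
#' @export
select_top_trio <- function(modules) {
  if (length(modules) < 3) stop("select_top_trio: need at least 3 TF modules")
  sets <- lapply(modules, function(m) {
    if (is.data.frame(m)) unique(m$gene) else unique(as.character(m))
  })
  tf_ids <- sort(names(sets))
  combos <- utils::combn(tf_ids, 3, simplify = FALSE)
  best <- NULL
  best_cov <- -1L
  for (trio in combos) {  # combn order over sorted ids = lexicographic
    cov <- length(unique(unlist(sets[trio], use.names = FALSE)))
    if (cov > best_cov) {
      best_cov <- cov
      best <- trio
    }
  }
  list(tfs = best, coverage = best_cov,
       targets = sort(unique(unlist(sets[best], use.names = FALSE))))
}
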