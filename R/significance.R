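#' 1-Mb window label for a genomic position
#'
#' Windows are consecutive, non-overlapping, half-open megabase intervals
#' `[k*1e6, (k+1)*1e6)`; the label is `"chrom_k"` (the chromosome_megabase
#' convention of window-based GWAS reports, e.g. `"2_162"`).
#'
#' @param chrom chromosome (integer or character); vectorised.
#' @param pos_bp base-pair position, `>= 0`.
#' @param window_bp window size in bp (1 Mb).
#' @return character vector of window labels.
#' @export
assign_window <- function(chrom, pos_bp, window_bp = 1e6) {
  if (any(pos_bp < 0)) stop("assign_window: negative position")
  paste(chrom, floor(pos_bp / window_bp), sep = "_")
}

#' Bayes factor from a marker's model frequency
#'
#' `BF = [p/(1-p)] / [(1-pi)/pi]`: the posterior odds that the marker is in
#' the model divided by its prior odds. `p = 1` maps to `Inf`, `p = 0` to 0.
#'
#' @param model_freq posterior inclusion frequency `p` in \[0,1\];
#'   vectorised.
#' @param pi prior exclusion fraction, in (0,1).
#' @return numeric Bayes factors (possibly `Inf`).
#' @export
bayes_factor <- function(model_freq, pi) {
  if (!(pi > 0 && pi < 1)) stop("bayes_factor: pi must lie in (0,1)")
  if (any(model_freq < 0 | model_freq > 1))
    stop("bayes_factor: model_freq must lie in [0,1]")
  prior_odds <- (1 - pi) / pi
  ifelse(model_freq == 1, Inf,
         (model_freq / (1 - model_freq)) / prior_odds)
}

#' Evidence class of a Bayes factor
#'
#' Applies the conventional interpretation scale: `BF > 3.2` suggestive,
#' `> 20` strong, `> 100` decisive (strict inequalities), else none.
#'
#' @param bf numeric Bayes factors, `>= 0` (`Inf` allowed).
#' @return factor with levels none, suggestive, strong, decisive.
#' @export
classify_evidence <- function(bf) {
  if (any(bf < 0, na.rm = TRUE)) stop("classify_evidence: negative BF")
  cls <- ifelse(bf > 100, "decisive",
         ifelse(bf > 20, "strong",
         ifelse(bf > 3.2, "suggestive", "none")))
  factor(cls, levels = c("none", "suggestive", "strong", "decisive"))
}

#' Per-SNP significance table from a BayesB fit
#'
#' Joins the marker posterior with the map and derives window labels, Bayes
#' factors and evidence classes.
#'
#' @param fit a [run_chain()] fit.
#' @param map marker map (`marker_id`, `chrom`, `pos_bp`).
#' @return data.frame `marker_id`, `chrom`, `pos_bp`, `window_id`, `effect`,
#'   `model_freq`, `bf`, `evidence`.
#' @export
snp_significance <- function(fit, map) {
  stopifnot(inherits(fit, "bayesb_fit"))
  mp <- fit$marker_posterior
  idx <- match(mp$marker_id, map$marker_id)
  if (anyNA(idx)) stop("snp_significance: markers missing from map")
  bf <- bayes_factor(mp$model_freq, fit$config$pi)
  data.frame(
    marker_id = mp$marker_id,
    chrom = map$chrom[idx],
    pos_bp = map$pos_bp[idx],
    window_id = assign_window(map$chrom[idx], map$pos_bp[idx]),
    effect = mp$post_mean_effect,
    model_freq = mp$model_freq,
    bf = bf,
    evidence = classify_evidence(bf),
    stringsAsFactors = FALSE
  )
}

#' Posterior 1-Mb window shares of genomic variance
#'
#' For every saved MCMC sample, computes the variance across animals of each
#' window's genomic values `Z_w u_w` as a share of the variance of the total
#' genomic values `Z u`, then averages the shares over samples
#' (`gv_pct = 100 * posterior mean share`). Shares of one sample sum to 100%
#' when markers in different windows are uncorrelated; under LD the sum can
#' deviate. Samples with zero total genomic variance are skipped with a
#' warning. `basis = "postmean"` instead computes shares once from the
#' posterior-mean effects (cheaper, but underestimates shares of uncertain
#' windows).
#'
#' @param fit a [run_chain()] fit with `save_effects = TRUE` (for
#'   `basis = "sample"`).
#' @param G the dosage matrix the fit was run on.
#' @param map marker map.
#' @param basis `"sample"` (default) or `"postmean"`.
#' @param window_bp window size in bp.
#' @return data.frame `window_id`, `chrom`, `mb`, `gv_pct`, `n_markers`,
#'   plus attribute `"members"` (list of marker ids per window).
#' @export
window_variance_table <- function(fit, G, map, basis = c("sample", "postmean"),
                                  window_bp = 1e6) {
  stopifnot(inherits(fit, "bayesb_fit"))
  basis <- match.arg(basis)
  G <- as.matrix(G)
  storage.mode(G) <- "double"
  ids <- fit$marker_posterior$marker_id
  idx <- match(ids, map$marker_id)
  if (anyNA(idx)) stop("window_variance_table: markers missing from map")
  win <- assign_window(map$chrom[idx], map$pos_bp[idx], window_bp)
  Z <- sweep(G, 2, fit$center)

  if (basis == "sample") {
    if (is.null(fit$u_samples))
      stop("window_variance_table: fit has no saved effect samples; ",
           "rerun with save_effects = TRUE or use basis = 'postmean'")
    U <- fit$u_samples                      # saved x m
  } else {
    U <- matrix(fit$marker_posterior$post_mean_effect, nrow = 1)
  }
  tot <- Z %*% t(U)                          # animals x saved
  vtot <- apply(tot, 2, stats::var)
  ok <- vtot > 0
  if (!any(ok)) stop("window_variance_table: all samples have zero genomic variance")
  if (!all(ok))
    warning("window_variance_table: ", sum(!ok),
            " sample(s) with zero genomic variance skipped")
  wins <- unique(win[order(map$chrom[idx], map$pos_bp[idx])])
  share <- matrix(NA_real_, length(wins), sum(ok),
                  dimnames = list(wins, NULL))
  for (w in wins) {
    jj <- which(win == w)
    gw <- Z[, jj, drop = FALSE] %*% t(U[, jj, drop = FALSE])
    share[w, ] <- apply(gw[, ok, drop = FALSE], 2, stats::var) / vtot[ok]
  }
  members <- split(ids, win)[wins]
  chrom_mb <- do.call(rbind, strsplit(wins, "_(?=[0-9]+$)", perl = TRUE))
  out <- data.frame(
    window_id = wins,
    chrom = chrom_mb[, 1],
    mb = as.integer(chrom_mb[, 2]),
    gv_pct = 100 * rowMeans(share),
    n_markers = lengths(members),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(out, "members") <- members
  attr(out, "share_samples") <- share
  out
}

#' Informative genomic regions
#'
#' Reports windows that pass the variance-share threshold (`gv_pct` above
#' `gv_threshold` percent of genomic variance) or that contain a SNP whose
#' Bayes factor exceeds `bf_threshold` (OR combination). For each reported
#' window, the member SNP with the largest Bayes factor is listed with its
#' position, posterior effect and evidence class.
#'
#' @param windows output of [window_variance_table()].
#' @param snps output of [snp_significance()].
#' @param gv_threshold window variance share threshold in percent
#'   (default 1.0).
#' @param bf_threshold SNP Bayes factor threshold (default 20).
#' @param trait optional trait label carried into the report.
#' @return data.frame `trait`, `window_id`, `gv_pct`, `marker_id`,
#'   `pos_mb`, `effect`, `bf`, `evidence`, sorted by decreasing `gv_pct`.
#' @export
informative_regions <- function(windows, snps, gv_threshold = 1.0,
                                bf_threshold = 20, trait = NA_character_) {
  best <- snps[order(snps$window_id, -snps$bf), ]
  best <- best[!duplicated(best$window_id), ]
  maxbf <- setNames(best$bf, best$window_id)
  keep <- windows$gv_pct > gv_threshold |
    ifelse(is.na(maxbf[windows$window_id]), FALSE,
           maxbf[windows$window_id] > bf_threshold)
  w <- windows[keep, , drop = FALSE]
  if (nrow(w) == 0) {
    return(data.frame(trait = character(), window_id = character(),
                      gv_pct = numeric(), marker_id = character(),
                      pos_mb = numeric(), effect = numeric(), bf = numeric(),
                      evidence = character(), stringsAsFactors = FALSE))
  }
  b <- best[match(w$window_id, best$window_id), ]
  out <- data.frame(
    trait = trait,
    window_id = w$window_id,
    gv_pct = w$gv_pct,
    marker_id = b$marker_id,
    pos_mb = round(b$pos_bp / 1e6, 2),
    effect = b$effect,
    bf = b$bf,
    evidence = as.character(b$evidence),
    stringsAsFactors = FALSE
  )
  out[order(-out$gv_pct), , drop = FALSE]
}
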