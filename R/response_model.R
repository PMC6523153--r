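#' Weighting factor for deregressed breeding values
#'
#' Computes the per-record weight that accounts for heterogeneous DEBV
#' variance across animals with different reliabilities,
#' \deqn{w = \frac{1-h^2}{[c + (1-r^2)/r^2]\,h^2}}
#' where \eqn{r^2} is the DEBV reliability, \eqn{h^2} the trait heritability
#' and \eqn{c} the proportion of genetic variance not explained by markers
#' (0.40 by default). The weight scales the residual variance of a record in
#' the whole-genome regression: reliable records get large weights.
#'
#' `form = "literal"` evaluates the product form
#' \eqn{w = (1-h^2)\{c + (1-r^2)/r^2\}h^2} instead; it is provided for
#' comparison only, since it decreases with reliability and therefore cannot
#' serve its stated purpose.
#'
#' @param reliability DEBV reliability \eqn{r^2} in (0, 1]; vectorised.
#' @param h2 trait heritability in (0,1).
#' @param c_gen proportion of genetic variance not captured by markers,
#'   in \[0,1).
#' @param form `"ratio"` (default) or `"literal"`.
#' @return numeric vector of weights.
#' @export
compute_weight <- function(reliability, h2, c_gen = 0.40,
                           form = c("ratio", "literal")) {
  form <- match.arg(form)
  if (!(h2 > 0 && h2 < 1)) stop("compute_weight: h2 must lie in (0,1)")
  if (!(c_gen >= 0 && c_gen < 1)) stop("compute_weight: c_gen must lie in [0,1)")
  if (any(reliability <= 0)) stop("compute_weight: reliability must be > 0")
  if (any(reliability > 1)) stop("compute_weight: reliability must be <= 1")
  inner <- c_gen + (1 - reliability) / reliability
  if (form == "ratio") (1 - h2) / (inner * h2) else (1 - h2) * inner * h2
}

#' Deregress an EBV against its parent average
#'
#' Removes the shrinkage and parental contribution from an estimated
#' breeding value so that the result reflects only the animal's own and
#' descendants' information:
#' `debv = pa + (ebv - pa) / r2` (with `pa = 0` when no parent average is
#' available). This is the single-record shrinkage approximation of full
#' information-matrix deregression; users holding properly deregressed
#' proofs can skip it.
#'
#' @param ebv estimated breeding value(s).
#' @param reliability reliability \eqn{r^2} in (0,1].
#' @param parent_average parent average EBV; defaults to 0.
#' @return deregressed EBV.
#' @export
deregress <- function(ebv, reliability, parent_average = 0) {
  if (any(reliability <= 0)) stop("deregress: reliability must be > 0")
  if (any(reliability > 1)) stop("deregress: reliability must be <= 1")
  parent_average + (ebv - parent_average) / reliability
}

#' Filter response records by reliability
#'
#' Keeps records whose reliability is at least `min_r2` (boundary included),
#' preserving order. Mirrors the usual pre-GWAS cleaning step of dropping
#' animals whose deregressed proofs are nearly uninformative.
#'
#' @param records data.frame with a `reliability` column.
#' @param min_r2 minimum reliability retained; default 0.10.
#' @return the filtered data.frame.
#' @export
filter_by_reliability <- function(records, min_r2 = 0.10) {
  stopifnot(min_r2 >= 0, min_r2 <= 1)
  if (nrow(records) == 0) return(records)
  records[records$reliability >= min_r2, , drop = FALSE]
}

#' Prepare a weighted response table
#'
#' Applies the reliability filter and attaches the weighting factor to each
#' record of a long-format response table, per trait.
#'
#' @param records data.frame `animal_id`, `trait`, `debv`, `reliability`.
#' @param h2_by_trait named numeric vector of heritabilities per trait.
#' @param c_gen see [compute_weight()].
#' @param min_r2 reliability threshold; records below are removed.
#' @param form weight form, see [compute_weight()].
#' @return the records with a `weight` column added.
#' @export
prepare_response <- function(records, h2_by_trait, c_gen = 0.40,
                             min_r2 = 0.10, form = "ratio") {
  missing_h2 <- setdiff(unique(records$trait), names(h2_by_trait))
  if (length(missing_h2))
    stop("prepare_response: no h2 supplied for trait(s): ",
         paste(missing_h2, collapse = ", "))
  out <- filter_by_reliability(records, min_r2)
  w <- numeric(nrow(out))
  for (tr in unique(out$trait)) {
    idx <- out$trait == tr
    w[idx] <- compute_weight(out$reliability[idx], h2 = h2_by_trait[[tr]],
                             c_gen = c_gen, form = form)
  }
  out$weight <- w
  out
}
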