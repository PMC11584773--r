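# Differential-feature thresholding and the enrichment-direction z-score.

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: with p-values sorted ascending,
#' `q_(i) = min_{j >= i} m * p_(j) / j`, clipped at 1, returned in the input
#' order. Ties receive equal adjusted values (stable by construction since
#' equal p-values share `m * p / j` minima).
#'
#' @param p Numeric vector of p-values in `[0, 1]`; `NA` propagated.
#' @return Adjusted p-values, same length and order as `p`.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))  # all 0.04
#' @export
bh_adjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m) {
    o <- order(p[ok], decreasing = TRUE)
    q <- pmin(1, cummin(m / (m:1) * p[ok][o]))
    tmp <- out[ok]
    tmp[o] <- q
    out[ok] <- tmp
  }
  out
}

#' Filter a differential-expression table by fold-change and FDR
#'
#' Retains features with `|log2fc| >= lfc_min` and `p_adj <= alpha` (both
#' inclusive, the conventional "FDR-adjusted p <= 0.1 and |log2FC| >= 1"
#' rule), annotating each with its direction (`"up"` for positive,
#' `"down"` for negative fold-change).
#'
#' @param table A data.frame with columns `feature_id`, `log2fc`, `p_adj`
#'   (e.g. from [generate_de_table()]).
#' @param lfc_min Minimum absolute log2 fold-change; non-negative.
#' @param alpha FDR level in `(0, 1]`.
#' @return The retained rows with an added `direction` column.
#' @export
filter_differential <- function(table, lfc_min = 1, alpha = 0.1) {
  if (lfc_min < 0) stop("lfc_min must be non-negative")
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  need <- c("feature_id", "log2fc", "p_adj")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("table lacks column(s): ", paste(miss, collapse = ", "))
  if (anyNA(table$p_adj))
    stop("p_adj must be set for all rows (run bh_adjust first)")
  keep <- abs(table$log2fc) >= lfc_min & table$p_adj <= alpha
  out <- table[keep, , drop = FALSE]
  out$direction <- ifelse(out$log2fc > 0, "up", "down")
  rownames(out) <- NULL
  out
}

#' Enrichment-direction z-score of a gene-set term
#'
#' Summarizes the direction of regulation within an enriched term:
#' \deqn{z = (up - down) / \sqrt{count}}
#' where `up` and `down` count the up- and down-regulated differential
#' features annotated to the term and `count` is the term's total feature
#' count. Positive z means predominantly upregulated members.
#'
#' @param up,down Non-negative integer counts with `up + down <= count`.
#' @param count Positive integer, total features in the term.
#' @return The z-score (bounded by `sqrt(count)` in absolute value).
#' @examples
#' term_zscore(4, 0, 4)   # 2
#' term_zscore(0, 9, 9)   # -3
#' @export
term_zscore <- function(up, down, count) {
  if (count <= 0) stop("count must be positive")
  if (up < 0 || down < 0) stop("up and down must be non-negative")
  if (up + down > count) stop("up + down must not exceed count")
  (up - down) / sqrt(count)
}

#' Summarize direction z-scores for a table of terms
#'
#' @param terms Data.frame with columns `term_id`, `up`, `down`, `count`.
#' @return The same table with a `z` column appended.
#' @export
term_zscore_table <- function(terms) {
  need <- c("term_id", "up", "down", "count")
  miss <- setdiff(need, names(terms))
  if (length(miss))
    stop("terms lacks column(s): ", paste(miss, collapse = ", "))
  terms$z <- mapply(term_zscore, terms$up, terms$down, terms$count)
  terms
}
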