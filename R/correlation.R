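#' Pearson correlation with its t-test
#'
#' Sample Pearson correlation between two paired vectors with the exact
#' t-test (`t = r * sqrt(n - 2) / sqrt(1 - r^2)`) and a two-sided p-value.
#' Zero variance in either variable leaves `r` undefined (NA, with a
#' warning) rather than erroring.
#'
#' @param x,y paired numeric vectors, n >= 4.
#' @return list with `r`, `n`, `t`, `p`.
#' @export
pd_pearson <- function(x, y) {
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  stopifnot(n >= 4)
  if (sd(x) == 0 || sd(y) == 0) {
    warning("zero variance; correlation undefined")
    return(list(r = NA_real_, n = n, t = NA_real_, p = NA_real_))
  }
  ct <- cor.test(x, y)
  list(r = unname(ct$estimate), n = n,
       t = unname(ct$statistic), p = ct$p.value)
}

#' Compare two independent correlations via Fisher's r-to-z
#'
#' Transforms both correlation magnitudes with `atanh` and compares them as
#' independent normals with variances `1/(n - 3)`:
#' `z = (atanh(|r1|) - atanh(|r2|)) / sqrt(1/(n1-3) + 1/(n2-3))`.
#' Magnitudes are compared (sign-free reporting of correlation size), so
#' swapping the samples negates z. One-sided p-values test whether the
#' larger observed magnitude is larger in the population.
#'
#' @param r1,r2 sample correlations, `|r| < 1`.
#' @param n1,n2 sample sizes, both > 3.
#' @param tail `"two_sided"` (default) or `"one_sided"`.
#' @return list with `r1`, `n1`, `r2`, `n2`, `z`, `p`, `tail`.
#' @export
#' @examples
#' fisher_compare(-0.16, 75, -0.45, 75, tail = "one_sided")  # z ~ -1.94
fisher_compare <- function(r1, n1, r2, n2,
                           tail = c("two_sided", "one_sided")) {
  tail <- match.arg(tail)
  stopifnot(abs(r1) < 1, abs(r2) < 1, n1 > 3, n2 > 3)
  z <- (atanh(abs(r1)) - atanh(abs(r2))) /
    sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  p1 <- pnorm(abs(z), lower.tail = FALSE)
  p <- if (tail == "two_sided") 2 * p1 else p1
  list(r1 = r1, n1 = n1, r2 = r2, n2 = n2, z = z, p = p, tail = tail)
}

#' All pairwise Fisher-z comparisons between condition cells
#'
#' Compares the D-U correlation of every unordered pair of condition cells.
#' Within each pair the cells are ordered so that the reported z is
#' non-negative for the larger correlation magnitude.
#'
#' @param cells data.frame with columns `cell` (label), `r`, `n`.
#' @param tail passed to [fisher_compare()].
#' @return data.frame of comparisons (`cell1`, `cell2`, `r1`, `r2`, `z`,
#'   `p`) with attributes `max_abs_z` and `min_p`.
#' @export
pairwise_condition_comparisons <- function(cells,
                                           tail = c("two_sided",
                                                    "one_sided")) {
  tail <- match.arg(tail)
  stopifnot(nrow(cells) >= 2,
            all(c("cell", "r", "n") %in% names(cells)))
  pairs <- combn(nrow(cells), 2)
  out <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    # larger-magnitude cell second, so z >= 0 reported as |larger| > |smaller|
    if (abs(cells$r[i]) > abs(cells$r[j])) { tmp <- i; i <- j; j <- tmp }
    fc <- fisher_compare(cells$r[j], cells$n[j], cells$r[i], cells$n[i],
                         tail = tail)
    data.frame(cell1 = cells$cell[i], cell2 = cells$cell[j],
               r1 = cells$r[i], r2 = cells$r[j],
               z = fc$z, p = fc$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  attr(out, "max_abs_z") <- max(abs(out$z))
  attr(out, "min_p") <- min(out$p)
  attr(out, "tail") <- tail
  out
}
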