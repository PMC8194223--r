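# Nonparametric battery for rate differences between structural categories.
# Conventions: two-sided p-values from tie-corrected normal or chi-square
# approximations, no continuity correction, no multiple-testing adjustment.

#' Collapse paired positions to single rates
#'
#' Each primary-layer pair (i, j) is represented by the mean of its two
#' rates — one value per stem pair, avoiding pseudoreplication — while
#' definite unpaired positions contribute their own rates as loops.  Pairs
#' with either member lacking a rate, and unpaired positions without a
#' rate, are excluded.
#'
#' @param rateTable Site rate table from [tiger_rates()] (columns
#'   \code{column}, \code{rate}).
#' @param structureMap A [structure_map()] whose positions index the rate
#'   table's coordinate system.
#' @return List with \code{pairs} (data frame \code{i}, \code{j},
#'   \code{rate_i}, \code{rate_j}, \code{collapsed}) and \code{loops}
#'   (numeric vector of loop rates).
#' @export
collapse_paired <- function(rateTable, structureMap) {
  rate <- rep(NA_real_, max(rateTable$column))
  rate[rateTable$column] <- rateTable$rate
  n <- nchar(structureMap$seq)
  if (n > length(rate)) rate <- c(rate, rep(NA_real_, n - length(rate)))
  p <- structureMap$pair
  op <- which(p > 0L & p > seq_len(n))
  ri <- rate[op]; rj <- rate[p[op]]
  ok <- !is.na(ri) & !is.na(rj)
  pairs <- data.frame(i = op[ok], j = p[op][ok],
                      rate_i = ri[ok], rate_j = rj[ok],
                      collapsed = (ri[ok] + rj[ok]) / 2)
  loop_pos <- which(p == 0L & seq_len(n) <= length(rate))
  loops <- rate[loop_pos]
  loops <- loops[!is.na(loops)]
  list(pairs = pairs, loops = loops)
}

test_result <- function(test, statistic, Z = NA_real_, df = NA_real_,
                        p = NA_real_, n = NULL, note = NA_character_) {
  structure(list(test = test, statistic = statistic, Z = Z, df = df,
                 p = p, n = n, note = note), class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(x$test, ": statistic = ", format(x$statistic),
      if (!is.na(x$Z)) paste0(", Z = ", format(round(x$Z, 3))) else "",
      if (!is.na(x$df)) paste0(", df = ", x$df) else "",
      ", p = ", format(signif(x$p, 3)),
      if (length(x$n)) paste0(", n = ", paste(x$n, collapse = "/")) else "",
      "\n", sep = "")
  if (!is.na(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Wilcoxon signed-rank test (normal approximation)
#'
#' Zero differences are dropped (their count is reported alongside the
#' total); W is the sum of the ranks of the positive differences among the
#' non-zero ones, reported as the larger of the two signed-rank sums to
#' match the usual reporting convention.  Z uses the tie-corrected variance
#' with no continuity correction; p is two-sided.
#'
#' @param x,y Equal-length paired numeric samples.
#' @return A \code{test_result} with \code{n = c(n_nonzero, n_total)}.
#' @export
wilcoxon_signed_rank <- function(x, y) {
  stopifnot(length(x) == length(y))
  d <- x - y
  total <- length(d)
  d <- d[d != 0]
  nz <- length(d)
  if (nz == 0L)
    return(test_result("Wilcoxon signed-rank", NA_real_, n = c(0L, total),
                       note = "all differences are zero; no test performed"))
  r <- rank(abs(d))
  Wpos <- sum(r[d > 0]); Wneg <- sum(r[d < 0])
  W <- max(Wpos, Wneg)
  EW <- nz * (nz + 1) / 4
  ties <- table(r)
  varW <- nz * (nz + 1) * (2 * nz + 1) / 24 -
    sum(ties^3 - ties) / 48
  Z <- (Wpos - EW) / sqrt(varW)
  p <- 2 * pnorm(-abs(Z))
  test_result("Wilcoxon signed-rank", W, Z = abs(Z), p = min(1, p),
              n = c(nz, total))
}

#' Mann-Whitney U test (normal approximation)
#'
#' U from rank sums with midranks for ties; Z from the tie-corrected
#' variance, no continuity correction; two-sided p.  The reported U is the
#' larger of the two sample statistics.
#'
#' @param a,b Numeric samples.
#' @return A \code{test_result} with \code{n = c(length(a), length(b))}.
#' @export
mann_whitney_u <- function(a, b) {
  stopifnot(length(a) > 0L, length(b) > 0L)
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  R1 <- sum(r[seq_len(n1)])
  U1 <- R1 - n1 * (n1 + 1) / 2
  U2 <- n1 * n2 - U1
  U <- max(U1, U2)
  N <- n1 + n2
  ties <- table(r)
  varU <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  Z <- if (varU > 0) (U1 - n1 * n2 / 2) / sqrt(varU) else 0
  p <- if (varU > 0) 2 * pnorm(-abs(Z)) else 1
  test_result("Mann-Whitney U", U, Z = abs(Z), p = min(1, p), n = c(n1, n2))
}

#' Kruskal-Wallis test (chi-square approximation)
#'
#' Tie-corrected H with a chi-square approximation on k - 1 degrees of
#' freedom.
#'
#' @param groups List of 2+ non-empty numeric samples.
#' @return A \code{test_result} with \code{n} = group sizes.
#' @export
kruskal_wallis <- function(groups) {
  stopifnot(length(groups) >= 2L, all(lengths(groups) > 0L))
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(r)
  corr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  note <- NA_character_
  if (corr == 0) {
    H <- 0; note <- "all observations identical"
  } else H <- H / corr
  df <- length(groups) - 1L
  test_result("Kruskal-Wallis", H, df = df,
              p = pchisq(H, df, lower.tail = FALSE),
              n = lengths(groups), note = note)
}

#' Pearson chi-square test on a 2x2 contingency table
#'
#' Pearson statistic without continuity correction, df = 1.
#'
#' @param table 2x2 matrix of non-negative counts with positive margins.
#' @return A \code{test_result}.
#' @export
chi2_2x2 <- function(table) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == 2L), all(table >= 0))
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("contingency table has a zero margin")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  note <- if (any(ct$expected < 5))
    "expected count < 5; chi-square approximation is rough" else NA_character_
  test_result("Pearson chi-square", unname(ct$statistic), df = 1,
              p = unname(ct$p.value), n = sum(table), note = note)
}

#' Run the full rate-difference test battery for one data set
#'
#' Five tests per data set: (1) Wilcoxon signed-rank between the rates of
#' paired positions; (2) Mann-Whitney on collapsed stem rates versus loop
#' rates; (3) chi-square on constant/variable counts in hypervariable
#' versus non-hypervariable regions; (4) Mann-Whitney on rates in
#' non-hypervariable versus pooled hypervariable regions; (5)
#' Kruskal-Wallis across the individual hypervariable regions plus the
#' pooled non-hypervariable remainder.  Tests needing a structure map are
#' reported as explicit gaps when the map is missing.
#'
#' @param rateTable Site rate table from [tiger_rates()].
#' @param structureMap A [structure_map()] in the rate table's coordinates,
#'   or NULL.
#' @param regions A [region_set()].
#' @return Named list of \code{test_result} objects (entries
#'   \code{paired}, \code{stems_vs_loops}, \code{chi2_constant_variable},
#'   \code{hyper_vs_non_rates}, \code{among_regions}).
#' @export
run_test_battery <- function(rateTable, structureMap = NULL, regions) {
  reg <- region_of(regions, rateTable$column)
  hyper <- reg != "non-hypervariable"
  rated <- !is.na(rateTable$rate)

  out <- list()
  if (!is.null(structureMap)) {
    cp <- collapse_paired(rateTable, structureMap)
    out$paired <- wilcoxon_signed_rank(cp$pairs$rate_i, cp$pairs$rate_j)
    out$stems_vs_loops <- mann_whitney_u(cp$pairs$collapsed, cp$loops)
  } else {
    out$paired <- out$stems_vs_loops <- test_result(
      "not run", NA_real_, note = "no structure map supplied")
  }
  cls <- rateTable$class[rated]
  tab <- rbind(`non-hypervariable` = c(constant = sum(cls == "constant" & !hyper[rated]),
                                       variable = sum(cls == "variable" & !hyper[rated])),
               hypervariable = c(constant = sum(cls == "constant" & hyper[rated]),
                                 variable = sum(cls == "variable" & hyper[rated])))
  out$chi2_constant_variable <- chi2_2x2(tab)
  out$hyper_vs_non_rates <- mann_whitney_u(rateTable$rate[rated & !hyper],
                                           rateTable$rate[rated & hyper])
  grp_names <- c(regions$name, "non-hypervariable")
  samples <- lapply(grp_names, function(g) rateTable$rate[rated & reg == g])
  names(samples) <- grp_names
  samples <- samples[lengths(samples) > 0L]
  out$among_regions <- kruskal_wallis(samples)
  out
}
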