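# TIGER relative site rates.  The rate of an alignment column is the mean
# agreement between its taxon partition (taxa grouped by character state)
# and the partitions of every other column with sufficient coverage.
# Constant columns agree with everything (rate 1); rapidly evolving columns
# conflict with most of the alignment and score low.

# membership lookup: base_mask[state, code] is TRUE when `state` is a
# component of IUPAC code `code`
base_component_mask <- function() {
  m <- matrix(FALSE, 4L, length(ALN_ALPHABET),
              dimnames = list(c("A", "C", "G", "T"), ALN_ALPHABET))
  for (code in names(IUPAC_COMPONENTS)) m[IUPAC_COMPONENTS[[code]], code] <- TRUE
  m
}

#' Site partition of one alignment column
#'
#' Groups the taxa scored at a column by character state.  Terminal
#' (flanking) gaps and \code{N} are ignored; internal gaps drop the taxon
#' from the site unless \code{gap_as_state} is set, in which case internal
#' gaps form a fifth state.  An ambiguity code places its taxon in each
#' component state's set.
#'
#' @param aln Alignment matrix.
#' @param column 1-based column index.
#' @param gap_as_state Treat internal gaps as a fifth character state
#'   (sensitivity-analysis mode; default FALSE).
#' @param terminal Optional precomputed logical matrix from the terminal gap
#'   mask (internal use; recomputed when NULL).
#' @return List with \code{taxa} (character vector of scored taxa) and
#'   \code{sets} (named list of taxon-id vectors, one per state present).
#' @export
site_partition <- function(aln, column, gap_as_state = FALSE, terminal = NULL) {
  stopifnot(column >= 1L, column <= ncol(aln))
  if (is.null(terminal)) terminal <- terminal_mask_matrix(aln)
  ch <- aln[, column]
  scored <- !terminal[, column] & ch != "N"
  if (!gap_as_state) scored <- scored & ch != "-"
  ids <- rownames(aln)[scored]
  ch <- ch[scored]
  bm <- base_component_mask()
  sets <- list()
  for (s in c("A", "C", "G", "T")) {
    members <- ids[bm[s, ch]]
    if (length(members)) sets[[s]] <- members
  }
  if (gap_as_state) {
    members <- ids[ch == "-"]
    if (length(members)) sets[["-"]] <- members
  }
  list(taxa = ids, sets = sets)
}

#' Agreement between two site partitions
#'
#' pa(i, j) is the fraction of partition j's state sets whose restriction to
#' partition i's scored taxa is nested within some state set of i.  Empty
#' restrictions are excluded from numerator and denominator; when every
#' restriction is empty the agreement is undefined (\code{NA}) and the pair
#' is skipped in rate averaging.
#'
#' @param P_i,P_j Partitions from [site_partition()]; \code{P_j}'s sets are
#'   tested for subset-hood against \code{P_i}'s.
#' @return Numeric agreement in \[0, 1\], or \code{NA}.
#' @export
partition_agreement <- function(P_i, P_j) {
  if (length(P_i$sets) == 0L || length(P_j$sets) == 0L) return(NA_real_)
  num <- 0L; den <- 0L
  for (A in P_j$sets) {
    r <- intersect(A, P_i$taxa)
    if (length(r) == 0L) next
    den <- den + 1L
    for (S in P_i$sets) {
      if (all(r %in% S)) { num <- num + 1L; break }
    }
  }
  if (den == 0L) return(NA_real_)
  num / den
}

#' Site-specific relative rates from site-pattern congruence
#'
#' Computes the TIGER relative rate of every alignment column with coverage
#' at or above \code{threshold}: the mean partition agreement pa(i, j) over
#' all other passing columns j.  Rates lie in \[0, 1\]; constant columns are
#' exactly 1; low values mark rapidly evolving positions.  Columns below the
#' coverage threshold are flagged and excluded from both roles (focal and
#' comparison).
#'
#' @param aln Alignment matrix.
#' @param threshold Minimum coverage fraction (default 0.15).
#' @param gap_as_state Fifth-state mode for internal gaps (default FALSE).
#' @return Data frame (the site rate table) with columns \code{column},
#'   \code{coverage}, \code{class}, \code{rate} (\code{NA} when coverage is
#'   insufficient).
#' @export
tiger_rates <- function(aln, threshold = 0.15, gap_as_state = FALSE) {
  cls <- classify_sites(aln, threshold)
  passing <- which(cls$class != "insufficient_coverage")
  if (length(passing) < 2L)
    stop("need at least 2 columns passing the coverage threshold")
  terminal <- terminal_mask_matrix(aln)
  idx <- setNames(seq_len(nrow(aln)) - 1L, rownames(aln))   # 0-based for C++
  parts <- vector("list", length(passing))
  for (k in seq_along(passing)) {
    p <- site_partition(aln, passing[k], gap_as_state, terminal)
    parts[[k]] <- list(taxa = unname(idx[p$taxa]),
                       sets = lapply(unname(p$sets), function(s) unname(idx[s])))
  }
  rates <- tiger_rates_cpp(parts, nrow(aln))
  out <- data.frame(column = cls$column, coverage = cls$coverage,
                    class = cls$class, rate = NA_real_,
                    stringsAsFactors = FALSE)
  out$rate[passing] <- rates
  out
}

#' Mean and standard error of site rates
#'
#' @param table Site rate table from [tiger_rates()].
#' @param subset \code{"all"} (every rated column) or \code{"variable_only"}.
#' @return List with \code{mean}, \code{se}, \code{n}.
#' @export
summarize_rates <- function(table, subset = c("all", "variable_only")) {
  subset <- match.arg(subset)
  r <- table$rate
  keep <- !is.na(r)
  if (subset == "variable_only") keep <- keep & table$class == "variable"
  vals <- r[keep]
  n <- length(vals)
  list(mean = if (n) mean(vals) else NA_real_,
       se = if (n > 1L) sd(vals) / sqrt(n) else NA_real_,
       n = n)
}

#' Centred rolling average of a rate series
#'
#' Mean of the defined rates within a window centred on each position;
#' the window truncates at the ends of the series, and undefined
#' (insufficient-coverage) positions are excluded from each window mean.
#'
#' @param rate_series Numeric vector (may contain \code{NA}).
#' @param window Odd window size (default 35).
#' @return Numeric vector of the same length.
#' @export
rolling_average <- function(rate_series, window = 35L) {
  stopifnot(window >= 1L, window %% 2L == 1L)
  h <- (window - 1L) %/% 2L
  L <- length(rate_series)
  out <- numeric(L)
  for (i in seq_len(L)) {
    lo <- max(1L, i - h); hi <- min(L, i + h)
    w <- rate_series[lo:hi]
    w <- w[!is.na(w)]
    out[i] <- if (length(w)) mean(w) else NA_real_
  }
  out
}

#' Histogram of site rates with an insufficient-coverage bin
#'
#' Bins are left-closed, right-open (\code{[k*w, (k+1)*w)}), so a rate of
#' exactly 1 falls in the bin starting at 1 when \code{1/bin_width} is an
#' integer.  Counts over all bins plus the \code{n/a} bin partition the
#' alignment columns.
#'
#' @param table Site rate table from [tiger_rates()].
#' @param bin_width Positive bin width.
#' @return Data frame with columns \code{bin_start}, \code{bin_end},
#'   \code{count}; the final row is the \code{n/a} (insufficient-coverage)
#'   bin with \code{NA} bounds.
#' @export
rate_histogram <- function(table, bin_width = 0.05) {
  stopifnot(bin_width > 0)
  r <- table$rate
  na_count <- sum(is.na(r))
  r <- r[!is.na(r)]
  n_bins <- floor(1 / bin_width) + 1L
  bin <- pmin(floor(r / bin_width), n_bins - 1L)
  counts <- tabulate(bin + 1L, nbins = n_bins)
  out <- data.frame(bin_start = (seq_len(n_bins) - 1L) * bin_width,
                    bin_end = seq_len(n_bins) * bin_width,
                    count = counts)
  rbind(out, data.frame(bin_start = NA_real_, bin_end = NA_real_,
                        count = na_count))
}
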