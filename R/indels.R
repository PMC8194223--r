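# Indel-run statistics per exemplar row and region, and detection of the
# variably expressed deletion window at the 3' end of V3.

# maximal '-' runs of one row as (start, length) pairs
gap_runs_of_row <- function(row) {
  r <- rle(row == "-")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], length = r$lengths[keep])
}

#' Indel runs of one taxon, split by region
#'
#' An indel is a maximal contiguous gap run in the taxon's row relative to
#' the group alignment.  Runs crossing a region boundary are split at the
#' boundary so that per-region nucleotide + gap counts stay exact.  In the
#' pooled non-hypervariable region, run segments descending from a run that
#' overlaps the taxon's terminal gap spans are excluded (terminal gaps
#' usually mean an incomplete sequence, not an indel).
#'
#' @param aln Alignment matrix.
#' @param taxon Taxon id.
#' @param regions A [region_set()].
#' @param terminal_policy \code{"exclude_nonhyper"} (default: drop
#'   terminal-overlapping runs from the pooled non-hypervariable region
#'   only), \code{"exclude_all"}, or \code{"include"}.
#' @return Data frame with columns \code{taxon}, \code{region},
#'   \code{start}, \code{length}.
#' @export
indel_runs <- function(aln, taxon, regions,
                       terminal_policy = c("exclude_nonhyper", "exclude_all",
                                           "include")) {
  terminal_policy <- match.arg(terminal_policy)
  stopifnot(taxon %in% rownames(aln))
  row <- aln[taxon, ]
  runs <- gap_runs_of_row(row)
  if (nrow(runs) == 0L)
    return(data.frame(taxon = character(0), region = character(0),
                      start = integer(0), length = integer(0)))
  mask <- terminal_gap_mask(aln)
  mk <- mask[mask$taxon == taxon, ]
  L <- ncol(aln)
  is_terminal_run <- (runs$start <= mk$leading) |
    (runs$start + runs$length - 1L > L - mk$trailing)

  out <- list()
  for (k in seq_len(nrow(runs))) {
    s <- runs$start[k]; e <- s + runs$length[k] - 1L
    cols <- s:e
    reg <- region_of(regions, cols)
    # split the run at region boundaries
    seg <- rle(reg)
    seg_end <- cumsum(seg$lengths)
    seg_start <- seg_end - seg$lengths + 1L
    for (m in seq_along(seg$values)) {
      rname <- seg$values[m]
      if (is_terminal_run[k]) {
        if (terminal_policy == "exclude_all") next
        if (terminal_policy == "exclude_nonhyper" &&
            rname == "non-hypervariable") next
      }
      out[[length(out) + 1L]] <- data.frame(
        taxon = taxon, region = rname,
        start = cols[seg_start[m]], length = seg$lengths[m],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(taxon = character(0), region = character(0),
                      start = integer(0), length = integer(0)))
  do.call(rbind, out)
}

#' Per-region indel summary for one taxon
#'
#' Counts, per named region and for the pooled non-hypervariable remainder:
#' nucleotides (non-gap characters), number of indel runs, and mean run
#' length (\code{NA} when there are no runs).
#'
#' @inheritParams indel_runs
#' @return Data frame with columns \code{taxon}, \code{region},
#'   \code{region_length}, \code{nucleotides}, \code{n_indels},
#'   \code{mean_indel_length}.
#' @export
region_indel_summary <- function(aln, taxon, regions,
                                 terminal_policy = "exclude_nonhyper") {
  runs <- indel_runs(aln, taxon, regions, terminal_policy)
  row <- aln[taxon, ]
  reg_all <- region_of(regions, seq_len(ncol(aln)))
  reg_names <- c(regions$name, "non-hypervariable")
  out <- lapply(reg_names, function(rn) {
    cols <- which(reg_all == rn)
    rr <- runs[runs$region == rn, , drop = FALSE]
    n <- nrow(rr)
    data.frame(taxon = taxon, region = rn, region_length = length(cols),
               nucleotides = sum(row[cols] != "-"),
               n_indels = n,
               mean_indel_length = if (n) mean(rr$length) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Deletion window at the 3' end of a hypervariable region
#'
#' Builds the (start, length) window spanning the last \code{tail} columns
#' of the named region plus the following \code{extension} columns, the
#' configuration used to characterize the variably expressed bdelloid
#' deletion downstream of V3.
#'
#' @param regions A [region_set()].
#' @param region Region name (default \code{"V3"}).
#' @param tail Columns taken from the region's 3' end (default 14).
#' @param extension Columns beyond the region (default 78).
#' @return Named numeric vector \code{c(start, length)}.
#' @export
deletion_window <- function(regions, region = "V3", tail = 14L,
                            extension = 78L) {
  k <- which(regions$name == region)
  if (length(k) != 1L) stop("region not found: ", region)
  c(start = regions$end[k] - tail + 1L, length = tail + extension)
}

#' Detect and classify deletion motifs within a window
#'
#' For each taxon (optionally restricted to one clade), reports the gap
#' runs intersecting the window, the expressed deletion length (gapped
#' columns within the window), and a motif class defined by the exact span
#' coordinates, so equal-length deletions at different positions are
#' distinct classes.  Taxa with no gap in the window form the
#' \code{"absent"} class.
#'
#' @param aln Alignment matrix.
#' @param window Named vector \code{c(start, length)}, e.g. from
#'   [deletion_window()].
#' @param groups Optional named clade vector; when given with
#'   \code{group}, restricts to taxa of that clade.
#' @param group Optional clade label to restrict to.
#' @return Data frame with columns \code{taxon}, \code{expressed_length},
#'   \code{spans} (e.g. \code{"593-600;605-610"}), \code{class} (identical
#'   to spans, or \code{"absent"}).
#' @export
detect_deletion <- function(aln, window, groups = NULL, group = NULL) {
  s <- as.integer(window[["start"]]); len <- as.integer(window[["length"]])
  e <- s + len - 1L
  if (s < 1L || e > ncol(aln)) stop("deletion window outside the alignment")
  taxa <- rownames(aln)
  if (!is.null(groups) && !is.null(group)) taxa <- taxa[groups[taxa] == group]
  out <- lapply(taxa, function(tx) {
    runs <- gap_runs_of_row(aln[tx, ])
    if (nrow(runs)) {
      re <- runs$start + runs$length - 1L
      keep <- runs$start <= e & re >= s
      runs <- runs[keep, , drop = FALSE]
      re <- re[keep]
    }
    if (nrow(runs) == 0L) {
      spans <- "absent"; expressed <- 0L
    } else {
      cs <- pmax(runs$start, s); ce <- pmin(re, e)
      spans <- paste(paste0(cs, "-", ce), collapse = ";")
      expressed <- sum(ce - cs + 1L)
    }
    data.frame(taxon = tx, expressed_length = expressed,
               spans = spans, class = spans, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
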