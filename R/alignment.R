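#' Read a gapped multiple sequence alignment from FASTA
#'
#' Reads an aligned, gapped FASTA file into a character matrix with one row
#' per taxon and one column per alignment position.  Input is
#' case-insensitive; rows are normalized to uppercase and RNA \code{U} is
#' converted to \code{T}.  Characters outside the IUPAC nucleotide alphabet
#' (plus \code{N} and the gap character \code{-}) are a hard error naming the
#' offending taxon and column.
#'
#' @param path Path to an aligned FASTA file.
#' @return A character matrix (taxa x columns) with taxon ids as row names.
#' @export
read_aligned_fasta <- function(path) {
  if (!file.exists(path)) stop("alignment file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) stop("alignment file is empty: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  rows <- toupper(as.character(seqs))
  as_alignment(rows, ids)
}

#' Build an alignment matrix from character rows
#'
#' @param rows Character vector of equal-length sequence strings.
#' @param ids Taxon identifiers, one per row; must be unique.
#' @return Validated character matrix (taxa x columns).
#' @export
as_alignment <- function(rows, ids = names(rows)) {
  if (is.null(ids)) ids <- paste0("t", seq_along(rows))
  if (anyDuplicated(ids)) stop("duplicate taxon ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  rows <- toupper(rows)
  rows <- gsub("U", "T", rows, fixed = TRUE)
  lens <- nchar(rows)
  if (length(unique(lens)) != 1L) {
    bad <- ids[lens != lens[1L]][1L]
    stop("unequal row lengths: taxon '", bad, "' has ", nchar(rows[ids == bad]),
         " columns, expected ", lens[1L])
  }
  m <- do.call(rbind, strsplit(rows, "", fixed = TRUE))
  rownames(m) <- ids
  bad <- which(!(m %in% ALN_ALPHABET))
  if (length(bad)) {
    i <- ((bad[1L] - 1L) %% nrow(m)) + 1L
    j <- ((bad[1L] - 1L) %/% nrow(m)) + 1L
    stop("illegal character '", m[bad[1L]], "' in taxon '", rownames(m)[i],
         "' at column ", j, " (", length(bad), " illegal cells in total)")
  }
  m
}

#' Write an alignment matrix to FASTA
#'
#' @param aln Character matrix as returned by [read_aligned_fasta()].
#' @param path Output file path.
#' @export
write_aligned_fasta <- function(aln, path) {
  rows <- apply(aln, 1L, paste0, collapse = "")
  x <- Biostrings::BStringSet(rows)
  names(x) <- rownames(aln)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Subset an alignment to a taxon set and drop all-gap columns
#'
#' Restricts the alignment to the taxa in \code{keep} and removes columns
#' that contain only gaps after the restriction (compaction).  A column map
#' records where each original column went, so downstream per-column results
#' can be lifted back to the master coordinate system.
#'
#' @param aln Alignment matrix.
#' @param keep Character vector of taxon ids to retain.
#' @return A list with elements \code{aln} (the compacted sub-alignment) and
#'   \code{column_map} (integer vector, length = original columns; new column
#'   index or \code{NA} for columns dropped as all-gap).
#' @export
subset_and_compact <- function(aln, keep) {
  if (length(keep) == 0L) stop("'keep' must name at least one taxon")
  missing <- setdiff(keep, rownames(aln))
  if (length(missing)) stop("taxa not in alignment: ", paste(missing, collapse = ", "))
  sub <- aln[keep, , drop = FALSE]
  nongap <- colSums(sub != "-") > 0L
  column_map <- rep(NA_integer_, ncol(aln))
  column_map[nongap] <- seq_len(sum(nongap))
  list(aln = sub[, nongap, drop = FALSE], column_map = column_map)
}

#' Leading/trailing gap spans per taxon
#'
#' Terminal gap runs usually reflect incomplete sequencing rather than real
#' indels, so several statistics mask them.  Returns, per taxon, the maximal
#' leading and trailing runs of \code{-}.
#'
#' @param aln Alignment matrix.
#' @return Data frame with columns \code{taxon}, \code{leading},
#'   \code{trailing}, \code{all_gap} (TRUE for a degenerate all-gap row, in
#'   which case the whole row counts as leading).
#' @export
terminal_gap_mask <- function(aln) {
  L <- ncol(aln)
  lead <- trail <- integer(nrow(aln))
  all_gap <- logical(nrow(aln))
  for (i in seq_len(nrow(aln))) {
    ng <- which(aln[i, ] != "-")
    if (length(ng) == 0L) {
      lead[i] <- L; trail[i] <- 0L; all_gap[i] <- TRUE
    } else {
      lead[i] <- ng[1L] - 1L
      trail[i] <- L - ng[length(ng)]
    }
  }
  data.frame(taxon = rownames(aln), leading = lead, trailing = trail,
             all_gap = all_gap, stringsAsFactors = FALSE)
}

# logical matrix marking cells inside terminal gap spans
terminal_mask_matrix <- function(aln, mask = terminal_gap_mask(aln)) {
  L <- ncol(aln)
  m <- matrix(FALSE, nrow(aln), L, dimnames = dimnames(aln))
  for (i in seq_len(nrow(aln))) {
    if (mask$leading[i] > 0L) m[i, seq_len(mask$leading[i])] <- TRUE
    if (mask$trailing[i] > 0L) m[i, (L - mask$trailing[i] + 1L):L] <- TRUE
  }
  m
}

#' Internal-gap statistics with terminal gaps ignored
#'
#' Computes the percentage of gap cells in an alignment after discounting
#' terminal gap spans, so that incomplete sequences do not inflate the
#' apparent indel load.  Assessed cells = all cells minus terminal-gap cells;
#' the numerator counts gap cells outside the terminal spans.
#'
#' @param aln Alignment matrix.
#' @param mask Optional precomputed [terminal_gap_mask()].
#' @return List with \code{aligned_length}, \code{internal_gap_cells},
#'   \code{assessed_cells}, \code{pct_gaps} (in percent; \code{NA} when no
#'   cells are assessed).
#' @export
gap_statistics <- function(aln, mask = terminal_gap_mask(aln)) {
  tm <- terminal_mask_matrix(aln, mask)
  assessed <- sum(!tm)
  internal <- sum(aln == "-" & !tm)
  list(aligned_length = ncol(aln),
       internal_gap_cells = internal,
       assessed_cells = assessed,
       pct_gaps = if (assessed == 0L) NA_real_ else 100 * internal / assessed)
}

#' Per-column coverage fraction
#'
#' Coverage counts taxa carrying an informative character at the column:
#' anything that is not a gap and not \code{N}.  (Ambiguity codes other than
#' N are informative.)
#'
#' @param aln Alignment matrix.
#' @return Numeric vector of length \code{ncol(aln)} in \[0, 1\].
#' @export
site_coverage <- function(aln) {
  colSums(aln != "-" & aln != "N") / nrow(aln)
}

#' Classify columns as constant, variable, or insufficient coverage
#'
#' A column is \emph{constant} when all informative characters are mutually
#' consistent with at least one shared nucleotide state: an ambiguity code
#' counts as consistent with a state when the state is among its components;
#' gaps and \code{N} are excluded.  Columns whose coverage falls below
#' \code{threshold} are flagged \code{insufficient_coverage} and excluded
#' from downstream rate estimation.
#'
#' @param aln Alignment matrix.
#' @param threshold Minimum coverage fraction in (0, 1\]; default 0.15.
#' @return Data frame with columns \code{column}, \code{coverage},
#'   \code{class} (factor: constant/variable/insufficient_coverage).
#' @export
classify_sites <- function(aln, threshold = 0.15) {
  stopifnot(threshold > 0, threshold <= 1)
  cov <- site_coverage(aln)
  cls <- character(ncol(aln))
  base_mask <- matrix(FALSE, 4L, length(ALN_ALPHABET),
                      dimnames = list(c("A", "C", "G", "T"), ALN_ALPHABET))
  for (code in names(IUPAC_COMPONENTS))
    base_mask[IUPAC_COMPONENTS[[code]], code] <- TRUE
  for (j in seq_len(ncol(aln))) {
    if (cov[j] < threshold) { cls[j] <- "insufficient_coverage"; next }
    ch <- aln[, j]
    ch <- ch[ch != "-" & ch != "N"]
    if (length(ch) == 0L) { cls[j] <- "insufficient_coverage"; next }
    # consistent iff some base is a component of every observed code
    shared <- rowSums(base_mask[, ch, drop = FALSE]) == length(ch)
    cls[j] <- if (any(shared)) "constant" else "variable"
  }
  data.frame(column = seq_len(ncol(aln)), coverage = cov,
             class = factor(cls, levels = c("constant", "variable",
                                            "insufficient_coverage")),
             stringsAsFactors = FALSE)
}
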