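#' Region tables and group assignments
#'
#' A region set names intervals of the alignment (typically the
#' hypervariable regions V1--V9 of the small-subunit rRNA) as 1-based
#' inclusive (start, length) pairs.  Columns outside every named region are
#' pooled as "non-hypervariable".
#'
#' @param name,start,length Equal-length vectors defining the regions.
#' @return Data frame of class \code{region_set} with columns \code{name},
#'   \code{start}, \code{length}, \code{end}.
#' @export
region_set <- function(name, start, length) {
  stopifnot(length(name) == length(start), length(start) == length(length),
            all(start >= 1L), all(length >= 1L))
  rs <- data.frame(name = as.character(name), start = as.integer(start),
                   length = as.integer(length), stringsAsFactors = FALSE)
  rs$end <- rs$start + rs$length - 1L
  o <- order(rs$start)
  rs <- rs[o, , drop = FALSE]
  if (nrow(rs) > 1L && any(rs$start[-1L] <= rs$end[-nrow(rs)]))
    stop("regions overlap")
  class(rs) <- c("region_set", "data.frame")
  rs
}

#' Read a region table from TSV
#'
#' Expects a header row and columns \code{name}, \code{start}, \code{length}
#' (1-based inclusive alignment coordinates).
#'
#' @param path Path to the TSV file.
#' @return A [region_set()].
#' @export
read_regions <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  region_set(d$name, d$start, d$length)
}

#' Map alignment columns to region names
#'
#' @param regions A [region_set()].
#' @param column Integer vector of 1-based alignment columns.
#' @return Character vector: the region name, or \code{"non-hypervariable"}
#'   for columns outside every region.
#' @export
region_of <- function(regions, column) {
  out <- rep("non-hypervariable", length(column))
  for (k in seq_len(nrow(regions))) {
    hit <- column >= regions$start[k] & column <= regions$end[k]
    out[hit] <- regions$name[k]
  }
  out
}

#' Read a taxon-to-clade mapping from TSV
#'
#' Two-column TSV (with header) mapping \code{taxon_id} to \code{clade}.
#'
#' @param path Path to the TSV file.
#' @param aln Optional alignment matrix; when given, every alignment taxon
#'   must be mapped, and extra mappings are dropped.
#' @return Named character vector: clade label per taxon id.
#' @export
read_groups <- function(path, aln = NULL) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  g <- setNames(as.character(d[[2L]]), as.character(d[[1L]]))
  if (!is.null(aln)) {
    missing <- setdiff(rownames(aln), names(g))
    if (length(missing))
      stop("taxa without a clade label: ", paste(head(missing, 5L), collapse = ", "))
    g <- g[rownames(aln)]
  }
  g
}

#' Bundled hypervariable-region coordinates for the rotifer 18S alignment
#'
#' Returns the V1--V9 start/length table for the aligned rotifer 18S data
#' set (1-based alignment coordinates), shipped with the package.
#'
#' @return A [region_set()].
#' @export
rotifer_regions <- function() {
  read_regions(system.file("extdata", "regions_rotifera.tsv",
                           package = "ssuvar", mustWork = TRUE))
}
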