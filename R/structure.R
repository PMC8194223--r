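# Secondary-structure containers and the two-step structure-transfer
# procedure: a consensus constraint from reference structure maps, a
# constrained folding engine, per-region folding with bracketing stems,
# splicing of region folds into the core backbone, and transfer of
# pseudoknot pairings (which cross the primary layer) by homology.

CANONICAL_PAIRS <- c("AT", "TA", "GC", "CG", "GT", "TG")

#' Construct a structure map
#'
#' A structure map holds a sequence, a primary pairing layer (an involution
#' whose pairings are non-crossing) and a pseudoknot layer (an involution
#' whose pairings may cross the primary layer).
#'
#' @param seq Character string (nucleotides; U is normalized to T
#'   internally, gaps allowed when the map lives in alignment coordinates).
#' @param pair Integer vector: partner position per position, 0 = unpaired.
#' @param knot Integer vector for the pseudoknot layer (default all 0).
#' @return List of class \code{structure_map}.
#' @export
structure_map <- function(seq, pair = integer(nchar(seq)),
                          knot = integer(nchar(seq))) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  n <- nchar(seq)
  pair <- as.integer(pair); knot <- as.integer(knot)
  stopifnot(length(pair) == n, length(knot) == n)
  check_involution(pair, "primary")
  check_involution(knot, "pseudoknot")
  check_noncrossing(pair)
  structure(list(seq = seq, pair = pair, knot = knot),
            class = "structure_map")
}

check_involution <- function(pair, layer) {
  idx <- which(pair > 0L)
  if (any(pair[idx] > length(pair)) || any(pair[pair[idx]] != idx) ||
      any(pair[idx] == idx))
    stop(layer, " layer is not an involution")
  invisible(TRUE)
}

check_noncrossing <- function(pair) {
  idx <- which(pair > 0L & pair > seq_along(pair))
  if (length(idx) < 2L) return(invisible(TRUE))
  op <- idx; cl <- pair[idx]
  for (a in seq_along(op)) for (b in seq_along(op)) {
    if (op[a] < op[b] && op[b] < cl[a] && cl[a] < cl[b])
      stop("primary layer has crossing pairings (", op[a], ",", cl[a],
           ") x (", op[b], ",", cl[b], ")")
  }
  invisible(TRUE)
}

# --- dot-bracket I/O -------------------------------------------------------

BRACKET_OPEN <- c("(", "[", "{", "<")
BRACKET_CLOSE <- c(")", "]", "}", ">")

#' Parse a multi-layer dot-bracket string
#'
#' \code{()} encodes the primary layer; \code{[]}, \code{\{\}} and \code{<>}
#' encode pseudoknot-layer pairings (allowed to cross the primary layer).
#'
#' @param s Dot-bracket string.
#' @return List with integer vectors \code{pair} and \code{knot}.
#' @export
parse_dotbracket <- function(s) {
  ch <- strsplit(s, "", fixed = TRUE)[[1L]]
  n <- length(ch)
  pair <- integer(n); knot <- integer(n)
  for (alpha in seq_along(BRACKET_OPEN)) {
    stack <- integer(0)
    for (i in seq_len(n)) {
      if (ch[i] == BRACKET_OPEN[alpha]) stack <- c(stack, i)
      else if (ch[i] == BRACKET_CLOSE[alpha]) {
        if (length(stack) == 0L)
          stop("unbalanced '", BRACKET_CLOSE[alpha], "' at position ", i)
        j <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (alpha == 1L) { pair[j] <- i; pair[i] <- j }
        else { knot[j] <- i; knot[i] <- j }
      }
    }
    if (length(stack))
      stop("unbalanced '", BRACKET_OPEN[alpha], "' at position ",
           stack[length(stack)])
  }
  bad <- which(!(ch %in% c(".", BRACKET_OPEN, BRACKET_CLOSE)))
  if (length(bad))
    stop("illegal structure character '", ch[bad[1L]], "' at position ", bad[1L])
  list(pair = pair, knot = knot)
}

#' Encode a structure map as a multi-layer dot-bracket string
#'
#' @param map A [structure_map()].
#' @return Dot-bracket string; pseudoknot pairings are written with
#'   \code{[]} (and \code{\{\}}, \code{<>} when knot pairings themselves
#'   cross).
#' @export
format_dotbracket <- function(map) {
  n <- nchar(map$seq)
  out <- rep(".", n)
  idx <- which(map$pair > 0L & map$pair > seq_len(n))
  out[idx] <- "("; out[map$pair[idx]] <- ")"
  # assign knot pairings greedily to bracket alphabets so same-alphabet
  # pairings never cross
  kidx <- which(map$knot > 0L & map$knot > seq_len(n))
  if (length(kidx)) {
    kidx <- kidx[order(kidx)]
    layer_pairs <- list(integer(0), integer(0), integer(0))
    for (i in kidx) {
      j <- map$knot[i]
      placed <- FALSE
      for (a in 1:3) {
        ok <- TRUE
        for (p in layer_pairs[[a]]) {
          q <- map$knot[p]
          if ((p < i && i < q && q < j) || (i < p && p < j && j < q)) {
            ok <- FALSE; break
          }
        }
        if (ok) {
          layer_pairs[[a]] <- c(layer_pairs[[a]], i)
          out[i] <- BRACKET_OPEN[a + 1L]; out[j] <- BRACKET_CLOSE[a + 1L]
          placed <- TRUE; break
        }
      }
      if (!placed) stop("pseudoknot layer needs more than 3 bracket alphabets")
    }
  }
  paste0(out, collapse = "")
}

#' Read structure maps from a Vienna-style file
#'
#' Expects records of the form: an optional \code{>name} header, a sequence
#' line, and a dot-bracket line of the same length (pseudoknot layers in
#' \code{[]}, \code{\{\}}, \code{<>}).
#'
#' @param path File path.
#' @return Named list of [structure_map()] objects.
#' @export
read_vienna <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  maps <- list(); name <- NULL; seqline <- NULL; counter <- 0L
  i <- 1L
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) { name <- sub("^>\\s*", "", ln); i <- i + 1L; next }
    seqline <- ln
    if (i + 1L > length(lines)) stop("sequence without structure line: ", seqline)
    st <- trimws(lines[i + 1L])
    st <- sub("\\s*\\(-?[0-9.]+\\)$", "", st)   # tolerate trailing energies
    if (nchar(st) != nchar(seqline))
      stop("structure length ", nchar(st), " != sequence length ",
           nchar(seqline))
    pk <- parse_dotbracket(st)
    counter <- counter + 1L
    nm <- if (is.null(name)) paste0("structure_", counter) else name
    maps[[nm]] <- structure_map(seqline, pk$pair, pk$knot)
    name <- NULL
    i <- i + 2L
  }
  maps
}

#' Write structure maps to a Vienna-style file
#'
#' @param maps A [structure_map()] or named list of them.
#' @param path Output path.
#' @export
write_vienna <- function(maps, path) {
  if (inherits(maps, "structure_map")) maps <- list(structure = maps)
  con <- file(path, "w"); on.exit(close(con))
  for (nm in names(maps)) {
    writeLines(c(paste0(">", nm), maps[[nm]]$seq,
                 format_dotbracket(maps[[nm]])), con)
  }
  invisible(path)
}

# --- reference folding engine ---------------------------------------------

#' Constrained base-pair maximization (reference folding engine)
#'
#' A deterministic dynamic-programming folder maximizing the number of
#' canonical base pairs (AT/AU, GC, GT/GU) with a minimum hairpin loop of
#' \code{min_loop} unpaired positions.  Constraint symbols: \code{x} = never
#' paired (always honoured), \code{(}/\code{)} = paired with the matched
#' partner (honoured only when \code{enforce} is TRUE, in which case forced
#' pairs bypass the canonical and loop-length checks), \code{.} =
#' unconstrained.  Ties are broken deterministically: prefer pairing the
#' 5'-most position, then the shortest-range pair.
#'
#' This engine plays the role of an external minimum-free-energy folder
#' behind the same interface; scores are pair counts, not energies.
#'
#' @param seq Nucleotide string.
#' @param constraint Constraint string of the same length, or NULL.
#' @param enforce Enforce \code{(}/\code{)} pairs (default FALSE: treated as
#'   unconstrained, mirroring a folder run without strict enforcement).
#' @param min_loop Minimum unpaired positions inside a hairpin (default 3).
#' @return List with \code{map} (a [structure_map()]) and \code{score}
#'   (number of pairs).
#' @export
reference_fold <- function(seq, constraint = NULL, enforce = FALSE,
                           min_loop = 3L) {
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  s <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(s)
  if (is.null(constraint)) constraint <- strrep(".", n)
  if (nchar(constraint) != n) stop("constraint length != sequence length")
  cvec <- strsplit(constraint, "", fixed = TRUE)[[1L]]
  bad <- which(!(cvec %in% c(".", "x", "(", ")")))
  if (length(bad)) stop("illegal constraint symbol '", cvec[bad[1L]],
                        "' at position ", bad[1L])
  forced <- integer(n)
  if (enforce) {
    pk <- parse_dotbracket(gsub("x", ".", constraint, fixed = TRUE))
    forced <- pk$pair
  }
  can_pair <- function(i, k) {
    if (cvec[i] == "x" || cvec[k] == "x") return(FALSE)
    if (forced[i] > 0L || forced[k] > 0L) return(forced[i] == k)
    if (k - i <= min_loop) return(FALSE)
    paste0(s[i], s[k]) %in% CANONICAL_PAIRS
  }
  if (n == 0L) return(list(map = structure_map(""), score = 0L))
  M <- matrix(0L, n, n)
  for (span in 2:max(2L, n)) {
    if (span > n) break
    for (i in seq_len(n - span + 1L)) {
      j <- i + span - 1L
      best <- M[i + 1L, j]   # i unpaired (M[i+1,j] valid: i+1 <= j)
      for (k in (i + 1L):j) {
        if (!can_pair(i, k)) next
        v <- 1L + (if (k - i > 1L) M[i + 1L, k - 1L] else 0L) +
          (if (k < j) M[k + 1L, j] else 0L)
        if (v > best) best <- v
      }
      M[i, j] <- best
    }
  }
  pair <- integer(n)
  trace <- function(i, j) {
    while (i < j) {
      target <- M[i, j]
      paired <- FALSE
      for (k in (i + 1L):j) {    # smallest k first = shortest-range pair
        if (!can_pair(i, k)) next
        v <- 1L + (if (k - i > 1L) M[i + 1L, k - 1L] else 0L) +
          (if (k < j) M[k + 1L, j] else 0L)
        if (v == target) {
          pair[i] <<- k; pair[k] <<- i
          if (k - i > 1L) trace(i + 1L, k - 1L)
          i <- k + 1L
          paired <- TRUE
          break
        }
      }
      if (!paired) i <- i + 1L
    }
  }
  trace(1L, n)
  list(map = structure_map(seq, pair), score = sum(pair > 0L) %/% 2L)
}

#' Folding-engine adapter for an external minimum-free-energy folder
#'
#' Wraps the \code{RNAfold} command-line program behind the same contract
#' as [reference_fold()]: \code{x} positions are passed as unpairable
#' constraints, and \code{enforce} adds \code{--enforceConstraint}.  The
#' score is the negated free energy.
#'
#' @inheritParams reference_fold
#' @param rnafold Path to the RNAfold binary.
#' @return List with \code{map} and \code{score}.
#' @export
rnafold_engine <- function(seq, constraint = NULL, enforce = FALSE,
                           rnafold = Sys.which("RNAfold")) {
  if (!nzchar(rnafold)) stop("RNAfold binary not found")
  n <- nchar(seq)
  if (is.null(constraint)) constraint <- strrep(".", n)
  tmp <- tempfile(fileext = ".fa")
  writeLines(c(">query", seq, constraint), tmp)
  on.exit(unlink(tmp))
  args <- c("-C", "--noPS")
  if (enforce) args <- c(args, "--enforceConstraint")
  out <- system2(rnafold, args, stdin = tmp, stdout = TRUE, stderr = FALSE)
  stline <- out[3L]
  db <- sub("\\s*\\(\\s*(-?[0-9.]+)\\)$", "", stline)
  energy <- as.numeric(sub(".*\\(\\s*(-?[0-9.]+)\\)$", "\\1", stline))
  pk <- parse_dotbracket(db)
  list(map = structure_map(seq, pk$pair, pk$knot), score = -energy)
}

# --- consensus constraint and structure transfer ---------------------------

# map ungapped sequence positions to alignment columns for a gapped row
seqpos_to_column <- function(gapped_row) {
  which(strsplit(gapped_row, "", fixed = TRUE)[[1L]] != "-")
}

#' Lift a per-sequence structure map into alignment coordinates
#'
#' @param map A [structure_map()] of an ungapped sequence.
#' @param gapped_row The same sequence as a gapped alignment row (string).
#' @return A [structure_map()] whose sequence is the gapped row and whose
#'   pairings are in alignment-column coordinates.
#' @export
map_to_alignment <- function(map, gapped_row) {
  cols <- seqpos_to_column(gapped_row)
  n_seq <- nchar(map$seq)
  if (length(cols) != n_seq)
    stop("gapped row has ", length(cols), " bases but map has ", n_seq)
  L <- nchar(gapped_row)
  pair <- integer(L); knot <- integer(L)
  pos <- which(map$pair > 0L)
  pair[cols[pos]] <- cols[map$pair[pos]]
  pos <- which(map$knot > 0L)
  knot[cols[pos]] <- cols[map$knot[pos]]
  structure_map(gapped_row, pair, knot)
}

#' Consensus folding constraint from aligned reference structures
#'
#' Positions consistently paired (with the same partner column) across all
#' reference maps are constrained as pairs; positions consistently unpaired
#' become \code{x}; disagreements are unconstrained (\code{.}).
#' Hypervariable regions, pseudoknot positions and other nested pairings
#' are forced unpaired (\code{x}) so they fold as unresolved extended
#' loops.  Columns where every reference is gapped (target-only
#' insertions) are \code{.} outside and \code{x} inside hypervariable
#' regions.
#'
#' @param refMaps List of 2+ [structure_map()] objects in common
#'   (backbone-alignment) coordinates, e.g. from [map_to_alignment()].
#' @param hyper A [region_set()] of hypervariable intervals in backbone
#'   coordinates (may be NULL).
#' @param knots Two-column matrix/data frame of pseudoknot (and other
#'   nested) pairing coordinates in backbone columns (may be NULL); both
#'   partners are forced unpaired.
#' @return Constraint string over backbone columns.
#' @export
build_consensus_constraint <- function(refMaps, hyper = NULL, knots = NULL) {
  stopifnot(length(refMaps) >= 2L)
  L <- unique(vapply(refMaps, function(m) nchar(m$seq), integer(1)))
  if (length(L) != 1L) stop("reference maps are not on a common backbone")
  gap <- do.call(rbind, lapply(refMaps, function(m)
    strsplit(m$seq, "", fixed = TRUE)[[1L]] == "-"))
  pairm <- do.call(rbind, lapply(refMaps, function(m) m$pair))

  cons <- rep(".", L)
  cons_pair <- integer(L)
  for (j in seq_len(L)) {
    votes <- which(!gap[, j])
    if (length(votes) == 0L) next                     # target-only insertion
    p <- pairm[votes, j]
    if (all(p == 0L)) cons[j] <- "x"
    else if (all(p > 0L) && length(unique(p)) == 1L) cons_pair[j] <- p[1L]
    # else: inconsistent -> '.'
  }
  # keep only reciprocal consensus pairs
  for (j in which(cons_pair > 0L)) {
    if (cons_pair[cons_pair[j]] != j) cons_pair[j] <- 0L
  }
  idx <- which(cons_pair > 0L)
  cons[idx[idx < cons_pair[idx]]] <- "("
  cons[idx[idx > cons_pair[idx]]] <- ")"

  force_x <- logical(L)
  if (!is.null(hyper) && nrow(hyper))
    for (k in seq_len(nrow(hyper)))
      force_x[hyper$start[k]:hyper$end[k]] <- TRUE
  if (!is.null(knots) && NROW(knots))
    force_x[c(as.matrix(knots))] <- TRUE
  # insertions inside hypervariable regions are forced unpaired too
  all_gap <- colSums(!gap) == 0L
  for (j in which(force_x)) {
    if (cons[j] %in% c("(", ")")) {
      partner <- cons_pair[j]
      if (partner > 0L && !force_x[partner]) cons[partner] <- "."
    }
    cons[j] <- "x"
  }
  cons[all_gap & !force_x] <- "."
  # sanity: remaining parentheses must still be balanced
  parse_dotbracket(gsub("x", ".", paste0(cons, collapse = ""), fixed = TRUE))
  paste0(cons, collapse = "")
}

#' Project a backbone constraint onto a target sequence
#'
#' Drops backbone columns where the target row is gapped; a constrained
#' pair whose partner is deleted in the target degrades to \code{.}.
#'
#' @param constraint Backbone constraint string.
#' @param target_row Gapped target row on the same backbone.
#' @return Constraint string over the ungapped target sequence.
#' @export
project_constraint <- function(constraint, target_row) {
  cvec <- strsplit(constraint, "", fixed = TRUE)[[1L]]
  if (nchar(target_row) != length(cvec))
    stop("constraint and target row lengths differ")
  cols <- seqpos_to_column(target_row)
  pk <- parse_dotbracket(gsub("x", ".", constraint, fixed = TRUE))
  keep <- logical(length(cvec)); keep[cols] <- TRUE
  for (j in which(pk$pair > 0L)) {
    if (keep[j] && !keep[pk$pair[j]]) cvec[j] <- "."
  }
  paste0(cvec[cols], collapse = "")
}

#' Fold one hypervariable region with a bracketing stem
#'
#' Folds a hypervariable region in isolation, seeded with a basal stem of
#' \code{bracket_len} forced pairs ("bracketing") so the fold has
#' structural context: \code{adjacent} takes the bracket from the real
#' flanking sequence, \code{internal} from the region's own ends, and
#' \code{artificial} appends a strong-pairing frame (removed afterwards).
#' Pairings involving positions outside the region are stripped from the
#' returned map.
#'
#' @param seq Full (ungapped) target sequence string.
#' @param region Named vector \code{c(start, length)} in sequence
#'   coordinates.
#' @param bracket_mode One of \code{"adjacent"}, \code{"internal"},
#'   \code{"artificial"}.
#' @param engine Folding engine honouring the [reference_fold()] contract.
#' @param bracket_len Stem length of the bracket (default 2).
#' @param artificial_bracket Sequence used for the 5' artificial bracket;
#'   its reverse complement closes the 3' side (default \code{"GGGG"}).
#' @return List with \code{pair}: integer partner vector over the region
#'   (local coordinates, 0 = unpaired), \code{start}: region start, and
#'   \code{score}.
#' @export
fold_hypervariable_region <- function(seq, region,
                                      bracket_mode = c("adjacent", "internal",
                                                       "artificial"),
                                      engine = reference_fold,
                                      bracket_len = 2L,
                                      artificial_bracket = "GGGG") {
  bracket_mode <- match.arg(bracket_mode)
  seq <- gsub("U", "T", toupper(seq), fixed = TRUE)
  s0 <- as.integer(region[["start"]]); rl <- as.integer(region[["length"]])
  e0 <- s0 + rl - 1L
  if (s0 < 1L || e0 > nchar(seq)) stop("region outside the sequence")
  b <- as.integer(bracket_len)
  if (rl < 2L * b + 1L) stop("region shorter than the bracketing stem")

  if (bracket_mode == "adjacent") {
    if (s0 - b < 1L || e0 + b > nchar(seq))
      stop("no adjacent sequence available for the bracket")
    sub <- substr(seq, s0 - b, e0 + b)
    offset <- b                                  # local pos of region start - 1
  } else if (bracket_mode == "internal") {
    sub <- substr(seq, s0, e0)
    offset <- 0L
  } else {
    left <- gsub("U", "T", toupper(artificial_bracket), fixed = TRUE)
    right <- rev_comp(left)
    sub <- paste0(left, substr(seq, s0, e0), right)
    b <- nchar(left)
    offset <- b
  }
  n <- nchar(sub)
  cvec <- rep(".", n)
  if (bracket_mode == "internal") {
    # bracket from the start of the region: force the first b positions to
    # pair with the last b
    cvec[seq_len(b)] <- "("
    cvec[(n - b + 1L):n] <- ")"
  } else {
    cvec[seq_len(b)] <- "("
    cvec[(n - b + 1L):n] <- ")"
  }
  res <- engine(sub, paste0(cvec, collapse = ""), enforce = TRUE)
  pair_loc <- res$map$pair
  # translate to region-local coordinates, dropping bracket/outside pairs
  region_pair <- integer(rl)
  for (i in seq_len(n)) {
    j <- pair_loc[i]
    if (j == 0L || j < i) next
    ri <- i - offset; rj <- j - offset
    if (bracket_mode == "internal") { ri <- i; rj <- j }
    if (ri >= 1L && ri <= rl && rj >= 1L && rj <= rl) {
      region_pair[ri] <- rj; region_pair[rj] <- ri
    }
  }
  list(pair = region_pair, start = s0, score = res$score)
}

rev_comp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  paste(rev(comp[strsplit(x, "", fixed = TRUE)[[1L]]]), collapse = "")
}

#' Splice a region fold into a core backbone structure
#'
#' Adds the pairings of a region sub-structure (from
#' [fold_hypervariable_region()]) into a core map in which the region was
#' forced unpaired.  A position paired in both maps is an error; the
#' primary layer must remain an involution and non-crossing.
#'
#' @param core A [structure_map()] of the full sequence.
#' @param sub List with \code{pair} (local partner vector) and \code{start}.
#' @param region Named vector \code{c(start, length)}; must match
#'   \code{sub$start}.
#' @return A [structure_map()].
#' @export
splice <- function(core, sub, region) {
  s0 <- as.integer(region[["start"]]); rl <- as.integer(region[["length"]])
  if (length(sub$pair) != rl) stop("sub-structure length != region length")
  if (!is.null(sub$start) && sub$start != s0)
    stop("sub-structure start does not match the region")
  pair <- core$pair
  for (i in seq_len(rl)) {
    j <- sub$pair[i]
    if (j == 0L || j < i) next
    gi <- s0 + i - 1L; gj <- s0 + j - 1L
    if (pair[gi] != 0L || pair[gj] != 0L)
      stop("splice collision: position ", if (pair[gi] != 0L) gi else gj,
           " already paired in the core")
    pair[gi] <- gj; pair[gj] <- gi
  }
  structure_map(core$seq, pair, core$knot)
}

#' Transfer pseudoknot pairings by homologous position
#'
#' Carries each pseudoknot-layer pairing of a reference map to the target
#' via a two-row (reference, target) alignment.  A pairing whose partner
#' lands on a gap in the target is reported as unmapped, never silently
#' dropped.
#'
#' @param refMap A [structure_map()] of the ungapped reference sequence
#'   (knot layer populated).
#' @param ref_row,target_row Gapped rows of a pairwise alignment of the
#'   reference and target sequences.
#' @param target A [structure_map()] of the ungapped target sequence.
#' @return List with \code{map} (target map with transferred knot layer)
#'   and \code{unmapped} (data frame of reference pairings that could not
#'   be placed: \code{ref_i}, \code{ref_j}, \code{reason}).
#' @export
transfer_pseudoknots <- function(refMap, ref_row, target_row, target) {
  if (nchar(ref_row) != nchar(target_row))
    stop("reference and target rows are not aligned")
  ref_cols <- seqpos_to_column(ref_row)
  if (length(ref_cols) != nchar(refMap$seq))
    stop("reference row does not match the reference map")
  tcols <- seqpos_to_column(target_row)
  col_to_target <- integer(nchar(target_row))
  col_to_target[tcols] <- seq_along(tcols)

  knot <- target$knot
  unmapped <- list()
  idx <- which(refMap$knot > 0L)
  for (i in idx[refMap$knot[idx] > idx]) {
    j <- refMap$knot[i]
    ti <- col_to_target[ref_cols[i]]
    tj <- col_to_target[ref_cols[j]]
    if (ti == 0L || tj == 0L) {
      unmapped[[length(unmapped) + 1L]] <- data.frame(
        ref_i = i, ref_j = j, reason = "partner deleted in target",
        stringsAsFactors = FALSE)
      next
    }
    if (knot[ti] != 0L || knot[tj] != 0L) {
      unmapped[[length(unmapped) + 1L]] <- data.frame(
        ref_i = i, ref_j = j, reason = "target position already in knot layer",
        stringsAsFactors = FALSE)
      next
    }
    knot[ti] <- tj; knot[tj] <- ti
  }
  list(map = structure_map(target$seq, target$pair, knot),
       unmapped = if (length(unmapped)) do.call(rbind, unmapped)
       else data.frame(ref_i = integer(0), ref_j = integer(0),
                       reason = character(0)))
}
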