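# Independent brute-force oracles.  These deliberately re-derive every rule
# from first principles with their own code paths (character vectors and
# plain set operations), so agreement with the package implementations is a
# meaningful check.

oracle_iupac <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T"))

# --- naive TIGER oracle ----------------------------------------------------

oracle_terminal_spans <- function(row) {
  s <- paste0(ifelse(row == "-", "g", "b"), collapse = "")
  lead <- attr(regexpr("^g*", s), "match.length")
  trail <- attr(regexpr("g*$", s), "match.length")
  c(lead, trail)
}

oracle_partition <- function(aln, j) {
  taxa <- rownames(aln)
  scored <- character(0)
  sets <- list(A = character(0), C = character(0), G = character(0),
               T = character(0))
  L <- ncol(aln)
  for (t in taxa) {
    ch <- aln[t, j]
    sp <- oracle_terminal_spans(aln[t, ])
    if (ch == "-" || ch == "N") next
    if (j <= sp[1] || j > L - sp[2]) next   # inside a terminal gap span
    scored <- c(scored, t)
    for (s in oracle_iupac[[ch]]) sets[[s]] <- c(sets[[s]], t)
  }
  list(taxa = scored, sets = Filter(length, sets))
}

oracle_pa <- function(Pi, Pj) {
  num <- 0; den <- 0
  for (A in Pj$sets) {
    r <- A[A %in% Pi$taxa]
    if (length(r) == 0) next
    den <- den + 1
    if (any(vapply(Pi$sets, function(S) all(r %in% S), logical(1))))
      num <- num + 1
  }
  if (den == 0) NA_real_ else num / den
}

oracle_tiger <- function(aln, threshold = 0.15) {
  L <- ncol(aln)
  cov <- apply(aln, 2, function(col) mean(col != "-" & col != "N"))
  passing <- which(cov >= threshold)
  parts <- lapply(passing, function(j) oracle_partition(aln, j))
  r <- rep(NA_real_, L)
  for (a in seq_along(passing)) {
    vals <- c()
    for (b in seq_along(passing)) {
      if (a == b) next
      vals <- c(vals, oracle_pa(parts[[a]], parts[[b]]))
    }
    vals <- vals[!is.na(vals)]
    r[passing[a]] <- if (length(vals)) mean(vals) else NA_real_
  }
  r
}

# random test alignment with gaps, terminal gaps, N and ambiguity codes
random_alignment <- function(n_taxa, n_cols, p_gap = 0.08, p_n = 0.03,
                             p_ambig = 0.03) {
  states <- c("A", "C", "G", "T")
  m <- matrix(sample(states, n_taxa * n_cols, replace = TRUE), n_taxa, n_cols)
  mut <- matrix(runif(n_taxa * n_cols), n_taxa, n_cols)
  m[mut < p_gap] <- "-"
  m[mut >= p_gap & mut < p_gap + p_n] <- "N"
  amb <- c("R", "Y", "S", "W", "K", "M")
  sel <- mut >= p_gap + p_n & mut < p_gap + p_n + p_ambig
  m[sel] <- sample(amb, sum(sel), replace = TRUE)
  # some incomplete sequences (terminal gaps)
  for (i in seq_len(n_taxa)) {
    if (runif(1) < 0.3) m[i, seq_len(sample.int(max(1, n_cols %/% 5), 1))] <- "-"
    if (runif(1) < 0.3) m[i, (n_cols - sample.int(max(1, n_cols %/% 5), 1) + 1):n_cols] <- "-"
  }
  rownames(m) <- paste0("t", seq_len(n_taxa))
  m
}

# --- exhaustive folding oracle ---------------------------------------------

# enumerate every legal non-crossing structure (canonical pairs, minimum
# hairpin loop, 'x' never paired) as an explicit list of pair sets, and
# return the maximum pair count over all of them
oracle_enumerate_structures <- function(seq, constraint = NULL, min_loop = 3) {
  s <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  n <- length(s)
  cvec <- if (is.null(constraint)) rep(".", n) else strsplit(constraint, "")[[1]]
  canon <- c("AT", "TA", "GC", "CG", "GT", "TG")
  pairable <- function(i, k) {
    cvec[i] != "x" && cvec[k] != "x" && k - i > min_loop &&
      paste0(s[i], s[k]) %in% canon
  }
  # every structure is reached exactly once, partitioned by the fate of i
  enum <- function(i, j) {
    if (i >= j) return(list(list()))
    out <- enum(i + 1, j)                    # i unpaired
    for (k in (i + 1):j) {
      if (!pairable(i, k)) next
      inner <- enum(i + 1, k - 1)
      outer <- enum(k + 1, j)
      for (s1 in inner) for (s2 in outer)
        out[[length(out) + 1]] <- c(list(c(i, k)), s1, s2)
    }
    out
  }
  if (n < 2) return(list(list()))
  enum(1, n)
}

oracle_max_pairs <- function(seq, constraint = NULL, min_loop = 3) {
  max(vapply(oracle_enumerate_structures(seq, constraint, min_loop),
             length, integer(1)))
}

# validity check for a returned structure
oracle_structure_valid <- function(map, constraint = NULL, min_loop = 3) {
  p <- map$pair
  n <- length(p)
  s <- strsplit(map$seq, "")[[1]]
  canon <- c("AT", "TA", "GC", "CG", "GT", "TG")
  cvec <- if (is.null(constraint)) rep(".", n) else strsplit(constraint, "")[[1]]
  for (i in which(p > 0)) {
    if (p[p[i]] != i) return(FALSE)
    if (cvec[i] == "x") return(FALSE)
    if (p[i] > i) {
      if (p[i] - i <= min_loop) return(FALSE)
      if (!(paste0(s[i], s[p[i]]) %in% canon)) return(FALSE)
    }
  }
  op <- which(p > 0 & p > seq_len(n))
  for (a in op) for (b in op)
    if (a < b && b < p[a] && p[a] < p[b]) return(FALSE)
  TRUE
}

# --- statistic oracles -----------------------------------------------------

# U by direct counting of pairwise wins (+ half-ties)
oracle_u_statistic <- function(a, b) {
  wins <- 0
  for (x in a) for (y in b) wins <- wins + (x > y) + 0.5 * (x == y)
  wins
}

# exact two-sided p for the signed-rank test by enumerating sign patterns
oracle_wilcoxon_exact_p <- function(x, y) {
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  E <- n * (n + 1) / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  null_w <- signs %*% r
  mean(abs(null_w - E) >= abs(obs - E) - 1e-12)
}

# exact two-sided p for the rank-sum test by enumerating group assignments
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  E <- n1 * length(b) / 2
  combos <- utils::combn(length(pooled), n1)
  null_u <- apply(combos, 2, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  mean(abs(null_u - E) >= abs(obs - E) - 1e-12)
}
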