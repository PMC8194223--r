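# Pairwise distances under pairwise deletion.  Ambiguity codes are treated
# as missing for distance purposes (only A/C/G/T cells are compared), the
# conservative reading when overlap is defined by shared sequence data.

# encode an alignment as integers: 1..4 = A,C,G,T; 0 = gap/N/ambiguity
encode_acgt <- function(aln) {
  code <- matrix(match(aln, c("A", "C", "G", "T"), nomatch = 0L),
                 nrow(aln), ncol(aln), dimnames = dimnames(aln))
  code
}

#' Uncorrected p-distance between two aligned rows
#'
#' Proportion of differing sites among columns where both rows carry an
#' unambiguous nucleotide (pairwise deletion).  \code{NA} when the rows share
#' no such column.
#'
#' @param rowA,rowB Character vectors of equal length (alignment rows).
#' @return Numeric distance in \[0, 1\], or \code{NA}.
#' @export
p_distance <- function(rowA, rowB) {
  a <- match(rowA, c("A", "C", "G", "T"), nomatch = 0L)
  b <- match(rowB, c("A", "C", "G", "T"), nomatch = 0L)
  ok <- a > 0L & b > 0L
  n <- sum(ok)
  if (n == 0L) return(NA_real_)
  sum(a[ok] != b[ok]) / n
}

#' Pairwise distance matrix (uncorrected p or GTR)
#'
#' @param aln Alignment matrix.
#' @param model \code{"p"} for uncorrected proportion of differences, or
#'   \code{"GTR"} for maximum-likelihood distances under a general
#'   time-reversible model.
#' @param params GTR parameters from [estimate_gtr_params()]; estimated from
#'   the alignment when \code{NULL} and \code{model = "GTR"}.
#' @return Symmetric numeric matrix with zero diagonal; \code{NA} marks
#'   undefined distances (no overlapping unambiguous sites).
#' @export
distance_matrix <- function(aln, model = c("p", "GTR"), params = NULL) {
  model <- match.arg(model)
  code <- encode_acgt(aln)
  n <- nrow(code)
  D <- matrix(0, n, n, dimnames = list(rownames(aln), rownames(aln)))
  if (model == "GTR") {
    if (is.null(params)) params <- estimate_gtr_params(aln)
    eig <- gtr_eigen(params)
  }
  for (i in seq_len(n - 1L)) {
    ai <- code[i, ]
    for (j in (i + 1L):n) {
      bj <- code[j, ]
      ok <- ai > 0L & bj > 0L
      m <- sum(ok)
      if (m == 0L) { D[i, j] <- D[j, i] <- NA_real_; next }
      if (model == "p") {
        d <- sum(ai[ok] != bj[ok]) / m
      } else {
        counts <- tabulate((ai[ok] - 1L) * 4L + bj[ok], nbins = 16L)
        d <- gtr_pair_distance(matrix(counts, 4L, 4L, byrow = TRUE), eig, params$freqs)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  D
}

# --- GTR machinery ---------------------------------------------------------

# rate order follows the usual lexicographic convention; the G<->T rate is
# the reference and fixed at 1
GTR_RATE_NAMES <- c("AC", "AG", "AT", "CG", "CT", "GT")

#' Assemble a GTR parameter object
#'
#' @param rates Six relative exchangeabilities in the order AC, AG, AT, CG,
#'   CT, GT; GT is conventionally 1.
#' @param freqs Four stationary base frequencies (A, C, G, T); must be
#'   positive and sum to 1 (renormalized).
#' @return List of class \code{gtr_params}.
#' @export
gtr_params <- function(rates, freqs) {
  stopifnot(length(rates) == 6L, length(freqs) == 4L,
            all(rates > 0), all(freqs > 0))
  freqs <- freqs / sum(freqs)
  structure(list(rates = setNames(as.numeric(rates), GTR_RATE_NAMES),
                 freqs = setNames(as.numeric(freqs), c("A", "C", "G", "T"))),
            class = "gtr_params")
}

# rate matrix Q scaled to one expected substitution per unit time
gtr_Q <- function(params) {
  r <- params$rates; f <- params$freqs
  Q <- matrix(0, 4L, 4L, dimnames = list(names(f), names(f)))
  Q["A", "C"] <- r["AC"]; Q["A", "G"] <- r["AG"]; Q["A", "T"] <- r["AT"]
  Q["C", "G"] <- r["CG"]; Q["C", "T"] <- r["CT"]; Q["G", "T"] <- r["GT"]
  Q <- Q + t(Q)
  Q <- sweep(Q, 2L, f, `*`)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(f * diag(Q))
  Q / scale
}

# symmetric eigendecomposition of the reversible rate matrix
gtr_eigen <- function(params) {
  Q <- gtr_Q(params)
  f <- params$freqs
  s <- sqrt(f)
  B <- diag(s) %*% Q %*% diag(1 / s)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / s) %*% e$vectors,   # Q = right diag(values) left
       left = t(e$vectors) %*% diag(s))
}

# transition probability matrix P(t)
gtr_P <- function(eig, t) {
  P <- eig$right %*% (exp(eig$values * t) * eig$left)
  # numerical guard: clamp tiny negatives from roundoff
  P[P < 0] <- 0
  P
}

# ML branch length for one pair from its 4x4 site-pattern count matrix
gtr_pair_distance <- function(counts, eig, freqs, t_max = 10) {
  if (sum(counts) == 0) return(NA_real_)
  if (sum(counts) == sum(diag(counts))) return(0)
  nll <- function(t) {
    P <- gtr_P(eig, t)
    lik <- freqs * P
    lik[lik < 1e-300] <- 1e-300
    -sum(counts * log(lik))
  }
  opt <- optimize(nll, c(1e-8, t_max))
  if (opt$minimum > t_max * 0.99) {
    # saturated pair: likelihood still decreasing at the boundary
    return(structure(opt$minimum, saturated = TRUE))
  }
  opt$minimum
}

#' Maximum-likelihood GTR distance between two aligned rows
#'
#' Finds the branch length t maximizing the pairwise likelihood
#' \eqn{\prod \pi_a P_{ab}(t)} under the GTR rate matrix (matrix exponential
#' via eigendecomposition; 1-D numerical optimization).  \code{NA} when the
#' rows share no unambiguous overlap.
#'
#' @param rowA,rowB Character vectors (alignment rows).
#' @param params A [gtr_params()] object.
#' @return Distance in expected substitutions/site, or \code{NA}.
#' @export
gtr_distance <- function(rowA, rowB, params) {
  a <- match(rowA, c("A", "C", "G", "T"), nomatch = 0L)
  b <- match(rowB, c("A", "C", "G", "T"), nomatch = 0L)
  ok <- a > 0L & b > 0L
  if (!any(ok)) return(NA_real_)
  counts <- tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L)
  gtr_pair_distance(matrix(counts, 4L, 4L, byrow = TRUE), gtr_eigen(params),
                    params$freqs)
}

#' Estimate GTR parameters from an alignment
#'
#' Base frequencies come from empirical counts over unambiguous cells.
#' Exchangeabilities maximize the summed pairwise log-likelihood over a
#' deterministic sample of taxon pairs, alternating between a 5-parameter
#' optimization of the log-rates (GT fixed at 1) and per-pair branch-length
#' updates.
#'
#' @param aln Alignment matrix with at least 2 taxa.
#' @param max_pairs Maximum number of taxon pairs entering the likelihood.
#' @param n_iter Alternating optimization sweeps.
#' @return A [gtr_params()] object.
#' @export
estimate_gtr_params <- function(aln, max_pairs = 200L, n_iter = 3L) {
  if (nrow(aln) < 2L) stop("need at least 2 taxa to estimate GTR parameters")
  code <- encode_acgt(aln)
  base_counts <- tabulate(code[code > 0L], nbins = 4L)
  if (any(base_counts == 0L))
    stop("degenerate base composition: base ",
         c("A", "C", "G", "T")[which(base_counts == 0L)[1L]],
         " absent; supply params explicitly via gtr_params()")
  freqs <- base_counts / sum(base_counts)

  pairs <- utils::combn(nrow(aln), 2L)
  if (ncol(pairs) > max_pairs) {
    sel <- unique(round(seq(1L, ncol(pairs), length.out = max_pairs)))
    pairs <- pairs[, sel, drop = FALSE]
  }
  counts_list <- list(); keep <- logical(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    a <- code[pairs[1L, k], ]; b <- code[pairs[2L, k], ]
    ok <- a > 0L & b > 0L
    if (!any(ok)) next
    cm <- matrix(tabulate((a[ok] - 1L) * 4L + b[ok], nbins = 16L), 4L, 4L,
                 byrow = TRUE)
    if (sum(cm) > sum(diag(cm))) { counts_list[[k]] <- cm; keep[k] <- TRUE }
  }
  counts_list <- counts_list[keep]
  if (length(counts_list) == 0L)
    return(gtr_params(rep(1, 6L), freqs))   # no variation: rates unidentifiable

  log_rates <- rep(0, 5L)                   # AC, AG, AT, CG, CT; GT = 1
  t_hat <- vapply(counts_list, function(cm) {
    p <- 1 - sum(diag(cm)) / sum(cm)
    max(1e-4, -0.75 * log(max(1e-6, 1 - 4 * p / 3)))
  }, numeric(1))

  sum_nll <- function(lr, ts) {
    par <- gtr_params(c(exp(lr), 1), freqs)
    eig <- gtr_eigen(par)
    tot <- 0
    for (k in seq_along(counts_list)) {
      P <- gtr_P(eig, ts[k])
      lik <- freqs * P
      lik[lik < 1e-300] <- 1e-300
      tot <- tot - sum(counts_list[[k]] * log(lik))
    }
    tot
  }
  for (it in seq_len(n_iter)) {
    opt <- optim(log_rates, sum_nll, ts = t_hat, method = "Nelder-Mead",
                 control = list(maxit = 300L))
    log_rates <- opt$par
    par <- gtr_params(c(exp(log_rates), 1), freqs)
    eig <- gtr_eigen(par)
    t_hat <- vapply(counts_list, gtr_pair_distance, numeric(1),
                    eig = eig, freqs = freqs)
    t_hat[!is.finite(t_hat)] <- 1e-4
  }
  gtr_params(c(exp(log_rates), 1), freqs)
}

#' Group-wise distance summaries
#'
#' Mean, standard error and count of defined pairwise distances within and
#' between clades, mirroring the usual "within on the diagonal, between
#' below it" distance summary table.
#'
#' @param D Distance matrix from [distance_matrix()].
#' @param groups Named character vector mapping taxon ids to clade labels.
#' @return Data frame with columns \code{group1}, \code{group2}, \code{mean},
#'   \code{se}, \code{n}, \code{n_undefined}.  Within-group rows have
#'   \code{group1 == group2}; groups with fewer than 2 members report
#'   \code{n = 0} and \code{NA} statistics.
#' @export
group_summary <- function(D, groups) {
  taxa <- rownames(D)
  stopifnot(all(taxa %in% names(groups)))
  g <- groups[taxa]
  labs <- unique(g)
  res <- list()
  for (a in seq_along(labs)) for (b in seq_len(a)) {
    ia <- which(g == labs[a]); ib <- which(g == labs[b])
    if (a == b) {
      if (length(ia) < 2L) { vals <- numeric(0); und <- 0L }
      else {
        idx <- utils::combn(ia, 2L)
        vals <- D[cbind(idx[1L, ], idx[2L, ])]
        und <- sum(is.na(vals)); vals <- vals[!is.na(vals)]
      }
    } else {
      vals <- as.vector(D[ia, ib, drop = FALSE])
      und <- sum(is.na(vals)); vals <- vals[!is.na(vals)]
    }
    n <- length(vals)
    res[[length(res) + 1L]] <- data.frame(
      group1 = labs[a], group2 = labs[b],
      mean = if (n) mean(vals) else NA_real_,
      se = if (n > 1L) sd(vals) / sqrt(n) else if (n == 1L) NA_real_ else NA_real_,
      n = n, n_undefined = und, stringsAsFactors = FALSE)
  }
  do.call(rbind, res)
}
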