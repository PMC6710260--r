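#' 2x2 contingency table for a variant pair
#'
#' Counts the subpools in which both variants, exactly one, or neither were
#' detected. These four counts summarise everything the co-occurrence test
#' uses about a pair.
#'
#' @param matrix An \code{occurrence_matrix}.
#' @param a,b Variant ids present in the matrix, \code{a != b}.
#' @return A named list \code{n11}, \code{n10}, \code{n01}, \code{n00},
#'   \code{N} with \code{n11+n10+n01+n00 == N}.
#' @export
contingency <- function(matrix, a, b) {
  stopifnot(inherits(matrix, "occurrence_matrix"), a != b)
  ids <- matrix$variants$variant_id
  ia <- match(a, ids); ib <- match(b, ids)
  if (is.na(ia) || is.na(ib))
    stop("unknown variant: ", if (is.na(ia)) a else b)
  pa <- as.logical(matrix$counts[ia, ] > 0)
  pb <- as.logical(matrix$counts[ib, ] > 0)
  n11 <- sum(pa & pb)
  n10 <- sum(pa & !pb)
  n01 <- sum(!pa & pb)
  N <- matrix$n_subpools
  list(n11 = n11, n10 = n10, n01 = n01, n00 = N - n11 - n10 - n01, N = N)
}

#' One-sided (right-tail) Fisher's exact test p-value
#'
#' For a 2x2 table with margins fixed, the number of subpools containing both
#' variants is hypergeometric under the null of independent dispersal across
#' subpools; physical linkage inflates it. The p-value is the upper tail
#' P(X >= n11), summed exactly in log space via log-gamma binomial
#' coefficients so that libraries with thousands of subpools stay accurate.
#'
#' Vectorised over tables.
#'
#' @param n11,n10,n01,n00 Cell counts (both / A only / B only / neither).
#' @return Right-tail p-value(s) in \code{[0, 1]}.
#' @export
fisher_right_tail <- function(n11, n10, n01, n00) {
  stopifnot(length(n10) == length(n11), length(n01) == length(n11),
            length(n00) == length(n11),
            all(n11 >= 0), all(n10 >= 0), all(n01 >= 0), all(n00 >= 0))
  vapply(seq_along(n11), function(i) {
    .fisher_right_tail1(n11[i], n10[i], n01[i], n00[i])
  }, numeric(1))
}

.fisher_right_tail1 <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  K <- n11 + n10          # subpools containing A
  n <- n11 + n01          # subpools containing B
  if (n11 == 0L) return(1)
  k <- n11:min(K, n)
  lp <- lchoose(K, k) + lchoose(N - K, n - k) - lchoose(N, n)
  m <- max(lp)
  min(1, exp(m) * sum(exp(lp - m)))
}

#' Candidate variant pairs by shared-subpool count
#'
#' Restricts testing to pairs detected together in at least
#' \code{min_shared} distinct subpools; pairs below this carry too little
#' information. Implemented by sparse co-occurrence counting
#' (\code{P \%*\% t(P)} on the sparse presence matrix), so the full set of
#' variant pairs is never materialised.
#'
#' @param matrix An \code{occurrence_matrix}.
#' @param min_shared Minimum number of co-occupied subpools (default 3).
#' @return A data.frame with columns \code{a}, \code{b} (variant ids,
#'   \code{a < b} lexicographically by matrix order) and \code{n11}.
#' @export
candidate_pairs <- function(matrix, min_shared = 3L) {
  stopifnot(inherits(matrix, "occurrence_matrix"))
  P <- (matrix$counts > 0) * 1
  co <- Matrix::tcrossprod(P)
  co <- methods::as(Matrix::triu(co, k = 1L), "TsparseMatrix")
  keep <- co@x >= min_shared
  ids <- matrix$variants$variant_id
  data.frame(a = ids[co@i[keep] + 1L], b = ids[co@j[keep] + 1L],
             n11 = as.integer(co@x[keep]), stringsAsFactors = FALSE)
}

## Number of rejections of the two-stage step-up at FDR level q, given
## sorted p-values. The rejected set is always the r smallest p-values.
.tsbky_nreject <- function(p_sorted, q) {
  m <- length(p_sorted)
  q1 <- q / (1 + q)
  bh <- function(level) {
    below <- p_sorted <= level * seq_len(m) / m
    if (any(below)) max(which(below)) else 0L
  }
  r1 <- bh(q1)
  if (r1 == 0L) return(0L)
  if (r1 == m) return(m)
  bh(q1 * m / (m - r1))
}

#' Two-stage Benjamini-Krieger-Yekutieli FDR adjustment
#'
#' Adaptive linear step-up: stage 1 is Benjamini-Hochberg at
#' \code{q' = q/(1+q)}; its rejection count estimates the number of true
#' nulls, and stage 2 reruns BH at \code{q' * m/(m - r1)}. If stage 1
#' rejects none (all) of the hypotheses, none (all) are rejected outright.
#' The adjusted value reported for each hypothesis is the smallest level q
#' at which the procedure would reject it (step-up q-value convention).
#'
#' The inversion is exact and vectorised. Writing \code{b_i} for the
#' ordinary BH q-values (nondecreasing in rank) and
#' \code{t_r = b_r / (1 - b_r)} for the level at which stage 1 first
#' rejects \code{r} hypotheses, rank \code{i} is rejected at level q with
#' stage-1 count r iff \code{q >= t_r} and
#' \code{b_i <= (q/(1+q)) * m/(m-r)}; minimising over r gives
#' \code{min_r max(t_r, g_i(r))} with \code{g_i(r)} the level solving the
#' second condition with equality. Since \code{t_r} is nondecreasing and
#' \code{g_i(r)} nonincreasing in r, the minimum sits at their crossing,
#' located for all ranks at once by a monotone search. Values are capped
#' at 1 when no level up to 1 rejects.
#'
#' @param p Numeric vector of p-values in \code{[0, 1]}.
#' @param q FDR level used for the \code{rejected} flags (default 0.05).
#' @return A list with \code{p_adj} (adjusted values, same order as input)
#'   and \code{rejected} (logical flags at level \code{q}).
#' @export
adjust_fdr_tsbky <- function(p, q = 0.05) {
  if (any(p < 0 | p > 1 | is.na(p)))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L)
    return(list(p_adj = numeric(0), rejected = logical(0)))
  ord <- order(p)
  ps <- p[ord]
  r_at_q <- .tsbky_nreject(ps, q)
  rejected_sorted <- seq_len(m) <= r_at_q
  # BH q-values: b_i = min_{j >= i} p_(j) * m / j, nondecreasing in i
  b <- pmin(1, rev(cummin(rev(ps * m / seq_len(m)))))
  # level at which stage 1 first rejects r hypotheses: q/(1+q) = b_r
  t_of <- function(x) ifelse(x >= 1, Inf, x / (1 - x))
  adj_sorted <- rep(Inf, m)
  if (m >= 2L) {
    r_seq <- seq_len(m - 1L)
    # predicate "t_r >= g_i(r)" reduces to s_r >= b_i with
    # s_r = b_r * m/(m-r), nondecreasing in r
    s <- b[r_seq] * m / (m - r_seq)
    # smallest r with s_r >= b_i
    rstar <- findInterval(b, s, left.open = TRUE) + 1L
    g_of <- function(i, r) {
      u <- b[i] * (m - r) / m
      t_of(u)
    }
    idx <- seq_len(m)
    # branch r = rstar - 1 (largest r below the crossing): f = g_i(r)
    left_ok <- rstar > 1L
    left_r <- pmin(pmax(rstar - 1L, 1L), m - 1L)
    left_val <- ifelse(left_ok, g_of(idx, left_r), Inf)
    # branch r = rstar (at/above the crossing): f = t_r
    right_ok <- rstar <= m - 1L
    right_r <- pmin(rstar, m - 1L)
    right_val <- ifelse(right_ok, t_of(b[right_r]), Inf)
    adj_sorted <- pmin(left_val, right_val)
  }
  # reject-all branch: at q >= t_m stage 1 rejects everything
  adj_sorted <- pmin(adj_sorted, t_of(b[m]))
  adj_sorted <- pmin(1, cummax(adj_sorted))
  p_adj <- numeric(m); p_adj[ord] <- adj_sorted
  rejected <- logical(m); rejected[ord] <- rejected_sorted
  list(p_adj = p_adj, rejected = rejected)
}

#' Detect significantly co-occurring variant pairs
#'
#' Runs the full linkage test: candidate pairs sharing at least
#' \code{min_shared} subpools are scored with the one-sided Fisher's exact
#' test, p-values are adjusted by the two-stage Benjamini-Krieger-Yekutieli
#' procedure over the family of tested pairs, and pairs with adjusted
#' p-value below \code{alpha} are flagged as physically linked.
#'
#' @param matrix An \code{occurrence_matrix}.
#' @param alpha Significance threshold on adjusted p-values
#'   (default \code{1e-6}).
#' @param min_shared Minimum co-occupied subpools per tested pair
#'   (default 3).
#' @param q FDR level passed to the adjustment (defaults to \code{alpha}).
#' @return An object of class \code{"link_set"}: a data.frame of tests with
#'   columns \code{variant_a}, \code{variant_b}, \code{n11}, \code{n10},
#'   \code{n01}, \code{n00}, \code{p_raw}, \code{p_adj},
#'   \code{significant}, and attributes \code{alpha}, \code{min_shared},
#'   \code{n_subpools}.
#' @export
detect_links <- function(matrix, alpha = 1e-6, min_shared = 3L, q = alpha) {
  stopifnot(inherits(matrix, "occurrence_matrix"))
  cand <- candidate_pairs(matrix, min_shared = min_shared)
  N <- matrix$n_subpools
  if (nrow(cand) == 0L) {
    out <- data.frame(variant_a = character(), variant_b = character(),
                      n11 = integer(), n10 = integer(), n01 = integer(),
                      n00 = integer(), p_raw = numeric(),
                      p_adj = numeric(), significant = logical())
  } else {
    occ <- Matrix::rowSums(presence(matrix))
    names(occ) <- matrix$variants$variant_id
    n10 <- as.integer(occ[cand$a] - cand$n11)
    n01 <- as.integer(occ[cand$b] - cand$n11)
    n00 <- N - cand$n11 - n10 - n01
    p_raw <- fisher_right_tail(cand$n11, n10, n01, n00)
    adj <- adjust_fdr_tsbky(p_raw, q = q)
    out <- data.frame(variant_a = cand$a, variant_b = cand$b,
                      n11 = cand$n11, n10 = n10, n01 = n01, n00 = n00,
                      p_raw = p_raw, p_adj = adj$p_adj,
                      significant = adj$p_adj < alpha,
                      stringsAsFactors = FALSE)
    out <- out[order(out$p_adj, out$p_raw, out$variant_a, out$variant_b), ]
    rownames(out) <- NULL
  }
  structure(out, class = c("link_set", "data.frame"),
            alpha = alpha, min_shared = min_shared, n_subpools = N)
}

#' @export
print.link_set <- function(x, ...) {
  cat(sprintf("link_set: %d tested pairs, %d significant (alpha %g, n11 >= %d, N = %d)\n",
              nrow(x), sum(x$significant), attr(x, "alpha"),
              attr(x, "min_shared"), attr(x, "n_subpools")))
  if (nrow(x) > 0L) print.data.frame(utils::head(as.data.frame(x), 10L))
  invisible(x)
}

#' Write a link set as TSV
#'
#' @param links A \code{link_set}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_links <- function(links, path) {
  utils::write.table(as.data.frame(links), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
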