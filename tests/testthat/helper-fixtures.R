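# Deterministic fixtures and independent oracles shared across tests.

# deterministic k-mer encoding of an integer (base-4 digits -> ACGT)
int_kmer <- function(i, k = 4L) {
  b <- c("A", "C", "G", "T")
  out <- character(k)
  for (j in k:1) {
    out[j] <- b[i %% 4L + 1L]
    i <- i %/% 4L
  }
  paste(out, collapse = "")
}

toy_scheme <- function(plate = "P1", primer_len = 4L, total_len = 24L) {
  subpool_scheme(
    plate_id = plate,
    column_barcodes = vapply(0:23, function(i)
      paste0("ACGA", int_kmer(i)), ""),
    row_barcodes = vapply(0:15, function(i)
      paste0("TGCA", int_kmer(i)), ""),
    primer_len = primer_len, total_len = total_len,
    domain_type = "AD")
}

rand_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), "")
}

# substitute the base at each position with the next base in cycle
mutate_at <- function(seq, pos) {
  nxt <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in pos) substr(seq, p, p) <- nxt[[substr(seq, p, p)]]
  seq
}

# first-codon reverse translation (no stops except '*')
rev_translate <- function(aa) {
  gc <- Biostrings::GENETIC_CODE
  paste(vapply(strsplit(aa, "")[[1]], function(r)
    names(gc)[match(r, gc)], ""), collapse = "")
}

make_network <- function(centroids, domain_type = "AD", id = "t1",
                         reads = NULL) {
  if (is.null(reads)) reads <- rep(10L, length(centroids))
  nodes <- data.frame(
    variant_id = sprintf("%s_v%02d", id, seq_along(centroids)),
    centroid = centroids, domain_type = domain_type,
    reads = as.integer(reads), stringsAsFactors = FALSE)
  nodes$subpools <- replicate(length(centroids), character(0),
                              simplify = FALSE)
  mf <- as.list(nodes$variant_id)
  names(mf) <- nodes$variant_id
  structure(list(network_id = paste0("net_", id), nodes = nodes,
                 edges = data.frame(a = character(), b = character(),
                                    p_adj = numeric()),
                 merged_from = mf),
            class = "domain_network")
}

# --- independent oracles -------------------------------------------------

# hypergeometric right tail by term enumeration (R's dhyper as the pmf)
oracle_fisher <- function(n11, n10, n01, n00) {
  N <- n11 + n10 + n01 + n00
  K <- n11 + n10
  n <- n11 + n01
  if (n11 == 0) return(1)
  sum(stats::dhyper(n11:min(K, n), K, N - K, n))
}

# brute-force two-stage BKY step-up rejection set at level q
oracle_tsbky <- function(p, q) {
  m <- length(p)
  o <- order(p)
  sp <- p[o]
  step_up <- function(level) {
    hits <- which(sp <= level * seq_len(m) / m)
    if (length(hits) == 0) 0L else max(hits)
  }
  q1 <- q / (1 + q)
  r1 <- step_up(q1)
  r <- if (r1 == 0L) 0L else if (r1 == m) m else
    step_up(q1 * m / (m - r1))
  rej <- logical(m)
  if (r > 0L) rej[o[seq_len(r)]] <- TRUE
  rej
}

# exhaustive best assignment over candidate tables (same conflict rule)
oracle_assignment <- function(candidates, overlap_frac = 0.25) {
  n <- length(candidates)
  conflict <- function(c1, c2) {
    if (c1$target != c2$target) return(FALSE)
    ov <- min(c1$end, c2$end) - max(c1$start, c2$start)
    ov > 0 && ov > overlap_frac * (c1$end - c1$start) &&
      ov > overlap_frac * (c2$end - c2$start)
  }
  best <- list(total = -1, assigned = numeric(n))
  opts <- lapply(candidates, function(d) 0:nrow(d))
  grid <- expand.grid(opts)
  for (g in seq_len(nrow(grid))) {
    sel <- as.integer(grid[g, ])
    claims <- list(); total <- 0; ok <- TRUE
    for (i in seq_len(n)) {
      if (sel[i] == 0L) next
      cl <- candidates[[i]][sel[i], , drop = FALSE]
      for (c2 in claims) if (conflict(cl, c2)) { ok <- FALSE; break }
      if (!ok) break
      claims <- c(claims, list(cl))
      total <- total + cl$identity
    }
    if (ok && total > best$total) {
      assigned <- numeric(n)
      for (i in seq_len(n)) if (sel[i] > 0L)
        assigned[i] <- candidates[[i]]$identity[sel[i]]
      best <- list(total = total, assigned = assigned)
    }
  }
  best$assigned
}

# union-find connected components over an edge list of labels
oracle_components <- function(edges) {
  labs <- sort(unique(c(edges$a, edges$b)))
  parent <- seq_along(labs)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (k in seq_len(nrow(edges))) {
    i <- find(match(edges$a[k], labs))
    j <- find(match(edges$b[k], labs))
    if (i != j) parent[max(i, j)] <- min(i, j)
  }
  comp <- vapply(seq_along(labs), find, integer(1))
  split(labs, comp)
}
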