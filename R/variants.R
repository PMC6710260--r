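#' Dereplicate trimmed reads within subpools
#'
#' Collapses identical sequences per subpool into unique records with read
#' counts, the unit on which centroid clustering operates.
#'
#' @param reads A data.frame with columns \code{subpool_id} and \code{seq}
#'   (all sequences the same length), one row per read.
#' @return A data.frame with columns \code{seq}, \code{subpool_id},
#'   \code{count}; counts sum to the input read count.
#' @export
dereplicate <- function(reads) {
  if (nrow(reads) == 0L)
    return(data.frame(seq = character(), subpool_id = character(),
                      count = integer(), stringsAsFactors = FALSE))
  stopifnot(all(c("subpool_id", "seq") %in% names(reads)))
  lens <- unique(nchar(reads$seq))
  if (length(lens) != 1L)
    stop("dereplicate expects equal-length reads")
  key <- paste(reads$seq, reads$subpool_id, sep = "\r")
  tt <- table(key)
  parts <- strsplit(names(tt), "\r", fixed = TRUE)
  agg <- data.frame(seq = vapply(parts, `[`, "", 1L),
                    subpool_id = vapply(parts, `[`, "", 2L),
                    count = as.integer(tt), stringsAsFactors = FALSE)
  agg <- agg[order(-agg$count, agg$seq, agg$subpool_id), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

# +1 match / -1 mismatch / -2 per gap position; identity is computed from the
# resulting optimal global alignment, counting gaps as columns.
.nuc_submat <- function() {
  Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                           baseOnly = FALSE, type = "DNA")
}

#' Global pairwise nucleotide identity
#'
#' End-to-end (Needleman-Wunsch) alignment under a fixed scoring scheme
#' (match +1, mismatch -1, gap -2 per position); identity is the fraction of
#' identical aligned columns over all alignment columns, gaps counted as
#' columns. This mirrors the "matching columns / alignment length" identity
#' definition used by centroid clustering tools.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity in \code{[0, 1]}.
#' @export
pairwise_identity <- function(a, b) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  .identities_to(as.character(b), as.character(a))
}

## Vectorised global identity of one query against many targets (exact DP).
.identities_to <- function(query, targets) {
  if (length(targets) == 0L) return(numeric(0))
  qlen <- nchar(query)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(targets),
    subject = Biostrings::DNAString(query),
    type = "global", substitutionMatrix = .nuc_submat(),
    gapOpening = 0, gapExtension = 2)
  # total alignment columns incl. terminal gaps: La + Lb - aligned pairs
  pairs <- Biostrings::nmatch(aln) + Biostrings::nmismatch(aln)
  cols <- nchar(targets) + qlen - pairs
  Biostrings::nmatch(aln) / cols
}

#' Greedy centroid clustering of unique sequences into domain variants
#'
#' Distinct sequences (pooled across subpools) are sorted by total abundance
#' (descending, ties broken lexicographically) and processed in order: each
#' sequence joins the first existing centroid it matches at
#' \code{>= id_threshold} global identity, otherwise it founds a new cluster
#' and becomes its centroid. Centroids are static (no re-centroiding), so the
#' procedure is deterministic and idempotent on its own centroids.
#'
#' @param uniques Output of [dereplicate()] pooled across all subpools of a
#'   domain (columns \code{seq}, \code{subpool_id}, \code{count}).
#' @param id_threshold Identity threshold for joining a cluster
#'   (default 0.95).
#' @param domain_type Domain label propagated to variants.
#' @return An object of class \code{"domain_clusters"}: a list with
#'   \code{centroids} (data.frame \code{cluster}, \code{centroid}),
#'   \code{members} (data.frame \code{cluster}, \code{seq},
#'   \code{subpool_id}, \code{count}), \code{domain_type} and
#'   \code{id_threshold}.
#' @export
greedy_cluster <- function(uniques, id_threshold = 0.95, domain_type = "AD") {
  if (nrow(uniques) == 0L) {
    return(structure(list(
      centroids = data.frame(cluster = integer(), centroid = character()),
      members = data.frame(cluster = integer(), seq = character(),
                           subpool_id = character(), count = integer()),
      domain_type = domain_type, id_threshold = id_threshold),
      class = "domain_clusters"))
  }
  totals <- tapply(uniques$count, uniques$seq, sum)
  seqs <- names(totals)
  ord <- order(-as.numeric(totals), seqs)
  seqs <- seqs[ord]
  centroids <- character(0)
  assignment <- integer(length(seqs))
  lens <- nchar(seqs)
  all_equal_len <- length(unique(lens)) == 1L
  # Equal-length fast path: gapless (Hamming) identity is a cheap screen.
  # A gapped alignment can raise identity only so far above the gapless
  # value, so full DP is reserved for the border zone below the threshold;
  # sequences far below it can never clear id_threshold.
  dp_slack <- 0.05
  if (all_equal_len) {
    L <- lens[1L]
    qmat <- do.call(cbind, strsplit(seqs, ""))   # L x n char matrix
    cmat <- matrix("", nrow = L, ncol = 0L)
    for (i in seq_along(seqs)) {
      hit <- 0L
      k <- ncol(cmat)
      if (k > 0L) {
        hid <- (L - colSums(cmat != qmat[, i])) / L
        for (j in which(hid >= id_threshold - dp_slack)) {
          if (hid[j] >= id_threshold ||
              .identities_to(seqs[i], centroids[j]) >= id_threshold) {
            hit <- j
            break
          }
        }
      }
      if (hit == 0L) {
        centroids <- c(centroids, seqs[i])
        cmat <- cbind(cmat, qmat[, i])
        hit <- length(centroids)
      }
      assignment[i] <- hit
    }
  } else {
    for (i in seq_along(seqs)) {
      hit <- 0L
      if (length(centroids) > 0L) {
        ids <- .identities_to(seqs[i], centroids)
        ok <- which(ids >= id_threshold)
        if (length(ok) > 0L) hit <- ok[1L]
      }
      if (hit == 0L) {
        centroids <- c(centroids, seqs[i])
        hit <- length(centroids)
      }
      assignment[i] <- hit
    }
  }
  members <- uniques
  members$cluster <- assignment[match(members$seq, seqs)]
  members <- members[order(members$cluster, -members$count, members$seq),
                     c("cluster", "seq", "subpool_id", "count")]
  rownames(members) <- NULL
  structure(list(
    centroids = data.frame(cluster = seq_along(centroids),
                           centroid = centroids, stringsAsFactors = FALSE),
    members = members,
    domain_type = domain_type, id_threshold = id_threshold),
    class = "domain_clusters")
}

#' @export
print.domain_clusters <- function(x, ...) {
  cat(sprintf("domain_clusters: %d clusters, %d member sequences (%s, id >= %g)\n",
              nrow(x$centroids), length(unique(x$members$seq)),
              x$domain_type, x$id_threshold))
  invisible(x)
}

#' Filter clustered domain variants
#'
#' Applies three abundance/evidence filters in order: (i) member sequences
#' with total read count below \code{min_reads} are removed; (ii) member
#' sequences with total read count below \code{rel_frac} of the centroid
#' sequence's total read count are removed (the centroid itself is exempt);
#' (iii) clusters whose surviving members span fewer than \code{min_wells}
#' distinct subpools are removed, as they carry too little information for
#' co-occurrence inference.
#'
#' @param clusters A \code{domain_clusters} object.
#' @param min_reads Minimum total read count per member sequence (default 2).
#' @param rel_frac Minimum member/centroid read-count ratio (default 0.05).
#' @param min_wells Minimum number of distinct subpools per cluster
#'   (default 3).
#' @return A filtered \code{domain_clusters} object with a \code{"report"}
#'   attribute (counts removed by each rule).
#' @export
filter_clusters <- function(clusters, min_reads = 2L, rel_frac = 0.05,
                            min_wells = 3L) {
  stopifnot(inherits(clusters, "domain_clusters"))
  m <- clusters$members
  if (nrow(m) == 0L) return(clusters)
  seq_tot <- tapply(m$count, m$seq, sum)
  m$seq_total <- as.numeric(seq_tot[m$seq])
  is_centroid <- m$seq %in% clusters$centroids$centroid
  drop_i <- m$seq_total < min_reads
  cent_tot <- seq_tot[clusters$centroids$centroid]
  names(cent_tot) <- clusters$centroids$cluster
  m$cent_total <- as.numeric(cent_tot[as.character(m$cluster)])
  drop_ii <- !is_centroid & !drop_i & m$seq_total < rel_frac * m$cent_total
  keep <- !(drop_i | drop_ii)
  m2 <- m[keep, c("cluster", "seq", "subpool_id", "count")]
  wells <- tapply(m2$subpool_id, m2$cluster,
                  function(s) length(unique(s)))
  ok_clusters <- as.integer(names(wells)[wells >= min_wells])
  dropped_iii <- setdiff(unique(m2$cluster), ok_clusters)
  m3 <- m2[m2$cluster %in% ok_clusters, , drop = FALSE]
  rownames(m3) <- NULL
  out <- clusters
  out$members <- m3
  out$centroids <- clusters$centroids[clusters$centroids$cluster %in%
                                        ok_clusters, , drop = FALSE]
  attr(out, "report") <- data.frame(
    rule = c("min_reads", "rel_frac", "min_wells"),
    removed = c(sum(drop_i), sum(drop_ii),
                length(dropped_iii) +
                  length(setdiff(unique(m$cluster), unique(m2$cluster)))))
  out
}

#' Variant-by-subpool occurrence matrix
#'
#' The statistical substrate of the co-occurrence analysis: read counts of
#' each retained domain variant in each library subpool, with presence
#' defined as count > 0. Variants present in fewer than \code{min_wells}
#' subpools are dropped on construction, so every retained variant satisfies
#' the minimum-evidence requirement.
#'
#' @param counts An integer matrix or \code{Matrix::sparseMatrix} (variants
#'   as rows, subpools as columns), with dimnames.
#' @param variants A data.frame with columns \code{variant_id},
#'   \code{domain_type}, \code{centroid}, aligned to the rows of
#'   \code{counts}.
#' @param min_wells Minimum number of occupied subpools per variant
#'   (default 3).
#' @return An object of class \code{"occurrence_matrix"} with elements
#'   \code{counts} (sparse), \code{variants}, \code{subpools},
#'   \code{n_subpools}.
#' @export
occurrence_matrix <- function(counts, variants, min_wells = 3L) {
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  stopifnot(nrow(counts) == nrow(variants),
            all(c("variant_id", "domain_type", "centroid") %in%
                  names(variants)))
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id")
  if (is.null(colnames(counts)))
    stop("counts must have subpool column names")
  rownames(counts) <- variants$variant_id
  occ <- Matrix::rowSums(counts > 0)
  keep <- occ >= min_wells
  structure(list(counts = counts[keep, , drop = FALSE],
                 variants = variants[keep, , drop = FALSE],
                 subpools = colnames(counts),
                 n_subpools = ncol(counts)),
            class = "occurrence_matrix")
}

#' @export
print.occurrence_matrix <- function(x, ...) {
  cat(sprintf("occurrence_matrix: %d variants x %d subpools (%s)\n",
              nrow(x$counts), x$n_subpools,
              paste(unique(x$variants$domain_type), collapse = "+")))
  invisible(x)
}

#' Boolean presence matrix of an occurrence matrix
#'
#' @param x An \code{occurrence_matrix}.
#' @return A sparse logical matrix, variants x subpools.
#' @export
presence <- function(x) {
  stopifnot(inherits(x, "occurrence_matrix"))
  x$counts > 0
}

#' Build an occurrence matrix from filtered clusters
#'
#' @param clusters A filtered \code{domain_clusters} object.
#' @param subpools Character vector giving the full subpool universe
#'   (columns); subpools without reads appear as all-zero columns.
#' @param min_wells Passed to [occurrence_matrix()].
#' @return An \code{occurrence_matrix} with variant ids
#'   \code{<domain_type>_v<cluster>}.
#' @export
clusters_to_matrix <- function(clusters, subpools, min_wells = 3L) {
  stopifnot(inherits(clusters, "domain_clusters"))
  m <- clusters$members
  cl_ids <- clusters$centroids$cluster
  vid <- sprintf("%s_v%04d", clusters$domain_type, cl_ids)
  i <- match(m$cluster, cl_ids)
  j <- match(m$subpool_id, subpools)
  if (anyNA(j))
    stop("member subpool not in provided subpool universe")
  counts <- Matrix::sparseMatrix(i = i, j = j, x = m$count,
                                 dims = c(length(cl_ids), length(subpools)),
                                 dimnames = list(vid, subpools))
  variants <- data.frame(variant_id = vid,
                         domain_type = clusters$domain_type,
                         centroid = clusters$centroids$centroid,
                         stringsAsFactors = FALSE)
  occurrence_matrix(counts, variants, min_wells = min_wells)
}

#' Merge occurrence matrices from multiple primer systems
#'
#' Row-wise union of per-domain tables over a shared subpool universe, e.g.
#' to jointly analyse adenylation- and ketosynthase-domain amplicons from the
#' same library.
#'
#' @param tables A list of \code{occurrence_matrix} objects sharing the same
#'   subpool universe.
#' @return A single merged \code{occurrence_matrix}.
#' @export
merge_tables <- function(tables) {
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "occurrence_matrix")))
  universe <- tables[[1L]]$subpools
  for (t in tables[-1L]) {
    if (!setequal(t$subpools, universe) ||
        length(t$subpools) != length(universe))
      stop("dimension error: subpool universes differ")
  }
  counts <- do.call(rbind, lapply(tables, function(t)
    t$counts[, universe, drop = FALSE]))
  variants <- do.call(rbind, lapply(tables, `[[`, "variants"))
  if (anyDuplicated(variants$variant_id))
    stop("duplicate variant_id across tables; namespace by domain_type")
  occurrence_matrix(counts, variants, min_wells = 0L)
}

#' Write an occurrence matrix as TSV
#'
#' Rows are variants, columns are subpools, cells are read counts; variant
#' metadata (\code{domain_type}, \code{centroid}) occupy the leading columns.
#'
#' @param x An \code{occurrence_matrix}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_occurrence <- function(x, path) {
  stopifnot(inherits(x, "occurrence_matrix"))
  dense <- as.matrix(x$counts)
  out <- cbind(x$variants, as.data.frame(dense, optional = TRUE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an occurrence matrix written by [write_occurrence()]
#'
#' @param path Path to the TSV.
#' @param min_wells Passed to [occurrence_matrix()] (default 0: trust the
#'   file as already filtered).
#' @return An \code{occurrence_matrix}.
#' @export
read_occurrence <- function(path, min_wells = 0L) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  meta <- c("variant_id", "domain_type", "centroid")
  stopifnot(all(meta %in% names(tab)))
  counts <- as.matrix(tab[, setdiff(names(tab), meta), drop = FALSE])
  rownames(counts) <- tab$variant_id
  occurrence_matrix(counts, tab[, meta], min_wells = min_wells)
}

#' Cluster demultiplexed reads into a filtered occurrence matrix
#'
#' Convenience pipeline: dereplicate per subpool, cluster greedily at
#' \code{id_threshold}, apply the three variant filters and build the
#' occurrence matrix over the scheme's full subpool universe.
#'
#' @param reads data.frame with \code{subpool_id}, \code{seq} (trimmed reads).
#' @param subpools Character vector of all addressable subpool ids.
#' @param domain_type Domain label.
#' @param id_threshold Clustering identity threshold (default 0.95).
#' @param min_reads,rel_frac,min_wells Filter parameters, see
#'   [filter_clusters()].
#' @return An \code{occurrence_matrix}.
#' @export
build_variant_table <- function(reads, subpools, domain_type = "AD",
                                id_threshold = 0.95, min_reads = 2L,
                                rel_frac = 0.05, min_wells = 3L) {
  uniq <- dereplicate(reads)
  cl <- greedy_cluster(uniq, id_threshold = id_threshold,
                       domain_type = domain_type)
  fl <- filter_clusters(cl, min_reads = min_reads, rel_frac = rel_frac,
                        min_wells = min_wells)
  clusters_to_matrix(fl, subpools, min_wells = min_wells)
}
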